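treatment,hosts,beetles,wnodf,Q,h2_prime,niche_overlap_host,niche_overlap_beetle
Rc,22,21,8.14,0.47,0.71,0.21,0.06
Rg,28,22,14.03,0.62,0.72,0.25,0.06
Dc,47,40,7.42,0.61,0.70,0.16,0.05
Dg,42,34,6.72,0.56,0.64,0.16,0.04
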