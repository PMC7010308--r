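#!/usr/bin/env Rscript
# Compositional and interaction dissimilarity between every treatment pair:
# Baselga's Sorensen partition (turnover vs nestedness-resultant) for beetles,
# and the Poisot decomposition of link dissimilarity (rewiring vs species
# turnover).

suppressMessages(library(rearnet))

nets <- build_networks(read_records("results/data/records.csv"))

bs <- baselga_all_pairs(nets, "beetle")
write.csv(bs, "results/beta_species.csv", row.names = FALSE)
ib <- interaction_beta_all_pairs(nets)
write.csv(ib, "results/beta_interactions.csv", row.names = FALSE)

fmt <- function(s) sprintf("%s %.2f +/- %.2f", s$component, s$mean, s$sd)
cat("species composition:\n ", paste(fmt(attr(bs, "summary")), collapse = "\n  "), "\n")
cat("interactions:\n ", paste(fmt(attr(ib, "summary")), collapse = "\n  "), "\n")
cat("pairs dominated by rewiring (beta_OS > beta_ST):",
    sum(ib$beta_OS > ib$beta_ST), "of", nrow(ib), "\n")
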