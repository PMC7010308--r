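#!/usr/bin/env Rscript
# Generate the study-design synthetic rearing experiment (four treatments:
# rain/dry x canopy/ground) and write the record, trait and truth files the
# later stages read.  Magnitudes follow the motivating field design: regional
# pools of 65 host and 57 beetle species, ~1,300 emergences.

suppressMessages(library(rearnet))

seed <- 20260923L
ds <- generate_dataset(tdf_preset(seed = seed))
write_dataset(ds, "results/data")

nets <- build_networks(ds$records)
cat("simulated", sum(ds$records$count), "emergences over",
    length(unique(ds$records$beetle)), "beetle and",
    length(unique(ds$records$host)), "host species\n")
for (tr in names(nets))
  cat(sprintf("  %s: %d hosts x %d beetles (network size %d)\n", tr,
              nrow(nets[[tr]]), ncol(nets[[tr]]), network_size(nets, tr)))
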