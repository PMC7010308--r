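#!/usr/bin/env Rscript
# Species-level indices (degree, d', effective partners, species strength),
# Kruskal-Wallis comparisons across treatments, and the correlation PCA
# joining network roles to wood and body traits (loadings flagged at
# |r| >= 0.6).

suppressMessages(library(rearnet))

nets <- build_networks(read_records("results/data/records.csv"))
traits <- read_traits("results/data/traits.csv")

for (lv in c("beetle", "host")) {
  tab <- do.call(rbind, lapply(names(nets), function(tr)
    cbind(data.frame(treatment = tr), species_indices(nets[[tr]], lv))))
  write.csv(tab, sprintf("results/species_%s.csv", lv), row.names = FALSE)
  assign(paste0("idx_", lv), tab)
}

kw <- rbind(
  cbind(test = "d_prime_beetle",
        kruskal_wallis(split(idx_beetle$d_prime, idx_beetle$treatment))),
  cbind(test = "effective_partners_beetle",
        kruskal_wallis(split(idx_beetle$effective_partners,
                             idx_beetle$treatment))),
  cbind(test = "species_strength_host",
        kruskal_wallis(split(idx_host$species_strength, idx_host$treatment))))
write.csv(kw, "results/kruskal_wallis.csv", row.names = FALSE)
cat("treatment differences at species level:\n")
for (i in seq_len(nrow(kw)))
  cat(sprintf("  %s: H = %.2f, p = %.2f\n", kw$test[i], kw$H[i],
              kw$p_value[i]))

for (lv in c("beetle", "host")) {
  rows <- lapply(names(nets), function(tr) {
    p <- trait_pca(nets[[tr]], traits, lv)
    ld <- as.data.frame(p$loadings[, 1:2, drop = FALSE])
    data.frame(treatment = tr, variable = rownames(ld), ld,
               flagged_PC1 = p$flagged[, 1], flagged_PC2 = p$flagged[, 2],
               prop_PC1 = p$proportion[1], prop_PC2 = p$proportion[2],
               row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  write.csv(tab, sprintf("results/pca_%s.csv", lv), row.names = FALSE)
  cat(sprintf("%s PCA: first two components explain %.0f%% (mean)\n",
              lv, 100 * mean(tab$prop_PC1 + tab$prop_PC2)))
}
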