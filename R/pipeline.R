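#' Pipeline configuration
#'
#' @param records_path path to a rearing-records CSV, or `NULL` to generate
#'   synthetic data from `synthetic`.
#' @param traits_path optional trait CSV (required for the PCA stage when
#'   reading records from disk).
#' @param synthetic a [synthetic_config()] used when no records path is given
#'   (default [tdf_preset()]).
#' @param n_boot diversity bootstrap replicates (default 100).
#' @param n_rand null-model randomizations (default 1000).
#' @param n_trials modularity restarts for observed networks (default 20);
#'   null draws use a fast 5-restart mode.
#' @param p_threshold significance threshold for null-model p-values
#'   (default 0.01).
#' @param z_threshold modularity z-score threshold (default 2).
#' @param run_nulls,run_pca stage switches (default on).
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(records_path = NULL, traits_path = NULL,
                            synthetic = tdf_preset(), n_boot = 100L,
                            n_rand = 1000L, n_trials = 20L,
                            p_threshold = 0.01, z_threshold = 2,
                            run_nulls = TRUE, run_pca = TRUE,
                            seed = 1L, out_dir = "results") {
  stopifnot(n_boot >= 2, n_rand >= 1, n_trials >= 1,
            p_threshold > 0, p_threshold < 1)
  structure(list(records_path = records_path, traits_path = traits_path,
                 synthetic = synthetic, n_boot = as.integer(n_boot),
                 n_rand = as.integer(n_rand), n_trials = as.integer(n_trials),
                 p_threshold = p_threshold, z_threshold = z_threshold,
                 run_nulls = run_nulls, run_pca = run_pca,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Reads (or generates) rearing records, builds one network per treatment,
#' and emits: a diversity table (qD with bootstrap CIs, coverage and
#' significance letters), species and interaction beta-dissimilarity tables,
#' a per-treatment structure table with a cross-treatment mean +/- sample-SD
#' summary, species-level index tables, null-model reports, trait PCAs, and
#' a JSON manifest.  Every stage is seeded from the master seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with all tables; CSV/JSON files are written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("rearnet %s | seed %d | R %s", "0.1.0", config$seed,
       paste(R.version$major, R.version$minor, sep = "."))

  stage <- "input"
  res <- tryCatch({
    if (is.null(config$records_path)) {
      ds <- generate_dataset(config$synthetic)
      records <- ds$records
      traits <- ds$traits
      logf("input: synthetic (seed %d)", config$synthetic$seed)
    } else {
      records <- read_records(config$records_path)
      traits <- if (!is.null(config$traits_path))
        read_traits(config$traits_path) else NULL
      logf("input: %s", config$records_path)
    }

    stage <- "networks"
    nets <- build_networks(records)
    out <- list(networks = nets)

    stage <- "diversity"
    div <- do.call(rbind, lapply(c(0, 1, 2), function(q)
      diversity_profile(nets, q, n_boot = config$n_boot,
                        seed = derive_seed(config$seed, 10L + q))))
    out$diversity <- div
    write.csv2_safe(div, file.path(config$out_dir, "diversity.csv"))

    if (length(nets) >= 2L) {
      stage <- "beta"
      bs <- baselga_all_pairs(nets, "beetle")
      ib <- interaction_beta_all_pairs(nets)
      out$beta_species <- bs
      out$beta_interactions <- ib
      write.csv2_safe(bs, file.path(config$out_dir, "beta_species.csv"))
      write.csv2_safe(ib, file.path(config$out_dir, "beta_interactions.csv"))
    } else {
      warning("single treatment: beta stages skipped")
      logf("beta: skipped (single treatment)")
    }

    stage <- "structure"
    struct <- do.call(rbind, lapply(names(nets), function(tr)
      cbind(data.frame(treatment = tr, stringsAsFactors = FALSE),
            network_structure(nets[[tr]], n_trials = config$n_trials,
                              seed = derive_seed(config$seed, 20L)))))
    out$structure <- struct
    write.csv2_safe(struct, file.path(config$out_dir, "structure.csv"))

    stage <- "species_indices"
    for (lv in c("beetle", "host")) {
      tab <- do.call(rbind, lapply(names(nets), function(tr)
        cbind(data.frame(treatment = tr, stringsAsFactors = FALSE),
              species_indices(nets[[tr]], lv))))
      out[[paste0("species_", lv)]] <- tab
      write.csv2_safe(tab, file.path(config$out_dir,
                                     paste0("species_", lv, ".csv")))
    }

    stage <- "kruskal_wallis"
    if (length(nets) >= 2L) {
    kw <- rbind(
      cbind(test = "d_prime_beetle",
            kruskal_wallis(split(out$species_beetle$d_prime,
                                 out$species_beetle$treatment))),
      cbind(test = "effective_partners_beetle",
            kruskal_wallis(split(out$species_beetle$effective_partners,
                                 out$species_beetle$treatment))),
      cbind(test = "species_strength_host",
            kruskal_wallis(split(out$species_host$species_strength,
                                 out$species_host$treatment))))
    out$kruskal_wallis <- kw
    write.csv2_safe(kw, file.path(config$out_dir, "kruskal_wallis.csv"))
    }

    if (config$run_nulls) {
      stage <- "null_models"
      metrics <- c("wnodf", "h2_prime", "niche_overlap_beetle",
                   "niche_overlap_host", "modularity")
      nulls <- do.call(rbind, lapply(names(nets), function(tr)
        do.call(rbind, lapply(metrics, function(mt) {
          ne <- null_test(nets[[tr]], mt, n_rand = config$n_rand,
                          seed = derive_seed(config$seed, 30L),
                          n_trials = config$n_trials)
          data.frame(treatment = tr, metric = mt, observed = ne$observed,
                     null_mean = ne$null_mean, null_sd = ne$null_sd,
                     p = ne$p_value, z = ne$z_score,
                     significant = ne$significant, stringsAsFactors = FALSE)
        }))))
      out$null_report <- nulls
      write.csv2_safe(nulls, file.path(config$out_dir, "null_report.csv"))
    }

    if (config$run_pca && !is.null(traits)) {
      stage <- "pca"
      for (lv in c("beetle", "host")) {
        pcs <- lapply(names(nets), function(tr) {
          p <- trait_pca(nets[[tr]], traits, lv)
          ld <- as.data.frame(p$loadings[, 1:2, drop = FALSE])
          data.frame(treatment = tr, variable = rownames(ld), ld,
                     prop_PC1 = p$proportion[1], prop_PC2 = p$proportion[2],
                     row.names = NULL, stringsAsFactors = FALSE)
        })
        tab <- do.call(rbind, pcs)
        out[[paste0("pca_", lv)]] <- tab
        write.csv2_safe(tab, file.path(config$out_dir,
                                       paste0("pca_", lv, ".csv")))
      }
    }

    stage <- "summary"
    out$summary <- structure_summary(struct)
    write.csv2_safe(out$summary, file.path(config$out_dir, "summary.csv"))

    manifest <- list(seed = config$seed,
                     treatments = names(nets),
                     n_boot = config$n_boot, n_rand = config$n_rand,
                     n_trials = config$n_trials,
                     files = list.files(config$out_dir))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    logf("done: %d treatment networks", length(nets))
    out
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Cross-treatment summary (mean and sample SD) of structure metrics
#'
#' @param struct per-treatment structure table (as written by
#'   [run_pipeline()] or shaped like it, with columns `wnodf`, `Q`,
#'   `h2_prime`, `niche_overlap_beetle`, `niche_overlap_host`).
#' @return data frame: metric, mean, sd (sample SD, n - 1).
#' @export
structure_summary <- function(struct) {
  cols <- intersect(c("wnodf", "Q", "h2_prime",
                      "niche_overlap_beetle", "niche_overlap_host"),
                    names(struct))
  data.frame(metric = cols,
             mean = vapply(cols, function(cl) mean(struct[[cl]]), numeric(1)),
             sd = vapply(cols, function(cl) sd_sample(struct[[cl]]),
                         numeric(1)),
             row.names = NULL)
}

#' @noRd
write.csv2_safe <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
}
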