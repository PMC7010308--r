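#' Configuration for the synthetic rearing-experiment generator
#'
#' Describes a four-treatment rearing experiment with latent block (module)
#' structure, a nestedness gradient, and tunable beetle host-specialization.
#' Small `kappa` concentrates each beetle's Dirichlet-style host preference on
#' few hosts (specialists); large `kappa` approaches uniform use.  `rho` is
#' the expected fraction of a treatment's species pool shared with any other
#' treatment; pools are drawn from a common regional pool whose size is
#' `round(mean(n)/rho)` unless overridden.
#'
#' @param n_hosts,n_beetles named integer vectors (per treatment Rc, Rg, Dc,
#'   Dg) of host and beetle species counts.
#' @param total_emergences target total number of emerged individuals summed
#'   over treatments (split across treatments proportionally to beetle
#'   richness).
#' @param n_modules number of latent modules K shared by hosts and beetles.
#' @param kappa Dirichlet concentration of beetle host preferences (> 0).
#' @param gamma nestedness-gradient weight (>= 0); larger values concentrate
#'   emergences on low-rank ("popular") hosts.
#' @param module_boost multiplicative preference for hosts in a beetle's own
#'   module (>= 1; 1 disables block structure).
#' @param rho cross-treatment species retention in (0, 1]; expected shared
#'   fraction of a treatment's pool.
#' @param host_pool,beetle_pool optional explicit regional pool sizes
#'   (override the `rho`-derived pool size).
#' @param abundance_meanlog,abundance_sdlog lognormal parameters of latent
#'   beetle abundances.
#' @param module_persistence probability in \[0, 1\] that a species retained
#'   across treatments keeps its module label (below 1 induces rewiring).
#' @param overdispersion `NA` for Poisson counts (default); a positive
#'   negative-binomial size parameter switches on overdispersion.
#' @param pdd_degree_slope slope of the negative association between a host's
#'   realized degree and its decomposition rate.
#' @param seed integer seed; a fixed seed yields byte-identical datasets.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_hosts = c(Rc = 14L, Rg = 14L, Dc = 14L, Dg = 14L),
                             n_beetles = c(Rc = 12L, Rg = 12L, Dc = 12L, Dg = 12L),
                             total_emergences = 1300,
                             n_modules = 4L,
                             kappa = 0.3,
                             gamma = 0.5,
                             module_boost = 10,
                             rho = 0.5,
                             host_pool = NULL,
                             beetle_pool = NULL,
                             abundance_meanlog = 1,
                             abundance_sdlog = 1,
                             module_persistence = 1,
                             overdispersion = NA_real_,
                             pdd_degree_slope = 0.25,
                             seed = 1L) {
  n_hosts <- to_treatment_vector(n_hosts, "n_hosts")
  n_beetles <- to_treatment_vector(n_beetles, "n_beetles")
  if (any(n_hosts < 2L) || any(n_beetles < 2L))
    stop("each treatment needs at least 2 host and 2 beetle species")
  if (kappa <= 0) stop("kappa must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (module_boost < 1) stop("module_boost must be >= 1")
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  if (module_persistence < 0 || module_persistence > 1)
    stop("module_persistence must be in [0, 1]")
  if (total_emergences <= 0) stop("total_emergences must be positive")
  cfg <- list(n_hosts = n_hosts, n_beetles = n_beetles,
              total_emergences = total_emergences, n_modules = as.integer(n_modules),
              kappa = kappa, gamma = gamma, module_boost = module_boost,
              rho = rho, host_pool = host_pool, beetle_pool = beetle_pool,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              module_persistence = module_persistence,
              overdispersion = overdispersion,
              pdd_degree_slope = pdd_degree_slope,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' @noRd
to_treatment_vector <- function(x, name) {
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, 4L)
    if (length(x) != 4L) stop(name, " needs one value per treatment")
    names(x) <- TREATMENTS
  }
  if (!all(TREATMENTS %in% names(x)))
    stop(name, " must be named with treatments ", paste(TREATMENTS, collapse = ", "))
  stats::setNames(as.integer(x[TREATMENTS]), TREATMENTS)
}

#' Study-design preset mirroring the published experiment's magnitudes
#'
#' Treatment richness (22/28/47/42 host species, 21/22/40/34 beetle species),
#' a total of 1,323 emergences, and regional pools of 65 host and 57 beetle
#' species, with high specialization and modular block structure.
#'
#' @param seed integer seed.
#' @return a `synthetic_config`.
#' @export
tdf_preset <- function(seed = 1L) {
  synthetic_config(
    n_hosts = c(Rc = 22L, Rg = 28L, Dc = 47L, Dg = 42L),
    n_beetles = c(Rc = 21L, Rg = 22L, Dc = 40L, Dg = 34L),
    total_emergences = 1323,
    n_modules = 4L,
    kappa = 0.3,
    gamma = 0.5,
    module_boost = 10,
    rho = 0.5,
    host_pool = 65L,
    beetle_pool = 57L,
    seed = seed)
}

#' Generate a synthetic rearing-experiment dataset
#'
#' Per treatment: beetle abundances are lognormal; each beetle draws a
#' Dirichlet(kappa) host-preference vector, up-weighted by `module_boost` for
#' hosts in its own latent module and by `exp(-gamma * rank)` along a
#' nestedness gradient of host popularity; counts are Poisson (or negative
#' binomial) with rate proportional to abundance x preference.  Species pools
#' of the four treatments are drawn from a common regional pool so any two
#' treatments share an expected fraction `rho` of species; retained species
#' keep their module label with probability `module_persistence`.  Counts are
#' split multinomially over the four collection intervals (2, 4, 6, 8
#' months); downstream aggregation pools them.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (a `rearing_records` data frame), `traits`
#'   (a `trait_table`), and `truth` (latent module labels per treatment,
#'   abundances, and the generating parameters), for recovery tests.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pools <- with(config, {
    hp <- host_pool %||% pool_size(n_hosts, rho)
    bp <- beetle_pool %||% pool_size(n_beetles, rho)
    list(host = hp, beetle = bp)
  })
  if (pools$host < max(config$n_hosts))
    stop("infeasible retention: host pool (", pools$host,
         ") smaller than largest treatment (", max(config$n_hosts), ")")
  if (pools$beetle < max(config$n_beetles))
    stop("infeasible retention: beetle pool (", pools$beetle,
         ") smaller than largest treatment (", max(config$n_beetles), ")")

  host_names <- sprintf("host%03d", seq_len(pools$host))
  beetle_names <- sprintf("beetle%03d", seq_len(pools$beetle))

  set.seed(derive_seed(config$seed, 0L))
  K <- config$n_modules
  host_module0 <- sample(rep_len(seq_len(K), pools$host))
  beetle_module0 <- sample(rep_len(seq_len(K), pools$beetle))
  # global popularity ranks drive the nestedness gradient
  host_rank <- sample(seq_len(pools$host))

  # per-treatment emergence targets, proportional to beetle richness
  target <- config$total_emergences * config$n_beetles / sum(config$n_beetles)

  records <- list()
  truth_modules <- list()
  realized_degree <- setNames(numeric(pools$host), host_names)

  for (k in seq_along(TREATMENTS)) {
    tr <- TREATMENTS[k]
    set.seed(derive_seed(config$seed, k))
    hosts_idx <- sort(sample.int(pools$host, config$n_hosts[tr]))
    beetles_idx <- sort(sample.int(pools$beetle, config$n_beetles[tr]))

    hmod <- rewire_modules(host_module0[hosts_idx], K, config$module_persistence)
    bmod <- rewire_modules(beetle_module0[beetles_idx], K, config$module_persistence)

    nh <- length(hosts_idx); nb <- length(beetles_idx)
    lambda <- stats::rlnorm(nb, config$abundance_meanlog, config$abundance_sdlog)
    lambda <- lambda / sum(lambda) * target[tr]

    grad <- exp(-config$gamma * (rank(host_rank[hosts_idx]) - 1) / max(nh - 1, 1))
    A <- matrix(0L, nh, nb,
                dimnames = list(host_names[hosts_idx], beetle_names[beetles_idx]))
    for (b in seq_len(nb)) {
      w <- stats::rgamma(nh, shape = config$kappa, rate = 1)
      w[w < 1e-12] <- 1e-12
      w <- w * ifelse(hmod == bmod[b], config$module_boost, 1) * grad
      pref <- w / sum(w)
      mu <- lambda[b] * pref
      A[, b] <- if (is.na(config$overdispersion)) stats::rpois(nh, mu)
                else stats::rnbinom(nh, size = config$overdispersion, mu = mu)
    }

    realized_degree[rownames(A)] <- realized_degree[rownames(A)] + rowSums(A > 0)
    truth_modules[[tr]] <- list(hosts = setNames(hmod, rownames(A)),
                                beetles = setNames(bmod, colnames(A)),
                                lambda = setNames(lambda, colnames(A)))

    nz <- which(A > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      # split each cell's emergences across the four collection intervals
      splits <- apply(nz, 1L, function(ij)
        as.vector(stats::rmultinom(1L, A[ij[1], ij[2]], rep(0.25, 4))))
      iv <- c("2", "4", "6", "8")
      rec <- data.frame(
        treatment = tr,
        host = rep(rownames(A)[nz[, 1]], each = 4L),
        beetle = rep(colnames(A)[nz[, 2]], each = 4L),
        count = as.integer(splits),
        interval = rep(iv, nrow(nz)),
        stringsAsFactors = FALSE)
      records[[tr]] <- rec[rec$count > 0, , drop = FALSE]
    }
  }

  rec <- do.call(rbind, records)
  rownames(rec) <- NULL
  rec <- rearing_records(rec$treatment, rec$host, rec$beetle, rec$count,
                         rec$interval)

  set.seed(derive_seed(config$seed, 99L))
  wd <- stats::rlnorm(pools$host, log(0.6), 0.25)
  deg <- scale(realized_degree)[, 1]
  deg[!is.finite(deg)] <- 0
  pdd <- exp(log(0.08) - config$pdd_degree_slope * deg +
               stats::rnorm(pools$host, 0, 0.2))
  bsi <- stats::rlnorm(pools$beetle, log(35), 0.6)
  traits <- trait_table(data.frame(
    species = c(host_names, beetle_names),
    role = rep(c("host", "beetle"), c(pools$host, pools$beetle)),
    wood_density = c(wd, rep(NA_real_, pools$beetle)),
    pdd = c(pdd, rep(NA_real_, pools$beetle)),
    bsi = c(rep(NA_real_, pools$host), bsi),
    stringsAsFactors = FALSE))

  list(records = rec, traits = traits,
       truth = list(modules = truth_modules, kappa = config$kappa,
                    rho = config$rho, gamma = config$gamma,
                    pools = pools, seed = config$seed))
}

#' @noRd
pool_size <- function(n, rho) as.integer(round(mean(n) / rho))

#' @noRd
rewire_modules <- function(mod, K, persistence) {
  if (persistence >= 1) return(mod)
  flip <- stats::runif(length(mod)) > persistence
  mod[flip] <- sample.int(K, sum(flip), replace = TRUE)
  mod
}

#' Write a synthetic dataset to disk in the package's CSV dialects
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; writes `records.csv`, `traits.csv`,
#'   `truth.json`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_records(dataset$records, file.path(dir, "records.csv"))
  write_traits(dataset$traits, file.path(dir, "traits.csv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
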