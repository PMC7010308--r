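#' Baselga partition of Sorensen dissimilarity for a species-set pair
#'
#' With `a` shared species and `b`, `c` species unique to each side:
#' `beta_sor = (b+c)/(2a+b+c)` (total dissimilarity),
#' `beta_sim = min(b,c)/(a+min(b,c))` (turnover), and
#' `beta_sne = beta_sor - beta_sim` (nestedness-resultant component).
#'
#' @param s1,s2 character vectors of species labels (non-empty).
#' @return data frame row: a, b, c, beta_sor, beta_sim, beta_sne.
#' @examples
#' baselga_pair(c("a", "b", "c"), c("b", "c", "d"))
#' @export
baselga_pair <- function(s1, s2) {
  s1 <- unique(as.character(s1)); s2 <- unique(as.character(s2))
  if (length(s1) == 0 && length(s2) == 0) stop("both species sets are empty")
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2))
  c_ <- length(setdiff(s2, s1))
  sor <- if (a + b + c_ == 0) 0 else (b + c_) / (2 * a + b + c_)
  sim <- if (a + min(b, c_) == 0) 0 else min(b, c_) / (a + min(b, c_))
  data.frame(a = a, b = b, c = c_, beta_sor = sor, beta_sim = sim,
             beta_sne = sor - sim)
}

#' Baselga partition for every treatment pair
#'
#' A species occurs in a treatment iff it has at least one emergence there
#' (presence from the trimmed matrices).
#'
#' @param set a `treatment_network_set`.
#' @param level `"beetle"` (default) or `"host"`.
#' @return data frame with one row per unordered treatment pair plus
#'   attribute `summary` (mean and sample SD of each component).
#' @export
baselga_all_pairs <- function(set, level = c("beetle", "host")) {
  level <- match.arg(level)
  trs <- names(set)
  if (length(trs) < 2L) stop("need at least 2 treatments")
  pool <- lapply(set, function(A)
    if (level == "beetle") colnames(A) else rownames(A))
  out <- do.call(rbind, lapply(utils::combn(trs, 2, simplify = FALSE),
    function(pr) cbind(data.frame(treatment1 = pr[1], treatment2 = pr[2],
                                  stringsAsFactors = FALSE),
                       baselga_pair(pool[[pr[1]]], pool[[pr[2]]]))))
  attr(out, "summary") <- component_summary(
    out, c("beta_sor", "beta_sim", "beta_sne"))
  out
}

#' Link set of a network
#' @param A an `interaction_matrix`.
#' @return character vector of `"host||beetle"` keys for cells with a > 0.
#' @export
link_set <- function(A) {
  nz <- which(A > 0, arr.ind = TRUE)
  paste(rownames(A)[nz[, 1]], colnames(A)[nz[, 2]], sep = "||")
}

#' Interaction (network) dissimilarity decomposition
#'
#' Sorensen dissimilarity of the two binary link sets (`beta_WN`), the same
#' measure restricted to links among species present in both networks
#' (`beta_OS`, rewiring among shared species), and their difference
#' (`beta_ST`, the contribution of species turnover).  When the networks
#' share no species `beta_OS` is defined as 0 with a warning.
#'
#' @param N1,N2 `interaction_matrix` objects.
#' @return data frame row: beta_WN, beta_OS, beta_ST.
#' @export
network_dissimilarity <- function(N1, N2) {
  wn <- sorensen_links(link_set(N1), link_set(N2))
  sh <- shared_subweb_links(N1, N2)
  if (is.null(sh)) {
    warning("networks share no species at both levels; beta_OS set to 0")
    os <- 0
  } else if (length(sh$l1) == 0 && length(sh$l2) == 0) {
    os <- 0
  } else {
    os <- sorensen_links(sh$l1, sh$l2)
  }
  data.frame(beta_WN = wn, beta_OS = os, beta_ST = wn - os)
}

#' @noRd
sorensen_links <- function(l1, l2) {
  a <- length(intersect(l1, l2))
  b <- length(setdiff(l1, l2))
  c_ <- length(setdiff(l2, l1))
  if (2 * a + b + c_ == 0) return(0)
  (b + c_) / (2 * a + b + c_)
}

# links whose host AND beetle occur in both networks; NULL when no species
# is shared at either level
#' @noRd
shared_subweb_links <- function(N1, N2) {
  hosts <- intersect(rownames(N1), rownames(N2))
  beetles <- intersect(colnames(N1), colnames(N2))
  if (length(hosts) == 0 && length(beetles) == 0) return(NULL)
  restrict <- function(A) {
    l <- link_set(A)
    parts <- strsplit(l, "||", fixed = TRUE)
    keep <- vapply(parts, function(p) p[1] %in% hosts && p[2] %in% beetles,
                   logical(1))
    l[keep]
  }
  list(l1 = restrict(N1), l2 = restrict(N2))
}

#' Interaction dissimilarity for every treatment pair
#' @param set a `treatment_network_set`.
#' @return data frame, one row per unordered pair, with attribute `summary`
#'   (mean and sample SD per component).
#' @export
interaction_beta_all_pairs <- function(set) {
  trs <- names(set)
  if (length(trs) < 2L) stop("need at least 2 treatments")
  out <- do.call(rbind, lapply(utils::combn(trs, 2, simplify = FALSE),
    function(pr) cbind(data.frame(treatment1 = pr[1], treatment2 = pr[2],
                                  stringsAsFactors = FALSE),
                       network_dissimilarity(set[[pr[1]]], set[[pr[2]]]))))
  attr(out, "summary") <- component_summary(
    out, c("beta_WN", "beta_OS", "beta_ST"))
  out
}

#' @noRd
component_summary <- function(df, cols) {
  data.frame(component = cols,
             mean = vapply(cols, function(cl) mean(df[[cl]]), numeric(1)),
             sd = vapply(cols, function(cl) sd_sample(df[[cl]]), numeric(1)),
             row.names = NULL)
}
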