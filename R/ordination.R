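#' Correlation-matrix PCA with loading flags
#'
#' Standardizes the columns, eigen-decomposes their correlation matrix, and
#' reports loadings as variable-component correlations (eigenvector element
#' times the square root of the eigenvalue).  A variable is flagged as
#' related to a component when `|r| >= threshold` (default 0.6).  The sign of
#' each component is fixed so its largest-magnitude loading is positive.
#' Rows with missing values are dropped with a message.
#'
#' @param table numeric data frame or matrix (species x variables), at least
#'   3 rows and 2 columns; zero-variance variables are rejected.
#' @param threshold loading flag threshold (default 0.6).
#' @return list of class `pca_result`: `eigenvalues`, `proportion`,
#'   `loadings` (correlation matrix, variables x components), `flagged`
#'   (logical matrix), `scores` (species x components), `n_dropped`.
#' @export
pca_correlation <- function(table, threshold = 0.6) {
  X <- as.matrix(as.data.frame(table))
  if (!is.numeric(X)) stop("all variables must be numeric")
  keep <- stats::complete.cases(X)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("dropping ", n_dropped, " row(s) with missing values")
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 3L) stop("need at least 3 complete species rows")
  if (ncol(X) < 2L) stop("need at least 2 variables")
  v <- apply(X, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(X)[v == 0], collapse = ", "))
  Z <- scale(X)
  R <- stats::cor(X)
  e <- eigen(R, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  V <- e$vectors
  # deterministic orientation: largest |loading| positive per component
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  loadings <- V * rep(sqrt(lambda), each = nrow(V))
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_along(lambda)))
  scores <- Z %*% V
  colnames(scores) <- colnames(loadings)
  structure(list(eigenvalues = lambda,
                 proportion = lambda / sum(lambda),
                 loadings = loadings,
                 flagged = abs(loadings) >= threshold,
                 scores = scores,
                 n_dropped = n_dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", length(x$eigenvalues), "components\n")
  cat("proportion of variance:",
      paste(sprintf("%.3f", x$proportion), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Kruskal-Wallis rank test across treatments
#'
#' Thin wrapper over `stats::kruskal.test` (rank-based H with tie
#' correction; p from the chi-squared approximation on k - 1 degrees of
#' freedom).  When every value is identical across all groups the statistic
#' is 0 and p is 1.
#'
#' @param groups named list of numeric vectors (one per treatment).
#' @return data frame: H, p_value, df, and group sizes as attribute `sizes`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) == 0))
    stop("need at least 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L) {
    out <- data.frame(H = 0, p_value = 1, df = length(groups) - 1L)
  } else {
    kt <- stats::kruskal.test(x, g)
    out <- data.frame(H = unname(kt$statistic), p_value = kt$p.value,
                      df = unname(kt$parameter))
  }
  attr(out, "sizes") <- lengths(groups)
  out
}

#' Trait-network PCA for one treatment and trophic level
#'
#' Joins species-level network indices to the trait table and runs the
#' correlation PCA on the conventional variable set: beetles use degree, d',
#' effective partners and BSI; hosts use degree, d', species strength, wood
#' density (hardness) and PDD (degradation rate).
#'
#' @param A an `interaction_matrix`.
#' @param traits a `trait_table`.
#' @param level `"beetle"` or `"host"`.
#' @param threshold loading flag threshold.
#' @return a `pca_result` with the joined table as attribute `data`.
#' @export
trait_pca <- function(A, traits, level = c("beetle", "host"),
                      threshold = 0.6) {
  level <- match.arg(level)
  idx <- species_indices(A, level)
  tr <- traits[traits$role == level, , drop = FALSE]
  df <- merge(idx, tr, by = "species")
  vars <- if (level == "beetle")
    c("degree", "d_prime", "effective_partners", "bsi")
  else
    c("degree", "d_prime", "species_strength", "wood_density", "pdd")
  X <- df[, vars, drop = FALSE]
  rownames(X) <- df$species
  res <- pca_correlation(X, threshold = threshold)
  attr(res, "data") <- df
  res
}
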