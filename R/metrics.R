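#' Weighted NODF nestedness
#'
#' Rows and columns are sorted by decreasing marginal total (ties broken by
#' decreasing number of non-zero cells, then label).  For an ordered pair
#' (i above j) with strictly larger total, the pair score is 100 times the
#' fraction of j's non-zero cells whose count is positive but strictly
#' smaller than the corresponding cell of i; pairs with equal totals score 0.
#' WNODF is the mean over all row pairs and all column pairs: 0 (not nested)
#' to 100 (perfectly nested).
#'
#' @param A an `interaction_matrix` (or plain count matrix), at least 2 x 2.
#' @return WNODF in \[0, 100\].
#' @examples
#' wnodf(matrix(c(3, 2, 1, 2, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE,
#'              dimnames = list(paste0("h", 1:3), paste0("b", 1:3))))  # 100
#' @export
wnodf <- function(A) {
  A <- unclass(as.matrix(A))
  if (nrow(A) < 2L || ncol(A) < 2L)
    stop("WNODF needs at least 2 rows and 2 columns")
  axis_mean <- function(M) {
    tot <- rowSums(M)
    fill <- rowSums(M > 0)
    ord <- order(-tot, -fill, rownames(M) %||% seq_len(nrow(M)))
    M <- M[ord, , drop = FALSE]
    tot <- tot[ord]
    n <- nrow(M)
    scores <- numeric(0)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (tot[i] > tot[j]) {
        nzj <- M[j, ] > 0
        scores <- c(scores,
                    100 * sum(nzj & M[j, ] < M[i, ]) / sum(nzj))
      } else {
        scores <- c(scores, 0)
      }
    }
    scores
  }
  s <- c(axis_mean(A), axis_mean(t(A)))
  mean(s)
}

#' Barber bipartite modularity of a given partition
#'
#' `Q = (1/m) * sum_ij (a_ij - r_i c_j / m) * [g(host_i) == g(beetle_j)]`.
#'
#' @param A count matrix.
#' @param row_labels,col_labels integer module labels for hosts and beetles.
#' @return Q (at most (K-1)/K for K equal modules; 0 for a single module).
#' @export
barber_Q <- function(A, row_labels, col_labels) {
  A <- unclass(as.matrix(A))
  m <- sum(A)
  B <- A - outer(rowSums(A), colSums(A)) / m
  sum(B * outer(row_labels, col_labels, "==")) / m
}

#' Weighted bipartite modularity by label propagation
#'
#' Maximizes Barber's weighted bipartite modularity with a label-propagation
#' scheme: every host starts in its own module; beetles then hosts repeatedly
#' adopt the label with the largest modularity gain (ties to the smallest
#' label); an agglomerative phase merges module pairs while Q increases.  The
#' search restarts from `n_trials` seeded random initializations plus
#' constrained module-count starts, and the best Q found is returned.
#'
#' @param A an `interaction_matrix` or count matrix.
#' @param n_trials number of restarts (default 20).
#' @param seed integer seed.
#' @return list: `Q`, `row_labels`, `col_labels` (integer module ids).
#' @export
modularity_lp <- function(A, n_trials = 20L, seed = 1L) {
  A <- unclass(as.matrix(A))
  m <- sum(A)
  if (m <= 0) stop("empty matrix")
  nr <- nrow(A); nc <- ncol(A)
  B <- A - outer(rowSums(A), colSums(A)) / m

  set.seed(seed)
  best <- NULL
  # start 1: every host its own module; further starts: random k-label inits
  starts <- vector("list", max(1L, n_trials))
  starts[[1]] <- seq_len(nr)
  if (n_trials > 1L) {
    kmax <- max(2L, min(nr, nc))
    ks <- rep_len(2:kmax, n_trials - 1L)
    for (t in seq_len(n_trials - 1L))
      starts[[t + 1L]] <- sample.int(ks[t], nr, replace = TRUE)
  }
  for (init in starts) {
    res <- lp_one_trial(B, m, init)
    if (is.null(best) || res$Q > best$Q + 1e-12) best <- res
  }
  relab <- function(x) match(x, unique(c(best$row_labels, best$col_labels)))
  rl <- relab(best$row_labels)
  cl <- match(best$col_labels, unique(c(best$row_labels, best$col_labels)))
  list(Q = best$Q,
       row_labels = stats::setNames(rl, rownames(A)),
       col_labels = stats::setNames(cl, colnames(A)))
}

#' @noRd
lp_one_trial <- function(B, m, row_init, max_sweeps = 200L) {
  nr <- nrow(B); nc <- ncol(B)
  rl <- as.integer(row_init)
  # initial column labels: best response to the initial row labels
  cl <- integer(nc)
  for (j in seq_len(nc)) cl[j] <- best_label(B[, j], rl)
  q <- sum(B * outer(rl, cl, "==")) / m
  for (sweep in seq_len(max_sweeps)) {
    for (j in seq_len(nc)) cl[j] <- best_label(B[, j], rl)
    for (i in seq_len(nr)) rl[i] <- best_label(B[i, ], cl)
    qn <- sum(B * outer(rl, cl, "==")) / m
    if (qn - q < 1e-10) { q <- qn; break }
    q <- qn
  }
  # agglomerative phase: merge module pairs while Q increases
  repeat {
    labs <- sort(unique(c(rl, cl)))
    k <- length(labs)
    if (k < 2L) break
    # module-level matrix: G[u, v] = sum of B over (rows in u, cols in v)
    Ir <- outer(rl, labs, "==") * 1
    Ic <- outer(cl, labs, "==") * 1
    G <- t(Ir) %*% B %*% Ic
    gain <- G + t(G)
    diag(gain) <- -Inf
    bestgain <- max(gain)
    if (bestgain <= 1e-12) break
    ij <- which(gain == bestgain, arr.ind = TRUE)[1, ]
    u <- labs[ij[1]]; v <- labs[ij[2]]
    keep <- min(u, v); drop <- max(u, v)
    rl[rl == drop] <- keep
    cl[cl == drop] <- keep
    q <- q + bestgain / m
  }
  list(Q = sum(B * outer(rl, cl, "==")) / m, row_labels = rl, col_labels = cl)
}

# label maximizing the summed modularity contribution; ties -> smallest label
#' @noRd
best_label <- function(bvec, labels) {
  s <- rowsum(bvec, labels, reorder = TRUE)
  cand <- as.integer(rownames(s))
  cand[which.max(s)]
}

#' Network-level interaction specialization H2'
#'
#' Shannon entropy of the interaction proportions, standardized between the
#' maximum-entropy integer table under the observed marginals (H2max,
#' approximated by proportional apportionment of the independence table plus
#' local 2x2 improvement on small webs) and a greedy integer concentration
#' of the marginals (H2min, perfect specialization):
#' `H2' = (H2max - H2) / (H2max - H2min)`, clamped to \[0, 1\].  0 means
#' interactions follow partner availability; 1 means maximal partner
#' selectivity given the marginals.
#'
#' @param A an `interaction_matrix` or count matrix.
#' @return H2' in \[0, 1\].
#' @examples
#' h2_prime(matrix(c(2, 0, 0, 2), 2, 2))  # 1
#' h2_prime(matrix(c(1, 1, 1, 1), 2, 2))  # 0
#' @export
h2_prime <- function(A) {
  A <- unclass(as.matrix(A))
  m <- sum(A)
  if (m <= 0) stop("empty matrix")
  if (nrow(A) == 1L && ncol(A) == 1L) {
    warning("1x1 matrix has no degrees of freedom; H2' set to 0")
    return(0)
  }
  h2 <- shannon(A / m)
  ex <- h2_extremes(rowSums(A), colSums(A))
  if (ex$h2max - ex$h2min < 1e-12) {
    warning("degenerate marginals (H2max == H2min); H2' set to 0")
    return(0)
  }
  min(max((ex$h2max - h2) / (ex$h2max - ex$h2min), 0), 1)
}

# entropy extremes over integer tables with the given marginals; memoized
# because a null ensemble evaluates thousands of tables with one marginal set
.h2_cache <- new.env(parent = emptyenv())

#' @noRd
h2_extremes <- function(r, cs) {
  key <- paste(paste(r, collapse = ","), paste(cs, collapse = ","), sep = "|")
  hit <- .h2_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- sum(r)
  # small webs: exact entropy range by bounded exhaustive search over all
  # integer tables with these marginals
  exact <- if (length(r) * length(cs) <= 16 && m <= 40)
    entropy_range_exact(r, cs) else NULL
  if (!is.null(exact)) {
    out <- list(h2max = exact$max, h2min = exact$min)
  } else {
    small <- length(r) * length(cs) <= 64
    tmax <- h2max_table(r, cs)
    # two deterministic concentration heuristics; keep the lower entropy
    mins <- list(h2min_table(r, cs, best_fit = FALSE),
                 h2min_table(r, cs, best_fit = TRUE))
    if (small) {
      tmax <- improve_entropy(tmax, maximize = TRUE)
      mins <- lapply(mins, improve_entropy, maximize = FALSE)
    }
    hmins <- vapply(mins, function(t) shannon(t / m), numeric(1))
    out <- list(h2max = shannon(tmax / m), h2min = min(hmins))
  }
  if (length(ls(.h2_cache)) > 64) rm(list = ls(.h2_cache), envir = .h2_cache)
  .h2_cache[[key]] <- out
  out
}

# exact entropy range over all integer tables with the given marginals,
# by depth-first enumeration with a node budget (NULL when exceeded)
#' @noRd
entropy_range_exact <- function(r, cs, budget = 2e5) {
  nr <- length(r); nc <- length(cs); m <- sum(r)
  f <- function(a) if (a > 0) a * log(a) else 0
  lo <- Inf; hi <- -Inf
  nodes <- 0L
  overrun <- FALSE
  rec_row <- function(i, rem_cols, acc) {
    if (overrun) return(invisible())
    if (i > nr) {
      h <- log(m) - acc / m
      if (h < lo) lo <<- h
      if (h > hi) hi <<- h
      return(invisible())
    }
    rec_cell <- function(j, left, rem, acc2) {
      if (overrun) return(invisible())
      nodes <<- nodes + 1L
      if (nodes > budget) { overrun <<- TRUE; return(invisible()) }
      if (j == nc) {
        if (left <= rem[nc]) {
          rem[nc] <- rem[nc] - left
          rec_row(i + 1L, rem, acc2 + f(left))
        }
        return(invisible())
      }
      for (v in 0:min(left, rem[j])) {
        rem2 <- rem; rem2[j] <- rem2[j] - v
        rec_cell(j + 1L, left - v, rem2, acc2 + f(v))
      }
    }
    rec_cell(1L, r[i], rem_cols, acc)
  }
  rec_row(1L, as.numeric(cs), 0)
  if (overrun) return(NULL)
  list(min = lo, max = hi)
}

# integer apportionment of the independence table r c'/m: floor, then repair
# marginal deficits cell by cell at the largest fractional parts
#' @noRd
h2max_table <- function(r, cs) {
  m <- sum(r)
  E <- outer(as.numeric(r), as.numeric(cs)) / m
  A <- floor(E)
  F <- E - A
  repeat {
    dr <- r - rowSums(A)
    dc <- cs - colSums(A)
    if (sum(dr) == 0) break
    Fm <- F
    Fm[dr == 0, ] <- -Inf
    Fm[, dc == 0] <- -Inf
    ij <- which(Fm == max(Fm), arr.ind = TRUE)[1, ]
    A[ij[1], ij[2]] <- A[ij[1], ij[2]] + 1
    F[ij[1], ij[2]] <- F[ij[1], ij[2]] - 1   # discourage re-picking
  }
  A
}

# hill-climb the table entropy with 2x2 exchange moves (small webs only);
# entropy order is equivalent to minimizing sum a*log(a)
#' @noRd
improve_entropy <- function(A, maximize) {
  f <- function(a) ifelse(a > 0, a * log(a), 0)
  n <- nrow(A); k <- ncol(A)
  if (n < 2 || k < 2) return(A)
  sgn <- if (maximize) 1 else -1   # maximize entropy == minimize sum f
  repeat {
    improved <- FALSE
    for (i1 in 1:(n - 1)) for (i2 in (i1 + 1):n)
      for (j1 in 1:(k - 1)) for (j2 in (j1 + 1):k) {
        dmax <- min(A[i1, j2], A[i2, j1])
        dmin <- -min(A[i1, j1], A[i2, j2])
        if (dmax == 0 && dmin == 0) next
        for (d in setdiff(seq.int(dmin, dmax), 0L)) {
          a <- A[i1, j1] + d; b <- A[i1, j2] - d
          cc <- A[i2, j1] - d; dd <- A[i2, j2] + d
          if (min(a, b, cc, dd) < 0) next
          delta <- f(a) + f(b) + f(cc) + f(dd) -
            (f(A[i1, j1]) + f(A[i1, j2]) + f(A[i2, j1]) + f(A[i2, j2]))
          if (sgn * delta < -1e-12) {
            A[i1, j1] <- a; A[i1, j2] <- b
            A[i2, j1] <- cc; A[i2, j2] <- dd
            improved <- TRUE
          }
        }
      }
    if (!improved) break
  }
  A
}

# greedy integer concentration: repeatedly pair the largest remaining row
# total with either the largest remaining column total or (best_fit) the
# column whose remaining total is closest to it, favouring exact fits
#' @noRd
h2min_table <- function(r, cs, best_fit = FALSE) {
  M <- matrix(0, length(r), length(cs))
  r <- as.numeric(r); cs <- as.numeric(cs)
  while (sum(r) > 0) {
    i <- which.max(r)
    j <- if (best_fit) {
      cand <- which(cs > 0)
      cand[which.min(abs(cs[cand] - r[i]))]
    } else which.max(cs)
    x <- min(r[i], cs[j])
    M[i, j] <- M[i, j] + x
    r[i] <- r[i] - x; cs[j] <- cs[j] - x
  }
  M
}

#' Horn's niche overlap, averaged over species pairs of one trophic level
#'
#' For each unordered pair of species at the level, Horn's index on their
#' normalized interaction-frequency vectors `p`, `q`:
#' `R = [sum (p+q) log(p+q) - sum p log p - sum q log q] / (2 log 2)`,
#' 0 for disjoint partner use, 1 for identical use.  The network value is the
#' unweighted mean over all pairs.
#'
#' @param A an `interaction_matrix` or count matrix.
#' @param level `"beetle"` (columns; default) or `"host"` (rows).
#' @return mean pairwise overlap in \[0, 1\].
#' @export
niche_overlap <- function(A, level = c("beetle", "host")) {
  level <- match.arg(level)
  A <- unclass(as.matrix(A))
  V <- if (level == "beetle") t(A) else A
  if (nrow(V) < 2L) stop("need at least 2 species at the level")
  P <- V / rowSums(V)
  n <- nrow(P)
  tot <- 0; np <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    tot <- tot + horn_pair(P[i, ], P[j, ])
    np <- np + 1L
  }
  tot / np
}

#' @noRd
horn_pair <- function(p, q) {
  s <- p + q
  num <- sum(s[s > 0] * log(s[s > 0])) -
    sum(p[p > 0] * log(p[p > 0])) - sum(q[q > 0] * log(q[q > 0]))
  val <- num / (2 * log(2))
  min(max(val, 0), 1)
}

#' Species-level indices
#'
#' For every species of one trophic level: `degree` (number of partners),
#' `effective_partners` (exponential of the Shannon entropy of its
#' interaction frequencies), `species_strength` (sum over its partners of the
#' partner's proportional dependence on it), and the standardized
#' Kullback-Leibler specialization `d'`: `d = sum_j p_j log(p_j / q_j)` with
#' `p` the species' usage proportions and `q` partner availability (partner
#' marginal totals / m), scaled by `d_max` from concentrating the species'
#' integer total onto the lowest-availability partners (exhaustive over
#' allocations for totals <= 8, greedy otherwise) and `d_min = 0`, then
#' clamped to \[0, 1\].
#'
#' @param A an `interaction_matrix` or count matrix.
#' @param level `"beetle"` (columns; default) or `"host"` (rows).
#' @return data frame: species, level, degree, d_prime, effective_partners,
#'   species_strength.
#' @export
species_indices <- function(A, level = c("beetle", "host")) {
  level <- match.arg(level)
  A <- unclass(as.matrix(A))
  m <- sum(A)
  V <- if (level == "beetle") t(A) else A          # species x partners
  avail <- colSums(V) / m                          # partner availability q_j
  dep <- V / rep(colSums(V), each = nrow(V))       # partner dependence on s
  out <- lapply(seq_len(nrow(V)), function(s) {
    x <- V[s, ]
    p <- x / sum(x)
    nz <- p > 0
    d <- sum(p[nz] * log(p[nz] / avail[nz]))
    dmax <- d_max_value(sum(x), avail)
    data.frame(species = rownames(V)[s], level = level,
               degree = sum(nz),
               d_prime = if (dmax > 0) min(max(d / dmax, 0), 1) else 0,
               effective_partners = exp(shannon(p)),
               species_strength = sum(dep[s, ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# maximal KL divergence achievable by an integer allocation of `total`
# individuals across partners with availabilities `q`
#' @noRd
d_max_value <- function(total, q) {
  if (total <= 8) {
    # exhaustive over allocations concentrated on the few least-available
    # partners (an optimum never spreads over more than `total` partners)
    ord <- order(q)
    k <- min(length(q), total)
    qs <- q[ord[seq_len(k)]]
    best <- 0
    alloc <- function(rem, idx, cur) {
      if (idx == length(qs)) {
        cur[idx] <- rem
        p <- cur / total
        nz <- p > 0
        best <<- max(best, sum(p[nz] * log(p[nz] / qs[nz])))
        return(invisible())
      }
      for (v in rem:0) { cur[idx] <- v; alloc(rem - v, idx + 1L, cur) }
    }
    alloc(total, 1L, numeric(length(qs)))
    best
  } else {
    log(1 / min(q))   # all individuals on the least-available partner
  }
}

#' Whole-network structure summary
#'
#' @param A an `interaction_matrix`.
#' @param n_trials modularity restarts.
#' @param seed integer seed.
#' @return one-row data frame: hosts, beetles, network_size, emergences,
#'   wnodf, Q, h2_prime, niche_overlap_beetle, niche_overlap_host.
#' @export
network_structure <- function(A, n_trials = 20L, seed = 1L) {
  mod <- modularity_lp(A, n_trials = n_trials, seed = seed)
  data.frame(hosts = nrow(A), beetles = ncol(A),
             network_size = nrow(A) + ncol(A), emergences = sum(A),
             wnodf = wnodf(A), Q = mod$Q, h2_prime = h2_prime(A),
             niche_overlap_beetle = niche_overlap(A, "beetle"),
             niche_overlap_host = niche_overlap(A, "host"))
}
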