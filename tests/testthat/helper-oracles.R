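# Independent oracles and fixture generators used across the suite.
# Each oracle is a deliberately naive, separate computation path from the
# package implementation it checks.

# random labelled count matrix with no all-zero row or column
rand_count_matrix <- function(nr, nc, max_count = 9, p_zero = 0.4) {
  repeat {
    A <- matrix(ifelse(stats::runif(nr * nc) < p_zero, 0L,
                       sample.int(max_count, nr * nc, replace = TRUE)),
                nr, nc)
    if (all(rowSums(A) > 0) && all(colSums(A) > 0)) break
  }
  dimnames(A) <- list(sprintf("h%02d", seq_len(nr)),
                      sprintf("b%02d", seq_len(nc)))
  A
}

# naive WNODF: explicit decreasing-fill pair enumeration on both axes
oracle_wnodf <- function(A) {
  pair_scores <- function(M) {
    tot <- rowSums(M)
    ord <- order(tot, decreasing = TRUE)
    M <- M[ord, , drop = FALSE]; tot <- tot[ord]
    out <- c()
    for (i in seq_len(nrow(M) - 1)) {
      for (j in (i + 1):nrow(M)) {
        if (tot[i] <= tot[j]) { out <- c(out, 0); next }
        below <- 0; fillj <- 0
        for (k in seq_len(ncol(M))) {
          if (M[j, k] > 0) {
            fillj <- fillj + 1
            if (M[j, k] < M[i, k]) below <- below + 1
          }
        }
        out <- c(out, 100 * below / fillj)
      }
    }
    out
  }
  mean(c(pair_scores(A), pair_scores(t(A))))
}

# all non-negative integer tables with the given marginals (small cases)
enumerate_tables <- function(r, cs) {
  nr <- length(r); nc <- length(cs)
  res <- list()
  fill_row <- function(tab, i, rem_cols) {
    if (i > nr) {
      if (all(rem_cols == 0)) res[[length(res) + 1L]] <<- tab
      return(invisible())
    }
    # enumerate compositions of r[i] across nc cells bounded by rem_cols
    comp <- function(left, j, row) {
      if (j == nc) {
        if (left <= rem_cols[nc]) {
          row[nc] <- left
          tab[i, ] <- row
          fill_row(tab, i + 1L, rem_cols - row)
        }
        return(invisible())
      }
      for (v in 0:min(left, rem_cols[j])) {
        row[j] <- v
        comp(left - v, j + 1L, row)
      }
    }
    comp(r[i], 1L, integer(nc))
  }
  fill_row(matrix(0L, nr, nc), 1L, cs)
  res
}

entropy_tab <- function(M) { p <- M / sum(M); p <- p[p > 0]; -sum(p * log(p)) }

# H2' standardized by exhaustive enumeration of the integer-table entropy
# range under the observed marginals
oracle_h2_prime <- function(A) {
  tabs <- enumerate_tables(rowSums(A), colSums(A))
  ent <- vapply(tabs, entropy_tab, numeric(1))
  h2 <- entropy_tab(A)
  if (max(ent) - min(ent) < 1e-12) return(0)
  min(max((max(ent) - h2) / (max(ent) - min(ent)), 0), 1)
}

# all set partitions of n items as restricted-growth label vectors
all_set_partitions <- function(n) {
  res <- list()
  grow <- function(labels, next_max) {
    k <- length(labels)
    if (k == n) { res[[length(res) + 1L]] <<- labels; return(invisible()) }
    for (l in seq_len(next_max)) grow(c(labels, l), max(next_max, l + 1L))
  }
  grow(integer(0), 1L)
  res
}

# best Barber Q over every partition of the rows+columns node set
oracle_best_Q <- function(A) {
  nr <- nrow(A); nc <- ncol(A); m <- sum(A)
  B <- A - outer(rowSums(A), colSums(A)) / m
  best <- -Inf
  for (p in all_set_partitions(nr + nc)) {
    rl <- p[seq_len(nr)]; cl <- p[nr + seq_len(nc)]
    q <- sum(B * outer(rl, cl, "==")) / m
    if (q > best) best <- q
  }
  best
}

# Horn overlap of two usage vectors via the Jensen-Shannon form:
# R = 1 - [2 H(mix) - H(p) - H(q)] / (2 log 2)
oracle_horn_mean <- function(A, level) {
  V <- if (level == "beetle") t(A) else A
  P <- V / rowSums(V)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  vals <- c()
  for (i in seq_len(nrow(P) - 1)) for (j in (i + 1):nrow(P)) {
    mix <- (P[i, ] + P[j, ]) / 2
    vals <- c(vals, 1 - (2 * H(mix) - H(P[i, ]) - H(P[j, ])) / (2 * log(2)))
  }
  mean(vals)
}

# tiny record fixture builder
records_fixture <- function(treatment, host, beetle, count) {
  rearing_records(treatment, host, beetle, count)
}
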