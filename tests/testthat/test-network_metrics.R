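test_that("WNODF matches hand-enumerated cases", {
  perfect <- matrix(c(3, 2, 1, 2, 1, 0, 1, 0, 0), 3, 3, byrow = TRUE,
                    dimnames = list(paste0("h", 1:3), paste0("b", 1:3)))
  expect_equal(wnodf(perfect), 100)
  flat <- matrix(1, 2, 2, dimnames = list(c("h1", "h2"), c("b1", "b2")))
  expect_equal(wnodf(flat), 0)   # equal marginal totals score 0
  expect_error(wnodf(matrix(1:3, 1, 3)), "at least 2")
})

test_that("WNODF equals the brute-force pair enumeration oracle", {
  set.seed(61)
  for (i in 1:50) {
    A <- rand_count_matrix(sample(2:5, 1), sample(2:5, 1))
    expect_equal(wnodf(A), oracle_wnodf(A), tolerance = 1e-12)
  }
})

test_that("WNODF is invariant under row/column permutation", {
  set.seed(71)
  for (i in 1:20) {
    A <- rand_count_matrix(5, 5)
    B <- A[sample(5), sample(5)]
    expect_equal(wnodf(A), wnodf(B))
  }
})

test_that("Barber Q matches closed forms on block matrices", {
  d <- matrix(c(5, 0, 0, 5), 2, 2,
              dimnames = list(c("h1", "h2"), c("b1", "b2")))
  expect_equal(barber_Q(d, 1:2, 1:2), 0.5)
  expect_equal(barber_Q(d, c(1, 1), c(1, 1)), 0)  # single module telescopes
  res <- modularity_lp(d, n_trials = 5, seed = 1)
  expect_equal(res$Q, 0.5)
  for (K in 2:4) {
    blocks <- kronecker(diag(K), matrix(3, 1, 1))
    dimnames(blocks) <- list(paste0("h", 1:K), paste0("b", 1:K))
    expect_equal(modularity_lp(blocks, n_trials = 10, seed = 2)$Q,
                 (K - 1) / K, tolerance = 1e-10)
  }
})

test_that("label propagation attains the exhaustive-partition optimum", {
  set.seed(81)
  for (i in 1:25) {
    nr <- sample(2:3, 1); nc <- sample(2:3, 1)
    A <- rand_count_matrix(nr, nc, max_count = 3, p_zero = 0.5)
    got <- modularity_lp(A, n_trials = 12, seed = i)
    expect_gte(got$Q, oracle_best_Q(A) - 1e-9)
    expect_equal(got$Q,
                 barber_Q(A, got$row_labels, got$col_labels))
  }
})

test_that("H2' hits its analytic anchors", {
  expect_equal(h2_prime(matrix(c(2, 0, 0, 2), 2, 2)), 1)
  expect_equal(h2_prime(matrix(1, 2, 2)), 0)
  # independence-proportional tables carry no specialization signal
  ind <- outer(c(2, 4), c(3, 3))
  expect_equal(h2_prime(ind), 0)
  expect_warning(h2_prime(matrix(5, 1, 1)), "H2'")
})

test_that("H2' stays within 0.05 of the exhaustive-enumeration oracle", {
  set.seed(91)
  n_done <- 0
  while (n_done < 20) {
    A <- rand_count_matrix(3, 3, max_count = 3, p_zero = 0.45)
    if (sum(A) > 12) next
    expect_equal(h2_prime(A), oracle_h2_prime(A), tolerance = 0.05)
    n_done <- n_done + 1
  }
})

test_that("Horn overlap matches pairwise anchors and the JSD oracle", {
  same <- matrix(c(2, 2, 4, 4), 2, 2, byrow = TRUE,
                 dimnames = list(c("h1", "h2"), c("b1", "b2")))
  expect_equal(niche_overlap(same, "host"), 1)   # identical usage profiles
  disj <- matrix(c(3, 0, 0, 5), 2, 2,
                 dimnames = list(c("h1", "h2"), c("b1", "b2")))
  expect_equal(niche_overlap(disj, "host"), 0)
  set.seed(101)
  for (i in 1:25) {
    A <- rand_count_matrix(sample(3:5, 1), sample(3:5, 1))
    for (lv in c("host", "beetle"))
      expect_equal(niche_overlap(A, lv), oracle_horn_mean(A, lv),
                   tolerance = 1e-10)
  }
})

test_that("species indices match their definitions", {
  A <- matrix(c(3, 3, 3, 1, 0, 2), 2, 3, byrow = TRUE,
              dimnames = list(c("h1", "h2"), c("b1", "b2", "b3")))
  idx <- species_indices(A, "host")
  h1 <- idx[idx$species == "h1", ]
  expect_equal(h1$degree, 3L)
  expect_equal(h1$effective_partners, 3)
  row13 <- species_indices(matrix(c(1, 3, 2, 2), 2, 2, byrow = TRUE,
    dimnames = list(c("hA", "hB"), c("b1", "b2"))), "host")
  expect_equal(row13$effective_partners[1],
               exp(-(0.25 * log(0.25) + 0.75 * log(0.75))))
  expect_equal(row13$effective_partners[1], 1.7548, tolerance = 1e-4)

  sq <- matrix(2, 2, 2, dimnames = list(c("h1", "h2"), c("b1", "b2")))
  st <- species_indices(sq, "host")
  expect_equal(st$species_strength, c(1, 1))
})

test_that("species-index invariants hold on random networks", {
  set.seed(111)
  for (i in 1:20) {
    A <- rand_count_matrix(sample(3:6, 1), sample(3:6, 1))
    for (lv in c("host", "beetle")) {
      idx <- species_indices(A, lv)
      expect_true(all(idx$effective_partners <= idx$degree + 1e-9))
      expect_true(all(idx$effective_partners >= 1 - 1e-9))
      expect_true(all(idx$d_prime >= 0 & idx$d_prime <= 1))
      npartners <- if (lv == "host") ncol(A) else nrow(A)
      expect_equal(sum(idx$species_strength), npartners)
      expect_true(all(idx$species_strength <= npartners + 1e-9))
    }
  }
})

test_that("d' is zero for availability-proportional use and one at the greedy max", {
  # every host uses beetles proportionally to their availability
  A <- outer(c(4, 8), c(3, 6, 3))
  dimnames(A) <- list(c("h1", "h2"), c("b1", "b2", "b3"))
  idx <- species_indices(A, "host")
  expect_equal(idx$d_prime, c(0, 0))
  # a species concentrated fully on the rarest partner maxes out
  B <- matrix(c(0, 0, 2, 9, 6, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("h1", "h2"), c("b1", "b2", "b3")))
  idx <- species_indices(B, "host")
  expect_equal(idx$d_prime[1], 1)
})
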