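test_that("Baselga partition reproduces hand counts", {
  p <- baselga_pair(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(c(p$beta_sor, p$beta_sim, p$beta_sne), c(1/3, 1/3, 0))
  p <- baselga_pair(c("a", "b", "c", "d"), c("c", "d", "e"))
  expect_equal(p$beta_sor, 3/7, tolerance = 1e-10)
  expect_equal(p$beta_sim, 1/3, tolerance = 1e-10)
  expect_equal(p$beta_sne, 3/7 - 1/3, tolerance = 1e-10)
  ident <- baselga_pair(letters[1:5], letters[1:5])
  expect_equal(c(ident$beta_sor, ident$beta_sim, ident$beta_sne), c(0, 0, 0))
})

test_that("Baselga components are additive, bounded and symmetric", {
  set.seed(31)
  for (i in 1:200) {
    s1 <- sample(letters, sample(1:15, 1))
    s2 <- sample(letters, sample(1:15, 1))
    p <- baselga_pair(s1, s2)
    q <- baselga_pair(s2, s1)
    expect_equal(p$beta_sor, p$beta_sim + p$beta_sne)
    expect_true(all(c(p$beta_sor, p$beta_sim, p$beta_sne) >= -1e-12))
    expect_true(p$beta_sor <= 1 + 1e-12)
    expect_equal(p[c("beta_sor", "beta_sim", "beta_sne")],
                 q[c("beta_sor", "beta_sim", "beta_sne")])
  }
})

test_that("nested and disjoint pools hit the partition's edge cases", {
  nested <- baselga_pair(letters[1:3], letters[1:8])
  expect_equal(nested$beta_sim, 0)
  expect_equal(nested$beta_sne, nested$beta_sor)
  disjoint <- baselga_pair(letters[1:4], letters[10:14])
  expect_equal(disjoint$beta_sor, 1)
  expect_equal(disjoint$beta_sim, 1)
})

test_that("four treatments yield six pairs with a sample-SD summary", {
  ds <- generate_dataset(synthetic_config(seed = 12L))
  nets <- build_networks(ds$records)
  bp <- baselga_all_pairs(nets, "beetle")
  expect_equal(nrow(bp), 6L)
  s <- attr(bp, "summary")
  expect_equal(s$mean[s$component == "beta_sor"], mean(bp$beta_sor))
  expect_equal(s$sd[s$component == "beta_sor"], sd(bp$beta_sor))
})

test_that("network dissimilarity separates rewiring from turnover", {
  N1 <- interaction_matrix(matrix(c(1, 0, 0, 1), 2, 2,
    dimnames = list(c("A", "B"), c("x", "y"))))
  N2 <- interaction_matrix(matrix(c(1, 0, 0, 1), 2, 2,
    dimnames = list(c("A", "B"), c("x", "z"))))
  d <- network_dissimilarity(N1, N2)
  expect_equal(c(d$beta_WN, d$beta_OS, d$beta_ST), c(0.5, 0, 0.5))

  ident <- network_dissimilarity(N1, N1)
  expect_equal(c(ident$beta_WN, ident$beta_OS, ident$beta_ST), c(0, 0, 0))

  # same species on both sides, links swapped: all dissimilarity is rewiring
  M1 <- interaction_matrix(matrix(c(2, 0, 0, 2), 2, 2,
    dimnames = list(c("A", "B"), c("x", "y"))))
  M2 <- interaction_matrix(matrix(c(0, 2, 2, 0), 2, 2,
    dimnames = list(c("A", "B"), c("x", "y"))))
  d <- network_dissimilarity(M1, M2)
  expect_equal(d$beta_ST, 0)
  expect_equal(d$beta_WN, d$beta_OS)
})

test_that("beta_WN decomposes exactly and is count-magnitude invariant", {
  set.seed(41)
  for (i in 1:60) {
    A1 <- interaction_matrix(rand_count_matrix(sample(3:6, 1), sample(3:6, 1)))
    A2 <- interaction_matrix(rand_count_matrix(sample(3:6, 1), sample(3:6, 1)))
    d <- suppressWarnings(network_dissimilarity(A1, A2))
    expect_equal(d$beta_WN, d$beta_OS + d$beta_ST)
    expect_lte(d$beta_OS, d$beta_WN + 1e-12)
    # scaling all counts leaves the binary decomposition unchanged
    d3 <- suppressWarnings(
      network_dissimilarity(interaction_matrix(unclass(A1)[,] * 5L), A2))
    expect_equal(d, d3)
  }
})

test_that("deleting a shared link cannot decrease whole-network dissimilarity", {
  set.seed(51)
  for (i in 1:20) {
    A1 <- interaction_matrix(rand_count_matrix(4, 4, p_zero = 0.2))
    A2 <- interaction_matrix(unclass(A1)[,])
    shared <- which(A2 > 0, arr.ind = TRUE)
    k <- shared[sample(nrow(shared), 1), ]
    M <- unclass(A2)[,]
    M[k[1], k[2]] <- 0L
    if (any(rowSums(M) == 0) || any(colSums(M) == 0)) next
    before <- network_dissimilarity(A1, A2)$beta_WN
    after <- network_dissimilarity(A1, interaction_matrix(M))$beta_WN
    expect_gte(after, before)
  }
})

test_that("no shared species yields beta_OS = 0 with a warning", {
  N1 <- interaction_matrix(matrix(2, 1, 1, dimnames = list("A", "x")))
  N2 <- interaction_matrix(matrix(2, 1, 1, dimnames = list("B", "y")))
  expect_warning(d <- network_dissimilarity(N1, N2), "share no species")
  expect_equal(d$beta_OS, 0)
  expect_equal(d$beta_ST, d$beta_WN)
  expect_equal(d$beta_WN, 1)
})

test_that("full retention with ample sampling leaves little turnover signal", {
  ds <- generate_dataset(synthetic_config(
    rho = 1, n_hosts = 10L, n_beetles = 10L, total_emergences = 4000,
    module_persistence = 0.5, seed = 6L))
  nets <- build_networks(ds$records)
  ib <- interaction_beta_all_pairs(nets)
  expect_equal(nrow(ib), 6L)
  expect_lt(mean(ib$beta_ST), 0.15)
  expect_gt(mean(ib$beta_OS), mean(ib$beta_ST))
})
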