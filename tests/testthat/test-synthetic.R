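test_that("a fixed seed reproduces the dataset byte for byte", {
  a <- generate_dataset(synthetic_config(seed = 42L))
  b <- generate_dataset(synthetic_config(seed = 42L))
  expect_identical(a$records, b$records)
  expect_identical(a$traits, b$traits)
  c <- generate_dataset(synthetic_config(seed = 43L))
  expect_false(identical(a$records, c$records))
})

test_that("study-design preset matches the field experiment's magnitudes", {
  cfg <- tdf_preset(seed = 5L)
  expect_equal(unname(cfg$n_hosts), c(22L, 28L, 47L, 42L))
  expect_equal(unname(cfg$n_beetles), c(21L, 22L, 40L, 34L))
  expect_equal(cfg$beetle_pool, 57L)
  expect_equal(cfg$host_pool, 65L)
  # realized sizes and totals within 20% of their targets (trimming can only
  # shrink a treatment's realized richness)
  totals <- sapply(1:5, function(s) {
    ds <- generate_dataset(tdf_preset(seed = s))
    nets <- build_networks(ds$records)
    c(sum(ds$records$count),
      sapply(names(nets), function(tr) network_size(nets, tr)))
  })
  expect_gt(mean(totals[1, ]), 1323 * 0.8)
  expect_lt(mean(totals[1, ]), 1323 * 1.2)
  target_sizes <- c(Rc = 43, Rg = 50, Dc = 87, Dg = 76)
  for (tr in names(target_sizes)) {
    expect_gt(mean(totals[tr, ]), target_sizes[tr] * 0.8)
    expect_lt(mean(totals[tr, ]), target_sizes[tr] * 1.2)
  }
})

test_that("specialization limits behave as the preference model predicts", {
  # near-one-host-per-beetle: H2' close to 1
  ds <- generate_dataset(synthetic_config(
    kappa = 0.01, n_modules = 10L, module_boost = 50, gamma = 0,
    n_hosts = 10L, n_beetles = 10L, total_emergences = 1000, seed = 2L))
  h_spec <- mean(sapply(build_networks(ds$records), h2_prime))
  expect_gt(h_spec, 0.8)
  # near-uniform preferences: H2' near its null (low) expectation
  ds <- generate_dataset(synthetic_config(
    kappa = 50, module_boost = 1, gamma = 0,
    n_hosts = 10L, n_beetles = 10L, total_emergences = 1000, seed = 2L))
  h_gen <- mean(sapply(build_networks(ds$records), h2_prime))
  expect_lt(h_gen, 0.2)
  expect_gt(h_spec, h_gen)
})

test_that("infeasible species retention is rejected", {
  cfg <- synthetic_config(n_hosts = c(Rc = 10L, Rg = 10L, Dc = 40L, Dg = 10L),
                          rho = 1)
  expect_error(generate_dataset(cfg), "infeasible retention")
})

test_that("the retention knob rho lowers cross-treatment turnover", {
  sims <- sapply(c(0.3, 0.9), function(rho) {
    mean(sapply(1:8, function(s) {
      ds <- generate_dataset(synthetic_config(
        rho = rho, n_hosts = 12L, n_beetles = 12L,
        total_emergences = 900, seed = s))
      bp <- baselga_all_pairs(build_networks(ds$records), "beetle")
      mean(bp$beta_sim)
    }))
  })
  expect_gt(sims[1], sims[2])
})

test_that("interval splits pool back to the per-cell counts", {
  ds <- generate_dataset(synthetic_config(seed = 9L))
  expect_true(all(ds$records$interval %in% c("2", "4", "6", "8")))
  pooled <- build_networks(ds$records)
  agg <- stats::aggregate(count ~ treatment, data = ds$records, FUN = sum)
  for (tr in names(pooled))
    expect_equal(grand_total(pooled[[tr]]),
                 agg$count[agg$treatment == tr])
})

test_that("truth sidecar exposes the latent structure", {
  ds <- generate_dataset(synthetic_config(seed = 4L))
  expect_named(ds$truth$modules, c("Rc", "Rg", "Dc", "Dg"))
  expect_equal(ds$truth$kappa, 0.3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("records.csv", "traits.csv", "truth.json")))))
  r2 <- read_records(file.path(dir, "records.csv"))
  expect_equal(nrow(r2), nrow(ds$records))
})
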