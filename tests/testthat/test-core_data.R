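test_that("records aggregate by summing repeated keys", {
  r <- rearing_records(c("Rc", "Rc"), c("hostA", "hostA"),
                       c("bugX", "bugX"), c(2, 3))
  nets <- build_networks(r)
  expect_equal(dim(nets$Rc), c(1L, 1L))
  expect_equal(unname(nets$Rc[1, 1]), 5L)
  expect_equal(grand_total(nets$Rc), 5L)
})

test_that("network size is host richness plus beetle richness", {
  hosts <- sprintf("h%02d", 1:22)
  beetles <- sprintf("b%02d", 1:21)
  r <- rearing_records(rep("Rc", 22 + 21),
                       c(hosts, rep(hosts[1], 21)),
                       c(rep(beetles[1], 22), beetles),
                       rep(1L, 43))
  nets <- build_networks(r)
  expect_equal(network_size(nets, "Rc"), 43L)
  expect_equal(nrow(nets$Rc), 22L)
  expect_equal(ncol(nets$Rc), 21L)
})

test_that("trimming removes zero marginals without touching the total", {
  r <- rearing_records(rep("Dg", 3), c("hA", "hB", "hC"),
                       c("b1", "b2", "b3"), c(4, 0, 2))
  nets <- build_networks(r)
  expect_false("hB" %in% rownames(nets$Dg))
  expect_false("b2" %in% colnames(nets$Dg))
  expect_equal(grand_total(nets$Dg), 6L)
})

test_that("grand total equals record sum and labels sort lexicographically", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    r <- rearing_records(sample(c("Rc", "Rg", "Dc", "Dg"), n, replace = TRUE),
                         sample(sprintf("h%d", 1:6), n, replace = TRUE),
                         sample(sprintf("b%d", 1:5), n, replace = TRUE),
                         sample(0:6, n, replace = TRUE))
    totals <- tapply(r$count, r$treatment, sum)
    nets <- tryCatch(build_networks(r), error = function(e) NULL)
    if (is.null(nets)) next   # a treatment with all-zero counts
    for (tr in names(nets)) {
      expect_equal(grand_total(nets[[tr]]), unname(totals[tr]))
      expect_equal(rownames(nets[[tr]]), sort(rownames(nets[[tr]])))
      expect_equal(colnames(nets[[tr]]), sort(colnames(nets[[tr]])))
    }
  }
})

test_that("validation rejects malformed records", {
  expect_error(rearing_records("Rc", "h", "b", -1), "non-negative")
  expect_error(rearing_records("Rc", "h", "b", 1.5), "whole numbers")
  expect_error(rearing_records("Xx", "h", "b", 1), "treatment")
  expect_error(rearing_records("Rc", "", "b", 1), "non-empty")
  r <- rearing_records("Rc", "h", "b", 0)
  expect_error(build_networks(r), "Rc")
})

test_that("matrix CSV round-trips labels and counts", {
  set.seed(3)
  A <- interaction_matrix(rand_count_matrix(5, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix(A, path)
  B <- read_matrix(path)
  expect_identical(unclass(A)[,], unclass(B)[,])
})

test_that("record and trait readers enforce their headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("treatment,host,beetle,count,site",
               "Rc,hA,bX,2,s1", "Rg,hB,bY,3,s2"), path)
  expect_warning(r <- read_records(path), "site")
  expect_equal(nrow(r), 2L)
  writeLines(c("treatment,host,count", "Rc,hA,2"), path)
  expect_error(read_records(path), "beetle")

  writeLines(c("species,role,wood_density,pdd,bsi",
               "t1,host,0.6,0.1,", "i1,beetle,,,30"), path)
  tt <- read_traits(path)
  expect_s3_class(tt, "trait_table")
  writeLines(c("species,role,wood_density,pdd,bsi",
               "i1,beetle,0.6,,30"), path)
  expect_error(read_traits(path), "wood_density")
})

test_that("records round-trip through CSV", {
  r <- rearing_records(c("Rc", "Dg"), c("hA", "hB"), c("bX", "bY"),
                       c(2, 3), c("2", NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(r, path)
  r2 <- read_records(path)
  expect_equal(as.data.frame(r2), as.data.frame(r))
})
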