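test_that("relative difference is plain ratio arithmetic", {
  expect_equal(relative_difference(1.12, 1.00), 12)
  expect_equal(relative_difference(0.9, 1.2), -25)
  expect_equal(relative_difference(c(3, 7.7, 0.4), c(3, 7.7, 0.4)),
               c(0, 0, 0))
  expect_error(relative_difference(1, 0), "positive")
  expect_error(relative_difference(1, -2), "positive")
})

test_that("normalization factor: mean ratio, SEM with n-1, stratification", {
  rec <- make_record(sv = c(1.0, 1.1, 1.2), wkp = 1.0)
  nf <- normalization_factor(list(rec))
  expect_equal(nf$nf, 1.1)
  expect_equal(nf$sem, 0.1 / sqrt(3))
  expect_equal(nf$n, 3L)

  # identical ratios: degenerate spread
  same <- make_record(sv = rep(1.3 * 2.5, 4), wkp = 2.5)
  nf2 <- normalization_factor(list(same))
  expect_equal(nf2$nf, 1.3)
  expect_equal(nf2$sem, 0)

  expect_error(normalization_factor(list(make_record(1.1, 1.0))), "at least 2")

  # per-stratum table keeps conditions separate
  recs <- list(make_record(c(1.1, 1.1), 1.0, volume = 2, filter = 0),
               make_record(c(1.4, 1.4), 1.0, volume = 0.6, filter = 0))
  tab <- normalization_factor(recs, by = "stratum")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$nf[tab$sv_volume_ml == 2], 1.1)
  expect_equal(tab$nf[tab$sv_volume_ml == 0.6], 1.4)
})

test_that("normalization removes the in-sample bias exactly", {
  rec <- make_record(sv = c(2.24), wkp = 1.0)
  norm <- normalize_records(list(rec), 1.12)
  expect_equal(norm[[1]]$sv_doses_gy, 2.0)
  expect_equal(norm[[1]]$wkp_dose_gy, 1.0)   # WKP untouched

  expect_identical(normalize_records(list(rec), 1)[[1]], rec)
  expect_error(normalize_records(list(rec), 0), "nf")

  set.seed(21)
  recs <- make_sim_records(12, noise_params(0.12, 0.07, bias = 1.2))
  nf1 <- normalization_factor(recs)$nf
  renorm <- normalize_records(recs, nf1)
  expect_equal(normalization_factor(renorm)$nf, 1)
  # and the mean RD at k = 1 is zero to floating point
  expect_lt(abs(rd_bias(renorm, k = 1)), 1e-10)
  # normalize_by_stratum does the same per condition
  expect_lt(abs(rd_bias(normalize_by_stratum(recs), k = 1)), 1e-10)
})

test_that("rd_pool enumerates subsets deterministically", {
  rec <- make_record(sv = c(1.0, 1.2), wkp = 1.0)
  rd1 <- rd_pool(list(rec), k = 1)
  expect_equal(rd1$rd_percent, c(0, 20))
  expect_equal(rd1$subset_index, 1:2)

  # k = m: single subset, RD of the full mean
  rdm <- rd_pool(list(rec), k = 2)
  expect_equal(nrow(rdm), 1L)
  expect_equal(rdm$rd_percent, 10)

  # C(5, 2) = 10 subsets per kidney
  rec5 <- make_record(sv = c(1, 2, 3, 4, 5), wkp = 3)
  expect_equal(nrow(rd_pool(list(rec5), k = 2)), 10L)

  # pooled RDs are invariant (as a set) to SV ordering within a record
  shuf <- make_record(sv = c(4, 1, 5, 3, 2), wkp = 3)
  for (k in 1:3)
    expect_equal(sort(rd_pool(list(rec5), k)$rd_percent),
                 sort(rd_pool(list(shuf), k)$rd_percent))

  expect_error(rd_pool(list(rec), k = 3), "exceeds")
  expect_error(rd_pool(list(rec), k = 1, subset_policy = "random"),
               "n_subsets")

  # random policy: requested number of distinct subsets
  set.seed(5)
  rnd <- rd_pool(list(rec5), k = 2, subset_policy = "random", n_subsets = 4)
  expect_equal(nrow(rnd), 4L)
  expect_true(all(rnd$rd_percent %in% rd_pool(list(rec5), 2)$rd_percent))
})

test_that("precision curve matches a brute-force enumeration oracle", {
  # zero-noise: curve of exact zeros
  flat <- list(make_record(rep(2.5, 5), 2.5), make_record(rep(4, 5), 4))
  cv0 <- precision_curve(flat, 1:5)
  expect_equal(cv0$u_percent, rep(0, 5))

  # hand fixture, 3 kidneys x 3 SVs, k = 1..3: nested-loop oracle
  recs <- list(make_record(c(1.0, 1.2, 0.9), 1.0),
               make_record(c(2.0, 2.2, 1.8), 2.0),
               make_record(c(3.3, 2.7, 3.0), 3.0))
  cv <- precision_curve(recs, 1:3)
  for (k in 1:3)
    expect_equal(cv$u_percent[cv$k == k], oracle_curve_sd(recs, k),
                 tolerance = 1e-12)
  expect_equal(cv$n_samples, c(9L, 9L, 3L))
  cond <- attr(cv, "condition")
  expect_equal(unname(cond[["sv_volume_ml"]]), 2)

  expect_error(precision_curve(list(recs[[1]]), k_values = 3), "fewer than 2")
})

test_that("empirical precision curve approaches the analytic 10/sqrt(k)", {
  set.seed(31)
  recs <- make_sim_records(4000, noise_params(0.10, 0))
  cv <- precision_curve(recs, 1:5)
  for (k in 1:5) {
    expected <- 10 / sqrt(k)
    # conservative SE using the kidney count, not the (dependent) pooled n
    expect_lt(abs(cv$u_percent[cv$k == k] - expected),
              3 * expected / sqrt(2 * 4000))
  }
})

test_that("unnormalized RD bias matches the second-order expansion", {
  set.seed(41)
  recs <- make_sim_records(30000, noise_params(0.10, 0.07), m_sv = 1)
  b <- rd_bias(recs, k = 1)
  # se of the mean RD ~ sd/sqrt(n)
  se <- analytic_rd_sd(noise_params(0.10, 0.07), 1) / sqrt(30000)
  expect_lt(abs(b - 0.49), 3 * se)
})

test_that("rank-sum comparison: exact enumeration, ties, invariances", {
  # identical groups: no separation, maximal p
  same <- compare_precision(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$p_value, 1)

  # maximal separation at n = 3 per group: exact two-sided p = 2/20
  sep <- compare_precision(c(1, 2, 3), c(101, 102, 103))
  expect_equal(sep$p_value, 0.1)
  expect_match(sep$method, "exact")

  # order within groups is irrelevant
  a <- c(7.05, 7.27, 7.51, 7.33); b <- c(6.81, 6.92, 7.35, 6.95)
  expect_equal(compare_precision(a, b)$p_value,
               compare_precision(sample(a), sample(b))$p_value)

  # agrees with the independent exact implementation when there are no ties
  w <- wilcox.test(a, b, exact = TRUE)
  expect_equal(compare_precision(a, b)$p_value, w$p.value)

  # large groups switch to the midrank normal approximation
  set.seed(51)
  big_a <- rnorm(25, 10); big_b <- rnorm(25, 10.5)
  res <- compare_precision(big_a, big_b)
  expect_match(res$method, "normal")
  w2 <- wilcox.test(big_a, big_b, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, w2$p.value, tolerance = 1e-8)

  expect_error(compare_precision(c(1, 2), c(3, 4, 5)), "at least 3")
})
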