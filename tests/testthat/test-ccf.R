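test_that("expected_vaf evaluates the purity/copy-number mapping exactly", {
  expect_equal(expected_vaf(1, 1, 2, 2), 0.5)
  expect_equal(expected_vaf(0, 0.7, 2, 2), 0)
  expect_equal(expected_vaf(0.5, 0.8, 2, 2), 0.2)
  # strictly increasing in ccf and purity (diploid)
  g <- seq(0, 1, by = 0.01)
  expect_true(all(diff(expected_vaf(g, 0.6, 2, 2)) > 0))
  p <- seq(0.1, 1, by = 0.01)
  expect_true(all(diff(expected_vaf(0.5, p, 2, 2)) > 0))
})

test_that("mutation copy number inverts the VAF mapping", {
  expect_equal(mutation_copy_number(0.5, 1, 2, 2), 1)
  expect_equal(mutation_copy_number(0, 0.5, 2, 2), 0)
  expect_equal(mutation_copy_number(0.25, 0.5, 3, 2), 1.25)
  # round-trip at multiplicity 1 over a full parameter sweep
  for (p in seq(0.3, 1, by = 0.1)) {
    for (cnt in 1:4) {
      ccf <- seq(0.01, 1, by = 0.01)
      back <- mutation_copy_number(expected_vaf(ccf, p, cnt, 2), p, cnt, 2)
      expect_equal(back, ccf, tolerance = 1e-12)
    }
  }
})

test_that("the grid posterior matches a brute-force normalized likelihood", {
  withr::local_seed(101)
  for (i in 1:50) {
    n <- sample(20:500, 1)
    p <- runif(1, 0.3, 1)
    cnt <- sample(1:4, 1)
    x <- rbinom(1, n, runif(1, 0.05, min(0.95, ref_vaf(1, p, cnt, 2))))
    post <- ccf_posterior(x, n, p, cnt, 2)
    expect_equal(post$probs, ref_posterior(x, n, p, cnt, 2), tolerance = 1e-9)
    expect_equal(sum(post$probs), 1, tolerance = 1e-9)
    expect_true(post$ci_low <= post$point_estimate)
    expect_true(post$point_estimate <= post$ci_high)
  }
})

test_that("posterior point estimates and clonality calls behave at depth 100", {
  clonal <- ccf_posterior(50, 100, purity = 1)
  expect_equal(clonal$point_estimate, 1.00)
  expect_true(clonal$clonal)
  sub <- ccf_posterior(10, 100, purity = 1)
  expect_equal(sub$point_estimate, 0.20)
  expect_false(sub$clonal)
})

test_that("multiplicity inference picks the maximum-likelihood copy count", {
  m <- infer_multiplicity(48, 100, purity = 0.5)
  expect_equal(m$multiplicity, 2L)
  expect_equal(m$ccf, 0.96)
  expect_true(m$clonal)

  m2 <- infer_multiplicity(25, 100, purity = 0.5)
  expect_equal(m2$multiplicity, 1L)
  expect_equal(m2$ccf, 1.0)
  expect_true(m2$clonal)

  m3 <- infer_multiplicity(10, 100, purity = 1)
  expect_equal(m3$multiplicity, 1L)
  expect_equal(m3$ccf, 0.2)
  expect_false(m3$clonal)

  # raw CCF above 1 is retained while the capped value classifies
  m4 <- infer_multiplicity(60, 100, purity = 1)
  expect_gt(m4$ccf_raw, 1)
  expect_equal(m4$ccf, 1)
})

test_that("purity estimation is the mean diploid marker VAF", {
  m <- make_muts(c(100L, 100L, 100L), total_depth = 100L)
  expect_equal(estimate_purity(m)$p, 1.0)
  m2 <- make_muts(c(60L, 80L), total_depth = 100L)
  est <- estimate_purity(m2)
  expect_equal(est$p, 0.7)
  expect_equal(est$n_support, 2L)
  # markers outside diploid segments are excluded; none left is an error
  seg <- tibble::tibble(chrom = "chr1", start = 1L, end = 10L, cn_t = 4, cn_n = 2)
  expect_error(estimate_purity(m2, seg), "purity explicitly")
})

test_that("purity is recovered within 0.02 from 200 markers at depth 100", {
  withr::local_seed(7)
  for (p_true in c(0.5, 0.7, 0.9)) {
    x <- rbinom(200, 100, p_true)
    m <- make_muts(x, total_depth = 100L)
    expect_lt(abs(estimate_purity(m)$p - p_true), 0.02)
  }
})

test_that("clonality calibration matches the exact binomial oracle", {
  # Exact per-count classification under both rules, weighted by the
  # binomial sampling distribution, reproduced by simulation.
  depth <- 200L
  p <- 0.8
  v1 <- ref_vaf(1, p, 2, 2)
  calls_for <- function(x) {
    post <- ccf_posterior(x, depth, p)
    thr <- infer_multiplicity(x, depth, p)
    c(ci = post$clonal, thr = thr$clonal)
  }
  exact <- vapply(0:depth, calls_for, logical(2))
  p_ci <- sum(dbinom(0:depth, depth, v1) * exact["ci", ])
  p_thr <- sum(dbinom(0:depth, depth, v1) * exact["thr", ])

  withr::local_seed(11)
  x <- rbinom(400, depth, v1)
  calls <- ccf_calls(make_muts(x, total_depth = depth, pos = seq_along(x)),
                     purity = p)
  expect_lt(abs(mean(calls$clonal_ci) - p_ci), 0.06)
  expect_lt(abs(mean(calls$clonal_threshold) - p_thr), 0.06)

  # true CCF 0.3 is essentially always called subclonal by both rules
  x3 <- rbinom(400, depth, ref_vaf(0.3, p, 2, 2))
  calls3 <- ccf_calls(make_muts(x3, total_depth = depth, pos = seq_along(x3)),
                      purity = p)
  expect_gte(mean(!calls3$clonal_ci), 0.95)
  expect_gte(mean(!calls3$clonal_threshold), 0.95)
})

test_that("ccf_calls handles copy-number lookup, defaults and cn_t = 0", {
  seg <- tibble::tibble(chrom = "chr1", start = c(1L, 101L), end = c(100L, 200L),
                        cn_t = c(2, 0), cn_n = 2)
  m <- make_muts(c(30L, 30L, 30L), pos = c(50, 150, 500))
  expect_warning(
    expect_message(calls <- ccf_calls(m, purity = 1, segments = seg),
                   "cn_t = 0"),
    "no copy-number segment")
  expect_equal(nrow(calls), 2)              # the cn_t = 0 mutation is dropped
  expect_equal(attr(calls, "dropped_cn0"), 1)
  expect_equal(calls$cn_t, c(2, 2))         # default diploid for the orphan
})
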