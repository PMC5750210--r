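sim_dp_input <- function(seed, n, clones, purity = 1, depth = 100) {
  cfg <- sim_config(seed = seed, n_mutations = n, purity = purity,
                    depth_mean = depth, clones = clones)
  s <- simulate_sample(cfg)
  x <- s$mutations
  x$cn_t <- s$truth$cn_t
  x$cn_n <- s$truth$cn_n
  list(x = x, truth = s$truth, purity = purity)
}

test_that("planted clonal and subclonal clusters are recovered", {
  inp <- sim_dp_input(5, 300, tibble::tibble(ccf = c(1, 0.4),
                                             fraction = c(0.6, 0.4)))
  fit <- fit_dp(inp$x, purity = inp$purity)
  cl <- tidy(fit)
  expect_equal(nrow(cl), 2)
  expect_lt(max(abs(cl$location - c(0.4, 1.0))), 0.05)
  expect_lt(max(abs(cl$weight - c(0.4, 0.6))), 0.08)
  expect_equal(sum(cl$weight), 1, tolerance = 1e-9)
  # clusters are reported sorted by location: relabeling-safe output
  expect_true(all(diff(cl$location) > 0))
})

test_that("a homogeneous sample collapses to one clonal cluster", {
  inp <- sim_dp_input(3, 200, tibble::tibble(ccf = 1, fraction = 1))
  cl <- tidy(fit_dp(inp$x, purity = 1))
  expect_equal(nrow(cl), 1)
  expect_gte(cl$location, 0.95)
  expect_equal(cl$size, 200L)
})

test_that("the fit is deterministic given data and seed", {
  inp <- sim_dp_input(9, 100, tibble::tibble(ccf = c(1, 0.5),
                                             fraction = c(0.5, 0.5)))
  f1 <- fit_dp(inp$x, purity = 1, iterations = 800, burnin = 400, seed = 23)
  f2 <- fit_dp(inp$x, purity = 1, iterations = 800, burnin = 400, seed = 23)
  expect_identical(f1$clusters, f2$clusters)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(f1$samples$loc_idx, f2$samples$loc_idx)
})

test_that("with one mutation the location posterior matches the grid posterior", {
  x <- make_muts(30L, total_depth = 100L)
  fit <- fit_dp(x, purity = 1, iterations = 5500, burnin = 500, seed = 41)
  # location of the assigned component at each kept iteration
  kept <- nrow(fit$samples$weights)
  occ <- fit$samples$occupancy
  loc <- fit$samples$loc_idx[, , 1]
  drawn <- vapply(seq_len(kept), function(t) {
    k <- which(occ[t, ] == 1)[1]
    loc[t, k]
  }, numeric(1))
  emp_cdf <- cumsum(tabulate(drawn, 100)) / kept
  post <- ccf_posterior(30, 100, purity = 1)
  expect_lt(max(abs(emp_cdf - cumsum(post$probs))), 0.05)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_dp(make_muts(integer(0)), purity = 1), "at least one")
  bad <- make_muts(10L)
  bad$alt_reads <- NA_integer_
  expect_error(fit_dp(bad, purity = 1), "non-finite")
})

test_that("2D fits concentrate density on the diagonal for identical samples", {
  cfg <- sim_config(seed = 7, n_mutations = 300, purity = 1,
                    clones = tibble::tibble(ccf = c(1, 0.4),
                                            fraction = c(0.6, 0.4)))
  pr <- simulate_pair(cfg, editing = list(fraction = 0, target = "subclonal"))
  b <- pr$mutations[pr$mutations$sample_id == "baseline", ]
  d <- pr$mutations[pr$mutations$sample_id == "derived", ]
  fit <- fit_dp(pair_counts(b, d), purity = 1)
  dg <- density_grid(fit)
  expect_equal(sum(dg$density), 1, tolerance = 1e-6)
  diag_mass <- sum(dg$density[abs(dg$ccf_1 - dg$ccf_2) <= 0.1])
  expect_gte(diag_mass, 0.8)
})

test_that("a subclone absent from one sample shows off the diagonal", {
  cfg <- sim_config(seed = 13, n_mutations = 300, purity = 1,
                    clones = tibble::tibble(ccf = c(1, 0.4),
                                            fraction = c(0.6, 0.4)),
                    consequence_probs = c(missense = 1),
                    neoantigen_fraction = 1, expressed_fraction = 1)
  # every subclonal mutation is neoantigenic and removed: the whole
  # CCF-0.4 clone is missing from the derived sample
  pr <- simulate_pair(cfg, editing = list(fraction = 1, target = "subclonal"))
  b <- pr$mutations[pr$mutations$sample_id == "baseline", ]
  d <- pr$mutations[pr$mutations$sample_id == "derived", ]
  fit <- fit_dp(pair_counts(b, d), purity = 1)
  dg <- density_grid(fit)
  lost <- dg[dg$ccf_1 >= 0.3 & dg$ccf_1 <= 0.5, ]
  mode_row <- lost[which.max(lost$density), ]
  expect_lte(mode_row$ccf_2, 0.05)
})

test_that("clonal/subclonal fractions from calls and from cluster membership agree", {
  expect_equal(clonal_subclonal_fractions(c(TRUE, TRUE, FALSE, FALSE)),
               tibble::tibble(clonal = 0.5, subclonal = 0.5))
  expect_equal(clonal_subclonal_fractions(c(TRUE, TRUE))$clonal, 1)

  cfg <- sim_config(seed = 21, n_mutations = 400, purity = 1,
                    depth_mean = 200, depth_model = "fixed",
                    clones = tibble::tibble(ccf = c(1, 0.3),
                                            fraction = c(0.7, 0.3)))
  s <- simulate_sample(cfg)
  x <- s$mutations
  x$cn_t <- s$truth$cn_t
  x$cn_n <- s$truth$cn_n
  calls <- ccf_calls(x, purity = 1)

  # the per-mutation CI classifier has a known boundary bias at CCF = 1:
  # compare against its exact expectation under the binomial read model
  p_clonal <- function(ccf) {
    probs <- dbinom(0:200, 200, expected_vaf(ccf, 1, 2, 2))
    calls_x <- vapply(0:200, function(xx) {
      ccf_posterior(xx, 200, 1)$clonal
    }, logical(1))
    sum(probs * calls_x)
  }
  shares <- prop.table(table(s$truth$true_clonal))
  expected_clonal <- shares[["TRUE"]] * p_clonal(1) +
    shares[["FALSE"]] * p_clonal(0.3)
  fr <- clonal_subclonal_fractions(calls, column = "clonal_ci")
  expect_lt(abs(fr$clonal - expected_clonal), 0.05)

  # cluster membership is free of the boundary bias and recovers the truth
  fit <- fit_dp(x, purity = 1)
  fr2 <- clonal_subclonal_fractions(fit)
  expect_lt(abs(fr2$clonal - 0.7), 0.05)
  expect_equal(fr2$clonal + fr2$subclonal, 1)
})
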