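test_that("venn regions partition the union for 2 and 3 sets", {
  v <- venn_counts(list(A = c("m1", "m2", "m3"), B = c("m2", "m3", "m4")))
  expect_equal(v$count[v$region == "A&B"], 2L)
  expect_equal(v$count[v$region == "A"], 1L)
  expect_equal(v$count[v$region == "B"], 1L)
  expect_equal(sum(v$count), 4L)  # |A union B|

  v3 <- venn_counts(list(A = "m1", B = "m2", C = character(0)))
  expect_equal(sum(v3$count[grepl("&", v3$region)]), 0L)

  same <- c("m1", "m2")
  v_same <- venn_counts(list(A = same, B = same, C = same))
  expect_equal(v_same$count[v_same$region == "A&B&C"], 2L)
  expect_equal(sum(v_same$count), 2L)

  expect_error(venn_counts(list(a = "x")), "2 or 3")
  expect_error(venn_counts(as.list(letters[1:4])), "2 or 3")
})

test_that("editing reports obey the conservation identities", {
  base <- sprintf("m%d", 1:10)
  comp <- c(sprintf("m%d", 1:8), "m11")
  r <- editing_report(base, comp)$summary
  expect_equal(r$lost, 2L)
  expect_equal(r$gained, 1L)
  expect_equal(r$shared, 8L)
  expect_equal(r$pct_lost, 20)
  expect_equal(r$pct_new, 10)
  expect_equal(r$shared + r$lost, r$n_baseline)
  expect_equal(r$shared + r$gained, r$n_comparison)

  same <- editing_report(base, base)$summary
  expect_equal(same$pct_lost, 0)
  expect_equal(same$pct_new, 0)

  expect_error(editing_report(character(0), comp), "empty baseline")
})

test_that("simulated subclonal editing is recovered from the report", {
  cfg <- sim_config(seed = 42, n_mutations = 1000)
  pr <- simulate_pair(cfg, editing = list(fraction = 0.30, target = "subclonal"))
  muts <- filter_min_alt_reads(pr$mutations)
  bk <- collapse_group(muts, "baseline")
  dk <- collapse_group(muts, "derived")
  neo <- call_neoantigens(pr$peptides, pr$affinities, pr$expression)
  ann <- dplyr::left_join(
    tibble::tibble(key = neo$key, neoantigen = neo$neoantigen),
    dplyr::rename(pr$truth[, c("key", "true_clonal")], clonal = "true_clonal"),
    by = "key")
  s <- editing_report(bk, dk, ann)$summary
  expect_lt(abs(s$lost_frac_neo_subclonal - 0.30), 0.05)
  expect_lt(s$lost_frac_nonneo, 0.05)
  expect_lt(s$ratio_comparison, s$ratio_baseline)
})

test_that("the neoantigen:mutation ratio is a plain fraction of the group", {
  keys <- sprintf("m%d", 1:100)
  expect_equal(neoantigen_mutation_ratio(keys, sprintf("m%d", 1:25)), 0.25)
  expect_equal(neoantigen_mutation_ratio(keys, character(0)), 0)
  expect_error(neoantigen_mutation_ratio(character(0), "m1"), "zero mutations")
})

test_that("two unedited samples from one truth have matching ratios", {
  cfg <- sim_config(seed = 8, n_mutations = 1500)
  pr <- simulate_pair(cfg, editing = list(fraction = 0, target = "any"))
  muts <- filter_min_alt_reads(pr$mutations)
  neo <- call_neoantigens(pr$peptides, pr$affinities, pr$expression)
  neo_keys <- neo$key[neo$neoantigen]
  r1 <- neoantigen_mutation_ratio(collapse_group(muts, "baseline"), neo_keys)
  r2 <- neoantigen_mutation_ratio(collapse_group(muts, "derived"), neo_keys)
  expect_lt(abs(r1 - r2), 0.03)
})

test_that("LOH overlap is positional containment per chromosome", {
  loh <- tibble::tibble(chrom = "chr1", start = 50L, end = 200L)
  x <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                      pos = c(100L, 300L, 100L))
  ov <- loh_overlap(x, loh)
  expect_equal(ov$in_loh, c(TRUE, FALSE, FALSE))
  expect_equal(attr(ov, "n_overlap"), 1L)
  empty <- loh_overlap(x, loh[0, ])
  expect_false(any(empty$in_loh))
  expect_equal(attr(empty, "n_overlap"), 0L)
})

test_that("heterogeneity summaries capture spread and subclonal load", {
  calls <- tibble::tibble(sample_id = "s1", ccf = rep(1, 10), clonal_ci = TRUE)
  h <- heterogeneity_summary(calls)
  expect_equal(h$subclonal_fraction, 0)
  expect_equal(h$mad_ccf, 0)

  calls2 <- tibble::tibble(sample_id = "s1",
                           ccf = c(rep(1, 50), rep(0.4, 50)),
                           clonal_ci = rep(c(TRUE, FALSE), each = 50))
  expect_equal(heterogeneity_summary(calls2)$subclonal_fraction, 0.5)
  expect_error(heterogeneity_summary(calls2[0, ]), "at least one")

  # simulated 70/30 mixture at fixed depth 200: the summary must match the
  # exact expectation of the CI classifier under the binomial read model
  # (which under-calls clonality right at the CCF = 1 boundary)
  cfg <- sim_config(seed = 3, n_mutations = 600, depth_mean = 200,
                    depth_model = "fixed",
                    clones = tibble::tibble(ccf = c(1, 0.3),
                                            fraction = c(0.7, 0.3)))
  s <- simulate_sample(cfg)
  calls3 <- ccf_calls(filter_min_alt_reads(s$mutations), purity = 0.8,
                      segments = s$segments)
  h3 <- heterogeneity_summary(calls3)
  p_subclonal <- function(ccf) {
    det <- 10:200  # counts surviving the alt-read filter
    w <- dbinom(det, 200, expected_vaf(ccf, 0.8, 2, 2))
    calls_x <- vapply(det, function(xx) ccf_posterior(xx, 200, 0.8)$clonal,
                      logical(1))
    sum(w * !calls_x) / sum(w)
  }
  surv <- s$truth[s$truth$key %in% calls3$key, ]
  shares <- prop.table(table(surv$true_clonal))
  expected_sub <- shares[["TRUE"]] * p_subclonal(1) +
    shares[["FALSE"]] * p_subclonal(0.3)
  expect_lt(abs(h3$subclonal_fraction - expected_sub), 0.05)
})
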