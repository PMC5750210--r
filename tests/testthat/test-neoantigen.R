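# Brute-force window oracle: every substring of length 8-11 that covers the
# mutated position, enumerated directly from all (start, length) pairs.
ref_windows <- function(L, aa_pos) {
  n <- 0L
  for (k in 8:11) {
    for (s in seq_len(max(L - k + 1, 0))) {
      if (s <= aa_pos && aa_pos <= s + k - 1) n <- n + 1L
    }
  }
  n
}

test_that("peptide enumeration matches the brute-force window oracle", {
  expect_equal(nrow(enumerate_mutant_peptides(strrep("A", 30), 15, "W")), 38)
  expect_equal(nrow(enumerate_mutant_peptides(strrep("A", 30), 1, "W")), 4)
  expect_equal(nrow(enumerate_mutant_peptides(strrep("A", 8), 3, "W")), 1)
  for (L in 1:25) {
    seq <- strrep("A", L)
    for (pos in seq_len(L)) {
      expect_equal(nrow(enumerate_mutant_peptides(seq, pos, "W")),
                   ref_windows(L, pos),
                   info = sprintf("L=%d pos=%d", L, pos))
    }
  }
})

test_that("every enumerated peptide carries the mutant residue at its offset", {
  withr::local_seed(5)
  prot <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVY", "")[[1]], 40,
                       replace = TRUE), collapse = "")
  pep <- enumerate_mutant_peptides(prot, 17, "W")
  expect_true(all(substr(pep$peptide, pep$mut_offset + 1,
                         pep$mut_offset + 1) == "W"))
  expect_true(all(nchar(pep$peptide) >= 8 & nchar(pep$peptide) <= 11))
  expect_false(any(duplicated(paste(pep$start, pep$length))))
})

test_that("enumeration rejects invalid substitutions", {
  expect_error(enumerate_mutant_peptides("ACDEFGHIK", 99, "W"), "outside")
  expect_error(enumerate_mutant_peptides("ACDEFGHIK", 1, "A"), "reference")
  expect_error(enumerate_mutant_peptides("ACDEFGHIK", 1, "X"), "amino acid")
})

test_that("affinity attachment takes the allele minimum and flags unknowns", {
  cand <- tibble::tibble(key = c("m1", "m2"), gene = c("g1", "g2"),
                         peptide = c("AAAAAAAAK", "CCCCCCCCK"))
  aff <- tibble::tibble(peptide = c("AAAAAAAAK", "AAAAAAAAK"),
                        allele = c("H-2Kb", "H-2Db"), ic50_nM = c(40, 900))
  ann <- attach_affinities(cand, aff)
  expect_equal(ann$ic50, c(40, NA))
  expect_equal(ann$best_allele, c("H-2Kb", NA))
  expect_equal(nrow(attach_affinities(cand[0, ], aff)), 0)
  # unknown affinity is excluded by the binder filter, never imputed
  expect_equal(filter_strong_binders(ann)$key, "m1")
})

test_that("both filters are strict at their printed thresholds", {
  cand <- tibble::tibble(key = c("a", "b"), gene = c("g1", "g2"),
                         peptide = c("P1", "P2"), ic50 = c(499.9, 500.0))
  expect_equal(filter_strong_binders(cand)$key, "a")
  expect_equal(nrow(filter_strong_binders(cand, threshold = 50)), 0)

  expr <- tibble::tibble(gene = c("g1", "g2"), normalized_count = c(5.0, 5.1))
  out <- filter_expressed(cand, expr, keep_all = TRUE)
  expect_equal(out$expressed, c(FALSE, TRUE))
  expect_equal(filter_expressed(cand, expr)$key, "b")
  # absent gene and empty table are both unexpressed
  expect_equal(nrow(filter_expressed(cand, expr[0, ])), 0)
})

test_that("filter order does not matter", {
  withr::local_seed(31)
  cand <- tibble::tibble(
    key = sprintf("m%d", 1:50), gene = sprintf("g%d", 1:50),
    peptide = sprintf("P%d", 1:50),
    ic50 = exp(runif(50, log(5), log(5e4))))
  expr <- tibble::tibble(gene = sprintf("g%d", 1:50),
                         normalized_count = runif(50, 0, 20))
  a <- filter_expressed(filter_strong_binders(cand), expr)
  b <- filter_strong_binders(filter_expressed(cand, expr))
  expect_equal(a$key, b$key)
})

test_that("per-mutation calls collapse peptides and apply both filters", {
  peptides <- tibble::tibble(
    key = c("m1", "m1", "m2", "m3"), gene = c("g1", "g1", "g2", "g3"),
    peptide = c("PEPA", "PEPB", "PEPC", "PEPD"))
  aff <- tibble::tibble(peptide = c("PEPA", "PEPB", "PEPC"),
                        allele = "H-2Kb", ic50_nM = c(700, 30, 100))
  expr <- tibble::tibble(gene = c("g1", "g2"), normalized_count = c(50, 2))
  calls <- call_neoantigens(peptides, aff, expr)
  calls <- calls[match(c("m1", "m2", "m3"), calls$key), ]
  # m1: one strong peptide + expressed -> neoantigen
  # m2: strong binder but unexpressed; m3: no affinity entry
  expect_equal(calls$binder, c(TRUE, TRUE, FALSE))
  expect_equal(calls$neoantigen, c(TRUE, FALSE, FALSE))
  expect_equal(calls$best_ic50, c(30, 100, NA))
})
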