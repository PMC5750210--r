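# Small in-code fixtures shared across test files.

make_muts <- function(alt_reads, total_depth = 100L, sample_id = "s1",
                      chrom = "chr1", pos = seq_along(alt_reads),
                      gene = "", consequence = "missense") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = "A", alt = "T",
    gene = gene, consequence = consequence,
    alt_reads = as.integer(alt_reads),
    total_depth = as.integer(rep(total_depth, length.out = length(alt_reads))),
    sample_id = sample_id)
}

diploid_segment <- function(chrom = "chr1", end = 1e9) {
  tibble::tibble(chrom = chrom, start = 1L, end = as.integer(end),
                 cn_t = 2, cn_n = 2)
}

# Independent reference for the VAF(CCF) mapping, written as the algebraic
# inverse of the mutation-copy-number relation rather than via the package.
ref_vaf <- function(ccf, p, cnt, cnn) (p * ccf) / (cnn * (1 - p) + p * cnt)

# Brute-force grid posterior: raw binomial pmf products, no log space.
ref_posterior <- function(x, n, p, cnt, cnn) {
  g <- seq(0.01, 1, by = 0.01)
  lik <- stats::dbinom(x, n, ref_vaf(g, p, cnt, cnn))
  lik / sum(lik)
}
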