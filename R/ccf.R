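# Cancer cell fraction inference from variant allele frequencies, corrected
# for tumor purity and locus-specific copy number.
#
# Two classifiers are provided, mirroring the two procedures used in
# practice:
#   * a binomial posterior over a fixed 100-point CCF grid, with a 95%
#     equal-tailed credible interval; clonal iff the interval overlaps 1;
#   * mutation copy number n_mut with binomial maximum-likelihood
#     multiplicity; clonal iff CCF = n_mut / multiplicity exceeds 0.95.

#' The CCF evaluation grid
#'
#' 100 uniform values 0.01, 0.02, ..., 1.00 on which posteriors and cluster
#' locations are evaluated.
#'
#' @return Numeric vector of length 100.
#' @export
ccf_grid <- function() seq(0.01, 1, by = 0.01)

#' Expected variant allele frequency at a given CCF
#'
#' Maps a cancer cell fraction to the allele frequency expected in reads:
#' `VAF = p * CCF * m / (CN_n * (1 - p) + p * CN_t)`, where `p` is tumor
#' purity, `CN_t`/`CN_n` the tumor and normal locus-specific total copy
#' numbers and `m` the number of tumor copies carrying the mutation
#' (multiplicity, 1 for a typical heterozygous point mutation).
#'
#' @param ccf Cancer cell fraction in \[0, 1\].
#' @param purity Tumor purity in (0, 1\].
#' @param cn_t Tumor total copy number (>= 1 here; loci with `cn_t = 0` have
#'   no defined VAF and are excluded upstream).
#' @param cn_n Normal copy number (default 2).
#' @param multiplicity Mutated-copy count, default 1.
#' @return Expected VAF in \[0, 1\]; strictly increasing in `ccf` and, for a
#'   diploid locus, in `purity`.
#' @export
#' @examples
#' expected_vaf(1, 1, 2, 2)        # 0.5: clonal heterozygous, pure diploid
#' expected_vaf(0.5, 0.8, 2, 2)    # 0.2
expected_vaf <- function(ccf, purity, cn_t, cn_n = 2, multiplicity = 1) {
  stopifnot(all(ccf >= 0 & ccf <= 1), all(purity > 0 & purity <= 1),
            all(cn_t >= 1), all(cn_n >= 1))
  denom <- cn_n * (1 - purity) + purity * cn_t
  if (any(denom <= 0)) abort("non-positive denominator in expected_vaf")
  purity * ccf * multiplicity / denom
}

#' Mutation copy number from observed VAF
#'
#' `n_mut = VAF * (1 / p) * (p * CN_t + CN_n * (1 - p))`: the fraction of
#' tumor cells carrying the mutation multiplied by the number of mutated
#' chromosomal copies at the locus.
#'
#' @param vaf Observed variant allele frequency in \[0, 1\].
#' @inheritParams expected_vaf
#' @return The mutation copy number (non-negative real; exceeds 1 for
#'   mutations on multiple copies or clonal mutations in amplified regions).
#' @export
#' @examples
#' mutation_copy_number(0.5, 1, 2, 2)      # 1: one mutated copy
#' mutation_copy_number(0.25, 0.5, 3, 2)   # 1.25
mutation_copy_number <- function(vaf, purity, cn_t, cn_n = 2) {
  stopifnot(all(vaf >= 0 & vaf <= 1), all(purity > 0 & purity <= 1))
  vaf * (1 / purity) * (purity * cn_t + cn_n * (1 - purity))
}

# log binomial pmf matrix over the CCF grid; rows = mutations, cols = grid.
# Kept in log space so depths up to ~1e3 cannot underflow.
ccf_loglik_matrix <- function(alt_reads, total_depth, purity, cn_t, cn_n) {
  grid <- ccf_grid()
  denom <- cn_n * (1 - purity) + purity * cn_t
  vaf <- (purity / denom) %o% grid  # n x 100
  matrix(dbinom(rep(alt_reads, times = length(grid)),
                rep(total_depth, times = length(grid)),
                as.vector(vaf), log = TRUE),
         nrow = length(alt_reads))
}

# Equal-tailed 95% interval on a discrete grid posterior: drop the largest
# prefix and suffix each holding <= 2.5% of the mass.
grid_interval <- function(probs, level = 0.95) {
  tail_p <- (1 - level) / 2
  cum <- cumsum(probs)
  lo <- sum(c(0, cum[-length(cum)]) <= tail_p + 1e-12)
  suffix_mass <- 1 - c(0, cum[-length(cum)])  # mass from i..K
  hi <- max(which(suffix_mass > tail_p + 1e-12))
  c(lo = max(lo, 1L), hi = hi)
}

#' Grid posterior over the cancer cell fraction of one mutation
#'
#' The alternate read count `x` is modeled as Binomial(`N`, VAF(CCF)); the
#' likelihood is evaluated on the uniform 100-point CCF grid and normalized
#' into a posterior (flat prior over the grid). The mutation is called
#' clonal if the 95% equal-tailed credible interval overlaps 1, i.e. if the
#' upper bound reaches the last grid point.
#'
#' @param alt_reads Alternate (mutated) read count `x`.
#' @param total_depth Total read depth `N` (>= 1).
#' @inheritParams expected_vaf
#' @return An object of class `ccf_posterior`: a list with `grid`, `probs`
#'   (summing to 1), `point_estimate` (posterior mode), `ci_low`, `ci_high`
#'   and `clonal`.
#' @export
#' @examples
#' ccf_posterior(50, 100, purity = 1)  # clonal, point estimate 1.00
#' ccf_posterior(10, 100, purity = 1)  # subclonal, point estimate 0.20
ccf_posterior <- function(alt_reads, total_depth, purity, cn_t = 2, cn_n = 2) {
  stopifnot(length(alt_reads) == 1, total_depth >= 1,
            alt_reads >= 0, alt_reads <= total_depth)
  grid <- ccf_grid()
  ll <- ccf_loglik_matrix(alt_reads, total_depth, purity, cn_t, cn_n)[1, ]
  if (all(!is.finite(ll))) {
    abort("all grid likelihoods are zero; the read counts are inconsistent with every CCF")
  }
  probs <- exp(ll - max(ll))
  probs <- probs / sum(probs)
  iv <- grid_interval(probs)
  eps <- 0.005  # half grid step
  structure(list(
    grid = grid, probs = probs,
    point_estimate = grid[which.max(probs)],
    ci_low = grid[iv["lo"]], ci_high = grid[iv["hi"]],
    clonal = grid[iv["hi"]] >= 1 - eps
  ), class = "ccf_posterior")
}

#' @export
print.ccf_posterior <- function(x, ...) {
  cat(sprintf("CCF posterior: mode %.2f, 95%% CI [%.2f, %.2f], %s\n",
              x$point_estimate, x$ci_low, x$ci_high,
              if (x$clonal) "clonal" else "subclonal"))
  invisible(x)
}

#' Mutation multiplicity and threshold clonality
#'
#' Computes the observed mutation copy number `n_mut`, then compares the
#' observed fraction of mutated reads with the fraction expected from a
#' mutation on 1, 2, ..., `cn_t` copies under a binomial read model. The
#' maximum-likelihood copy count is the multiplicity `C`; CCF = `n_mut / C`
#' (capped at 1 for classification, raw value retained) and the mutation is
#' clonal iff CCF > 0.95. Expected fractions are clamped to
#' \[1e-6, 1 - 1e-6\] so a pure sample with `C = cn_t` cannot produce a
#' degenerate zero likelihood; likelihood ties break toward the smallest
#' `C` (the higher, more conservative CCF).
#'
#' @inheritParams ccf_posterior
#' @return An object of class `mutation_multiplicity`: a list with `n_mut`,
#'   `multiplicity`, `ccf_raw`, `ccf` (capped) and `clonal`.
#' @export
#' @examples
#' infer_multiplicity(48, 100, purity = 0.5)  # multiplicity 2, CCF 0.96
#' infer_multiplicity(10, 100, purity = 1)    # multiplicity 1, CCF 0.20
infer_multiplicity <- function(alt_reads, total_depth, purity, cn_t = 2, cn_n = 2) {
  stopifnot(total_depth >= 1, cn_t >= 1, alt_reads >= 0, alt_reads <= total_depth)
  vaf <- alt_reads / total_depth
  n_mut <- mutation_copy_number(vaf, purity, cn_t, cn_n)
  cc <- seq_len(cn_t)
  f <- pmin(pmax(purity * cc / (purity * cn_t + cn_n * (1 - purity)), 1e-6), 1 - 1e-6)
  ll <- dbinom(alt_reads, total_depth, f, log = TRUE)
  mult <- cc[which.max(ll)]  # which.max takes the first maximum: smallest C
  ccf_raw <- n_mut / mult
  ccf <- min(ccf_raw, 1)
  structure(list(n_mut = n_mut, multiplicity = mult, ccf_raw = ccf_raw,
                 ccf = ccf, clonal = ccf > 0.95),
            class = "mutation_multiplicity")
}

#' @export
print.mutation_multiplicity <- function(x, ...) {
  cat(sprintf("n_mut %.3f on %d copies: CCF %.3f (%s)\n",
              x$n_mut, x$multiplicity, x$ccf,
              if (x$clonal) "clonal" else "subclonal"))
  invisible(x)
}

#' Estimate tumor purity from homozygous marker mutations
#'
#' Marker mutations known to be homozygous in the originating cell line have
#' an expected VAF of 1 in a pure sample; normal contamination dilutes them
#' proportionally. The purity estimate is the arithmetic mean VAF of markers
#' falling in diploid regions (`cn_t = cn_n = 2`).
#'
#' @param markers Mutation tibble of the homozygous marker variants as
#'   observed in the sample under study.
#' @param segments Optional copy-number segments; markers outside a diploid
#'   segment are excluded. With `segments = NULL` every marker is assumed
#'   diploid.
#' @return A one-row tibble with `p`, `n_support` and `method`.
#' @export
estimate_purity <- function(markers, segments = NULL) {
  x <- markers
  if (!is.null(segments)) {
    idx <- match_segment(segments, x$chrom, x$pos)
    diploid <- !is.na(idx) & segments$cn_t[idx] == 2 & segments$cn_n[idx] == 2
    x <- x[diploid, , drop = FALSE]
  }
  if (nrow(x) == 0) {
    abort(paste0("no homozygous marker falls in a diploid region; ",
                 "supply the tumor purity explicitly"))
  }
  p <- mean(x$alt_reads / x$total_depth)
  tibble::tibble(p = min(p, 1), n_support = nrow(x),
                 method = "homozygous_diploid_mean")
}

#' Per-mutation CCF calls for a sample
#'
#' Runs both CCF procedures over a mutation table: the grid posterior with
#' 95%-interval clonality and the multiplicity/threshold rule. Copy numbers
#' are looked up per mutation from `segments`; mutations in no segment
#' default to diploid with a warning, and mutations in `cn_t = 0` segments
#' are excluded (the VAF model is undefined there) and counted in the
#' `dropped_cn0` attribute.
#'
#' @param x Mutation tibble (one or more samples).
#' @param purity Tumor purity: a single value, or a named vector /
#'   `estimate_purity()`-style tibble per `sample_id`.
#' @param segments Optional copy-number segment tibble.
#' @param cn_n Default normal copy number where no segment provides one.
#' @return A tibble with one row per retained mutation: the identity key,
#'   read counts, copy numbers, purity, `vaf`, grid-posterior columns
#'   (`ccf`, `ci_low`, `ci_high`, `clonal_ci`) and multiplicity columns
#'   (`n_mut`, `multiplicity`, `ccf_mult`, `clonal_threshold`).
#' @export
ccf_calls <- function(x, purity, segments = NULL, cn_n = 2) {
  stopifnot(nrow(x) >= 1)
  if (is.data.frame(purity)) purity <- setNames(purity$p, purity$sample_id %||% x$sample_id[1])
  p <- if (length(purity) == 1 && is.null(names(purity))) {
    rep(unname(purity), nrow(x))
  } else {
    unname(purity[x$sample_id])
  }
  if (any(is.na(p))) abort("no purity supplied for some sample_id")

  cn_t <- rep(2, nrow(x)); cnn <- rep(cn_n, nrow(x))
  if (!is.null(segments)) {
    idx <- match_segment(segments, x$chrom, x$pos)
    if (any(is.na(idx))) {
      warn(paste0(sum(is.na(idx)), " mutation(s) fall in no copy-number segment; ",
                  "assuming diploid (cn_t = cn_n = 2)"))
    }
    hit <- !is.na(idx)
    cn_t[hit] <- segments$cn_t[idx[hit]]
    if ("cn_n" %in% names(segments)) cnn[hit] <- segments$cn_n[idx[hit]]
  }
  drop0 <- cn_t == 0
  if (any(drop0)) {
    inform(paste0("excluding ", sum(drop0), " mutation(s) in cn_t = 0 segments from CCF analysis"))
  }
  keep <- !drop0
  x <- x[keep, , drop = FALSE]
  p <- p[keep]; cn_t <- cn_t[keep]; cnn <- cnn[keep]

  grid <- ccf_grid()
  ll <- ccf_loglik_matrix(x$alt_reads, x$total_depth, p, cn_t, cnn)
  mx <- apply(ll, 1, max)
  pr <- exp(ll - mx)
  pr <- pr / rowSums(pr)
  map_idx <- max.col(pr, ties.method = "first")
  eps <- 0.005
  ivs <- t(apply(pr, 1, grid_interval))

  mult <- purrr::pmap(
    list(x$alt_reads, x$total_depth, p, cn_t, cnn),
    function(a, n, pp, ct, cn) infer_multiplicity(a, n, pp, ct, cn))

  out <- tibble::tibble(
    key = mutation_key(x),
    sample_id = x$sample_id, gene = x$gene, consequence = x$consequence,
    alt_reads = x$alt_reads, total_depth = x$total_depth,
    cn_t = cn_t, cn_n = cnn, purity = p,
    vaf = x$alt_reads / x$total_depth,
    ccf = grid[map_idx],
    ci_low = grid[ivs[, "lo"]], ci_high = grid[ivs[, "hi"]],
    clonal_ci = grid[ivs[, "hi"]] >= 1 - eps,
    n_mut = purrr::map_dbl(mult, "n_mut"),
    multiplicity = purrr::map_int(mult, ~ as.integer(.x$multiplicity)),
    ccf_mult = purrr::map_dbl(mult, "ccf"),
    clonal_threshold = purrr::map_lgl(mult, "clonal")
  )
  attr(out, "dropped_cn0") <- sum(drop0)
  out
}
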