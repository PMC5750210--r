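# Readers, writers and pre-analysis filters for the tabular inputs:
# somatic mutation tables (TSV or VCF), copy-number segments (SEG-like TSV or
# BED), gene expression tables, LOH segments and MHC affinity tables.
# All coordinates are 1-based inclusive internally (VCF convention); BED
# inputs are converted on read.

MUTATION_COLS <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                   "alt_reads", "total_depth", "sample_id")

#' Mutation identity keys
#'
#' Builds the `chrom:pos:ref:alt` identity key used to compare mutations
#' across samples. Gene and consequence are annotations, not identity.
#'
#' @param x A mutation data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return A character vector of keys, one per row.
#' @export
#' @examples
#' mutation_key(tibble::tibble(chrom = "chr1", pos = 100, ref = "A", alt = "T"))
mutation_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

validate_mutations <- function(x, file = "<data>") {
  missing <- setdiff(MUTATION_COLS, names(x))
  if (length(missing) > 0) {
    abort(paste0("mutation table ", file, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(x$alt_reads) | is.na(x$total_depth) |
                 x$alt_reads < 0 | x$alt_reads > x$total_depth)
  if (length(bad) > 0) {
    abort(paste0("mutation table ", file, ": alt_reads outside [0, total_depth] at row(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(is.na(x$pos) | x$pos < 1)) {
    abort(paste0("mutation table ", file, ": positions must be >= 1"))
  }
  x
}

#' Read a somatic mutation table
#'
#' Reads per-sample somatic mutations with alt/total read counts from a TSV
#' (columns `chrom, pos, ref, alt, gene, consequence, alt_reads, total_depth,
#' sample_id`) or from a VCF v4.x with per-sample `AD`/`DP` genotype fields.
#' Multi-allelic VCF records are split into one row per alternate allele so
#' identity keys stay comparable across files.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A tibble of mutations, one row per variant per sample, in file
#'   order, validated against the record invariants.
#' @export
read_mutations <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("mutation file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") return(read_mutations_vcf(path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    gene = readr::col_character(), consequence = readr::col_character(),
    alt_reads = readr::col_integer(), total_depth = readr::col_integer(),
    sample_id = readr::col_character()
  ), progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    abort(paste0("parse error in ", path, " at line ", probs$row[1] + 1L,
                 ": ", probs$expected[1]))
  }
  x$gene[is.na(x$gene)] <- ""
  validate_mutations(tibble::as_tibble(x), path)
}

read_mutations_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP")
  samples <- colnames(ad)
  out <- vector("list", nrow(fix) * length(samples))
  n <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      ad_i <- suppressWarnings(as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
      depth <- suppressWarnings(as.integer(dp[i, s]))
      if (is.na(depth)) depth <- sum(ad_i, na.rm = TRUE)
      for (a in seq_along(alts)) {
        alt_reads <- if (length(ad_i) >= a + 1) ad_i[a + 1] else NA_integer_
        if (is.na(alt_reads)) {
          abort(paste0("VCF record ", fix[i, "CHROM"], ":", fix[i, "POS"],
                       " sample ", s, " lacks an AD entry for allele ", alts[a]))
        }
        n <- n + 1L
        out[[n]] <- tibble::tibble(
          chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[a], gene = "", consequence = "other",
          alt_reads = alt_reads, total_depth = depth, sample_id = s)
      }
    }
  }
  validate_mutations(dplyr::bind_rows(out[seq_len(n)]), path)
}

#' Write a mutation table in the canonical TSV dialect
#'
#' @param x A mutation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(x, path) {
  readr::write_tsv(validate_mutations(x)[, MUTATION_COLS], path, progress = FALSE)
  invisible(path)
}

#' Read copy-number segments
#'
#' SEG-like TSV with columns `chrom, start, end, cn_t` and optional
#' `major_cn, minor_cn, cn_n`; or BED (`.bed` extension, 0-based half-open,
#' 4th column read as `cn_t`), converted to 1-based inclusive coordinates.
#'
#' @param path Path to the segment file.
#' @param cn_n Default normal copy number for segments without a `cn_n`
#'   column (2 for autosomes).
#' @return A tibble with columns `chrom, start, end, cn_t, cn_n` and, when
#'   present, `major_cn, minor_cn`.
#' @export
read_segments <- function(path, cn_n = 2L) {
  if (!file.exists(path)) abort(paste0("segment file not found: ", path))
  if (grepl("\\.bed$", path)) {
    x <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "cn_t"),
                         col_types = "ciid", progress = FALSE)
    x$start <- x$start + 1L  # BED is 0-based half-open
  } else {
    x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"cn_n" %in% names(x)) x$cn_n <- as.numeric(cn_n)
  validate_segments(x, path)
}

validate_segments <- function(x, file = "<data>") {
  need <- c("chrom", "start", "end", "cn_t")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("segment table ", file, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(x$start > x$end)) abort(paste0("segment table ", file, ": start > end"))
  if (any(x$cn_t < 0)) abort(paste0("segment table ", file, ": cn_t must be >= 0"))
  if (all(c("major_cn", "minor_cn") %in% names(x))) {
    ok <- is.na(x$major_cn) | (x$major_cn + x$minor_cn == x$cn_t)
    if (!all(ok)) abort(paste0("segment table ", file, ": major_cn + minor_cn != cn_t"))
  }
  x
}

#' Write a segment table
#' @param x Segment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(x, path) {
  readr::write_tsv(validate_segments(x), path, progress = FALSE)
  invisible(path)
}

#' Read a gene expression table
#'
#' Two-column TSV `gene<TAB>normalized_count` of normalized counts (consumed
#' as produced by the upstream expression workflow; nothing is re-normalized
#' here).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene`, `normalized_count`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("expression file not found: ", path))
  x <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  names(x) <- c("gene", "normalized_count")
  if (any(x$normalized_count < 0)) abort(paste0(path, ": negative normalized counts"))
  tibble::as_tibble(x)
}

#' @rdname read_expression
#' @param x Expression tibble.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x[, c("gene", "normalized_count")], path, progress = FALSE)
  invisible(path)
}

#' Read LOH segments
#'
#' BED (0-based half-open, converted) or 3-column TSV `chrom, start, end`
#' with 1-based inclusive coordinates.
#'
#' @param path Path to the file.
#' @return A tibble with columns `chrom, start, end`.
#' @export
read_loh <- function(path) {
  if (!file.exists(path)) abort(paste0("LOH file not found: ", path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("chrom", first, fixed = TRUE)
  x <- readr::read_tsv(path, col_names = if (has_header) TRUE else c("chrom", "start", "end"),
                       col_types = "cii", progress = FALSE)
  x <- tibble::as_tibble(x[, 1:3])
  names(x) <- c("chrom", "start", "end")
  if (grepl("\\.bed$", path)) x$start <- x$start + 1L
  if (any(x$start > x$end)) abort(paste0(path, ": start > end"))
  x
}

#' @rdname read_loh
#' @param x LOH segment tibble.
#' @return `path`, invisibly.
#' @export
write_loh <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end")], path, progress = FALSE)
  invisible(path)
}

#' Read an MHC binding-affinity table
#'
#' TSV with columns `peptide, allele, ic50_nM`, as exported (after trivial
#' reshaping) by an external MHC class I binding predictor. Affinities are
#' always consumed, never computed.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `peptide, allele, ic50_nM`.
#' @export
read_affinities <- function(path) {
  if (!file.exists(path)) abort(paste0("affinity file not found: ", path))
  x <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  names(x) <- c("peptide", "allele", "ic50_nM")
  if (any(x$ic50_nM <= 0)) abort(paste0(path, ": IC50 values must be positive"))
  tibble::as_tibble(x)
}

#' @rdname read_affinities
#' @param x Affinity tibble.
#' @return `path`, invisibly.
#' @export
write_affinities <- function(x, path) {
  readr::write_tsv(x[, c("peptide", "allele", "ic50_nM")], path, progress = FALSE)
  invisible(path)
}

#' Filter mutations by alternate-read support
#'
#' Retains mutations with at least `k` reads supporting the alternate
#' allele (default 10), the detectability filter applied to every mutation
#' table before any downstream analysis.
#'
#' @param x Mutation tibble.
#' @param k Minimum number of alternate reads (inclusive).
#' @return The retained rows, order preserved.
#' @export
#' @examples
#' m <- tibble::tibble(chrom = "chr1", pos = 1:3, ref = "A", alt = "T",
#'                     gene = "", consequence = "missense",
#'                     alt_reads = c(9L, 10L, 11L), total_depth = 50L,
#'                     sample_id = "s1")
#' filter_min_alt_reads(m)  # keeps alt_reads 10 and 11
filter_min_alt_reads <- function(x, k = 10L) {
  stopifnot(k >= 0)
  x[x$alt_reads >= k, , drop = FALSE]
}

#' Collapse replicate samples to a group-level mutation set
#'
#' A mutation belongs to a sample group if it is present in at least one
#' replicate of the group (presence-in-any collapse).
#'
#' @param x Mutation tibble covering one or more samples.
#' @param members Character vector of `sample_id`s forming the group.
#' @return Sorted character vector of mutation keys present in any member.
#' @export
collapse_group <- function(x, members) {
  if (length(members) == 0) abort("a sample group needs at least one member")
  keys <- mutation_key(x[x$sample_id %in% members, , drop = FALSE])
  sort(unique(keys))
}

#' Locate the copy-number segment containing a position
#'
#' Segments must be non-overlapping per chromosome; an ambiguous query is an
#' error rather than a silent pick.
#'
#' @param segments Segment tibble.
#' @param chrom,pos Query coordinates (vectors of equal length).
#' @return Integer vector of row indices into `segments` (`NA` where no
#'   segment contains the position).
#' @export
match_segment <- function(segments, chrom, pos) {
  n <- length(pos)
  out <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hit <- which(segments$chrom == chrom[i] &
                   segments$start <= pos[i] & segments$end >= pos[i])
    if (length(hit) > 1) {
      abort(paste0("overlapping segments at ", chrom[i], ":", pos[i]))
    }
    if (length(hit) == 1) out[i] <- hit
  }
  out
}

#' @rdname match_segment
#' @return `lookup_segment()` returns the one-row segment tibble, or `NULL`
#'   when no segment contains the position.
#' @export
lookup_segment <- function(segments, chrom, pos) {
  stopifnot(length(chrom) == 1, length(pos) == 1)
  i <- match_segment(segments, chrom, pos)
  if (is.na(i)) NULL else segments[i, , drop = FALSE]
}
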