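# Mutant-peptide enumeration and the neoantigen filters.
#
# Binding affinities come from an external MHC class I predictor's output
# table and are only ever attached, never computed. The filters implement
# the printed thresholds: strong binder iff IC50 < 500 nM (strict), and
# expressed iff the gene's normalized count is > 5 (strict).

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Enumerate all mutant 8-11-mer peptides around a missense change
#'
#' Substitutes `alt_aa` at `aa_pos` of the protein and returns every window
#' of length 8-11 that contains the mutated residue and lies fully within
#' the protein (windows truncated by either terminus are omitted).
#'
#' @param protein_seq Protein sequence (single string of one-letter amino
#'   acid codes).
#' @param aa_pos 1-based position of the substituted residue.
#' @param alt_aa Mutant amino acid (must differ from the reference residue).
#' @return A tibble with `peptide`, `length`, `start` (1-based position in
#'   the protein) and `mut_offset` (0-based position of the mutated residue
#'   within the peptide). An interior mutation (>= 10 residues from both
#'   termini) yields exactly 8 + 9 + 10 + 11 = 38 peptides.
#' @export
#' @examples
#' enumerate_mutant_peptides(strrep("A", 30), 15, "W")
enumerate_mutant_peptides <- function(protein_seq, aa_pos, alt_aa) {
  L <- nchar(protein_seq)
  if (aa_pos < 1 || aa_pos > L) abort("aa_pos outside the protein")
  if (!alt_aa %in% AA_ALPHABET) abort(paste0("not a standard amino acid: ", alt_aa))
  ref_aa <- substr(protein_seq, aa_pos, aa_pos)
  if (identical(ref_aa, alt_aa)) {
    abort("alt_aa equals the reference residue; not a missense change")
  }
  mutated <- paste0(substr(protein_seq, 1, aa_pos - 1), alt_aa,
                    substr(protein_seq, aa_pos + 1, L))
  lens <- integer(0); starts <- integer(0)
  for (k in 8:11) {
    lo <- max(1L, aa_pos - k + 1L)
    hi <- min(aa_pos, L - k + 1L)
    if (hi < lo) next
    s <- seq.int(lo, hi)
    starts <- c(starts, s)
    lens <- c(lens, rep.int(k, length(s)))
  }
  tibble::tibble(
    peptide = if (length(starts)) substring(mutated, starts, starts + lens - 1)
              else character(0),
    length = lens, start = starts, mut_offset = aa_pos - starts)
}

#' Attach predicted binding affinities to peptide candidates
#'
#' Each candidate is annotated with the minimum IC50 over the supplied MHC
#' alleles (the strongest binder determines immunogenicity); candidates
#' whose peptide has no entry in the table keep `ic50 = NA` and are
#' excluded by the downstream binder filter rather than imputed.
#'
#' @param candidates Tibble with a `peptide` column.
#' @param affinities Affinity table `peptide, allele, ic50_nM` (see
#'   [read_affinities()]).
#' @return `candidates` with `ic50` (nM) and `best_allele` columns added.
#' @export
attach_affinities <- function(candidates, affinities) {
  if (nrow(candidates) == 0) {
    candidates$ic50 <- numeric(0)
    candidates$best_allele <- character(0)
    return(candidates)
  }
  best <- affinities |>
    dplyr::group_by(.data$peptide) |>
    dplyr::slice_min(.data$ic50_nM, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("peptide", ic50 = "ic50_nM", best_allele = "allele")
  dplyr::left_join(candidates, best, by = "peptide")
}

#' Retain strong MHC binders
#'
#' @param candidates Tibble with an `ic50` column (nM).
#' @param threshold IC50 cutoff in nM; strictly `ic50 < threshold` is
#'   retained (default 500; use 50 for the highest-affinity tier).
#' @return The retained candidates.
#' @export
filter_strong_binders <- function(candidates, threshold = 500) {
  candidates[!is.na(candidates$ic50) & candidates$ic50 < threshold, , drop = FALSE]
}

#' Mark and retain candidates from expressed genes
#'
#' A candidate counts as expressed iff its gene is present in the
#' expression table with normalized count strictly greater than
#' `threshold`. The `expressed` flag is set on every candidate; by default
#' only expressed candidates are returned.
#'
#' @param candidates Tibble with a `gene` column.
#' @param expression Expression table `gene, normalized_count`.
#' @param threshold Normalized-count cutoff (default 5, strict).
#' @param keep_all Return all candidates (with the flag set) instead of
#'   only the expressed ones.
#' @return Candidates with an `expressed` column, filtered unless
#'   `keep_all = TRUE`.
#' @export
filter_expressed <- function(candidates, expression, threshold = 5,
                             keep_all = FALSE) {
  counts <- expression$normalized_count[match(candidates$gene, expression$gene)]
  candidates$expressed <- !is.na(counts) & counts > threshold
  if (keep_all) candidates else candidates[candidates$expressed, , drop = FALSE]
}

#' Per-mutation neoantigen calls
#'
#' Collapses peptide-level candidates to mutation granularity: a mutation
#' is a (predicted) neoantigen if at least one of its mutant peptides is a
#' strong binder, and an expressed neoantigen if additionally its gene is
#' expressed.
#'
#' @param peptides Tibble mapping mutations to candidate peptides: columns
#'   `key`, `gene`, `peptide`.
#' @param affinities Affinity table (`peptide, allele, ic50_nM`).
#' @param expression Expression table (`gene, normalized_count`).
#' @param ic50_threshold,expr_threshold The two filter cutoffs (500 nM and
#'   5 normalized counts by default).
#' @return A tibble with one row per mutation key: `gene`, `best_ic50`,
#'   `binder`, `expressed`, `neoantigen` (= binder & expressed).
#' @export
call_neoantigens <- function(peptides, affinities, expression,
                             ic50_threshold = 500, expr_threshold = 5) {
  ann <- attach_affinities(peptides, affinities)
  ann <- filter_expressed(ann, expression, expr_threshold, keep_all = TRUE)
  ann |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      gene = .data$gene[1],
      best_ic50 = if (all(is.na(.data$ic50))) NA_real_ else min(.data$ic50, na.rm = TRUE),
      binder = any(!is.na(.data$ic50) & .data$ic50 < ic50_threshold),
      expressed = any(.data$expressed),
      .groups = "drop") |>
    dplyr::mutate(neoantigen = .data$binder & .data$expressed)
}
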