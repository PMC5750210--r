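# Replicate-aware comparison of mutation and neoantigen sets between sample
# groups: Venn partitions, gain/loss editing reports, neoantigen:mutation
# ratios, LOH overlap checks and CCF heterogeneity summaries.

#' Venn region counts for 2 or 3 mutation sets
#'
#' @param sets Named list of 2 or 3 character vectors of mutation keys
#'   (typically [collapse_group()] output).
#' @return A tibble `region, count`, one row per Venn region; exclusive
#'   regions are named by the set, intersections by `A&B` etc. Region
#'   counts sum to the size of the union.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2 || length(sets) > 3) {
    abort("venn_counts supports 2 or 3 sets")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), 0, length(sets), dimnames = list(NULL, names(sets)))
  }
  pattern <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(names(sets), k, paste, collapse = "&")
  }))
  counts <- table(factor(pattern, levels = combos))
  tibble::tibble(region = combos, count = as.integer(counts))
}

#' Gain/loss editing report between a baseline and a comparison group
#'
#' Partitions the two key sets into shared, lost (baseline only) and gained
#' (comparison only) mutations, with percentages relative to the baseline
#' set size. When per-mutation annotations are supplied the same partition
#' is reported for expressed strong-binder neoantigens, along with
#' per-class loss fractions (the estimate of the editing fraction applied
#' to each class) and clonal/subclonal neoantigen counts per group.
#'
#' @param baseline,comparison Character vectors of mutation keys.
#' @param annotations Optional tibble with `key` plus logical `neoantigen`
#'   (expressed strong binder) and/or `clonal` columns covering the keys.
#' @return An object of class `editing_report`: a list with `$summary`
#'   (one-row tibble) and `$keys` (shared/gained/lost key vectors).
#' @export
editing_report <- function(baseline, comparison, annotations = NULL) {
  baseline <- unique(baseline); comparison <- unique(comparison)
  if (length(baseline) == 0) {
    abort("empty baseline set; loss percentages are undefined")
  }
  shared <- intersect(baseline, comparison)
  lost <- setdiff(baseline, comparison)
  gained <- setdiff(comparison, baseline)

  n_lost <- length(lost); n_gained <- length(gained)
  s <- tibble::tibble(
    n_baseline = length(baseline), n_comparison = length(comparison),
    shared = length(shared), gained = n_gained, lost = n_lost,
    pct_lost = 100 * n_lost / length(baseline),
    pct_new = 100 * n_gained / length(baseline))

  if (!is.null(annotations)) {
    neo <- if ("neoantigen" %in% names(annotations)) {
      annotations$key[annotations$neoantigen %in% TRUE]
    } else character(0)
    clonal <- if ("clonal" %in% names(annotations)) {
      annotations$key[annotations$clonal %in% TRUE]
    } else NULL

    b_neo <- intersect(baseline, neo); c_neo <- intersect(comparison, neo)
    b_non <- setdiff(baseline, neo)
    s$neo_baseline <- length(b_neo)
    s$neo_comparison <- length(c_neo)
    s$neo_shared <- length(intersect(b_neo, c_neo))
    s$neo_lost <- length(setdiff(b_neo, c_neo))
    s$neo_gained <- length(setdiff(c_neo, b_neo))
    s$ratio_baseline <- length(b_neo) / length(baseline)
    s$ratio_comparison <- if (length(comparison) > 0) {
      length(c_neo) / length(comparison)
    } else NA_real_
    s$lost_frac_neo <- if (length(b_neo) > 0) s$neo_lost / length(b_neo) else NA_real_
    s$lost_frac_nonneo <- if (length(b_non) > 0) {
      length(setdiff(b_non, comparison)) / length(b_non)
    } else NA_real_

    if (!is.null(clonal)) {
      b_sub <- setdiff(baseline, clonal)
      b_neo_cl <- intersect(b_neo, clonal); b_neo_sub <- setdiff(b_neo, clonal)
      s$neo_clonal_baseline <- length(b_neo_cl)
      s$neo_subclonal_baseline <- length(b_neo_sub)
      s$lost_frac_neo_clonal <- if (length(b_neo_cl) > 0) {
        length(setdiff(b_neo_cl, comparison)) / length(b_neo_cl)
      } else NA_real_
      s$lost_frac_neo_subclonal <- if (length(b_neo_sub) > 0) {
        length(setdiff(b_neo_sub, comparison)) / length(b_neo_sub)
      } else NA_real_
      s$pct_clonal_loss <- if (length(lost) > 0) {
        100 * length(intersect(lost, clonal)) / length(lost)
      } else 0
      s$pct_subclonal_change <- if (length(intersect(baseline, b_sub)) > 0) {
        100 * length(setdiff(b_sub, comparison)) / length(b_sub)
      } else 0
    }
  }

  structure(list(summary = s,
                 keys = list(shared = shared, gained = gained, lost = lost)),
            class = "editing_report")
}

#' @export
print.editing_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Editing report: %d baseline / %d comparison mutations\n",
              s$n_baseline, s$n_comparison))
  cat(sprintf("  shared %d, lost %d (%.1f%%), gained %d (%.1f%%)\n",
              s$shared, s$lost, s$pct_lost, s$gained, s$pct_new))
  if (!is.null(s$neo_baseline)) {
    cat(sprintf("  neoantigens: %d baseline, %d lost, %d gained\n",
                s$neo_baseline, s$neo_lost, s$neo_gained))
  }
  invisible(x)
}

#' @export
tidy.editing_report <- function(x, ...) {
  tidyr::pivot_longer(x$summary, dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' @export
glance.editing_report <- function(x, ...) x$summary

#' Expressed-neoantigen to mutation ratio of a group
#'
#' @param keys Character vector of the group's mutation keys.
#' @param neoantigen_keys Keys of mutations that are expressed
#'   strong-binder neoantigens.
#' @return The fraction of the group's mutations that are neoantigenic, in
#'   \[0, 1\].
#' @export
neoantigen_mutation_ratio <- function(keys, neoantigen_keys) {
  keys <- unique(keys)
  if (length(keys) == 0) abort("cannot compute a ratio over zero mutations")
  mean(keys %in% neoantigen_keys)
}

#' LOH overlap at mutation positions
#'
#' Flags each mutation whose genomic position falls inside a loss-of-
#' heterozygosity segment on the same chromosome. Used to check whether
#' neoantigen-deriving mutations could have been lost through LOH.
#'
#' @param x Tibble with `chrom`, `pos` and (optionally) `key` columns.
#' @param loh LOH segment tibble (`chrom, start, end`, 1-based inclusive).
#' @return `x` with an `in_loh` logical column; the number of overlapping
#'   mutations is in the `n_overlap` attribute.
#' @export
loh_overlap <- function(x, loh) {
  in_loh <- rep(FALSE, nrow(x))
  if (!is.null(loh) && nrow(loh) > 0) {
    for (i in seq_len(nrow(x))) {
      in_loh[i] <- any(loh$chrom == x$chrom[i] &
                         loh$start <= x$pos[i] & loh$end >= x$pos[i])
    }
  }
  out <- x
  out$in_loh <- in_loh
  attr(out, "n_overlap") <- sum(in_loh)
  out
}

#' Per-sample heterogeneity summary of CCF calls
#'
#' @param calls CCF call tibble ([ccf_calls()] output or any tibble with
#'   `sample_id`, `ccf` and a clonality column).
#' @param column Clonality column to use (default `clonal_ci` when present).
#' @return A tibble with one row per sample: `n`, `median_ccf`, `mad_ccf`
#'   (median absolute deviation, consistency-scaled) and
#'   `subclonal_fraction`, plus a `ccf` list-column holding the full CCF
#'   vector for violin-style plotting.
#' @export
heterogeneity_summary <- function(calls, column = NULL) {
  if (nrow(calls) == 0) abort("heterogeneity_summary needs at least one CCF value")
  column <- column %||% intersect(c("clonal_ci", "clonal_threshold", "clonal"),
                                  names(calls))[1]
  if (!"sample_id" %in% names(calls)) calls$sample_id <- "sample1"
  calls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_ccf = median(.data$ccf),
      mad_ccf = mad(.data$ccf),
      subclonal_fraction = if (!is.na(column)) mean(!.data[[column]]) else NA_real_,
      ccf = list(.data$ccf),
      .groups = "drop")
}

#' Long-format CCF table for violin plots
#'
#' @param calls CCF call tibble with `sample_id` and `ccf` columns.
#' @return A two-column tibble `sample_id, ccf` suitable for export.
#' @export
ccf_long <- function(calls) {
  tibble::tibble(sample_id = calls$sample_id, ccf = calls$ccf)
}
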