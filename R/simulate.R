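# Synthetic tumor-sequencing cohort generator.
#
# Emulates the statistical structure the analysis assumes: a dominant
# clonal cluster at CCF 1 plus subclonal clusters, purity in (0.5, 1], a
# mostly diploid genome with focal amplification and deletion, exome-scale
# mutation counts with binomially sampled read counts, a subset of
# mutations carrying expressed strong-binder neoantigen peptides, and
# paired/replicated samples for editing scenarios. Every quantity that the
# pipeline estimates is recorded as ground truth.

#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic cohort
#' generator. Defaults describe a hypermutated, mostly diploid carcinoma
#' cell-line transplant: ~70% clonal mutations at CCF 1 with a subclone at
#' CCF 0.4, purity 0.8, ~100x exome depth, half of the missense mutations
#' carrying a strong-binder peptide and half of all genes expressed, so
#' roughly a quarter of mutations are expressed neoantigens.
#'
#' @param seed Integer seed fixing the full cohort.
#' @param n_mutations Number of somatic point mutations.
#' @param clones Tibble/data.frame with `ccf` (in (0, 1\]) and `fraction`
#'   columns; fractions must sum to 1.
#' @param purity Tumor purity in (0, 1\].
#' @param depth_mean Mean sequencing depth.
#' @param depth_model `"poisson"` (Poisson around the mean, floored at 10)
#'   or `"fixed"`.
#' @param segments Copy-number segments; `NULL` uses a default landscape of
#'   19 diploid autosomes with one focal amplification (`cn_t = 4`) and one
#'   deletion (`cn_t = 1`).
#' @param consequence_probs Named probabilities for `missense` and
#'   `stop_gained` consequences.
#' @param neoantigen_fraction Fraction of missense mutations whose peptide
#'   is a strong binder (IC50 drawn log-uniform on (5, 500) nM; non-binders
#'   log-uniform on (500, 5e4) nM).
#' @param expressed_fraction Fraction of genes with normalized counts > 5.
#' @param n_markers Number of homozygous diploid marker mutations emitted
#'   for purity estimation (multiplicity = cn_t, expected VAF = purity).
#' @param loh Optional LOH segments to emit with the cohort.
#' @param alleles MHC allele names used in the affinity table.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mutations = 2000L,
                       clones = tibble::tibble(ccf = c(1, 0.4),
                                               fraction = c(0.7, 0.3)),
                       purity = 0.8,
                       depth_mean = 100,
                       depth_model = c("poisson", "fixed"),
                       segments = NULL,
                       consequence_probs = c(missense = 0.94, stop_gained = 0.06),
                       neoantigen_fraction = 0.5,
                       expressed_fraction = 0.5,
                       n_markers = 200L,
                       loh = NULL,
                       alleles = c("H-2Kb", "H-2Db")) {
  depth_model <- match.arg(depth_model)
  clones <- tibble::as_tibble(clones)
  if (abs(sum(clones$fraction) - 1) > 1e-8) {
    abort("clone fractions must sum to 1")
  }
  if (any(clones$ccf <= 0 | clones$ccf > 1)) abort("clone CCFs must lie in (0, 1]")
  if (purity <= 0 || purity > 1) abort("purity must lie in (0, 1]")
  fracs <- c(neoantigen_fraction, expressed_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (is.null(segments)) segments <- default_segments()
  structure(list(
    seed = as.integer(seed), n_mutations = as.integer(n_mutations),
    clones = clones, purity = purity, depth_mean = depth_mean,
    depth_model = depth_model, segments = validate_segments(segments),
    consequence_probs = consequence_probs,
    neoantigen_fraction = neoantigen_fraction,
    expressed_fraction = expressed_fraction,
    n_markers = as.integer(n_markers), loh = loh, alleles = alleles
  ), class = "sim_config")
}

# Mostly diploid genome: 19 autosomes of 120 Mb, a focal amplification on
# chr15 and a focal deletion on chr4.
default_segments <- function() {
  chroms <- paste0("chr", 1:19)
  base <- tibble::tibble(chrom = chroms, start = 1L, end = 120000000L,
                         cn_t = 2, cn_n = 2)
  base$end[base$chrom == "chr15"] <- 59999999L
  base$end[base$chrom == "chr4"] <- 79999999L
  dplyr::bind_rows(
    base,
    tibble::tibble(chrom = "chr15", start = 60000000L, end = 65000000L,
                   cn_t = 4, cn_n = 2),
    tibble::tibble(chrom = "chr15", start = 65000001L, end = 120000000L,
                   cn_t = 2, cn_n = 2),
    tibble::tibble(chrom = "chr4", start = 80000000L, end = 85000000L,
                   cn_t = 1, cn_n = 2),
    tibble::tibble(chrom = "chr4", start = 85000001L, end = 120000000L,
                   cn_t = 2, cn_n = 2))
}

draw_depth <- function(n, config) {
  if (config$depth_model == "fixed") rep(as.integer(round(config$depth_mean)), n)
  else pmax(rpois(n, config$depth_mean), 10L)
}

random_peptide <- function(n, length = 9) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
  }, character(1))
}

# Shared latent truth: positions, clones, copy numbers, genes, peptides,
# affinities, expression. Read counts are drawn later, per sample.
sim_truth <- function(config) {
  n <- config$n_mutations
  seg <- config$segments
  seg_idx <- sample.int(nrow(seg), n, replace = TRUE,
                        prob = as.numeric(seg$end - seg$start + 1))
  pos <- seg$start[seg_idx] +
    floor(runif(n) * as.numeric(seg$end[seg_idx] - seg$start[seg_idx] + 1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  clone_id <- sample.int(nrow(config$clones), n, replace = TRUE,
                         prob = config$clones$fraction)
  consequence <- sample(names(config$consequence_probs), n, replace = TRUE,
                        prob = config$consequence_probs)
  gene <- sprintf("g%06d", seq_len(n))
  truth <- tibble::tibble(
    chrom = seg$chrom[seg_idx], pos = as.integer(pos), ref = ref, alt = alt,
    gene = gene, consequence = consequence,
    clone_id = clone_id, true_ccf = config$clones$ccf[clone_id],
    cn_t = seg$cn_t[seg_idx], cn_n = seg$cn_n[seg_idx],
    multiplicity = 1L)
  truth$key <- mutation_key(truth)
  truth$true_clonal <- truth$true_ccf > 0.95

  # stop-gained mutations yield no mutant peptide; only missense mutations
  # can be neoantigenic
  missense <- truth$consequence == "missense"
  binder <- rep(FALSE, n)
  binder[missense] <- runif(sum(missense)) < config$neoantigen_fraction
  truth$binder <- binder
  truth$expressed <- runif(n) < config$expressed_fraction
  truth$neoantigen <- truth$binder & truth$expressed

  peptides <- tibble::tibble(
    key = truth$key[missense], gene = truth$gene[missense],
    peptide = random_peptide(sum(missense)), mut_offset = 4L)
  ic50 <- numeric(sum(missense))
  b <- binder[missense]
  ic50[b] <- exp(runif(sum(b), log(5), log(500)))
  ic50[!b] <- exp(runif(sum(!b), log(500), log(5e4)))
  allele <- sample(config$alleles, sum(missense), replace = TRUE)
  affinities <- tibble::tibble(peptide = peptides$peptide, allele = allele,
                               ic50_nM = ic50)

  expression <- tibble::tibble(
    gene = truth$gene,
    normalized_count = ifelse(truth$expressed,
                              exp(runif(n, log(6), log(1000))),
                              runif(n, 0, 5)))
  list(truth = truth, peptides = peptides, affinities = affinities,
       expression = expression)
}

draw_reads <- function(truth, config, sample_id, removed = character(0)) {
  n <- nrow(truth)
  depth <- draw_depth(n, config)
  ev <- expected_vaf(truth$true_ccf, config$purity, truth$cn_t, truth$cn_n,
                     truth$multiplicity)
  ev[truth$key %in% removed] <- 0
  tibble::tibble(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    gene = truth$gene, consequence = truth$consequence,
    alt_reads = rbinom(n, depth, ev), total_depth = depth,
    sample_id = sample_id)
}

draw_markers <- function(config, sample_id) {
  n <- config$n_markers
  if (n == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), consequence = character(),
                          alt_reads = integer(), total_depth = integer(),
                          sample_id = character()))
  }
  depth <- draw_depth(n, config)
  # homozygous in the cell line: multiplicity = cn_t = 2, expected VAF = p
  ev <- expected_vaf(1, config$purity, 2, 2, multiplicity = 2)
  tibble::tibble(
    chrom = "chr1", pos = 1000000L + seq_len(n), ref = "A", alt = "G",
    gene = "", consequence = "other",
    alt_reads = rbinom(n, depth, ev), total_depth = depth,
    sample_id = sample_id)
}

#' Simulate one tumor sample with ground truth
#'
#' Draws a full synthetic sample under `config`: per-mutation depth from
#' the depth model and alternate reads from
#' `Binomial(depth, VAF(true CCF, purity, cn_t, cn_n))` at multiplicity 1
#' (homozygous purity markers use multiplicity = cn_t), plus segment,
#' expression, peptide and affinity tables in the package's file formats.
#'
#' @param config A [sim_config()].
#' @param sample_id Sample label.
#' @return A list of class `sim_cohort` with tibbles `mutations`,
#'   `markers`, `segments`, `expression`, `peptides`, `affinities`, `loh`
#'   and `truth`. Fully reproducible from `config$seed`.
#' @export
simulate_sample <- function(config, sample_id = "sample1") {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    parts <- sim_truth(config)
    mutations <- draw_reads(parts$truth, config, sample_id)
    markers <- draw_markers(config, sample_id)
  })
  structure(list(
    mutations = mutations, markers = markers, segments = config$segments,
    expression = parts$expression, peptides = parts$peptides,
    affinities = parts$affinities,
    loh = config$loh %||% tibble::tibble(chrom = character(),
                                         start = integer(), end = integer()),
    truth = parts$truth, config = config
  ), class = "sim_cohort")
}

#' Simulate a baseline/derived sample pair under immunoediting
#'
#' Both samples share one latent truth. The derived sample is generated
#' from the post-editing clone structure: a fraction of the neoantigenic
#' (expressed strong-binder) mutations of the targeted clonality class is
#' removed biologically, so their expected VAF in the derived sample is 0;
#' optional gained mutations are injected as new subclonal variants private
#' to the derived sample.
#'
#' @param config A [sim_config()].
#' @param editing List with `fraction` (of eligible neoantigenic mutations
#'   removed, default 0.3), `target` (`"subclonal"`, `"clonal"` or
#'   `"any"`), and `gain_n` (new subclonal mutations private to the
#'   derived sample, default 0) with `gain_ccf` (their CCF, default 0.2).
#' @param sample_ids Labels for the baseline and derived samples.
#' @return A list of class `sim_pair`: the shared tables of
#'   [simulate_sample()], `mutations` holding both samples stacked, and
#'   `truth` carrying an `edited` flag (and `gained` rows, if any).
#' @export
simulate_pair <- function(config,
                          editing = list(fraction = 0.3, target = "subclonal",
                                         gain_n = 0, gain_ccf = 0.2),
                          sample_ids = c("baseline", "derived")) {
  stopifnot(inherits(config, "sim_config"))
  fraction <- editing$fraction %||% 0.3
  target <- match.arg(editing$target %||% "subclonal",
                      c("subclonal", "clonal", "any"))
  gain_n <- editing$gain_n %||% 0
  gain_ccf <- editing$gain_ccf %||% 0.2
  if (fraction < 0 || fraction > 1) abort("editing fraction must lie in [0, 1]")

  withr::with_seed(config$seed, {
    parts <- sim_truth(config)
    truth <- parts$truth
    eligible <- truth$neoantigen & switch(target,
      subclonal = !truth$true_clonal,
      clonal = truth$true_clonal,
      any = TRUE)
    n_remove <- round(fraction * sum(eligible))
    if (fraction > 0 && sum(eligible) == 0) {
      abort("no neoantigenic mutations of the targeted class to edit")
    }
    removed <- sample(truth$key[eligible], n_remove)
    truth$edited <- truth$key %in% removed

    baseline <- draw_reads(truth, config, sample_ids[1])
    derived <- draw_reads(truth, config, sample_ids[2], removed = removed)
    markers_b <- draw_markers(config, sample_ids[1])
    markers_d <- draw_markers(config, sample_ids[2])

    gained <- NULL
    if (gain_n > 0) {
      gcfg <- config
      gcfg$n_mutations <- as.integer(gain_n)
      gcfg$clones <- tibble::tibble(ccf = gain_ccf, fraction = 1)
      gparts <- sim_truth(gcfg)
      gtruth <- gparts$truth
      gtruth$gene <- sprintf("h%06d", seq_len(gain_n))
      gtruth$key <- mutation_key(gtruth)
      gtruth$edited <- FALSE
      gtruth$binder <- FALSE
      gtruth$expressed <- FALSE
      gtruth$neoantigen <- FALSE
      gained <- gtruth
      derived <- dplyr::bind_rows(derived,
                                  draw_reads(gtruth, gcfg, sample_ids[2]))
      parts$expression <- dplyr::bind_rows(
        parts$expression,
        tibble::tibble(gene = gtruth$gene,
                       normalized_count = runif(gain_n, 0, 5)))
    }
  })
  truth$gained <- FALSE
  if (!is.null(gained)) {
    gained$gained <- TRUE
    truth <- dplyr::bind_rows(truth, gained)
  }
  structure(list(
    mutations = dplyr::bind_rows(baseline, derived),
    markers = dplyr::bind_rows(markers_b, markers_d),
    segments = config$segments, expression = parts$expression,
    peptides = parts$peptides, affinities = parts$affinities,
    loh = config$loh %||% tibble::tibble(chrom = character(),
                                         start = integer(), end = integer()),
    truth = truth, config = config, sample_ids = sample_ids,
    editing = list(fraction = fraction, target = target,
                   n_removed = length(removed), gain_n = gain_n)
  ), class = c("sim_pair", "sim_cohort"))
}

#' Simulate replicate samples with detection dropout
#'
#' Each replicate independently redraws read depths and counts from the
#' shared truth and then drops each mutation with probability `dropout`
#' (failure to detect, independent per mutation and replicate).
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of replicates (default 3).
#' @param dropout Per-mutation, per-replicate detection dropout
#'   probability in \[0, 1).
#' @param group Label prefix; replicates are named `<group>_rep<i>`.
#' @return A list of class `sim_cohort` whose `mutations` table stacks all
#'   replicates.
#' @export
simulate_replicates <- function(config, n_replicates = 3, dropout = 0.1,
                                group = "group") {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1,
            dropout >= 0, dropout < 1)
  withr::with_seed(config$seed, {
    parts <- sim_truth(config)
    reps <- lapply(seq_len(n_replicates), function(i) {
      m <- draw_reads(parts$truth, config, sprintf("%s_rep%d", group, i))
      m[runif(nrow(m)) >= dropout, , drop = FALSE]
    })
    markers <- draw_markers(config, sprintf("%s_rep1", group))
  })
  structure(list(
    mutations = dplyr::bind_rows(reps), markers = markers,
    segments = config$segments, expression = parts$expression,
    peptides = parts$peptides, affinities = parts$affinities,
    loh = config$loh %||% tibble::tibble(chrom = character(),
                                         start = integer(), end = integer()),
    truth = parts$truth, config = config,
    sample_ids = sprintf("%s_rep%d", group, seq_len(n_replicates))
  ), class = "sim_cohort")
}

#' Write a simulated cohort to disk in the package's file formats
#'
#' @param cohort A `sim_cohort` (or `sim_pair`).
#' @param dir Output directory (created if needed).
#' @return Tibble manifest of the written files (file name and md5), also
#'   written as `manifest.tsv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(dir, f)
  write_mutations(cohort$mutations, path("mutations.tsv"))
  write_mutations(cohort$markers, path("markers.tsv"))
  write_segments(cohort$segments, path("segments.tsv"))
  write_expression(cohort$expression, path("expression.tsv"))
  write_affinities(cohort$affinities, path("affinities.tsv"))
  readr::write_tsv(cohort$peptides, path("peptides.tsv"), progress = FALSE)
  write_loh(cohort$loh, path("loh.tsv"))
  readr::write_tsv(cohort$truth, path("ground_truth.tsv"), progress = FALSE)
  files <- c("mutations.tsv", "markers.tsv", "segments.tsv", "expression.tsv",
             "affinities.tsv", "peptides.tsv", "loh.tsv", "ground_truth.tsv")
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))))
  readr::write_tsv(manifest, path("manifest.tsv"), progress = FALSE)
  invisible(manifest)
}
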