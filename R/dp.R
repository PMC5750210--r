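# Dirichlet-process mixture clustering of mutations in CCF space.
#
# Truncated stick-breaking representation with K_max components; cluster
# locations live on the same 100-point CCF grid as the per-mutation
# posteriors and are resampled by grid-Gibbs using the binomial read-count
# likelihood, so the sampler needs no conjugate approximations. One sample
# gives a 1D fit (clonal/subclonal clusters); two samples fitted jointly
# give the 2D cluster-density representation whose diagonal marks shared
# clonal structure.

dp_prepare <- function(x, purity) {
  if (!"sample_id" %in% names(x)) x$sample_id <- "sample1"
  samples <- unique(x$sample_id)
  if (length(samples) > 2) {
    abort("joint DP fits support at most 2 samples; got more sample_id values")
  }
  if (length(samples) == 2) {
    if (!"key" %in% names(x)) {
      abort("a 2-sample fit needs a `key` column aligning mutations across samples")
    }
    wide <- lapply(samples, function(s) {
      xs <- x[x$sample_id == s, , drop = FALSE]
      xs[match(sort(unique(x$key)), xs$key), , drop = FALSE]
    })
    if (anyNA(wide[[1]]$alt_reads) || anyNA(wide[[2]]$alt_reads)) {
      abort(paste0("every mutation must have read counts in both samples; ",
                   "use pair_counts() to encode absences as zero alt reads"))
    }
  } else {
    wide <- list(x)
  }
  if (is.null(names(purity))) {
    purity <- setNames(rep(purity, length.out = length(samples)), samples)
  }
  ll <- lapply(seq_along(samples), function(d) {
    xs <- wide[[d]]
    cn_t <- if ("cn_t" %in% names(xs)) xs$cn_t else rep(2, nrow(xs))
    cn_n <- if ("cn_n" %in% names(xs)) xs$cn_n else rep(2, nrow(xs))
    ccf_loglik_matrix(xs$alt_reads, xs$total_depth, purity[samples[d]], cn_t, cn_n)
  })
  list(loglik = ll, samples = samples,
       keys = if (length(samples) == 2) sort(unique(x$key)) else
         (if ("key" %in% names(x)) x$key else mutation_key(x)))
}

gumbel_argmax <- function(logp) {
  g <- -log(-log(matrix(runif(length(logp)), nrow(logp), ncol(logp))))
  max.col(logp + g, ties.method = "first")
}

#' Fit a Dirichlet-process mixture over mutation CCFs
#'
#' Gibbs sampling under a truncated stick-breaking prior: stick weights
#' `Beta(1, alpha)` with the concentration `alpha` given a `Gamma(1, 1)`
#' prior and resampled each iteration; component locations drawn by
#' grid-Gibbs over the 100-point CCF grid per dimension. The likelihood of
#' mutation *i* in component *k* is the product over sample dimensions of
#' `Binomial(x_id; N_id, VAF(location_kd))` with each mutation's own purity
#' and copy numbers. Components attracting less than `min_weight` of the
#' posterior assignments are dropped and their members reassigned to the
#' nearest retained cluster.
#'
#' @param x Mutation-level tibble with columns `alt_reads`, `total_depth`
#'   and optionally `cn_t`, `cn_n` (default diploid), `key` and
#'   `sample_id`. One `sample_id` (or none) gives a 1D fit; two give a
#'   joint 2D fit, in which every `key` must appear in both samples (use
#'   [pair_counts()] to zero-fill absences).
#' @param purity Tumor purity; scalar or named per `sample_id`.
#' @param iterations,burnin Total Gibbs iterations and burn-in (defaults
#'   2000 / 1000).
#' @param kmax Truncation level of the stick-breaking representation.
#' @param seed RNG seed; the fit is a deterministic function of data + seed.
#' @param min_weight Minimum posterior assignment fraction for a cluster to
#'   be retained.
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @return An object of class `dp_fit` with `$clusters` (tibble: cluster id,
#'   location per dimension, weight, size), `$assignments`, `$alpha`
#'   (posterior mean), stored location/weight samples for density
#'   summaries, and fit metadata.
#' @export
fit_dp <- function(x, purity, iterations = 2000, burnin = 1000, kmax = 20,
                   seed = 17, min_weight = 0.01, thin = 1) {
  if (is.null(x) || nrow(x) == 0) abort("fit_dp needs at least one mutation")
  if (!all(is.finite(x$alt_reads)) || !all(is.finite(x$total_depth))) {
    abort("non-finite read counts in DP input")
  }
  stopifnot(iterations > burnin, kmax >= 2)
  prep <- dp_prepare(x, purity)
  ll <- prep$loglik
  d <- length(ll)
  n <- nrow(ll[[1]])
  G <- length(ccf_grid())

  withr::with_seed(seed, {
    z <- sample.int(kmax, n, replace = TRUE)
    loc <- matrix(sample.int(G, kmax * d, replace = TRUE), kmax, d)
    alpha <- 1
    kept <- floor((iterations - burnin) / thin)
    W <- matrix(0, kept, kmax)
    L <- array(0L, c(kept, kmax, d))
    OCC <- matrix(0, kept, kmax)
    assign_freq <- matrix(0, n, kmax)
    alpha_sum <- 0
    t_keep <- 0L

    for (it in seq_len(iterations)) {
      # stick weights given current occupancy
      nk <- tabulate(z, kmax)
      n_gt <- sum(nk) - cumsum(nk)
      v <- pmin(rbeta(kmax, 1 + nk, alpha + n_gt), 1 - 1e-12)
      v[kmax] <- 1
      logw <- log(v) + c(0, cumsum(log(1 - v[-kmax])))

      # concentration parameter (Gamma(1,1) prior)
      alpha <- rgamma(1, shape = 1 + (kmax - 1),
                      rate = 1 - sum(log(1 - v[seq_len(kmax - 1)])))

      # assignments
      A <- matrix(logw, n, kmax, byrow = TRUE)
      for (dd in seq_len(d)) A <- A + ll[[dd]][, loc[, dd], drop = FALSE]
      z <- gumbel_argmax(A)

      # component locations by grid-Gibbs (uniform prior over the grid)
      for (dd in seq_len(d)) {
        M <- matrix(0, kmax, G)
        S <- rowsum(ll[[dd]], group = z)
        M[as.integer(rownames(S)), ] <- S
        loc[, dd] <- gumbel_argmax(M)
      }

      if (it > burnin && (it - burnin) %% thin == 0) {
        t_keep <- t_keep + 1L
        W[t_keep, ] <- exp(logw)
        L[t_keep, , ] <- loc
        OCC[t_keep, ] <- tabulate(z, kmax)
        assign_freq[cbind(seq_len(n), z)] <- assign_freq[cbind(seq_len(n), z)] + 1
        alpha_sum <- alpha_sum + alpha
      }
    }
  })

  grid <- ccf_grid()
  # posterior-mode assignment per mutation; a component is retained if it
  # holds at least min_weight of the mutations at the mode
  modal <- max.col(assign_freq, ties.method = "first")
  size_frac <- tabulate(modal, kmax) / n
  retained <- which(size_frac >= min_weight)
  if (length(retained) == 0) retained <- which.max(size_frac)

  # occupancy-weighted posterior mean location per retained component
  loc_mean <- sapply(seq_len(d), function(dd) {
    vapply(retained, function(k) {
      w <- OCC[, k]
      if (sum(w) == 0) return(grid[round(mean(L[, k, dd]))])
      sum(grid[L[, k, dd]] * w) / sum(w)
    }, numeric(1))
  })
  loc_mean <- matrix(loc_mean, ncol = d)

  # members of dropped components move to the nearest retained cluster
  # (Euclidean distance in CCF location space)
  assignments <- modal
  dropped <- !(modal %in% retained)
  if (any(dropped)) {
    drop_loc <- sapply(seq_len(d), function(dd) {
      vapply(unique(modal[dropped]), function(k) {
        w <- OCC[, k]
        if (sum(w) == 0) return(grid[round(mean(L[, k, dd]))])
        sum(grid[L[, k, dd]] * w) / sum(w)
      }, numeric(1))
    })
    drop_loc <- matrix(drop_loc, ncol = d)
    rownames(drop_loc) <- unique(modal[dropped])
    for (i in which(dropped)) {
      dist <- rowSums((loc_mean - matrix(drop_loc[as.character(modal[i]), ],
                                         length(retained), d, byrow = TRUE))^2)
      assignments[i] <- retained[which.min(dist)]
    }
  }

  ord <- order(loc_mean[, 1])
  relabel <- match(assignments, retained[ord])
  clusters <- tibble::tibble(cluster = seq_along(retained))
  for (dd in seq_len(d)) {
    nm <- if (d == 1) "location" else paste0("location_", dd)
    clusters[[nm]] <- loc_mean[ord, dd]
  }
  clusters$size <- tabulate(relabel, length(retained))
  clusters$weight <- clusters$size / n

  structure(list(
    clusters = clusters,
    assignments = relabel,
    keys = prep$keys,
    alpha = alpha_sum / max(t_keep, 1),
    samples = list(weights = W, loc_idx = L, occupancy = OCC),
    meta = list(n = n, dims = d, sample_ids = prep$samples,
                iterations = iterations, burnin = burnin, kmax = kmax,
                seed = seed, min_weight = min_weight, thin = thin)
  ), class = "dp_fit")
}

#' @export
print.dp_fit <- function(x, ...) {
  cat(sprintf("Dirichlet-process fit: %d mutation(s), %dD, %d retained cluster(s)\n",
              x$meta$n, x$meta$dims, nrow(x$clusters)))
  print(x$clusters)
  invisible(x)
}

#' @export
tidy.dp_fit <- function(x, ...) x$clusters

#' @export
glance.dp_fit <- function(x, ...) {
  tibble::tibble(n = x$meta$n, dims = x$meta$dims,
                 k_retained = nrow(x$clusters), alpha = x$alpha,
                 iterations = x$meta$iterations, burnin = x$meta$burnin,
                 seed = x$meta$seed)
}

#' Align two samples' read counts for a joint 2D fit
#'
#' Joins two per-sample mutation tables by identity key; a mutation absent
#' from one sample is encoded as zero alternate reads at that sample's
#' local depth (its median observed depth, floored at `min_depth`), so
#' losses remain representable in the joint CCF space.
#'
#' @param baseline,comparison Mutation tibbles for the two samples.
#' @param min_depth Depth floor for zero-filled absences.
#' @return A long tibble (both samples stacked) ready for [fit_dp()].
#' @export
pair_counts <- function(baseline, comparison, min_depth = 30) {
  fill_depth <- function(x) max(min_depth, round(median(x$total_depth)))
  b <- baseline; cmp <- comparison
  b$key <- mutation_key(b); cmp$key <- mutation_key(cmp)
  keys <- sort(unique(c(b$key, cmp$key)))
  complete <- function(x, keys, sample_id) {
    i <- match(keys, x$key)
    out <- tibble::tibble(
      key = keys,
      sample_id = sample_id,
      alt_reads = ifelse(is.na(i), 0L, x$alt_reads[i]),
      total_depth = ifelse(is.na(i), fill_depth(x), x$total_depth[i]),
      cn_t = if ("cn_t" %in% names(x)) ifelse(is.na(i), 2, x$cn_t[i]) else 2,
      cn_n = if ("cn_n" %in% names(x)) ifelse(is.na(i), 2, x$cn_n[i]) else 2
    )
    out
  }
  dplyr::bind_rows(
    complete(b, keys, unique(b$sample_id)[1] %||% "baseline"),
    complete(cmp, keys, unique(cmp$sample_id)[1] %||% "comparison")
  )
}

#' Posterior cluster-location density on the CCF grid
#'
#' Histogram of the stored posterior samples of cluster locations, each
#' weighted by its stick weight, over the 100-point grid (per dimension for
#' 2D fits), normalized to total mass 1. This is the quantity shaded in
#' cluster-density heatmaps: cells of high density mark likely cluster
#' positions, and for a 2D fit of two samples with identical clonal
#' structure the mass concentrates on the leading diagonal.
#'
#' @param fit A `dp_fit`.
#' @return A tibble `ccf, density` (1D) or `ccf_1, ccf_2, density` (2D);
#'   densities are non-negative and sum to 1.
#' @export
density_grid <- function(fit) {
  stopifnot(inherits(fit, "dp_fit"))
  if (is.null(fit$samples)) abort("fit carries no stored posterior samples")
  grid <- ccf_grid()
  G <- length(grid)
  W <- fit$samples$weights
  L <- fit$samples$loc_idx
  if (fit$meta$dims == 1) {
    dens <- numeric(G)
    idx <- as.vector(L[, , 1])
    acc <- rowsum(as.vector(W), group = idx)
    dens[as.integer(rownames(acc))] <- acc
    tibble::tibble(ccf = grid, density = dens / sum(dens))
  } else {
    dens <- matrix(0, G, G)
    cell <- as.vector((L[, , 2] - 1L) * G + L[, , 1])
    acc <- rowsum(as.vector(W), group = cell)
    dens[as.integer(rownames(acc))] <- acc
    tibble::tibble(ccf_1 = rep(grid, times = G), ccf_2 = rep(grid, each = G),
                   density = as.vector(dens) / sum(dens))
  }
}

#' Clonal and subclonal fractions
#'
#' Computes the fraction of clonal vs subclonal mutations either from
#' per-mutation clonality calls (a logical vector or a tibble with a
#' clonality column) or from DP cluster membership, where a cluster is
#' clonal iff its (first-dimension) location is at least 0.95.
#'
#' @param x A logical vector of clonality calls, a tibble with a
#'   `clonal_ci`/`clonal_threshold`/`clonal` column, or a `dp_fit`.
#' @param column Which clonality column to use for tibbles (default
#'   `clonal_ci`, falling back to whichever is present).
#' @return A one-row tibble with `clonal` and `subclonal` fractions summing
#'   to 1.
#' @export
clonal_subclonal_fractions <- function(x, column = NULL) {
  calls <- if (inherits(x, "dp_fit")) {
    loc <- x$clusters[[if (x$meta$dims == 1) "location" else "location_1"]]
    loc[x$assignments] >= 0.95
  } else if (is.data.frame(x)) {
    column <- column %||% intersect(c("clonal_ci", "clonal_threshold", "clonal"),
                                    names(x))[1]
    if (is.na(column)) abort("no clonality column found")
    x[[column]]
  } else {
    as.logical(x)
  }
  if (length(calls) == 0) abort("no clonality calls supplied")
  tibble::tibble(clonal = mean(calls), subclonal = mean(!calls))
}
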