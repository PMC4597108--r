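## Co-occupancy of two peak sets: overlap partitioning, summit-restricted
## overlap, and permutation fold-enrichment against a random-placement null.

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places
#' (the convention used when printing region percentages, e.g.
#' 765/2,610 -> 29.31).
#'
#' @param numerator,denominator numerator and positive denominator.
#' @param decimals decimal places (default 2).
#' @export
percent <- function(numerator, denominator, decimals = 2) {
  if (denominator <= 0) stopf("denominator must be > 0")
  round_half_up(100 * numerator / denominator, decimals)
}

#' Partition peak set A by overlap with peak set B
#'
#' Counts how many distinct A-intervals overlap at least one B-interval by
#' `min_overlap_bp` (an A-interval hit several times counts once), and the
#' complementary A-only count, with the shared percentage at 2 decimals.
#'
#' @param set_a,set_b [peak_set()] objects; A must be non-empty.
#' @param min_overlap_bp minimum overlap in bp (>= 1).
#' @return Object of class `overlap_partition`: `n_a`, `n_b`, `n_shared_a`,
#'   `n_a_only`, `pct_shared_a`, and `shared_index_a` (sorted indices of the
#'   shared A-intervals).
#' @export
overlap_partition <- function(set_a, set_b, min_overlap_bp = 1) {
  n_a <- length(set_a)
  if (n_a == 0) stopf("set A is empty; shared percentage undefined")
  shared <- sort(unique(intersect_peaks(set_a, set_b, min_overlap_bp)$index_a))
  structure(list(n_a = n_a, n_b = length(set_b),
                 n_shared_a = length(shared),
                 n_a_only = n_a - length(shared),
                 pct_shared_a = percent(length(shared), n_a),
                 shared_index_a = shared),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("<overlap_partition: %d/%d A-intervals shared (%.2f%%), %d A-only>\n",
              x$n_shared_a, x$n_a, x$pct_shared_a, x$n_a_only))
  invisible(x)
}

#' Summit-restricted overlap partition
#'
#' Replaces both sets by their summit +/- k bp windows (so two peaks count
#' as shared only when their summits lie within 2k bp of each other) and
#' applies [overlap_partition()]; counts refer to the original intervals.
#'
#' @inheritParams overlap_partition
#' @param k summit half-width in bp (default 6, the direct-overlap criterion).
#' @param genome optional [genome_build()] for window clipping.
#' @export
summit_overlap <- function(set_a, set_b, k = 6, min_overlap_bp = 1,
                           genome = NULL) {
  overlap_partition(summit_window(set_a, k, genome),
                    summit_window(set_b, k, genome), min_overlap_bp)
}

#' Permutation fold-enrichment of peak-set overlap
#'
#' Null-distributes the shared-count statistic by repeatedly relocating set A
#' uniformly at random on the genome ([shuffle_peaks()], length-preserving)
#' while holding set B fixed. Fold enrichment is observed / permutation mean;
#' the empirical p-value uses the add-one estimator
#' `(1 + #{perm >= obs}) / (n_perm + 1)`, which cannot reach zero at finite
#' `n_perm`. Per-iteration seeds are derived from `seed` by a counter scheme,
#' so results do not depend on iteration order and are reproducible.
#'
#' @inheritParams overlap_partition
#' @param genome a [genome_build()].
#' @param n_perm number of random placements (default 10000).
#' @param seed master seed.
#' @return Object of class `enrichment_result`: `observed`, `n_perm`,
#'   `perm_mean`, `perm_sd`, `fold`, `empirical_p`, `seed`.
#' @export
permutation_enrichment <- function(set_a, set_b, genome, n_perm = 10000,
                                   seed = 1, min_overlap_bp = 1) {
  if (n_perm < 1) stopf("n_perm must be >= 1")
  observed <- overlap_partition(set_a, set_b, min_overlap_bp)$n_shared_a
  ## plain vectorised counter for the permutation loop: the statistic is
  ## identical to overlap_partition's n_shared_a, without per-iteration
  ## range-object construction overhead
  b_by_chrom <- split(set_b$intervals[, c("start", "end")],
                      set_b$intervals$chrom)
  count_shared <- function(adf) {
    cnt <- 0L
    for (ch in unique(adf$chrom)) {
      bi <- b_by_chrom[[ch]]
      if (is.null(bi)) next
      sel <- adf$chrom == ch
      as <- adf$start[sel]
      ae <- adf$end[sel]
      shared <- logical(length(as))
      for (k in seq_len(nrow(bi)))
        shared <- shared |
          (pmin(ae, bi$end[k]) - pmax(as, bi$start[k]) >= min_overlap_bp)
      cnt <- cnt + sum(shared)
    }
    cnt
  }
  perm <- vapply(seq_len(n_perm), function(i) {
    sh <- shuffle_peaks(set_a, genome, seed = derive_seed(seed, i))
    as.numeric(count_shared(sh$intervals))
  }, numeric(1))
  perm_mean <- mean(perm)
  fold <- if (perm_mean == 0) {
    warning("permutation mean is 0; fold enrichment reported as Inf")
    Inf
  } else observed / perm_mean
  structure(list(observed = observed, n_perm = n_perm,
                 perm_mean = perm_mean, perm_sd = stats::sd(perm),
                 fold = fold,
                 empirical_p = (1 + sum(perm >= observed)) / (n_perm + 1),
                 seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment: observed %d vs permutation mean %.2f (sd %.2f); %.1f-fold, p = %.4g [%d perms]>\n",
    x$observed, x$perm_mean, x$perm_sd, x$fold, x$empirical_p, x$n_perm))
  invisible(x)
}
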