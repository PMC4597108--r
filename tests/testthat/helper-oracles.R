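## Independent brute-force oracles and fixture builders shared across the
## suite. Oracles deliberately use naive enumeration, not the package's
## algorithms.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

rand_pwm <- function(width, motif_id = "rand") {
  counts <- matrix(sample(0:20, width * 4, replace = TRUE), width, 4)
  pwm_from_counts(counts, pseudocount = 0.5, motif_id = motif_id)
}

rand_peak_df <- function(n, chroms, chrom_len, max_width = 200) {
  w <- sample(10:max_width, n, replace = TRUE)
  st <- vapply(w, function(wi) sample.int(chrom_len - wi, 1), integer(1))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = st, end = st + w,
             name = sprintf("p%03d", seq_len(n)),
             score = round(runif(n, 0, 100), 2),
             summit = floor(w / 2),
             stringsAsFactors = FALSE)
}

## naive per-window rescoring scan (both strands), one window at a time
bf_scan <- function(pwm, sequence, threshold, strands = "both") {
  w <- pwm$width
  lo <- pwm$log_odds
  idx <- match(strsplit(sequence, "")[[1]], BASES)
  comp <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
  n <- length(idx) - w + 1
  starts <- numeric(0); strand <- character(0); score <- numeric(0)
  for (i in seq_len(max(0, n))) {
    win <- idx[i:(i + w - 1)]
    if (anyNA(win)) next
    sf <- 0
    for (j in seq_len(w)) sf <- sf + lo[j, win[j]]
    if (sf >= threshold) {
      starts <- c(starts, i - 1); strand <- c(strand, "+")
      score <- c(score, sf)
    }
    if (strands == "both") {
      rc <- comp[rev(win)]
      sr <- 0
      for (j in seq_len(w)) sr <- sr + lo[j, rc[j]]
      if (sr >= threshold) {
        starts <- c(starts, i - 1); strand <- c(strand, "-")
        score <- c(score, sr)
      }
    }
  }
  out <- data.frame(start = starts, strand = strand, score = score,
                    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

## exact null score distribution by enumerating all 4^w windows, on the
## same rounding grid the package's dynamic programme uses
bf_score_dist <- function(pwm, background = pwm$background,
                          granularity = 1e-3) {
  w <- pwm$width
  r <- round(pwm$log_odds / granularity)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  units <- numeric(nrow(grid))
  probs <- numeric(nrow(grid))
  for (i in seq_len(w)) {
    units <- units + r[i, grid[, i]]
  }
  probs <- apply(grid, 1, function(g) prod(background[g]))
  agg <- tapply(probs, units, sum)
  data.frame(score = as.numeric(names(agg)) * granularity,
             prob = as.numeric(agg))
}

## all-pairs interval intersection
bf_intersect <- function(df_a, df_b, min_ov = 1) {
  rows <- list()
  for (i in seq_len(nrow(df_a))) for (j in seq_len(nrow(df_b))) {
    if (df_a$chrom[i] != df_b$chrom[j]) next
    ov <- min(df_a$end[i], df_b$end[j]) - max(df_a$start[i], df_b$start[j])
    if (ov >= min_ov)
      rows[[length(rows) + 1]] <- data.frame(index_a = i, index_b = j,
                                             overlap_bp = ov)
  }
  if (!length(rows))
    return(data.frame(index_a = integer(), index_b = integer(),
                      overlap_bp = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$index_a, out$index_b), , drop = FALSE]
}

## exhaustive nearest-gene scan for one interval
bf_two_nearest <- function(iv, ann, max_dist = 1e6) {
  smt <- if (!is.na(iv$summit)) iv$start + iv$summit else
    floor((iv$start + iv$end) / 2)
  d <- abs(ann$tss - smt)
  keep <- ann$chrom == iv$chrom & d <= max_dist
  dd <- d[keep]
  ids <- ann$gene_id[keep]
  o <- order(dd, ids)
  o <- o[seq_len(min(2, length(o)))]
  data.frame(gene_id = ids[o], distance_bp = dd[o], stringsAsFactors = FALSE)
}

## two-sided Fisher p by direct enumeration over the hypergeometric support,
## using choose() only
bf_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## scaled-down generator configuration for cheap tests
small_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed,
         chrom_lengths = c(chr1 = 2e5, chr2 = 2e5, chrU = 5e4),
         n_peaks_a = 40, n_peaks_b = 80, shared_fraction = 0.3,
         n_genes_near = 60, n_genes_far = 20, n_de_only = 8),
    list(...))
  do.call(sim_config, args)
}

## threshold strictly between two attainable score values near quantile q,
## so scan/oracle comparisons never sit on a floating-point tie
mid_threshold <- function(scores, q) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(u[1] - 1)
  k <- max(1, min(length(u) - 1, findInterval(quantile(scores, q), u)))
  (u[k] + u[k + 1]) / 2
}

## length-50 sequences each carrying one exact copy of a planted motif
planted_seqs <- function(seed, n = 200, len = 50, motif = "TGACAG") {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    s <- sample(BASES, len, replace = TRUE)
    off <- sample.int(len - nchar(motif) + 1, 1)
    s[off:(off + nchar(motif) - 1)] <- strsplit(motif, "")[[1]]
    paste(s, collapse = "")
  }, character(1))
}

## tiny genome + sequence pair used by classification tests
toy_genome <- function(lens = c(chr1 = 5000, chr2 = 3000)) {
  genome_build(data.frame(chrom = names(lens), length = unname(lens)))
}
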