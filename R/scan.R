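## Log-odds scanning with FIMO-style exact p-value thresholds.

## Encode an ACGTN string as integer codes 1..4 (NA for N / anything else).
encode_dna <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)
}

## Vectorised window scores of a log-odds matrix along an encoded sequence;
## windows touching an NA code score NA and are skipped by callers.
window_scores <- function(lo, codes) {
  w <- nrow(lo)
  n <- length(codes) - w + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (i in seq_len(w)) {
    v <- lo[i, ][codes[i:(i + n - 1)]]
    s <- s + ifelse(is.na(codes[i:(i + n - 1)]), NA, v)
  }
  s
}

#' Scan a sequence with a PWM
#'
#' Scores every w-bp window with the PWM's log-odds matrix (bits) and
#' reports those reaching `score_threshold`. With `strands = "both"` the
#' reverse strand is scored via the reverse-complement motif; positions are
#' always reported in forward-strand coordinates (half-open, relative to the
#' sequence start plus `offset`). Windows containing N are skipped.
#'
#' @param pwm a [pwm_from_counts()] object.
#' @param sequence character string over A,C,G,T,N (or a length-1
#'   `Biostrings::DNAStringSet` element coerced with `as.character`).
#' @param score_threshold minimum log-odds score (bits) to report.
#' @param strands `"both"` (default) or `"forward"`.
#' @param score_dist optional [score_distribution()]. When supplied, match
#'   selection and p-values use the distribution's discretised score grid,
#'   so a threshold from [threshold_for_pvalue()] keeps its exact p-value
#'   semantics; reported scores are the exact (unrounded) log-odds. Without
#'   it, selection compares exact scores directly.
#' @param chrom,offset coordinate frame for reporting: matches get
#'   `chrom` and positions shifted by `offset` bp.
#' @return data.frame with columns `motif_id`, `chrom`, `start`, `end`,
#'   `strand`, `score`, `pvalue` (NA unless `score_dist` given).
#' @export
scan_pwm <- function(pwm, sequence, score_threshold, strands = c("both", "forward"),
                     score_dist = NULL, chrom = NA_character_, offset = 0) {
  strands <- match.arg(strands)
  codes <- encode_dna(as.character(sequence))
  strand_set <- if (strands == "both") c("+", "-") else "+"
  hits <- list()
  for (st in strand_set) {
    lo <- if (st == "+") pwm$log_odds else pwm_revcomp(pwm)$log_odds
    sc <- window_scores(lo, codes)
    if (is.null(score_dist)) {
      keep <- which(!is.na(sc) & sc >= score_threshold)
      pv <- rep(NA_real_, length(keep))
    } else {
      # select on the same discretised grid the null distribution uses
      g <- score_dist$granularity
      units <- window_scores(round(lo / g), codes)
      thr_units <- round(score_threshold / g)
      keep <- which(!is.na(units) & units >= thr_units)
      pv <- tail_at_units(score_dist, units[keep])
    }
    if (length(keep))
      hits[[st]] <- data.frame(start = keep - 1, score = sc[keep],
                               strand = st, pvalue = pv,
                               stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(motif_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      score = numeric(), pvalue = numeric()))
  df <- do.call(rbind, hits)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  out <- data.frame(motif_id = pwm$motif_id, chrom = chrom,
                    start = df$start + offset,
                    end = df$start + offset + pwm$width,
                    strand = df$strand, score = df$score, pvalue = df$pvalue,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## Exact tail probability P(score >= u) for integer-unit scores on the
## distribution's grid.
tail_at_units <- function(dist, units) {
  support_units <- round(dist$support / dist$granularity)
  idx <- findInterval(units - 0.5, support_units) + 1
  out <- numeric(length(units))
  inside <- idx <= length(support_units)
  out[inside] <- dist$tail[idx[inside]]
  out
}

#' Exact null distribution of PWM window scores
#'
#' Distribution of the log-odds score of a single random window drawn from
#' the background model, computed exactly by positional convolution after
#' rounding every log-odds entry to a multiple of `granularity` (bits).
#' This is the standard dynamic programme behind FIMO-style p-values.
#'
#' @param pwm a `pwm`.
#' @param background length-4 probability vector for the null (defaults to
#'   the PWM's own background).
#' @param granularity score rounding step in bits (> 0, default 1e-3).
#' @return Object of class `score_distribution`: support (ascending score
#'   grid values with positive mass), `prob`, and the tail function values.
#' @export
score_distribution <- function(pwm, background = pwm$background,
                               granularity = 1e-3) {
  if (granularity <= 0) stopf("granularity must be > 0")
  r <- round(pwm$log_odds / granularity)   # integer score units per entry
  lo_min <- sum(apply(r, 1, min))
  lo_max <- sum(apply(r, 1, max))
  width <- lo_max - lo_min + 1
  p <- numeric(width)
  # probability vector over achievable integer scores, offset by cur_min
  p[1] <- 1
  cur_min <- 0
  for (i in seq_len(pwm$width)) {
    row <- r[i, ]
    new_min <- cur_min + min(row)
    new <- numeric(length(p) + max(row) - min(row))
    for (j in 1:4) {
      sh <- row[j] - min(row)
      idx <- seq_along(p) + sh
      new[idx] <- new[idx] + p * background[j]
    }
    p <- new
    cur_min <- new_min
  }
  stopifnot(abs(sum(p) - 1) < 1e-9)
  keep <- p > 0
  support_units <- (cur_min + which(keep) - 1)
  structure(list(support = support_units * granularity,
                 prob = p[keep],
                 tail = rev(cumsum(rev(p[keep]))),
                 granularity = granularity),
            class = "score_distribution")
}

#' Score threshold attaining a p-value
#'
#' Smallest score s in the null [score_distribution()] such that
#' P(score >= s) <= p. `p = 1` returns the minimum attainable score. When
#' even the single best outcome has mass above `p`, the returned threshold
#' exceeds the maximum attainable score, so a scan at that threshold reports
#' nothing (documented contract).
#'
#' @param dist a [score_distribution()].
#' @param p target p-value in (0, 1].
#' @return Threshold score in bits.
#' @export
threshold_for_pvalue <- function(dist, p) {
  if (p <= 0 || p > 1) stopf("p must be in (0, 1]")
  ok <- which(dist$tail <= p)
  if (!length(ok)) return(max(dist$support) + dist$granularity)
  dist$support[min(ok)]
}

#' @rdname threshold_for_pvalue
#' @param score numeric vector of observed scores.
#' @return `score_pvalue()`: P(null score >= observed), exact up to the
#'   distribution's rounding granularity.
#' @export
score_pvalue <- function(dist, score) {
  # first support point >= score (within half a granularity step)
  idx <- findInterval(score - dist$granularity / 2, dist$support) + 1
  out <- numeric(length(score))
  inside <- idx <= length(dist$support)
  out[inside] <- dist$tail[idx[inside]]
  out[!inside] <- 0
  out
}

#' Write motif matches to disk
#'
#' `"tsv"` keeps every column including p-values; `"bed6"` writes the
#' standard six columns with the log-odds score (bits) in the score field.
#'
#' @param matches data.frame from [scan_pwm()].
#' @param path output path.
#' @param format `"tsv"` or `"bed6"`.
#' @export
write_matches <- function(matches, path, format = c("tsv", "bed6")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(matches, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(chrom = ifelse(is.na(matches$chrom), ".",
                                     matches$chrom),
                      start = matches$start, end = matches$end,
                      name = matches$motif_id, score = matches$score,
                      strand = matches$strand, stringsAsFactors = FALSE)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Composite (overlapping) sites from two match lists
#'
#' All pairs of matches, one from each list and on the same chromosome
#' and coordinate frame, whose footprints overlap by at least
#' `min_overlap_bp` with |start_b - start_a| at most `max_abs_offset`.
#' This is the geometry of a composite site where two factors' footprints
#' overlap so that simultaneous binding is mutually exclusive.
#'
#' @param matches_a,matches_b data.frames as returned by [scan_pwm()].
#' @param min_overlap_bp minimum footprint overlap (>= 1).
#' @param max_abs_offset maximum |start_b - start_a| (default: width of the
#'   `matches_a` motif, taken from its first row).
#' @return data.frame with one row per composite site: indices into the two
#'   inputs, `overlap_bp`, and signed `offset` (start_b - start_a).
#' @export
detect_composite <- function(matches_a, matches_b, min_overlap_bp = 1,
                             max_abs_offset = NULL) {
  if (min_overlap_bp < 1) stopf("min_overlap_bp must be >= 1")
  empty <- data.frame(index_a = integer(), index_b = integer(),
                      overlap_bp = numeric(), offset = numeric())
  if (!nrow(matches_a) || !nrow(matches_b)) return(empty)
  if (is.null(max_abs_offset))
    max_abs_offset <- matches_a$end[1] - matches_a$start[1]
  g <- expand.grid(index_a = seq_len(nrow(matches_a)),
                   index_b = seq_len(nrow(matches_b)))
  a <- matches_a[g$index_a, ]
  b <- matches_b[g$index_b, ]
  same <- is.na(a$chrom) & is.na(b$chrom) |
    (!is.na(a$chrom) & !is.na(b$chrom) & a$chrom == b$chrom)
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  off <- b$start - a$start
  keep <- same & ov >= min_overlap_bp & abs(off) <= max_abs_offset
  out <- data.frame(index_a = g$index_a[keep], index_b = g$index_b[keep],
                    overlap_bp = ov[keep], offset = off[keep])
  out <- out[order(out$index_a, out$index_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify summit windows by motif occurrence
#'
#' Scans the +/- k bp window around every peak summit with two PWMs (both
#' strands, thresholds set to an exact null p-value) and assigns each region
#' to one of four mutually exclusive classes: `denovo_only`, `selex_only`,
#' `both`, `neither`. The summary reports the marginal percentage of regions
#' carrying each motif (so "de novo present" = both + denovo_only) alongside
#' the partition percentages.
#'
#' @param peaks a [peak_set()] with summits.
#' @param genome_seq named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param pwm_selex,pwm_denovo the two motifs.
#' @param k summit-window half-width in bp (default 25).
#' @param p_threshold exact scan p-value threshold (default 1e-4, the
#'   conventional single-motif scanning default).
#' @param genome optional [genome_build()] for window clipping.
#' @return list with `classes` (data.frame: region, class, hit flags) and
#'   `summary` (counts and percentages, 1 decimal).
#' @export
classify_regions <- function(peaks, genome_seq, pwm_selex, pwm_denovo,
                             k = 25, p_threshold = 1e-4, genome = NULL) {
  seqs <- if (inherits(genome_seq, "DNAStringSet"))
    stats::setNames(as.character(genome_seq), names(genome_seq)) else genome_seq
  missing <- setdiff(unique(peaks$intervals$chrom), names(seqs))
  if (length(missing))
    stopf("region chromosome(s) absent from genome sequence: %s",
          paste(missing, collapse = ", "))
  win <- summit_window(peaks, k, genome = genome)$intervals
  dist_s <- score_distribution(pwm_selex)
  dist_d <- score_distribution(pwm_denovo)
  thr_s <- threshold_for_pvalue(dist_s, p_threshold)
  thr_d <- threshold_for_pvalue(dist_d, p_threshold)
  n <- nrow(win)
  hit_s <- hit_d <- logical(n)
  for (i in seq_len(n)) {
    subseq <- substr(seqs[[win$chrom[i]]], win$start[i] + 1, win$end[i])
    hit_s[i] <- nrow(scan_pwm(pwm_selex, subseq, thr_s,
                              score_dist = dist_s)) > 0
    hit_d[i] <- nrow(scan_pwm(pwm_denovo, subseq, thr_d,
                              score_dist = dist_d)) > 0
  }
  cls <- ifelse(hit_d & hit_s, "both",
         ifelse(hit_d, "denovo_only",
         ifelse(hit_s, "selex_only", "neither")))
  counts <- vapply(c("denovo_only", "selex_only", "both", "neither"),
                   function(cl) sum(cls == cl), integer(1))
  summary <- list(
    n = n,
    counts = counts,
    pct = vapply(counts, function(x) percent(x, n, 1), numeric(1)),
    pct_denovo = percent(sum(hit_d), n, 1),
    pct_selex = percent(sum(hit_s), n, 1),
    pct_both = percent(counts[["both"]], n, 1))
  list(classes = data.frame(region = seq_len(n), class = cls,
                            hit_denovo = hit_d, hit_selex = hit_s,
                            stringsAsFactors = FALSE),
       summary = summary)
}
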