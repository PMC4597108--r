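## Interval data model and interval-level operations.
##
## Coordinates are 0-based half-open throughout (BED convention): an interval
## [start, end) covers bases start .. end-1. A narrowPeak summit is a 0-based
## offset from `start`; NA means "no summit recorded", in which case the
## midpoint floor((start+end)/2) is used wherever a summit position is needed.

#' Construct a peak set
#'
#' A peak set is a labelled, sorted collection of genomic intervals with
#' optional name, score, and summit-offset columns. It is the unit of all
#' overlap, shuffling, and classification analyses in this package.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `summit` (0-based offset from `start`,
#'   NA when absent). Coordinates are 0-based half-open.
#' @param label free-text label for the set.
#' @param genome optional [genome_build()]; when supplied, coordinates are
#'   validated against chromosome bounds.
#' @return An object of class `peak_set` with elements `label` and
#'   `intervals` (sorted by chrom, start, end).
#' @examples
#' ps <- peak_set(data.frame(chrom = "chr1", start = 0, end = 100))
#' @export
peak_set <- function(intervals, label = "peaks", genome = NULL) {
  stopifnot(is.data.frame(intervals))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(intervals)))
    stopf("interval table needs columns chrom, start, end")
  n <- nrow(intervals)
  df <- data.frame(chrom = as.character(intervals$chrom),
                   start = as.numeric(intervals$start),
                   end = as.numeric(intervals$end),
                   name = if ("name" %in% names(intervals))
                     as.character(intervals$name) else rep(NA_character_, n),
                   score = if ("score" %in% names(intervals))
                     as.numeric(intervals$score) else rep(NA_real_, n),
                   summit = if ("summit" %in% names(intervals))
                     as.numeric(intervals$summit) else rep(NA_real_, n),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0)) stopf("negative start coordinate")
    bad <- which(df$start >= df$end)
    if (length(bad)) stopf("start >= end for interval %d", bad[1])
    s <- !is.na(df$summit)
    if (any(df$summit[s] < 0 | df$summit[s] >= (df$end - df$start)[s]))
      stopf("summit offset outside interval")
    if (!is.null(genome)) {
      if (any(df$end > chrom_length(genome, df$chrom)))
        stopf("interval end beyond chromosome length")
    }
    df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    if (anyDuplicated(df[, c("chrom", "start", "end", "name", "score", "summit")]))
      stopf("duplicate intervals in peak set")
  }
  structure(list(label = label, intervals = df), class = "peak_set")
}

## Internal constructor skipping the duplicate check (shuffled placements may
## legitimately coincide).
new_peak_set <- function(df, label) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(label = label, intervals = df), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set '%s': %d intervals on %d chromosome(s)>\n",
              x$label, nrow(x$intervals), length(unique(x$intervals$chrom))))
  invisible(x)
}

#' @export
length.peak_set <- function(x) nrow(x$intervals)

## Resolved summit positions (absolute bp) for every interval; midpoint
## fallback when no summit is recorded.
summit_positions <- function(peaks) {
  df <- peaks$intervals
  pos <- df$start + df$summit
  mid <- floor((df$start + df$end) / 2)
  ifelse(is.na(pos), mid, pos)
}

#' Read a BED-family peak file
#'
#' Supports three dialects: `bed3` (chrom, start, end), `bed6` (+ name,
#' score, strand), and ENCODE `narrowPeak` (10 columns; column 10 is the
#' 0-based summit offset, -1 meaning "none"). Coordinates are kept 0-based
#' half-open. Malformed lines raise an error naming the line number.
#'
#' @param path file path.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @param label label for the returned set (defaults to the file name).
#' @return A [peak_set()].
#' @export
read_bed <- function(path, dialect = c("narrowPeak", "bed3", "bed6"),
                     label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(peak_set(data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric()), label))
  ncol_need <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L)[[dialect]]
  fields <- strsplit(lines, "[ \t]+")
  n <- lengths(fields)
  if (any(n < ncol_need))
    stopf("line %d: expected %d columns for dialect '%s', found %d",
          which(n < ncol_need)[1], ncol_need, dialect, n[which(n < ncol_need)[1]])
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_need)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stopf("line %d: non-numeric coordinates", bad[1])
  bad <- which(start >= end | start < 0)
  if (length(bad)) stopf("line %d: invalid interval (start >= end or negative)",
                         bad[1])
  df <- data.frame(chrom = m[, 1], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (dialect %in% c("bed6", "narrowPeak")) {
    df$name <- m[, 4]
    df$score <- suppressWarnings(as.numeric(m[, 5]))
  }
  if (dialect == "narrowPeak") {
    smt <- suppressWarnings(as.numeric(m[, 10]))
    bad <- which(is.na(smt))
    if (length(bad)) stopf("line %d: non-numeric summit column", bad[1])
    df$summit <- ifelse(smt < 0, NA_real_, smt)
  }
  peak_set(df, label = label)
}

#' Write a peak set to a BED-family file
#'
#' Inverse of [read_bed()]: fields a dialect cannot carry are dropped
#' (bed3 keeps coordinates only; bed6 adds name/score; narrowPeak also
#' carries the summit, written as -1 when absent). Round-trips losslessly
#' for every field the dialect can represent.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @param dialect as in [read_bed()].
#' @export
write_bed <- function(peaks, path, dialect = c("narrowPeak", "bed3", "bed6")) {
  dialect <- match.arg(dialect)
  df <- peaks$intervals
  fmt_num <- function(x) {
    out <- formatC(x, format = "fg", digits = 15)
    out[is.na(x)] <- "0"
    trimws(out)
  }
  base <- cbind(df$chrom, fmt_num(df$start), fmt_num(df$end))
  lines <- switch(dialect,
    bed3 = base,
    bed6 = cbind(base, ifelse(is.na(df$name), ".", df$name),
                 fmt_num(df$score), "."),
    narrowPeak = cbind(base, ifelse(is.na(df$name), ".", df$name),
                       fmt_num(df$score), ".", "0", "-1", "-1",
                       ifelse(is.na(df$summit), "-1", fmt_num(df$summit))))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df)) writeLines(apply(lines, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Window around an interval's summit
#'
#' Returns the closed +/- k bp neighbourhood of each summit as a half-open
#' interval [summit - k, summit + k + 1), clipped to chromosome bounds when a
#' genome is supplied (and to zero always). Intervals without a recorded
#' summit use their midpoint. Width is at most 2k + 1.
#'
#' @param peaks a [peak_set()] (or single-interval data.frame).
#' @param k non-negative half-width in bp.
#' @param genome optional [genome_build()] used for right-edge clipping.
#' @return A [peak_set()] of summit windows, in the input's order-preserving
#'   sorted frame; names/scores are carried over.
#' @export
summit_window <- function(peaks, k, genome = NULL) {
  if (k < 0) stopf("k must be >= 0")
  df <- peaks$intervals
  pos <- summit_positions(peaks)
  start <- pmax(0, pos - k)
  end <- pos + k + 1
  if (!is.null(genome)) end <- pmin(end, chrom_length(genome, df$chrom))
  out <- data.frame(chrom = df$chrom, start = start, end = end,
                    name = df$name, score = df$score,
                    summit = pos - start, stringsAsFactors = FALSE)
  new_peak_set(out, label = sprintf("%s:summit+/-%d", peaks$label, k))
}

as_granges <- function(peaks) {
  df <- peaks$intervals
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' All overlapping interval pairs between two peak sets
#'
#' Complete list of (index in A, index in B, overlap bp) pairs with overlap
#' of at least `min_overlap_bp`; an interval may appear in several pairs.
#' Indices refer to the sorted order of each set.
#'
#' @param set_a,set_b [peak_set()] objects.
#' @param min_overlap_bp minimum overlap in bp (>= 1).
#' @return data.frame with columns `index_a`, `index_b`, `overlap_bp`.
#' @export
intersect_peaks <- function(set_a, set_b, min_overlap_bp = 1) {
  if (min_overlap_bp < 1) stopf("min_overlap_bp must be >= 1")
  if (!length(set_a) || !length(set_b))
    return(data.frame(index_a = integer(), index_b = integer(),
                      overlap_bp = numeric()))
  ga <- as_granges(set_a)
  gb <- as_granges(set_b)
  # sets with disjoint chromosome sets are a legitimate zero-overlap case;
  # silence the seqlevel-mismatch warning findOverlaps emits for them
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap_bp))
  qa <- S4Vectors::queryHits(hits)
  qb <- S4Vectors::subjectHits(hits)
  ov <- suppressWarnings(
    GenomicRanges::width(GenomicRanges::pintersect(ga[qa], gb[qb])))
  o <- order(qa, qb)
  data.frame(index_a = qa[o], index_b = qb[o], overlap_bp = as.numeric(ov[o]))
}

#' Length-preserving random relocation of a peak set
#'
#' Each interval is placed independently and uniformly over all feasible
#' positions in the genome: a chromosome is drawn with probability
#' proportional to (chrom length - interval length + 1) and the start
#' uniformly within the feasible range. Placements may overlap each other and
#' the original locations; the interval count and length multiset are
#' preserved exactly. Deterministic given `seed`.
#'
#' @param peaks a [peak_set()].
#' @param genome a [genome_build()].
#' @param seed integer seed (the caller's RNG state is untouched).
#' @return A [peak_set()] of relocated intervals.
#' @export
shuffle_peaks <- function(peaks, genome, seed) {
  df <- peaks$intervals
  if (!nrow(df)) return(new_peak_set(df, peaks$label))
  len <- df$end - df$start
  L <- genome$chroms$length
  if (any(len > max(L)))
    stopf("interval longer than every chromosome (length %d)", max(len))
  with_seed(seed, {
    out <- df
    for (grp in split(seq_len(nrow(df)), len)) {
      l <- len[grp[1]]
      w <- pmax(0, L - l + 1)
      ci <- sample.int(length(L), length(grp), replace = TRUE, prob = w)
      # floor(runif) rather than sample() keeps start uniform for huge ranges
      st <- floor(stats::runif(length(grp), min = 0, max = w[ci]))
      st <- pmin(st, w[ci] - 1)   # guard the measure-zero right edge
      out$chrom[grp] <- genome$chroms$chrom[ci]
      out$start[grp] <- st
      out$end[grp] <- st + l
    }
    new_peak_set(out, label = sprintf("%s:shuffled", peaks$label))
  })
}

#' Gene annotation table
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss` (bp
#'   position), `strand` ("+"/"-"); gene ids must be unique.
#' @param genome optional [genome_build()] for bounds validation.
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, genome = NULL) {
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(genes))) stopf("annotation needs columns %s",
                                          paste(need, collapse = ", "))
  df <- data.frame(gene_id = as.character(genes$gene_id),
                   chrom = as.character(genes$chrom),
                   tss = as.numeric(genes$tss),
                   strand = as.character(genes$strand),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stopf("duplicated gene_id in annotation")
  if (!all(df$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (!is.null(genome) &&
      any(df$tss < 0 | df$tss >= chrom_length(genome, df$chrom)))
    stopf("TSS outside chromosome bounds")
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' @rdname gene_annotation
#' @param path four-column tab-separated file (gene_id, chrom, tss, strand).
#' @export
read_gene_annotation <- function(path, genome = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  gene_annotation(df, genome = genome)
}

#' @rdname gene_annotation
#' @param annotation a `gene_annotation`.
#' @export
write_gene_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Two nearest genes within a distance cutoff
#'
#' For one interval, the (at most two) annotated genes on the same chromosome
#' whose TSS lies within `max_dist` of the interval's summit (midpoint when no
#' summit is recorded), sorted by distance with lexicographic gene-id
#' tie-break. With `mode = "edge"` the distance is measured from the interval
#' body instead (0 for a TSS inside the interval).
#'
#' @param interval single-row interval data.frame (chrom/start/end/summit) or
#'   a one-interval [peak_set()].
#' @param annotation a [gene_annotation()].
#' @param max_dist maximum distance in bp (default 1 Mb).
#' @param mode `"summit"` (default) or `"edge"`.
#' @return data.frame with columns `gene_id`, `distance_bp` (0-2 rows,
#'   distances non-decreasing).
#' @export
two_nearest_genes <- function(interval, annotation, max_dist = 1e6,
                              mode = c("summit", "edge")) {
  mode <- match.arg(mode)
  if (inherits(interval, "peak_set")) interval <- interval$intervals
  stopifnot(nrow(interval) == 1)
  if (!nrow(annotation)) stopf("annotation is empty")
  same <- annotation[annotation$chrom == interval$chrom, , drop = FALSE]
  if (!nrow(same))
    return(data.frame(gene_id = character(), distance_bp = numeric()))
  if (mode == "summit") {
    smt <- if (!is.null(interval$summit) && !is.na(interval$summit))
      interval$start + interval$summit else floor((interval$start + interval$end) / 2)
    d <- abs(same$tss - smt)
  } else {
    d <- pmax(0, pmax(interval$start - same$tss,
                      same$tss - (interval$end - 1)))
  }
  keep <- d <= max_dist
  same <- same[keep, , drop = FALSE]
  d <- d[keep]
  o <- order(d, same$gene_id)
  o <- o[seq_len(min(2, length(o)))]
  data.frame(gene_id = same$gene_id[o], distance_bp = d[o],
             stringsAsFactors = FALSE)
}
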