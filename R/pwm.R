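## Position weight matrices: probability + log-odds representation over the
## DNA alphabet A,C,G,T, with an explicit background model.

DNA_BASES <- c("A", "C", "G", "T")

new_pwm <- function(probs, motif_id, background) {
  colnames(probs) <- DNA_BASES
  structure(list(motif_id = motif_id,
                 width = nrow(probs),
                 probs = probs,
                 background = stats::setNames(background, DNA_BASES),
                 log_odds = log2(sweep(probs, 2, background, "/"))),
            class = "pwm")
}

#' Build a PWM from a count matrix
#'
#' Standard pseudocount-regularised construction:
#' `prob[i,j] = (count[i,j] + pc * bg[j]) / (rowsum + pc)`, i.e. the
#' pseudocount mass is distributed proportionally to the background. The
#' log-odds matrix is `log2(prob / bg)`.
#'
#' @param counts w x 4 non-negative matrix (columns A,C,G,T).
#' @param pseudocount total pseudocount mass per position (> 0, default 0.1).
#' @param background length-4 probability vector (default uniform).
#' @param motif_id identifier carried through match reports.
#' @return An object of class `pwm` with elements `motif_id`, `width`,
#'   `probs`, `background`, `log_odds`.
#' @examples
#' pwm_from_counts(matrix(c(10, 0, 0, 0), 1), pseudocount = 1)$probs
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.1,
                            background = rep(0.25, 4), motif_id = "motif") {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) stopf("counts must have 4 columns (A,C,G,T)")
  if (any(counts < 0)) stopf("negative counts")
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0))
    stopf("background must be a positive probability vector")
  probs <- sweep(counts, 2, pseudocount * background, "+") /
    (rowSums(counts) + pseudocount)
  new_pwm(probs, motif_id, background)
}

#' @rdname pwm_from_counts
#' @param probs w x 4 row-stochastic probability matrix (no zero entries
#'   after regularisation expected by downstream log-odds scoring).
#' @export
pwm_from_probs <- function(probs, background = rep(0.25, 4),
                           motif_id = "motif") {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stopf("probs must have 4 columns")
  if (any(abs(rowSums(probs) - 1) > 1e-9)) stopf("rows must sum to 1")
  if (any(probs <= 0)) stopf("zero probabilities; add a pseudocount first")
  new_pwm(probs, motif_id, background)
}

#' Sharp PWM from a consensus string
#'
#' Convenience constructor used by the synthetic-data generator and tests: a
#' count matrix with `nsites` observations of the consensus base per
#' position, regularised by [pwm_from_counts()]. With the defaults the
#' consensus scores far above any mismatched window.
#'
#' @param consensus string over ACGT.
#' @inheritParams pwm_from_counts
#' @param nsites pseudo-observation count per position.
#' @export
pwm_from_consensus <- function(consensus, nsites = 100, pseudocount = 0.1,
                               background = rep(0.25, 4),
                               motif_id = consensus) {
  b <- strsplit(toupper(consensus), "")[[1]]
  if (!all(b %in% DNA_BASES)) stopf("consensus must be over ACGT")
  counts <- matrix(0, length(b), 4, dimnames = list(NULL, DNA_BASES))
  counts[cbind(seq_along(b), match(b, DNA_BASES))] <- nsites
  pwm_from_counts(counts, pseudocount, background, motif_id)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm '%s': width %d, consensus %s>\n",
              x$motif_id, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus string of a PWM (most probable base per position)
#' @param pwm a `pwm`.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 1, which.max)], collapse = "")
}

## PWM for the reverse-complement motif: reverse positions, swap A<->T, C<->G.
pwm_revcomp <- function(pwm) {
  probs <- pwm$probs[rev(seq_len(pwm$width)), c("T", "G", "C", "A"),
                     drop = FALSE]
  new_pwm(probs, paste0(pwm$motif_id, "_rc"),
          unname(pwm$background[c("T", "G", "C", "A")]))
}

pwm_max_score <- function(pwm) sum(apply(pwm$log_odds, 1, max))

## Total information content in bits (relative entropy to background).
pwm_information <- function(pwm) {
  sum(pwm$probs * (log2(pwm$probs) -
                     rep(log2(pwm$background), each = pwm$width)))
}

#' Read / write a PWM as a plain probability-matrix TSV
#'
#' Tab-separated with header `A C G T`, one row per motif position. A
#' leading `# <id>` comment line carries the motif id.
#'
#' @param path file path.
#' @param background background vector attached on read (default uniform).
#' @param pseudocount small mass mixed in on read so log-odds are finite.
#' @return `read_pwm_matrix()` returns a `pwm`.
#' @export
read_pwm_matrix <- function(path, background = rep(0.25, 4),
                            pseudocount = 1e-4) {
  lines <- readLines(path)
  id <- if (grepl("^#", lines[1])) trimws(sub("^#", "", lines[1])) else
    basename(path)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   comment.char = "#"))
  m <- (m + pseudocount * rep(background, each = nrow(m))) / (1 + pseudocount)
  new_pwm(m / rowSums(m), id, background)
}

#' @rdname read_pwm_matrix
#' @param pwm a `pwm`.
#' @export
write_pwm_matrix <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", pwm$motif_id), con)
  writeLines(paste(DNA_BASES, collapse = "\t"), con)
  writeLines(apply(pwm$probs, 1, function(r)
    paste(sprintf("%.6f", r), collapse = "\t")), con)
  invisible(path)
}

#' Read / write PWMs in MEME minimal text format
#'
#' The minimal format: a `MEME version` header, alphabet, background letter
#' frequencies, then one `MOTIF` block per matrix with a
#' `letter-probability matrix:` line followed by w rows of 4 probabilities.
#'
#' @param path file path.
#' @param pseudocount small mass mixed in on read so log-odds are finite.
#' @return `read_meme()` returns a named list of `pwm` objects.
#' @export
read_meme <- function(path, pseudocount = 1e-4) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) && bgl[1] < length(lines)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1]), "[ \t]+")[[1]]
    if (length(tok) >= 8) bg <- as.numeric(tok[c(2, 4, 6, 8)])
  }
  starts <- grep("^MOTIF ", lines)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "[ \t]+")[[1]][2]
    h <- s + grep("letter-probability matrix", lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "[ \t]+"), as.numeric))
    m <- (m + pseudocount * rep(bg, each = w)) / (1 + pseudocount)
    out[[id]] <- new_pwm(m / rowSums(m), id, bg)
  }
  out
}

#' @rdname read_meme
#' @param pwms a `pwm` or list of `pwm` objects (shared background assumed).
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$width), con)
    writeLines(apply(p$probs, 1, function(r) paste(sprintf("%.6f", r),
                                                   collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
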