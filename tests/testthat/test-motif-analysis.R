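test_that("PWM construction follows the pseudocount formula", {
  p <- pwm_from_counts(matrix(c(10, 0, 0, 0), 1), pseudocount = 1,
                       motif_id = "x")
  expect_equal(unname(p$probs[1, "A"]), 10.25 / 11)
  flat <- pwm_from_counts(matrix(5, 3, 4))
  expect_equal(unname(flat$log_odds), matrix(0, 3, 4))
  set.seed(1)
  r <- rand_pwm(6)
  expect_equal(unname(rowSums(r$probs)), rep(1, 6))
  expect_error(pwm_from_counts(matrix(-1, 1, 4)), "negative")
})

test_that("consensus scan hits exactly once on forward and reverse strands", {
  p <- pwm_from_consensus("TCAAGTG")
  maxs <- sum(apply(p$log_odds, 1, max))
  hit <- scan_pwm(p, "TCAAGTG", maxs)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 0)
  expect_equal(hit$strand, "+")
  rc <- scan_pwm(p, revcomp_chr("TCAAGTG"), maxs)
  expect_equal(rc$strand, "-")
  # forward-only scanning ignores the reverse-strand site
  expect_equal(nrow(scan_pwm(p, revcomp_chr("TCAAGTG"), maxs,
                             strands = "forward")), 0L)
  # too-short sequences yield an empty list, not an error
  expect_equal(nrow(scan_pwm(p, "ACGT", -100)), 0L)
  # windows containing N are never scored
  expect_equal(nrow(scan_pwm(p, "TCANGTG", -100)), 0L)
})

test_that("scan equals naive per-window rescoring on random sequences", {
  set.seed(61)
  for (rep in 1:5) {
    w <- sample(5:8, 1)
    p <- rand_pwm(w)
    s <- rand_dna(500)
    all_scores <- bf_scan(p, s, -Inf)$score
    thr <- mid_threshold(all_scores, 0.9)
    got <- scan_pwm(p, s, thr)
    want <- bf_scan(p, s, thr)
    expect_equal(got[, c("start", "strand", "score")], want,
                 ignore_attr = TRUE)
  }
})

test_that("scanning is reverse-complement symmetric", {
  set.seed(62)
  p <- rand_pwm(6)
  s <- rand_dna(300)
  a <- scan_pwm(p, s, 2)
  b <- scan_pwm(p, revcomp_chr(s), 2)
  # positions mirror: start' = len - end, strands swap
  expect_equal(sort(nchar(s) - a$end), sort(b$start))
  expect_equal(sort(a$score), sort(b$score))
})

test_that("exact score distribution matches enumeration of all windows", {
  # single-position case with closed-form masses
  p1 <- pwm_from_probs(matrix(c(1/2, 1/6, 1/6, 1/6), 1), motif_id = "w1")
  d1 <- score_distribution(p1)
  expect_equal(length(d1$support), 2L)
  expect_equal(sort(d1$prob), c(1/4, 3/4))
  expect_equal(sum(d1$prob), 1)

  set.seed(71)
  for (w in 5:7) {
    p <- rand_pwm(w)
    d <- score_distribution(p)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    bf <- bf_score_dist(p)
    expect_equal(d$support, bf$score, tolerance = 1e-12)
    expect_lt(sum(abs(d$prob - bf$prob)) / 2, 1e-9)  # total variation
  }
})

test_that("p-value thresholds bound the null tail as tightly as possible", {
  set.seed(72)
  p <- rand_pwm(5)
  d <- score_distribution(p)
  expect_equal(threshold_for_pvalue(d, 1), min(d$support))
  # demanding more than the best single outcome -> unattainable threshold
  tiny <- min(d$prob) / 10
  thr <- threshold_for_pvalue(d, tiny)
  expect_gt(thr, max(d$support))
  expect_equal(nrow(scan_pwm(p, rand_dna(200), thr, score_dist = d)), 0L)
  # enumeration check: achieved tail <= p, and one grid step lower exceeds p
  bf <- bf_score_dist(p)
  for (pv in c(0.01, 0.05, 0.2)) {
    thr <- threshold_for_pvalue(d, pv)
    achieved <- sum(bf$prob[bf$score >= thr - 1e-12])
    expect_lte(achieved, pv)
    below <- bf$score < thr - 1e-12
    if (any(below))
      expect_gt(achieved + bf$prob[max(which(below))], pv)
  }
})

test_that("composite-site detection equals the all-pairs filter", {
  ma <- data.frame(motif_id = "a", chrom = "chr1", start = 10, end = 17,
                   strand = "+", score = 1, pvalue = NA)
  mb <- data.frame(motif_id = "b", chrom = "chr1", start = 13, end = 19,
                   strand = "+", score = 1, pvalue = NA)
  cs <- detect_composite(ma, mb)
  expect_equal(cs$overlap_bp, 4)
  expect_equal(cs$offset, 3)
  mb_far <- transform(mb, start = 40, end = 46)
  expect_equal(nrow(detect_composite(ma, mb_far)), 0L)
  expect_error(detect_composite(ma, mb, min_overlap_bp = 0), "min_overlap_bp")

  set.seed(81)
  mk <- function(n, w) {
    st <- sample.int(200, n)
    data.frame(motif_id = "m", chrom = sample(c("chr1", "chr2"), n, TRUE),
               start = st, end = st + w, strand = "+", score = 0, pvalue = NA)
  }
  a <- mk(30, 7); b <- mk(30, 6)
  got <- detect_composite(a, b, min_overlap_bp = 2, max_abs_offset = 5)
  manual <- list()
  for (i in 1:30) for (j in 1:30) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    off <- b$start[j] - a$start[i]
    if (ov >= 2 && abs(off) <= 5)
      manual[[length(manual) + 1]] <- data.frame(index_a = i, index_b = j,
                                                 overlap_bp = ov, offset = off)
  }
  manual <- do.call(rbind, manual)
  manual <- manual[order(manual$index_a, manual$index_b), ]
  expect_equal(got, manual, ignore_attr = TRUE)
})

test_that("summit-window classification separates the four motif classes", {
  set.seed(91)
  gb <- toy_genome(c(chr1 = 4000))
  sel <- pwm_from_consensus("TCAAGTG", motif_id = "selex")
  den <- pwm_from_consensus("TGAAGTGACAG", motif_id = "denovo")
  seq <- strsplit(rand_dna(4000), "")[[1]]
  plant <- function(pos, s) seq[(pos + 1):(pos + nchar(s))] <<- strsplit(s, "")[[1]]
  # four peaks, one per class, summits at 500/1500/2500/3500
  plant(495, "TGAAGTGACAG")              # denovo_only
  plant(1497, "TCAAGTG")                 # selex_only
  plant(2480, "TCAAGTG"); plant(2504, "TGAAGTGACAG")  # both
  peaks <- peak_set(data.frame(chrom = "chr1",
                               start = c(400, 1400, 2400, 3400),
                               end = c(600, 1600, 2600, 3600),
                               summit = 100))
  cl <- classify_regions(peaks, c(chr1 = paste(seq, collapse = "")),
                         sel, den, genome = gb)
  expect_equal(cl$classes$class,
               c("denovo_only", "selex_only", "both", "neither"))
  expect_equal(unname(cl$summary$counts), rep(1L, 4))
  expect_equal(sum(cl$summary$counts), cl$summary$n)
  expect_equal(cl$summary$pct_denovo, 50)  # both + denovo_only
  expect_equal(cl$summary$pct_selex, 50)
  expect_error(classify_regions(
    peak_set(data.frame(chrom = "chrX", start = 1, end = 100, summit = 50)),
    c(chr1 = "ACGT"), sel, den), "chrX")
})

test_that("matrix-TSV PWM and match outputs round-trip", {
  set.seed(96)
  p <- rand_pwm(6, "mx")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pwm_matrix(p, path)
  back <- read_pwm_matrix(path)
  expect_equal(back$motif_id, "mx")
  expect_equal(unname(back$probs), unname(p$probs), tolerance = 1e-3)

  m <- scan_pwm(p, rand_dna(300), -5, chrom = "chr1")
  tsv <- withr::local_tempfile(); bed <- withr::local_tempfile()
  write_matches(m, tsv, "tsv")
  write_matches(m, bed, "bed6")
  back_tsv <- read.table(tsv, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  expect_equal(back_tsv$start, m$start)
  back_bed <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(back_bed), nrow(m))
  expect_equal(back_bed$V6, m$strand)
  expect_equal(back_bed$V5, m$score, tolerance = 1e-12)
})

test_that("MEME minimal format round-trips probabilities and background", {
  set.seed(95)
  pwms <- list(a = rand_pwm(5, "a"), b = rand_pwm(8, "b"))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_equal(names(back), c("a", "b"))
  for (id in names(pwms)) {
    expect_equal(unname(back[[id]]$probs), unname(pwms[[id]]$probs),
                 tolerance = 1e-3)
    expect_equal(back[[id]]$width, pwms[[id]]$width)
  }
})
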