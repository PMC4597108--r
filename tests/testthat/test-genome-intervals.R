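test_that("BED round-trips are lossless for every field a dialect carries", {
  set.seed(11)
  df <- rand_peak_df(100, c("chr1", "chr2"), 5000)
  ps <- peak_set(df, "rt")
  for (dialect in c("bed3", "bed6", "narrowPeak")) {
    path <- withr::local_tempfile(fileext = ".bed")
    write_bed(ps, path, dialect)
    back <- read_bed(path, dialect, label = "rt")
    expect_equal(back$intervals[, c("chrom", "start", "end")],
                 ps$intervals[, c("chrom", "start", "end")])
    if (dialect %in% c("bed6", "narrowPeak")) {
      expect_equal(back$intervals$name, ps$intervals$name)
      expect_equal(back$intervals$score, ps$intervals$score)
    } else {
      expect_true(all(is.na(back$intervals$name)))
    }
    if (dialect == "narrowPeak")
      expect_equal(back$intervals$summit, ps$intervals$summit)
    else
      expect_true(all(is.na(back$intervals$summit)))
  }
})

test_that("narrowPeak summit -1 maps to absent; empty files round-trip", {
  path <- withr::local_tempfile()
  writeLines("chr1\t100\t300\tpk\t5\t.\t0\t-1\t-1\t25", path)
  ps <- read_bed(path, "narrowPeak")
  expect_equal(ps$intervals$summit, 25)
  writeLines("chr1\t100\t300\tpk\t5\t.\t0\t-1\t-1\t-1", path)
  expect_true(is.na(read_bed(path, "narrowPeak")$intervals$summit))

  empty <- peak_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric()))
  write_bed(empty, path, "bed3")
  expect_equal(length(read_bed(path, "bed3")), 0L)
})

test_that("malformed BED lines raise errors naming the line", {
  path <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100", "chr1\t200\t100"), path)
  expect_error(read_bed(path, "bed3"), "line 2")
  writeLines(c("chr1\t0\t100", "chr1\t50"), path)
  expect_error(read_bed(path, "bed3"), "line 2")
  writeLines("chr1\tzero\t100", path)
  expect_error(read_bed(path, "bed3"), "line 1")
})

test_that("summit windows follow the +/-k arithmetic and clip at edges", {
  ps <- peak_set(data.frame(chrom = "chr1", start = 100, end = 300,
                            summit = 50))
  w <- summit_window(ps, 25)$intervals
  expect_equal(c(w$start, w$end), c(125, 176))
  w0 <- summit_window(ps, 0)$intervals
  expect_equal(c(w0$start, w0$end), c(150, 151))

  gb <- toy_genome(c(chr1 = 155))
  near_start <- peak_set(data.frame(chrom = "chr1", start = 0, end = 10,
                                    summit = 3))
  wc <- summit_window(near_start, 6, gb)$intervals
  expect_equal(wc$start, 0)  # clipped left
  near_end <- peak_set(data.frame(chrom = "chr1", start = 140, end = 155,
                                  summit = 12))
  we <- summit_window(near_end, 6, gb)$intervals
  expect_equal(we$end, 155)  # clipped right
  # midpoint fallback when no summit is recorded
  nos <- peak_set(data.frame(chrom = "chr1", start = 10, end = 21))
  expect_equal(summit_window(nos, 2)$intervals$start, 15 - 2)
})

test_that("summit window width never exceeds 2k+1 and attains it off-edge", {
  set.seed(21)
  gb <- toy_genome()
  df <- rand_peak_df(50, c("chr1", "chr2"), 3000)
  for (k in c(0, 6, 25)) {
    w <- summit_window(peak_set(df), k, gb)$intervals
    expect_true(all(w$end - w$start <= 2 * k + 1))
    interior <- w$start > 0 &
      w$end < ifelse(w$chrom == "chr1", 5000, 3000)
    expect_true(all((w$end - w$start)[interior] == 2 * k + 1))
  }
})

test_that("intersection matches the all-pairs oracle and is symmetric", {
  a <- peak_set(data.frame(chrom = "chr1", start = 0, end = 10))
  b <- peak_set(data.frame(chrom = "chr1", start = 9, end = 20))
  expect_equal(intersect_peaks(a, b),
               data.frame(index_a = 1L, index_b = 1L, overlap_bp = 1))
  b2 <- peak_set(data.frame(chrom = "chr2", start = 0, end = 10))
  expect_equal(nrow(intersect_peaks(a, b2)), 0L)
  expect_error(intersect_peaks(a, b, min_overlap_bp = 0), "min_overlap_bp")

  set.seed(31)
  for (rep in 1:3) {
    da <- peak_set(rand_peak_df(50, c("chr1", "chr2"), 10000))$intervals
    db <- peak_set(rand_peak_df(50, c("chr1", "chr2"), 10000))$intervals
    for (mo in c(1, 5)) {
      got <- intersect_peaks(peak_set(da), peak_set(db), mo)
      want <- bf_intersect(da, db, mo)
      expect_equal(got, want, ignore_attr = TRUE)
      # symmetry up to index swap
      rev <- intersect_peaks(peak_set(db), peak_set(da), mo)
      rev2 <- rev[order(rev$index_b, rev$index_a),
                  c("index_b", "index_a", "overlap_bp")]
      names(rev2) <- names(got)
      expect_equal(got, rev2, ignore_attr = TRUE)
    }
  }
})

test_that("shuffling preserves count and length multiset, is seed-exact, and forced placements land at 0", {
  gb <- genome_build(data.frame(chrom = "chr1", length = 50))
  one <- peak_set(data.frame(chrom = "chr1", start = 0, end = 50))
  sh <- shuffle_peaks(one, gb, seed = 3)
  expect_equal(sh$intervals$start, 0)  # only one feasible placement

  gb2 <- toy_genome()
  set.seed(41)
  ps <- peak_set(rand_peak_df(40, c("chr1", "chr2"), 3000))
  for (seed in c(1, 99)) {
    sh <- shuffle_peaks(ps, gb2, seed)
    expect_equal(length(sh), length(ps))
    expect_equal(sort(sh$intervals$end - sh$intervals$start),
                 sort(ps$intervals$end - ps$intervals$start))
    expect_identical(sh, shuffle_peaks(ps, gb2, seed))
  }
  too_long <- peak_set(data.frame(chrom = "chr1", start = 0, end = 6000))
  expect_error(shuffle_peaks(too_long, gb2, 1), "longer than every chromosome")
})

test_that("shuffled starts are uniform over the feasible range", {
  gb <- genome_build(data.frame(chrom = "chr1", length = 100))
  ps <- peak_set(data.frame(chrom = "chr1", start = 0, end = 10))
  starts <- vapply(1:20000, function(s)
    shuffle_peaks(ps, gb, seed = s)$intervals$start, numeric(1))
  expect_true(all(starts >= 0 & starts <= 90))
  tab <- tabulate(starts + 1, 91)
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 1e-3)
})

test_that("two nearest genes match the exhaustive scan with deterministic ties", {
  ann <- gene_annotation(data.frame(
    gene_id = c("gA", "gB", "gC"), chrom = "chr1",
    tss = c(1510, 1520, 1530), strand = "+"))
  iv <- peak_set(data.frame(chrom = "chr1", start = 1000, end = 2000,
                            summit = 500))
  got <- two_nearest_genes(iv, ann)
  expect_equal(got$gene_id, c("gA", "gB"))
  expect_equal(got$distance_bp, c(10, 20))
  # lexicographic tie-break at equal distance
  ann_tie <- gene_annotation(data.frame(
    gene_id = c("gZ", "gA", "gM"), chrom = "chr1",
    tss = c(1490, 1510, 1700), strand = "+"))
  expect_equal(two_nearest_genes(iv, ann_tie)$gene_id, c("gA", "gZ"))
  # out-of-range and wrong-chromosome genes are excluded
  far <- gene_annotation(data.frame(gene_id = "gF", chrom = "chr2",
                                    tss = 1500, strand = "+"))
  expect_equal(nrow(two_nearest_genes(iv, far)), 0L)

  set.seed(51)
  ann_r <- gene_annotation(data.frame(
    gene_id = sprintf("g%03d", 1:200),
    chrom = sample(c("chr1", "chr2"), 200, TRUE),
    tss = sample.int(3000, 200), strand = "+"))
  peaks <- peak_set(rand_peak_df(50, c("chr1", "chr2"), 3000))
  for (i in seq_len(50)) {
    iv_i <- peaks$intervals[i, , drop = FALSE]
    got <- two_nearest_genes(iv_i, ann_r, max_dist = 800)
    want <- bf_two_nearest(iv_i, ann_r, max_dist = 800)
    expect_equal(got, want, ignore_attr = TRUE)
    expect_lte(nrow(got), 2)
    if (nrow(got) == 2) expect_lte(got$distance_bp[1], got$distance_bp[2])
  }
})

test_that("interval and annotation validation rejects inconsistent input", {
  expect_error(peak_set(data.frame(chrom = "chr1", start = 10, end = 10)),
               "start >= end")
  expect_error(peak_set(data.frame(chrom = "chr1", start = 0, end = 10,
                                   summit = 10)), "summit")
  gb <- toy_genome(c(chr1 = 100))
  expect_error(peak_set(data.frame(chrom = "chr1", start = 0, end = 200),
                        genome = gb), "beyond chromosome")
  expect_error(gene_annotation(data.frame(gene_id = c("a", "a"),
                                          chrom = "chr1", tss = 1:2,
                                          strand = "+")), "duplicated")
})
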