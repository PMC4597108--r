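test_that("DE filtering keeps the inclusive fold-change boundary", {
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   log2fc = c(log2(1.5), 0.3, -log2(1.5), -2),
                   adj_p = c(0.01, 0.01, 0.2, 0.001),
                   direction = c("up", "up", "down", "down"),
                   stringsAsFactors = FALSE)
  kept <- filter_de(de, min_fc = 1.5)
  expect_equal(kept$gene_id, c("g1", "g3", "g4"))
  kept2 <- filter_de(de, min_fc = 1.5, max_adj_p = 0.05)
  expect_equal(kept2$gene_id, c("g1", "g4"))
  # min_fc = 1 and max_adj_p = 1 is the identity
  expect_equal(filter_de(de, min_fc = 1, max_adj_p = 1), de)

  set.seed(111)
  big <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    log2fc = round(runif(200, -2, 2), 3),
                    adj_p = round(runif(200), 3),
                    stringsAsFactors = FALSE)
  got <- filter_de(big, min_fc = 1.5, max_adj_p = 0.1)$gene_id
  want <- big$gene_id[vapply(seq_len(200), function(i)
    abs(big$log2fc[i]) >= log2(1.5) - 1e-12 && big$adj_p[i] <= 0.1,
    logical(1))]
  expect_equal(got, want)
})

test_that("target assignment deduplicates genes across supporting peaks", {
  ann <- gene_annotation(data.frame(gene_id = "gShared", chrom = "chr1",
                                    tss = 1000, strand = "+"))
  peaks <- peak_set(data.frame(chrom = "chr1", start = c(500, 1400),
                               end = c(700, 1600), summit = 100))
  ta <- assign_targets(peaks, ann)
  expect_equal(ta$genes, "gShared")
  expect_equal(unname(ta$support["gShared"]), 2)
  expect_equal(nrow(ta$assignments), 2L)
})

test_that("direct-target intersection obeys set arithmetic and Venn identities", {
  de <- data.frame(gene_id = c("g2", "g3"), log2fc = c(1, -1),
                   adj_p = c(0.01, 0.01), direction = c("up", "down"),
                   stringsAsFactors = FALSE)
  dt <- direct_targets(c("g1", "g2"), de)
  expect_equal(dt$table$gene_id, "g2")
  expect_equal(dt$table$direction, "up")
  expect_equal(unname(dt$venn), c(1, 1, 1))

  none <- direct_targets(c("gA", "gB"), de)
  expect_equal(none$n_total, 0L)

  set.seed(112)
  for (rep in 1:5) {
    bound <- sample(sprintf("g%02d", 1:40), 15)
    de_r <- data.frame(gene_id = sample(sprintf("g%02d", 1:40), 20),
                       log2fc = runif(20, -2, 2), adj_p = runif(20, 0, 0.01),
                       stringsAsFactors = FALSE)
    de_r$direction <- ifelse(de_r$log2fc > 0, "up", "down")
    dt_r <- direct_targets(bound, de_r)
    expect_equal(unname(dt_r$venn["bound_only"] + dt_r$venn["shared"]),
                 length(bound))
    expect_equal(unname(dt_r$venn["de_only"] + dt_r$venn["shared"]),
                 nrow(de_r))
    expect_equal(dt_r$n_down + dt_r$n_up, dt_r$n_total)
  }
})

test_that("direction fractions are percentages of the target total", {
  mk <- function(n_down, n_up) {
    de <- data.frame(gene_id = sprintf("g%02d", seq_len(n_down + n_up)),
                     log2fc = c(rep(-1, n_down), rep(1, n_up)),
                     adj_p = 0.001, stringsAsFactors = FALSE)
    de$direction <- ifelse(de$log2fc > 0, "up", "down")
    direct_targets(de$gene_id, de)
  }
  expect_equal(unname(direction_fractions(mk(1, 1))), c(50, 50))
  expect_equal(unname(direction_fractions(mk(3, 1))), c(75, 25))
  expect_equal(unname(direction_fractions(mk(172, 137))), c(55.7, 44.3))
  expect_error(direction_fractions(direct_targets("gX",
    data.frame(gene_id = "gY", log2fc = 1, adj_p = 0, direction = "up"))),
    "empty")
})

test_that("two-sided Fisher p agrees with stats::fisher.test and enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_two_tailed, 1)
  extreme <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(extreme$p_two_tailed, 2 / choose(20, 10))
  expect_equal(extreme$odds_ratio, Inf)

  set.seed(113)
  for (i in 1:100) {
    m <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (min(rowSums(m)) == 0 || min(colSums(m)) == 0) next
    got <- fisher_exact_2x2(m)
    expect_equal(got$p_two_tailed, fisher.test(m)$p.value, tolerance = 1e-9)
    expect_equal(got$p_two_tailed,
                 bf_fisher_p(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-12)
    expect_equal(got$odds_ratio,
                 if (m[1, 2] * m[2, 1] == 0) {
                   if (m[1, 1] * m[2, 2] == 0) NA_real_ else Inf
                 } else (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]))
    # invariance to simultaneous row and column swaps
    swapped <- fisher_exact_2x2(m[2:1, 2:1])
    expect_equal(swapped$p_two_tailed, got$p_two_tailed, tolerance = 1e-12)
  }
  expect_warning(z <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_equal(z$p_two_tailed, 1)
})

test_that("category analysis flags a planted chamber-down bias with power", {
  set.seed(114)
  make_targets <- function() {
    cats <- c(rep("chamber", 50), rep("AVC", 50), rep("pan", 50))
    down_p <- ifelse(cats == "chamber", 0.8, 0.5)
    down <- runif(150) < down_p
    de <- data.frame(gene_id = sprintf("g%03d", 1:150),
                     log2fc = ifelse(down, -1, 1), adj_p = 0.001,
                     stringsAsFactors = FALSE)
    de$direction <- ifelse(down, "down", "up")
    list(targets = direct_targets(de$gene_id, de),
         map = data.frame(gene_id = de$gene_id, category = cats,
                          stringsAsFactors = FALSE))
  }
  flagged <- 0
  for (r in 1:100) {
    x <- make_targets()
    res <- category_direction_analysis(x$targets, x$map)$per_category
    p_chamber <- res$p[res$category == "chamber"]
    flagged <- flagged + (p_chamber < 0.05)
  }
  expect_gte(flagged, 90)
})

test_that("category analysis handles identical splits, exclusions, and empties", {
  de <- data.frame(gene_id = sprintf("g%02d", 1:8),
                   log2fc = rep(c(-1, 1), 4), adj_p = 0.001,
                   stringsAsFactors = FALSE)
  de$direction <- ifelse(de$log2fc > 0, "up", "down")
  dt <- direct_targets(de$gene_id, de)
  map <- data.frame(gene_id = sprintf("g%02d", 1:8),
                    category = rep(c("AVC", "chamber"), each = 4),
                    stringsAsFactors = FALSE)
  res <- category_direction_analysis(dt, map)
  expect_true(all(res$per_category$p == 1))  # identical down/up splits
  # an uncategorised gene is excluded and counted
  map2 <- map[-1, ]
  expect_message(res2 <- category_direction_analysis(dt, map2), "without a category")
  expect_equal(res2$n_uncategorized, 1L)
  # an empty category is skipped with a warning
  map3 <- transform(map, category = ifelse(gene_id == "g01", "ghost",
                                           category))
  map3$category[1] <- "AVC"
  map3 <- rbind(map3, data.frame(gene_id = "gZZ", category = "ghost"))
  expect_warning(category_direction_analysis(dt, map3), "ghost")
})

test_that("enhancer-validation comparison reproduces closed-form Fisher results", {
  eq <- enhancer_validation_compare(c(5, 10), c(5, 10))
  expect_equal(eq$pct_a, 50)
  expect_equal(eq$fisher$p_two_tailed, 1)
  ext <- enhancer_validation_compare(c(10, 10), c(0, 10))
  expect_equal(c(ext$pct_a, ext$pct_b), c(100, 0))
  expect_equal(ext$fisher$p_two_tailed, 2 / choose(20, 10))
  # illustrative reconstruction at 100-per-group denominators
  rec <- enhancer_validation_compare(c(83, 100), c(58, 100))
  expect_equal(c(rec$pct_a, rec$pct_b), c(83, 58))
  expect_lt(rec$fisher$p_two_tailed, 0.0007)
  expect_error(enhancer_validation_compare(c(5, 0), c(1, 2)), "tested")
})
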