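## Peak-to-gene target assignment, intersection with differential expression,
## and 2x2 exact contingency analyses.

#' Assign each peak its two nearest genes
#'
#' Applies [two_nearest_genes()] to every interval of a peak set and returns
#' the per-region assignments together with the union of assigned gene ids
#' (each gene counted once however many peaks support it).
#'
#' @param peaks a [peak_set()].
#' @param annotation a [gene_annotation()].
#' @param max_dist maximum summit-to-TSS distance in bp (default 1 Mb).
#' @param mode distance mode, see [two_nearest_genes()].
#' @return Object of class `target_assignment`: `assignments` (data.frame
#'   region / gene_id / distance_bp), `genes` (unique gene ids), `n_genes`,
#'   and `support` (peaks per gene).
#' @export
assign_targets <- function(peaks, annotation, max_dist = 1e6,
                           mode = c("summit", "edge")) {
  mode <- match.arg(mode)
  df <- peaks$intervals
  per <- lapply(seq_len(nrow(df)), function(i) {
    g <- two_nearest_genes(df[i, , drop = FALSE], annotation, max_dist, mode)
    if (nrow(g)) cbind(region = i, g) else NULL
  })
  assignments <- do.call(rbind, per)
  if (is.null(assignments))
    assignments <- data.frame(region = integer(), gene_id = character(),
                              distance_bp = numeric())
  genes <- sort(unique(assignments$gene_id))
  structure(list(assignments = assignments, genes = genes,
                 n_genes = length(genes),
                 support = table(assignments$gene_id)),
            class = "target_assignment")
}

#' @export
print.target_assignment <- function(x, ...) {
  cat(sprintf("<target_assignment: %d peak-gene links, %d unique genes>\n",
              nrow(x$assignments), x$n_genes))
  invisible(x)
}

#' Read a differential-expression table
#'
#' Tab-separated with header columns `gene_id`, `log2fc`, `adj_p`.
#' Malformed rows raise an error naming the row.
#'
#' @param path file path.
#' @return data.frame with a `direction` column derived from sign(log2fc)
#'   ("up" / "down"; exact zeros are kept with direction NA).
#' @export
read_de_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "adj_p")
  if (!all(need %in% names(df)))
    stopf("DE table needs columns %s", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$log2fc) | is.na(df$adj_p) |
                 df$adj_p < 0 | df$adj_p > 1)
  if (length(bad)) stopf("DE table row %d: invalid log2fc or adj_p", bad[1])
  df$direction <- ifelse(df$log2fc > 0, "up",
                         ifelse(df$log2fc < 0, "down", NA))
  df
}

#' Filter differential-expression calls
#'
#' Keeps records with fold change at least `min_fc` in either direction
#' (|log2fc| >= log2(min_fc), boundary inclusive) and, when `max_adj_p` is
#' supplied, adjusted p at most `max_adj_p`.
#'
#' @param de data.frame as from [read_de_table()].
#' @param min_fc minimum linear fold change (default 1.5).
#' @param max_adj_p optional adjusted-p cutoff.
#' @export
filter_de <- function(de, min_fc = 1.5, max_adj_p = NULL) {
  keep <- abs(de$log2fc) >= log2(min_fc) - 1e-12
  if (!is.null(max_adj_p)) keep <- keep & de$adj_p <= max_adj_p
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Direct targets: bound genes intersected with differential expression
#'
#' A direct target is a gene both assigned to at least one peak and present
#' in the filtered DE table. Returns one row per gene with its direction and
#' the number of supporting peaks, plus totals and the three Venn counts.
#'
#' @param bound either a [assign_targets()] result or a character vector of
#'   bound gene ids.
#' @param filtered_de data.frame of DE records surviving [filter_de()].
#' @return Object of class `direct_target_table`: `table` (gene_id,
#'   direction, log2fc, adj_p, n_supporting_regions), `n_total`, `n_down`,
#'   `n_up`, and `venn` = c(bound_only, shared, de_only).
#' @export
direct_targets <- function(bound, filtered_de) {
  if (inherits(bound, "target_assignment")) {
    genes <- bound$genes
    support <- bound$support
  } else {
    genes <- sort(unique(as.character(bound)))
    support <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  }
  de <- filtered_de[!duplicated(filtered_de$gene_id), , drop = FALSE]
  shared <- intersect(genes, de$gene_id)
  tab <- de[match(shared, de$gene_id),
            c("gene_id", "direction", "log2fc", "adj_p"), drop = FALSE]
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  tab$n_supporting_regions <- as.integer(support[tab$gene_id])
  rownames(tab) <- NULL
  structure(list(table = tab,
                 n_total = nrow(tab),
                 n_down = sum(tab$direction == "down", na.rm = TRUE),
                 n_up = sum(tab$direction == "up", na.rm = TRUE),
                 venn = c(bound_only = length(genes) - length(shared),
                          shared = length(shared),
                          de_only = nrow(de) - length(shared))),
            class = "direct_target_table")
}

#' @export
print.direct_target_table <- function(x, ...) {
  cat(sprintf("<direct_targets: %d genes (%d down, %d up); venn %d/%d/%d>\n",
              x$n_total, x$n_down, x$n_up,
              x$venn[1], x$venn[2], x$venn[3]))
  invisible(x)
}

#' Down/up percentages of a direct-target table
#'
#' @param targets a [direct_targets()] result.
#' @return c(pct_down, pct_up) at 1 decimal (half-up).
#' @export
direction_fractions <- function(targets) {
  if (targets$n_total == 0) stopf("empty direct-target table")
  c(pct_down = percent(targets$n_down, targets$n_total, 1),
    pct_up = percent(targets$n_up, targets$n_total, 1))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p by hypergeometric enumeration at fixed margins: the two-sided
#' p-value is the total probability of all tables with the same margins
#' whose probability does not exceed that of the observed table (the
#' standard exact convention; alternatives such as doubling the one-sided
#' tail exist and give different values). The odds ratio is the sample
#' ratio a*d / (b*c), reported as Inf when b*c = 0 (NA when both diagonals
#' vanish). A zero margin makes every table with those margins certain, so
#' p is defined as 1 (with a warning).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return Object of class `contingency_result`: `table`, `odds_ratio`,
#'   `p_two_tailed`.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m)))
    stopf("need a 2x2 table of non-negative integers")
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  or <- if (b * c_ == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c_)
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    warning("a margin of the 2x2 table is 0; p defined as 1")
    p <- 1
  } else {
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(support, r1, r2, c1)
    p_obs <- stats::dhyper(a, r1, r2, c1)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  structure(list(table = m, odds_ratio = or, p_two_tailed = p),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<fisher 2x2: OR = %.3g, two-tailed p = %.4g>\n",
              x$odds_ratio, x$p_two_tailed))
  invisible(x)
}

#' Direction-by-category exact tests
#'
#' Splits a direct-target table by an expression-domain category map (e.g.
#' atrioventricular canal / working-chamber / pan-myocardial) and, for each
#' category, tests direction against all other categorised targets with a
#' two-sided Fisher test. Uncategorised targets are excluded (their count is
#' reported); empty categories are skipped with a warning. Raw p-values are
#' reported with a Benjamini-Hochberg adjusted column alongside.
#'
#' @param targets a [direct_targets()] result.
#' @param category_map data.frame with columns `gene_id`, `category`.
#' @return list with `per_category` (data.frame: category, n_down, n_up,
#'   pct_down, odds_ratio, p, p_bh) and `n_uncategorized`.
#' @export
category_direction_analysis <- function(targets, category_map) {
  tab <- targets$table
  cat_of <- category_map$category[match(tab$gene_id, category_map$gene_id)]
  drop_n <- sum(is.na(cat_of))
  if (drop_n) message(sprintf("%d target(s) without a category excluded",
                              drop_n))
  keep <- !is.na(cat_of)
  tab <- tab[keep, , drop = FALSE]
  cat_of <- cat_of[keep]
  cats <- sort(unique(category_map$category))
  rows <- lapply(cats, function(cl) {
    inside <- cat_of == cl
    if (!any(inside)) {
      warning(sprintf("category '%s' is empty; skipped", cl))
      return(NULL)
    }
    n_down <- sum(tab$direction[inside] == "down")
    n_up <- sum(inside) - n_down
    rest_down <- sum(tab$direction[!inside] == "down")
    rest_up <- sum(!inside) - rest_down
    fr <- fisher_exact_2x2(matrix(c(n_down, rest_down, n_up, rest_up), 2))
    data.frame(category = cl, n_down = n_down, n_up = n_up,
               pct_down = percent(n_down, n_down + n_up, 1),
               odds_ratio = fr$odds_ratio, p = fr$p_two_tailed,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (!is.null(per)) per$p_bh <- stats::p.adjust(per$p, method = "BH")
  list(per_category = per, n_uncategorized = drop_n)
}

#' Compare enhancer-validation rates between two region groups
#'
#' Given (active, tested) counts for two groups of regions assayed for
#' enhancer activity, builds the 2x2 active/inactive-by-group table, and
#' returns both percentages (0 decimals) with the two-sided Fisher result.
#'
#' @param group_a,group_b integer vectors c(n_active, n_tested).
#' @return list: `pct_a`, `pct_b`, `fisher` (a [fisher_exact_2x2()] result).
#' @export
enhancer_validation_compare <- function(group_a, group_b) {
  for (g in list(group_a, group_b)) {
    if (length(g) != 2 || g[2] <= 0 || g[1] < 0 || g[1] > g[2])
      stopf("each group must be c(n_active, n_tested) with 0 <= active <= tested > 0")
  }
  tab <- matrix(c(group_a[1], group_b[1],
                  group_a[2] - group_a[1], group_b[2] - group_b[1]), 2,
                dimnames = list(c("A", "B"), c("active", "inactive")))
  list(pct_a = percent(group_a[1], group_a[2], 0),
       pct_b = percent(group_b[1], group_b[2], 0),
       fisher = fisher_exact_2x2(tab))
}

#' @rdname gene_annotation
#' @export
read_category_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(df)))
    stopf("category map needs columns gene_id, category")
  df
}
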