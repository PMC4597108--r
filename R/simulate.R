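## Synthetic-data generator: a small multi-chromosome genome with motif
## instances planted at peak summits, paired peak sets with a controlled
## shared fraction and summit jitter, a gene annotation, expression
## categories, and a differential-expression table -- together with a
## machine-readable truth record so every downstream stage has an exact
## expected output.

#' Simulation configuration
#'
#' Defaults define the study conditions the generator emulates: a ~6 Mb
#' genome, 261 A-peaks against 600 B-peaks with shared fraction 0.2931 (a
#' tenth-scale rendition of a 2,610-peak ChIP experiment with 29.31% shared
#' occupancy), a planted motif-class mix of 50/40/5/5
#' (denovo_only/selex_only/both/neither), summit jitter of sd 20 bp among
#' shared peaks so the summit +/- 6 bp criterion separates direct from
#' merely proximal co-binding, and a DE table in which 30% of bound genes
#' are dysregulated with fold changes >= 1.5 and adjusted p < 0.01 while all
#' other genes carry sub-threshold noise.
#'
#' @param seed master seed; all randomness in [simulate_dataset()] derives
#'   from it.
#' @param chrom_lengths named vector of chromosome lengths (bp); the
#'   chromosome named in `desert_chrom` carries genes but no peaks, so its
#'   genes can never be within range of a peak.
#' @param desert_chrom name of the peak-free chromosome.
#' @param background genome base composition (A,C,G,T).
#' @param selex_consensus,meis_consensus core consensus strings for the two
#'   factors.
#' @param denovo_selex_like degraded selex half-site forming the 5' part of
#'   the hybrid (de novo) motif; it should differ from `selex_consensus`
#'   (default: one substitution) so that regions planted with the hybrid do
#'   not also carry an exact selex site.
#' @param hybrid_overlap_bp bases shared between the 3' end of
#'   `denovo_selex_like` and the MEIS 5' end in the hybrid motif (the two
#'   must agree there); the hybrid is their overlap-merge, so its 3'
#'   portion is exactly the MEIS site while its 5' resembles the selex
#'   site.
#' @param nsites,pseudocount sharpness of the generated PWMs
#'   (see [pwm_from_consensus()]).
#' @param n_peaks_a,n_peaks_b sizes of the two peak sets.
#' @param shared_fraction fraction f of A-peaks overlapping B (exactly
#'   round-half-up(f * n_peaks_a) after rounding, recorded in truth).
#' @param peak_width_a,peak_width_b interval widths (bp).
#' @param min_gap,edge_margin minimum gap between A-peaks and clearance from
#'   chromosome ends (bp); chosen so jittered partners and +/-25 bp summit
#'   windows never collide across peaks.
#' @param summit_jitter_sd sd (bp) of the Normal summit offset between a
#'   shared B-peak and its A partner, truncated so intervals still overlap.
#' @param class_mix proportions of the four motif classes planted at A-peak
#'   summits (denovo_only, selex_only, both, neither).
#' @param n_genes_near,n_genes_far genes placed on peak chromosomes /
#'   on the desert chromosome.
#' @param frac_bound_de fraction of bound genes planted as direct targets.
#' @param n_de_only number of desert genes given strong DE calls (DE-only
#'   arm of the Venn diagram).
#' @param frac_down down-direction probability for DE-only genes.
#' @param category_mix,down_bias expression-domain category proportions over
#'   AVC / chamber / pan and the per-category probability that a planted
#'   target is downregulated (defaults give an expected overall down
#'   fraction of about 0.57).
#' @param lfc_shape,lfc_rate gamma parameters of the log2 fold-change
#'   magnitude in excess of log2(1.5).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 1.5e6, chr2 = 1.5e6,
                                         chr3 = 1.5e6, chr4 = 1.5e6,
                                         chrU = 2e5),
                       desert_chrom = "chrU",
                       background = rep(0.25, 4),
                       selex_consensus = "TCAAGTG",
                       meis_consensus = "TGACAG",
                       denovo_selex_like = "TGAAGTG",
                       hybrid_overlap_bp = 2,
                       nsites = 100, pseudocount = 0.1,
                       n_peaks_a = 261, n_peaks_b = 600,
                       shared_fraction = 0.2931,
                       peak_width_a = 250, peak_width_b = 250,
                       min_gap = 400, edge_margin = 300,
                       summit_jitter_sd = 20,
                       class_mix = c(denovo_only = 0.50, selex_only = 0.40,
                                     both = 0.05, neither = 0.05),
                       n_genes_near = 200, n_genes_far = 60,
                       frac_bound_de = 0.3, n_de_only = 20,
                       frac_down = 0.556,
                       category_mix = c(AVC = 0.30, chamber = 0.35,
                                        pan = 0.35),
                       down_bias = c(AVC = 0.50, chamber = 0.75,
                                     pan = 0.45),
                       lfc_shape = 2, lfc_rate = 4) {
  cfg <- as.list(environment())
  if (is.null(names(chrom_lengths)) || !desert_chrom %in% names(chrom_lengths))
    stopf("chrom_lengths must be named and include desert_chrom")
  if (shared_fraction < 0 || shared_fraction > 1)
    stopf("shared_fraction must be in [0, 1]")
  if (abs(sum(class_mix) - 1) > 1e-9 || abs(sum(category_mix) - 1) > 1e-9)
    stopf("class_mix and category_mix must each sum to 1")
  ov <- hybrid_overlap_bp
  w_s <- nchar(denovo_selex_like)
  if (ov < 1 || ov >= min(w_s, nchar(meis_consensus)))
    stopf("hybrid_overlap_bp must be in [1, min motif width)")
  if (substr(denovo_selex_like, w_s - ov + 1, w_s) !=
      substr(meis_consensus, 1, ov))
    stopf("denovo 5' half's 3' end and MEIS 5' end must agree over the hybrid overlap")
  cfg$hybrid_consensus <- paste0(denovo_selex_like,
                                 substr(meis_consensus, ov + 1,
                                        nchar(meis_consensus)))
  structure(cfg, class = "sim_config")
}

## Non-overlapping sorted starts: n intervals of width w with gaps >= gap,
## margins at both ends, uniformly among feasible sorted configurations.
place_sorted <- function(n, chrom_len, w, gap, margin) {
  if (n == 0) return(numeric(0))
  slack <- chrom_len - 2 * margin - n * w - (n - 1) * gap
  if (slack < 0) stopf("infeasible config: %d peaks of %d bp do not fit", n, w)
  u <- sort(floor(stats::runif(n, 0, slack + 1)))
  margin + u + (seq_len(n) - 1) * (w + gap)
}

#' Generate a synthetic dataset with recorded ground truth
#'
#' Emits a genome FASTA, chromosome sizes, two narrowPeak files, a gene
#' annotation, a DE table, a category map, the generating PWMs (MEME
#' format), and `truth.json` recording every planted fact: peak coordinates
#' and motif classes, planted site positions and sequences, the exact
#' shared-peak index set with summit distances, the bound-gene set, and the
#' planted direct-target table. Bit-identical outputs for identical
#' (config, seed). Motif instances are planted by substring substitution at
#' the summit so high-threshold scans recover them exactly.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `paths` (named file paths), `truth`, and
#'   `config`.
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  genome <- genome_build(data.frame(chrom = names(cfg$chrom_lengths),
                                    length = unname(cfg$chrom_lengths)),
                         name = "synthetic")
  peak_chroms <- setdiff(names(cfg$chrom_lengths), cfg$desert_chrom)

  res <- with_seed(cfg$seed, {
    ## --- genome sequence (per-base vectors; motifs substituted in place)
    seqs <- lapply(cfg$chrom_lengths, function(L)
      sample(DNA_BASES, L, replace = TRUE, prob = cfg$background))

    ## --- A peaks: non-overlapping, well separated, in sorted order
    lens <- cfg$chrom_lengths[peak_chroms]
    n_per <- apportion(cfg$n_peaks_a, lens)
    a_list <- lapply(seq_along(peak_chroms), function(ci) {
      st <- place_sorted(n_per[ci], lens[ci], cfg$peak_width_a,
                         cfg$min_gap, cfg$edge_margin)
      data.frame(chrom = peak_chroms[ci], start = st,
                 end = st + cfg$peak_width_a, stringsAsFactors = FALSE)
    })
    a_df <- do.call(rbind, a_list)
    n_a <- nrow(a_df)
    a_df$name <- sprintf("peakA_%03d", seq_len(n_a))
    a_df$score <- round(stats::runif(n_a, 50, 1000), 1)
    half <- floor(cfg$peak_width_a / 2)
    a_df$summit <- half + sample(-50:50, n_a, replace = TRUE)

    ## --- plant motif classes at A summits
    classes <- sample(rep(names(cfg$class_mix),
                          apportion(n_a, cfg$class_mix)))
    plant <- function(chrom, pos0, motif) {    # pos0: 0-based start
      seqs[[chrom]][(pos0 + 1):(pos0 + nchar(motif))] <<-
        strsplit(motif, "")[[1]]
      list(chrom = chrom, start = pos0, seq = motif)
    }
    planted <- vector("list", n_a)
    for (i in seq_len(n_a)) {
      s <- a_df$start[i] + a_df$summit[i]
      ch <- a_df$chrom[i]
      planted[[i]] <- switch(classes[i],
        denovo_only = list(plant(ch, s - 5, cfg$hybrid_consensus)),
        selex_only = list(plant(ch, s - 3, cfg$selex_consensus)),
        both = list(plant(ch, s - 20, cfg$selex_consensus),
                    plant(ch, s + 4, cfg$hybrid_consensus)),
        neither = list())
    }

    ## --- B peaks: shared copies with summit jitter + disjoint fillers
    n_shared <- round_half_up(cfg$shared_fraction * n_a)
    shared_idx <- sort(sample.int(n_a, n_shared))
    max_jit <- floor((cfg$peak_width_a + cfg$peak_width_b) / 2) - 1
    jitter <- round(stats::rnorm(n_shared, 0, cfg$summit_jitter_sd))
    jitter <- pmax(pmin(jitter, max_jit), -max_jit)
    half_b <- floor(cfg$peak_width_b / 2)
    b_shared <- data.frame(
      chrom = a_df$chrom[shared_idx],
      start = a_df$start[shared_idx] + a_df$summit[shared_idx] +
        jitter - half_b,
      stringsAsFactors = FALSE)
    b_shared$end <- b_shared$start + cfg$peak_width_b
    b_shared$summit <- rep(half_b, nrow(b_shared))
    bL <- chrom_length(genome, b_shared$chrom)
    if (nrow(b_shared) && (any(b_shared$start < 0) || any(b_shared$end > bL)))
      stopf("infeasible config: jittered shared peak leaves chromosome; increase edge_margin")

    n_fill <- cfg$n_peaks_b - n_shared
    if (n_fill < 0) stopf("infeasible config: more shared peaks than n_peaks_b")
    a_by_chrom <- split(a_df[, c("start", "end")], a_df$chrom)
    fills <- list()
    got <- 0
    attempts <- 0
    while (got < n_fill) {
      attempts <- attempts + 1
      if (attempts > 200) stopf("infeasible config: cannot place disjoint B peaks")
      k <- (n_fill - got) * 2
      ci <- sample.int(length(peak_chroms), k, replace = TRUE,
                       prob = lens - cfg$peak_width_b + 1)
      st <- floor(stats::runif(k, 0, lens[ci] - cfg$peak_width_b + 1))
      ok <- vapply(seq_len(k), function(j) {
        av <- a_by_chrom[[peak_chroms[ci[j]]]]
        is.null(av) ||
          !any(st[j] < av$end & st[j] + cfg$peak_width_b > av$start)
      }, logical(1))
      ci <- ci[ok][seq_len(min(sum(ok), n_fill - got))]
      st <- st[ok][seq_len(length(ci))]
      if (length(ci))
        fills[[length(fills) + 1]] <-
          data.frame(chrom = peak_chroms[ci], start = st,
                     end = st + cfg$peak_width_b, summit = half_b,
                     stringsAsFactors = FALSE)
      got <- got + length(ci)
    }
    b_df <- rbind(b_shared[, c("chrom", "start", "end", "summit")],
                  do.call(rbind, fills))
    b_df$name <- sprintf("peakB_%03d", seq_len(nrow(b_df)))
    b_df$score <- round(stats::runif(nrow(b_df), 50, 1000), 1)

    ## --- gene annotation: near genes on peak chromosomes, far genes on the
    ## desert chromosome (never within range of any peak)
    near_ci <- sample.int(length(peak_chroms), cfg$n_genes_near,
                          replace = TRUE, prob = lens)
    genes <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(cfg$n_genes_near + cfg$n_genes_far)),
      chrom = c(peak_chroms[near_ci],
                rep(cfg$desert_chrom, cfg$n_genes_far)),
      tss = c(floor(stats::runif(cfg$n_genes_near, 0, lens[near_ci])),
              floor(stats::runif(cfg$n_genes_far, 0,
                                 cfg$chrom_lengths[[cfg$desert_chrom]]))),
      strand = sample(c("+", "-"), cfg$n_genes_near + cfg$n_genes_far,
                      replace = TRUE),
      stringsAsFactors = FALSE)

    peaks_a <- peak_set(a_df, "peaks_a", genome)
    peaks_b <- new_peak_set(
      data.frame(chrom = b_df$chrom, start = b_df$start, end = b_df$end,
                 name = b_df$name, score = b_df$score, summit = b_df$summit,
                 stringsAsFactors = FALSE), "peaks_b")
    annotation <- gene_annotation(genes, genome)
    assign <- assign_targets(peaks_a, annotation, max_dist = 1e6)
    bound <- assign$genes

    ## --- planted direct targets among bound genes; DE-only genes far away
    n_t <- round_half_up(cfg$frac_bound_de * length(bound))
    target_genes <- sort(sample(bound, n_t))
    cat_names <- names(cfg$category_mix)
    t_cat <- sample(cat_names, n_t, replace = TRUE, prob = cfg$category_mix)
    t_down <- stats::runif(n_t) < cfg$down_bias[t_cat]
    mag <- log2(1.5) + stats::rgamma(n_t, cfg$lfc_shape, cfg$lfc_rate)
    t_lfc <- ifelse(t_down, -mag, mag)

    far_ids <- genes$gene_id[genes$chrom == cfg$desert_chrom]
    de_only <- sort(sample(far_ids, cfg$n_de_only))
    d_down <- stats::runif(cfg$n_de_only) < cfg$frac_down
    d_mag <- log2(1.5) + stats::rgamma(cfg$n_de_only, cfg$lfc_shape,
                                       cfg$lfc_rate)
    d_cat <- sample(cat_names, cfg$n_de_only, replace = TRUE,
                    prob = cfg$category_mix)

    de <- data.frame(gene_id = genes$gene_id,
                     log2fc = round(stats::runif(nrow(genes), -0.5, 0.5), 4),
                     adj_p = round(stats::runif(nrow(genes), 0.2, 1), 4),
                     stringsAsFactors = FALSE)
    de$log2fc[match(target_genes, de$gene_id)] <- round(t_lfc, 4)
    de$adj_p[match(target_genes, de$gene_id)] <-
      round(stats::runif(n_t, 1e-6, 0.01), 6)
    de$log2fc[match(de_only, de$gene_id)] <-
      round(ifelse(d_down, -d_mag, d_mag), 4)
    de$adj_p[match(de_only, de$gene_id)] <-
      round(stats::runif(cfg$n_de_only, 1e-6, 0.01), 6)

    cat_map <- data.frame(gene_id = c(target_genes, de_only),
                          category = c(t_cat, d_cat),
                          stringsAsFactors = FALSE)
    cat_map <- cat_map[order(cat_map$gene_id), ]

    list(seqs = seqs, peaks_a = peaks_a, peaks_b = peaks_b,
         annotation = annotation, de = de, cat_map = cat_map,
         truth = list(
           seed = cfg$seed,
           n_peaks_a = n_a, n_peaks_b = nrow(b_df),
           n_shared = n_shared,
           rounding = "round_half_up(shared_fraction * n_peaks_a)",
           shared_index_a = shared_idx,
           summit_dist = abs(jitter),
           n_direct_pm6 = sum(abs(jitter) <= 12),
           class = classes,
           class_counts = as.list(vapply(names(cfg$class_mix), function(cl)
             sum(classes == cl), integer(1))),
           planted_sites = planted,
           peaks_a_start = a_df$start, peaks_a_chrom = a_df$chrom,
           peaks_a_summit = a_df$summit,
           peaks_b_start = peaks_b$intervals$start,
           peaks_b_chrom = peaks_b$intervals$chrom,
           bound_genes = bound,
           target_genes = data.frame(gene_id = target_genes,
                                     direction = ifelse(t_down, "down", "up"),
                                     category = t_cat,
                                     log2fc = round(t_lfc, 4),
                                     stringsAsFactors = FALSE),
           de_only_genes = de_only,
           consensi = list(selex = cfg$selex_consensus,
                           meis = cfg$meis_consensus,
                           hybrid = cfg$hybrid_consensus)))
  })

  ## --- emit files
  paths <- list(
    genome_fasta = file.path(out_dir, "genome.fa"),
    chrom_sizes = file.path(out_dir, "chrom.sizes"),
    peaks_a = file.path(out_dir, "peaks_a.narrowPeak"),
    peaks_b = file.path(out_dir, "peaks_b.narrowPeak"),
    annotation = file.path(out_dir, "annotation.tsv"),
    de_table = file.path(out_dir, "de_table.tsv"),
    categories = file.path(out_dir, "categories.tsv"),
    motifs = file.path(out_dir, "motifs.meme"),
    truth = file.path(out_dir, "truth.json"))
  dna <- Biostrings::DNAStringSet(vapply(res$seqs, paste, character(1),
                                         collapse = ""))
  names(dna) <- names(cfg$chrom_lengths)
  Biostrings::writeXStringSet(dna, paths$genome_fasta)
  write_chrom_sizes(genome, paths$chrom_sizes)
  write_bed(res$peaks_a, paths$peaks_a, "narrowPeak")
  write_bed(res$peaks_b, paths$peaks_b, "narrowPeak")
  write_gene_annotation(res$annotation, paths$annotation)
  utils::write.table(res$de, paths$de_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$cat_map, paths$categories, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bg <- cfg$background
  write_meme(list(pwm_from_consensus(cfg$selex_consensus, cfg$nsites,
                                     cfg$pseudocount, bg, "selex"),
                  pwm_from_consensus(cfg$hybrid_consensus, cfg$nsites,
                                     cfg$pseudocount, bg, "denovo"),
                  pwm_from_consensus(cfg$meis_consensus, cfg$nsites,
                                     cfg$pseudocount, bg, "meis")),
             paths$motifs)
  jsonlite::write_json(res$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, truth = res$truth, config = cfg))
}

#' Audit a simulated dataset against its truth record
#'
#' Re-reads every emitted file and verifies the recorded ground truth:
#' planted motif sequences present at their recorded genome coordinates,
#' peak coordinates unchanged, exact shared-overlap counts and index set,
#' the summit +/- 6 bp direct-overlap count, recovery of the planted direct
#' target set (via [assign_targets()], [filter_de()], [direct_targets()]),
#' and sign-consistency of every recorded DE direction. Any mismatch is
#' reported as a named failure.
#'
#' @param dir directory written by [simulate_dataset()].
#' @return list with `pass` (logical) and `failures` (character vector of
#'   named failed assertions).
#' @export
audit_simulation <- function(dir) {
  pth <- function(f) file.path(dir, f)
  for (f in c("genome.fa", "peaks_a.narrowPeak", "peaks_b.narrowPeak",
              "annotation.tsv", "de_table.tsv", "truth.json"))
    if (!file.exists(pth(f))) stopf("missing file: %s", pth(f))
  truth <- jsonlite::read_json(pth("truth.json"), simplifyVector = TRUE)
  failures <- character(0)
  fail <- function(msg) failures <<- c(failures, msg)

  dna <- Biostrings::readDNAStringSet(pth("genome.fa"))
  seqs <- stats::setNames(as.character(dna), names(dna))
  sites <- truth$planted_sites
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    if (!is.data.frame(s) || !nrow(s)) next
    for (j in seq_len(nrow(s))) {
      found <- substr(seqs[[s$chrom[j]]], s$start[j] + 1,
                      s$start[j] + nchar(s$seq[j]))
      if (found != s$seq[j])
        fail(sprintf("planted site at region %d (%s:%d): found %s, expected %s",
                     i, s$chrom[j], s$start[j], found, s$seq[j]))
    }
  }

  peaks_a <- read_bed(pth("peaks_a.narrowPeak"), "narrowPeak")
  peaks_b <- read_bed(pth("peaks_b.narrowPeak"), "narrowPeak")
  for (chk in list(list("peaks_a", peaks_a, truth$peaks_a_start,
                        truth$peaks_a_chrom),
                   list("peaks_b", peaks_b, truth$peaks_b_start,
                        truth$peaks_b_chrom))) {
    df <- chk[[2]]$intervals
    bad <- which(df$start != chk[[3]] | df$chrom != chk[[4]])
    if (length(bad))
      fail(sprintf("%s interval %d: coordinates differ from truth",
                   chk[[1]], bad[1]))
  }
  smt_bad <- which(peaks_a$intervals$summit != truth$peaks_a_summit)
  if (length(smt_bad))
    fail(sprintf("peaks_a interval %d: summit differs from truth", smt_bad[1]))

  part <- overlap_partition(peaks_a, peaks_b)
  if (part$n_shared_a != truth$n_shared)
    fail(sprintf("shared count %d != truth %d", part$n_shared_a,
                 truth$n_shared))
  if (!identical(as.integer(part$shared_index_a),
                 as.integer(unlist(truth$shared_index_a))))
    fail("shared A-index set differs from truth")
  sm <- summit_overlap(peaks_a, peaks_b, k = 6)
  if (sm$n_shared_a != truth$n_direct_pm6)
    fail(sprintf("summit +/-6 shared count %d != truth %d", sm$n_shared_a,
                 truth$n_direct_pm6))

  annotation <- read_gene_annotation(pth("annotation.tsv"))
  de <- read_de_table(pth("de_table.tsv"))
  assign <- assign_targets(peaks_a, annotation, max_dist = 1e6)
  if (!identical(assign$genes, as.character(unlist(truth$bound_genes))))
    fail("bound gene set differs from truth")
  dt <- direct_targets(assign, filter_de(de, min_fc = 1.5, max_adj_p = 0.05))
  tg <- truth$target_genes
  if (!is.data.frame(tg))
    tg <- data.frame(gene_id = character(), direction = character())
  if (!identical(dt$table$gene_id, as.character(tg$gene_id))) {
    fail("direct-target gene set differs from truth")
  } else {
    bad <- which(dt$table$direction != tg$direction)
    if (length(bad))
      fail(sprintf("DE direction for gene %s inconsistent with truth",
                   dt$table$gene_id[bad[1]]))
  }
  mism <- which(sign(de$log2fc[match(tg$gene_id, de$gene_id)]) !=
                  ifelse(tg$direction == "down", -1, 1))
  if (length(mism))
    fail(sprintf("DE sign flipped for gene %s", tg$gene_id[mism[1]]))

  list(pass = length(failures) == 0, failures = failures)
}
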