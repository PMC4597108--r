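#' Genome build: named chromosomes with lengths
#'
#' A minimal genome description (chromosome names and lengths in bp) used to
#' validate coordinates, clip summit windows, and place shuffled intervals.
#'
#' @param chroms data.frame with columns `chrom` (character) and `length`
#'   (positive integer bp), one row per chromosome, names unique.
#' @param name free-text label for the build.
#' @return An object of class `genome_build`.
#' @examples
#' gb <- genome_build(data.frame(chrom = c("chr1", "chr2"),
#'                               length = c(1000L, 500L)))
#' @export
genome_build <- function(chroms, name = "custom") {
  stopifnot(is.data.frame(chroms), all(c("chrom", "length") %in% names(chroms)))
  chroms$chrom <- as.character(chroms$chrom)
  chroms$length <- as.numeric(chroms$length)
  if (anyDuplicated(chroms$chrom)) stopf("duplicated chromosome names")
  if (any(chroms$length <= 0) || nrow(chroms) == 0)
    stopf("chromosome lengths must be positive and at least one chromosome given")
  structure(list(name = name, chroms = chroms[, c("chrom", "length")]),
            class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build '%s': %d chromosomes, %.0f bp total>\n",
              x$name, nrow(x$chroms), sum(x$chroms$length)))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chroms$chrom)
  if (anyNA(i)) stopf("chromosome(s) not in genome: %s",
                      paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$chroms$length[i]
}

#' Read / write a chromosome-sizes table
#'
#' Two-column tab-separated file: chromosome name, length in bp (the UCSC
#' `chrom.sizes` convention).
#'
#' @param path file path.
#' @param name build label attached to the returned object.
#' @return `read_chrom_sizes()` returns a [genome_build()].
#' @export
read_chrom_sizes <- function(path, name = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_build(df, name = name)
}

#' @param genome a [genome_build()].
#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(genome$chroms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
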