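#' Fixed-width genomic binning for one chromosome
#'
#' Defines the bin grid on which all contact matrices and reconstructions
#' live. Bins are 0-based and half-open: bin \eqn{b} covers
#' \eqn{[b \cdot res, (b+1) \cdot res)} in 0-based coordinates, so a 1-based
#' genomic position \eqn{p} falls in bin \eqn{\lfloor (p-1)/res \rfloor}.
#'
#' @param chromosome Chromosome name, e.g. `"chr1"`.
#' @param chrom_length Chromosome length in base pairs (positive).
#' @param resolution Bin width in base pairs; default 25000 (25 kb).
#'
#' @return An object of class `genome_binning`: a list with elements
#'   `chromosome`, `chrom_length`, `resolution` and `n_bins`
#'   (\eqn{\lceil length/res \rceil}).
#' @examples
#' b <- genome_binning("chr1", 2.5e6)
#' b$n_bins   # 100
#' bin_index(c(1, 25000, 25001), b)  # 0 0 1
#' @export
genome_binning <- function(chromosome, chrom_length, resolution = 25000L) {
  stopifnot(length(chromosome) == 1L, is.character(chromosome))
  chrom_length <- as.numeric(chrom_length)
  resolution <- as.numeric(resolution)
  if (!is.finite(chrom_length) || chrom_length <= 0)
    stop("chrom_length must be a positive number of base pairs")
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be a positive number of base pairs")
  structure(
    list(
      chromosome = chromosome,
      chrom_length = chrom_length,
      resolution = resolution,
      n_bins = as.integer(ceiling(chrom_length / resolution))
    ),
    class = "genome_binning"
  )
}

#' @export
print.genome_binning <- function(x, ...) {
  cat(sprintf("<genome_binning> %s: %s bp at %s bp resolution (%d bins)\n",
              x$chromosome, format(x$chrom_length, big.mark = ","),
              format(x$resolution, big.mark = ","), x$n_bins))
  invisible(x)
}

#' Map 1-based genomic positions to 0-based bin indices
#'
#' @param position Integer vector of 1-based genomic positions.
#' @param binning A [genome_binning()].
#' @return Integer vector of 0-based bin indices.
#' @export
bin_index <- function(position, binning) {
  stopifnot(inherits(binning, "genome_binning"))
  if (any(position < 1)) stop("positions are 1-based and must be >= 1")
  as.integer(floor((as.numeric(position) - 1) / binning$resolution))
}

#' Genomic start coordinate (0-based) of a bin
#' @param bin Integer vector of 0-based bin indices.
#' @param binning A [genome_binning()].
#' @return Numeric vector of bin start coordinates in base pairs.
#' @export
bin_start <- function(bin, binning) {
  stopifnot(inherits(binning, "genome_binning"))
  as.numeric(bin) * binning$resolution
}
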