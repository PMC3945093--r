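# Genome layout: chromosome lengths and the 10-kb bin grid used for
# hot-spot detection. Lengths must be explicit because the number of bins
# (and hence the Bonferroni correction) depends on them.

# S. cerevisiae nuclear chromosome lengths (sacCer3 assembly, bp).
# Under 10-kb bins with a per-chromosome ceiling these yield 1,216 bins.
.yeast_chrom_lengths <- c(
  chr01 = 230218L,  chr02 = 813184L,  chr03 = 316620L,  chr04 = 1531933L,
  chr05 = 576874L,  chr06 = 270161L,  chr07 = 1090940L, chr08 = 562643L,
  chr09 = 439888L,  chr10 = 745751L,  chr11 = 666816L,  chr12 = 1078177L,
  chr13 = 924431L,  chr14 = 784333L,  chr15 = 1091291L, chr16 = 948066L
)

# Total genetic map length (cM) chosen so that 2,820 uniformly placed
# markers have ~1.5 cM mean spacing (equivalently ~0.356 cM/kb).
.yeast_map_cM_total <- 4300

#' Construct a genome layout
#'
#' A genome layout records chromosome identifiers, their physical lengths
#' (bp), optional genetic lengths (cM), and the bin size used to grid the
#' genome for hot-spot detection.
#'
#' @param chrom Character vector of chromosome ids (defines sort order).
#' @param length_bp Positive integer vector of physical lengths, one per
#'   chromosome.
#' @param length_cM Optional numeric vector of genetic lengths (cM).
#' @param bin_size Bin width in bp (default 10,000).
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chrom, length_bp, length_cM = NULL, bin_size = 10000) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("duplicate chromosome ids")
  if (length(length_bp) != length(chrom)) stop("length_bp/chrom length mismatch")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stop("chromosome lengths must be positive")
  if (!is.null(length_cM)) {
    if (length(length_cM) != length(chrom)) stop("length_cM/chrom length mismatch")
    if (any(!is.finite(length_cM)) || any(length_cM <= 0))
      stop("genetic lengths must be positive")
  }
  if (!is.finite(bin_size) || bin_size <= 0) stop("bin_size must be positive")
  structure(
    list(chrom = chrom,
         length_bp = stats::setNames(as.numeric(length_bp), chrom),
         length_cM = if (is.null(length_cM)) NULL else
           stats::setNames(as.numeric(length_cM), chrom),
         bin_size = as.numeric(bin_size)),
    class = "genome_layout")
}

#' Default yeast genome layout
#'
#' The 16 S. cerevisiae nuclear chromosome lengths (sacCer3), which produce
#' 1,216 bins at the default 10-kb bin size, and genetic lengths scaled so
#' the whole map is 4,300 cM (about 1.5 cM per 4.3 kb).
#'
#' @param bin_size Bin width in bp (default 10,000).
#' @return A `genome_layout`.
#' @export
yeast_genome_layout <- function(bin_size = 10000) {
  bp <- .yeast_chrom_lengths
  cM <- as.numeric(bp) / sum(as.numeric(bp)) * .yeast_map_cM_total
  genome_layout(names(bp), bp, cM, bin_size = bin_size)
}

#' Number of bins in a layout
#'
#' Total bin count: the sum over chromosomes of `ceiling(length/bin_size)`;
#' the last partial bin of each chromosome counts as a full bin.
#'
#' @param layout A `genome_layout`.
#' @return Integer bin count.
#' @export
n_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(.bins_per_chrom(layout))
}

.bins_per_chrom <- function(layout) {
  stats::setNames(as.integer(ceiling(layout$length_bp / layout$bin_size)),
                  layout$chrom)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %.3g Mb, bin size %g bp (%d bins)\n",
              length(x$chrom), sum(x$length_bp) / 1e6, x$bin_size, n_bins(x)))
  invisible(x)
}
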