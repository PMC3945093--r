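# Interval enrichment: count annotated genes overlapping QTL credible
# intervals and assess enrichment by relocating the intervals; plus the
# per-metabolite pathway-gene lookup. Overlap is closed-interval
# intersection in 1-based inclusive coordinates (partial overlap counts).

.interval_df <- function(intervals) {
  stopifnot(all(c("chrom", "lo_bp", "hi_bp") %in% names(intervals)),
            all(intervals$lo_bp <= intervals$hi_bp))
  intervals
}

#' Count distinct genes overlapping a set of intervals
#'
#' A gene counts once if `[start, end]` intersects any interval (partial
#' overlap suffices). Monotone in the interval set.
#'
#' @param intervals Data.frame with `chrom`, `lo_bp`, `hi_bp`.
#' @param genes A `gene_annotation`.
#' @param metabolic_only Count only genes flagged metabolic (default TRUE).
#' @return Integer count of distinct overlapped genes.
#' @export
count_overlapping_genes <- function(intervals, genes, metabolic_only = TRUE) {
  intervals <- .interval_df(intervals)
  if (metabolic_only) genes <- genes[genes$is_metabolic, , drop = FALSE]
  if (!nrow(intervals) || !nrow(genes)) return(0L)
  hit <- rep(FALSE, nrow(genes))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    q <- IRanges::IRanges(iv$lo_bp, iv$hi_bp)
    s <- IRanges::IRanges(genes$start[gi], genes$end[gi])
    hit[gi[unique(S4Vectors::subjectHits(IRanges::findOverlaps(q, s)))]] <- TRUE
  }
  sum(hit)
}

#' Permutation null for interval gene content
#'
#' Each permutation relocates every interval independently: a chromosome is
#' drawn with probability proportional to its length among chromosomes the
#' interval fits on, and the start is uniform over admissible positions.
#' The count of distinct (metabolic) genes overlapped is recorded per
#' permutation. Deterministic given the seed. `same_chrom = TRUE` restricts
#' each interval to its own chromosome (sensitivity variant).
#'
#' @param intervals Data.frame with `chrom`, `lo_bp`, `hi_bp`.
#' @param layout A `genome_layout`.
#' @param genes A `gene_annotation`.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed RNG seed.
#' @param metabolic_only Count only metabolic genes (default TRUE).
#' @param same_chrom Keep intervals on their own chromosome (default FALSE).
#' @return Integer vector of null counts, length `n_perm`.
#' @export
permute_intervals <- function(intervals, layout, genes, n_perm = 10000,
                              seed = NULL, metabolic_only = TRUE,
                              same_chrom = FALSE) {
  intervals <- .interval_df(intervals)
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.null(seed)) set.seed(seed)
  if (metabolic_only) genes <- genes[genes$is_metabolic, , drop = FALSE]
  n_int <- nrow(intervals)
  if (!n_int) return(rep(0L, n_perm))
  widths <- intervals$hi_bp - intervals$lo_bp + 1
  if (any(widths > max(layout$length_bp)))
    stop("interval longer than every chromosome")
  # draw all placements at once: chromosome ~ length among fitting ones
  ch_idx <- matrix(NA_integer_, n_int, n_perm)
  start <- matrix(NA_real_, n_int, n_perm)
  for (i in seq_len(n_int)) {
    if (same_chrom) {
      ci <- match(intervals$chrom[i], layout$chrom)
      if (layout$length_bp[ci] < widths[i])
        stop("interval does not fit its own chromosome")
      ch_idx[i, ] <- ci
    } else {
      fits <- which(layout$length_bp >= widths[i])
      ch_idx[i, ] <- fits[sample.int(length(fits), n_perm, replace = TRUE,
                                     prob = layout$length_bp[fits])]
    }
    nstart <- layout$length_bp[ch_idx[i, ]] - widths[i] + 1
    start[i, ] <- floor(stats::runif(n_perm) * nstart) + 1
  }
  # one overlap join per chromosome over all permutations at once
  perm_id <- matrix(rep(seq_len(n_perm), each = n_int), n_int)
  counts <- integer(n_perm)
  for (ci in seq_along(layout$chrom)) {
    gi <- which(genes$chrom == layout$chrom[ci])
    if (!length(gi)) next
    sel <- which(ch_idx == ci)
    if (!length(sel)) next
    q <- IRanges::IRanges(start[sel], start[sel] + rep(widths, n_perm)[sel] - 1)
    s <- IRanges::IRanges(genes$start[gi], genes$end[gi])
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    pid <- perm_id[sel][S4Vectors::queryHits(ov)]
    key <- (pid - 1) * length(gi) + S4Vectors::subjectHits(ov)
    key <- unique(key)
    counts <- counts + tabulate((key - 1) %/% length(gi) + 1, nbins = n_perm)
  }
  counts
}

#' Empirical upper-tail p-value with pseudo-count
#'
#' `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param observed Observed count.
#' @param null_counts Permutation null counts (nonempty).
#' @return p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed, null_counts) {
  stopifnot(length(null_counts) > 0)
  (1 + sum(null_counts >= observed)) / (1 + length(null_counts))
}

#' Interval enrichment test
#'
#' Observed distinct (metabolic) gene count over the intervals, a
#' relocation null, and the empirical p-value.
#'
#' @inheritParams permute_intervals
#' @return List of class `enrichment_result`: `observed_count`,
#'   `null_counts`, `p_value`, `n_perm`.
#' @export
interval_enrichment <- function(intervals, layout, genes, n_perm = 10000,
                                seed = NULL, metabolic_only = TRUE,
                                same_chrom = FALSE) {
  observed <- count_overlapping_genes(intervals, genes, metabolic_only)
  null_counts <- permute_intervals(intervals, layout, genes, n_perm, seed,
                                   metabolic_only, same_chrom)
  structure(list(observed_count = observed, null_counts = null_counts,
                 p_value = empirical_p(observed, null_counts),
                 n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("interval enrichment: observed %d genes, null mean %.1f, p = %.4g (%d permutations)\n",
              x$observed_count, mean(x$null_counts), x$p_value, x$n_perm))
  invisible(x)
}

#' Pathway genes inside an interval for a metabolite
#'
#' Genes overlapping the interval whose pathway set intersects the
#' metabolite's pathway set. An unmapped metabolite yields an empty result
#' with a warning.
#'
#' @param metabolite Metabolite id.
#' @param interval One-row data.frame (`chrom`, `lo_bp`, `hi_bp`) or a
#'   list/vector with those fields.
#' @param genes A `gene_annotation` with `pathways`.
#' @param pathway_map Named list: metabolite id -> character vector of
#'   pathway ids.
#' @return Character vector of gene ids (possibly empty).
#' @export
pathway_genes_in_interval <- function(metabolite, interval, genes, pathway_map) {
  pw <- pathway_map[[metabolite]]
  if (is.null(pw) || length(pw) == 0) {
    if (is.null(pw)) warning("metabolite ", metabolite, " has no pathway mapping")
    return(character(0))
  }
  ch <- as.character(interval[["chrom"]])
  lo <- as.numeric(interval[["lo_bp"]]); hi <- as.numeric(interval[["hi_bp"]])
  inside <- genes$chrom == ch & genes$start <= hi & genes$end >= lo
  in_pw <- vapply(genes$pathways, function(s) any(pathway_set(s) %in% pw),
                  logical(1), USE.NAMES = FALSE)
  genes$gene_id[inside & in_pw]
}
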