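# Hot-spot detection: bin linkage peaks on a 10-kb grid, derive the
# Poisson/Bonferroni per-bin cutoff, merge adjacent significant bins, and
# test cross-dataset hot-spot overlap by width-preserving relocation.

#' Assign linkage peaks to genome bins
#'
#' Bin index (0-based within chromosome) = `floor((bp - 1) / bin_size)`.
#'
#' @param peaks Data.frame with `chrom`, `peak_bp` and optionally `trait`
#'   columns.
#' @param layout A `genome_layout`.
#' @return An object of class `bin_counts`: data.frame of nonzero bins
#'   (`chrom`, `bin`, `count`, `traits`), total peak count, and the layout.
#' @export
assign_bins <- function(peaks, layout) {
  stopifnot(inherits(layout, "genome_layout"),
            all(c("chrom", "peak_bp") %in% names(peaks)))
  if (nrow(peaks)) {
    peaks$peak_bp <- as.numeric(peaks$peak_bp)
    len <- layout$length_bp[peaks$chrom]
    if (any(is.na(len))) stop("peak chromosome not in layout")
    if (any(peaks$peak_bp < 1 | peaks$peak_bp > len))
      stop("peak position beyond chromosome end")
  } else peaks$peak_bp <- numeric(0)
  bin <- floor((peaks$peak_bp - 1) / layout$bin_size)
  key <- paste(peaks$chrom, bin)
  traits <- if ("trait" %in% names(peaks)) peaks$trait else
    rep(NA_character_, nrow(peaks))
  agg <- tapply(seq_len(nrow(peaks)), key, identity)
  df <- if (nrow(peaks)) data.frame(
    chrom = vapply(agg, function(i) peaks$chrom[i[1]], character(1)),
    bin = vapply(agg, function(i) bin[i[1]], numeric(1)),
    count = lengths(agg),
    traits = vapply(agg, function(i) paste(traits[i], collapse = ";"),
                    character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  else data.frame(chrom = character(0), bin = numeric(0), count = integer(0),
                  traits = character(0), stringsAsFactors = FALSE)
  df <- df[order(match(df$chrom, layout$chrom), df$bin), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(bins = df, n_peaks = nrow(peaks), layout = layout),
            class = "bin_counts")
}

#' Poisson/Bonferroni hot-spot cutoff
#'
#' With `lambda = n_linkages / n_bins` and a per-bin Bonferroni level
#' `alpha_b = fw_alpha / n_bins`, the cutoff is the smallest per-bin count
#' `k` whose Poisson tail probability falls below `alpha_b`. The default
#' inclusive tail uses `P(X >= k)`; `tail = "gt"` uses the exclusive
#' `P(X > k)` convention.
#'
#' @param n_linkages Total number of linkage peaks.
#' @param n_bins Total number of genome bins.
#' @param fw_alpha Family-wise significance level (default 0.05).
#' @param tail `"ge"` (inclusive, default) or `"gt"` (exclusive).
#' @return The cutoff count `k`, with attributes `lambda` and `alpha_b`.
#' @export
poisson_cutoff <- function(n_linkages, n_bins, fw_alpha = 0.05,
                           tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  stopifnot(n_bins >= 1, n_linkages >= 0, fw_alpha > 0)
  lambda <- n_linkages / n_bins
  alpha_b <- fw_alpha / n_bins
  k <- 0L
  repeat {
    p <- if (tail == "ge") stats::ppois(k - 1, lambda, lower.tail = FALSE)
         else stats::ppois(k, lambda, lower.tail = FALSE)
    if (p < alpha_b) break
    k <- k + 1L
    if (k > 1e6) stop("cutoff search did not converge")
  }
  structure(k, lambda = lambda, alpha_b = alpha_b)
}

#' Detect hot spots from binned counts
#'
#' Bins with count >= cutoff are flagged; runs of immediately adjacent
#' flagged bins on the same chromosome are merged into one hot spot, with
#' member traits unioned. The tail p-value reported is the Poisson upper
#' tail of the maximum single-bin count in the merged spot.
#'
#' @param bin_counts A [assign_bins()] result.
#' @param cutoff The per-bin count cutoff (from [poisson_cutoff()]).
#' @return A data.frame of hot spots (possibly zero rows): `chrom`,
#'   `bin_lo`, `bin_hi`, `bp_lo`, `bp_hi`, `n_linkages`, `max_bin_count`,
#'   `p_tail`, `traits`.
#' @export
detect_hotspots <- function(bin_counts, cutoff) {
  stopifnot(inherits(bin_counts, "bin_counts"))
  lambda <- attr(cutoff, "lambda")
  if (is.null(lambda)) lambda <- bin_counts$n_peaks / n_bins(bin_counts$layout)
  df <- bin_counts$bins[bin_counts$bins$count >= as.numeric(cutoff), ,
                        drop = FALSE]
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$bin), , drop = FALSE]
    grp <- cumsum(c(1, diff(sub$bin) > 1))
    for (g in unique(grp)) {
      s <- sub[grp == g, , drop = FALSE]
      bs <- bin_counts$layout$bin_size
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, bin_lo = min(s$bin), bin_hi = max(s$bin),
        bp_lo = min(s$bin) * bs + 1,
        bp_hi = min((max(s$bin) + 1) * bs,
                    bin_counts$layout$length_bp[ch]),
        n_linkages = sum(s$count), max_bin_count = max(s$count),
        p_tail = stats::ppois(max(s$count) - 1, lambda, lower.tail = FALSE),
        traits = paste(unique(unlist(strsplit(s$traits, ";"))), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res <- res[order(match(res$chrom, bin_counts$layout$chrom), res$bin_lo), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
  } else .empty_results_df(.hotspot_columns)
}

#' Full hot-spot analysis from a peak table
#'
#' @param peaks Peak data.frame (`chrom`, `peak_bp`, `trait`).
#' @param layout A `genome_layout`.
#' @param fw_alpha Family-wise alpha for the cutoff (default 0.05).
#' @param tail Tail convention, see [poisson_cutoff()].
#' @return List with `hotspots`, `cutoff`, `lambda`, `n_bins`, `bin_counts`.
#' @export
find_hotspots <- function(peaks, layout, fw_alpha = 0.05, tail = "ge") {
  bc <- assign_bins(peaks, layout)
  cutoff <- poisson_cutoff(bc$n_peaks, n_bins(layout), fw_alpha, tail)
  list(hotspots = detect_hotspots(bc, cutoff), cutoff = as.integer(cutoff),
       lambda = attr(cutoff, "lambda"), n_bins = n_bins(layout),
       bin_counts = bc)
}

# global bin index bookkeeping for relocation
.global_bins <- function(layout) {
  per <- .bins_per_chrom(layout)
  data.frame(chrom = rep(layout$chrom, per),
             bin = unlist(lapply(per, function(k) seq_len(k) - 1L)),
             stringsAsFactors = FALSE)
}

#' Hot-spot overlap permutation test
#'
#' Two hot spots are shared when they inhabit at least one common genome
#' bin. `n_shared` counts the hot spots of `a` having >= 1 bin inside a hot
#' spot of `b`. The null relocates each hot spot of `a`, preserving its
#' width in bins, uniformly among genome bins (chromosome drawn with
#' probability proportional to the number of admissible start bins);
#' `p = (1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param a,b Hot-spot data.frames from [detect_hotspots()].
#' @param layout The shared `genome_layout`.
#' @param n_perm Number of relocations (default 10,000).
#' @param seed RNG seed.
#' @return List with `n_shared`, `p_value`, and the permutation counts.
#' @export
overlap_test <- function(a, b, layout, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  per <- .bins_per_chrom(layout)
  bbins <- lapply(stats::setNames(layout$chrom, layout$chrom), function(ch) {
    sub <- b[b$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) integer(0)
    else unlist(lapply(seq_len(nrow(sub)), function(i)
      seq(sub$bin_lo[i], sub$bin_hi[i])))
  })
  shared_count <- function(spots) {
    if (!nrow(spots)) return(0L)
    sum(vapply(seq_len(nrow(spots)), function(i) {
      any(seq(spots$bin_lo[i], spots$bin_hi[i]) %in% bbins[[spots$chrom[i]]])
    }, logical(1)))
  }
  observed <- shared_count(a)
  if (!nrow(a) || !nrow(b) || sum(lengths(bbins)) == 0)
    return(list(n_shared = observed, p_value = 1,
                perm_counts = rep(0L, n_perm)))
  widths <- a$bin_hi - a$bin_lo + 1L
  perm_counts <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    newchrom <- character(nrow(a))
    newlo <- integer(nrow(a))
    for (i in seq_len(nrow(a))) {
      admissible <- pmax(per - widths[i] + 1L, 0L)
      ci <- sample.int(length(per), 1, prob = admissible)
      newchrom[i] <- layout$chrom[ci]
      newlo[i] <- sample.int(admissible[ci], 1) - 1L
    }
    relocated <- data.frame(chrom = newchrom, bin_lo = newlo,
                            bin_hi = newlo + widths - 1L,
                            stringsAsFactors = FALSE)
    perm_counts[p] <- shared_count(relocated)
  }
  list(n_shared = observed,
       p_value = (1 + sum(perm_counts >= observed)) / (1 + n_perm),
       perm_counts = perm_counts)
}
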