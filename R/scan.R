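# Single-marker LOD genome scans (normal and nonparametric models),
# per-trait permutation thresholds, peak calling, and Bayesian credible
# intervals. The scan is marker-based: with a dense map and more than one
# expected recombination between adjacent markers, inter-marker positions
# add nothing.

# ---- vectorized LOD engines -------------------------------------------------
# Y: n x P matrix of trait columns sharing one non-missing pattern
# X01: n x m matrix of genotype indicators (RM = 1, BY = 0)
# returns m x P matrix of LOD scores

.lod_normal_matrix <- function(Y, X01) {
  n <- nrow(Y)
  m <- ncol(X01)
  P <- ncol(Y)
  n1 <- colSums(X01)
  n0 <- n - n1
  tot <- colSums(Y)
  rss0 <- colSums(Y^2) - tot^2 / n
  s1 <- crossprod(X01, Y)                       # m x P group-1 sums
  s0 <- matrix(tot, m, P, byrow = TRUE) - s1
  ok <- n1 > 0 & n0 > 0
  between <- matrix(0, m, P)
  if (any(ok))
    between[ok, ] <- s1[ok, , drop = FALSE]^2 / n1[ok] +
      s0[ok, , drop = FALSE]^2 / n0[ok] -
      matrix(tot^2 / n, sum(ok), P, byrow = TRUE)
  rss0m <- matrix(rss0, m, P, byrow = TRUE)
  rss1 <- pmax(rss0m - between, 0)
  # guard: constant trait -> LOD 0; perfect fit -> finite cap via eps floor
  lod <- matrix(0, m, P)
  pos <- rss0m > 0
  rss1[pos] <- pmax(rss1[pos], rss0m[pos] * .Machine$double.eps)
  lod[pos] <- (n / 2) * log10(rss0m[pos] / rss1[pos])
  lod
}

.lod_np_matrix <- function(Y, X01) {
  n <- nrow(Y)
  m <- ncol(X01)
  P <- ncol(Y)
  R <- apply(Y, 2, rank)                        # midranks for ties
  if (!is.matrix(R)) R <- matrix(R, nrow = n)
  tiecorr <- apply(Y, 2, function(y) {
    t <- table(y)
    1 - sum(t^3 - t) / (n^3 - n)
  })
  n1 <- colSums(X01)
  n0 <- n - n1
  r1 <- crossprod(X01, R)                       # m x P rank sums in group 1
  rtot <- n * (n + 1) / 2
  r0 <- rtot - r1
  ok <- n1 > 0 & n0 > 0
  H <- matrix(0, m, P)
  if (any(ok))
    H[ok, ] <- 12 / (n * (n + 1)) *
      (r1[ok, , drop = FALSE]^2 / n1[ok] + r0[ok, , drop = FALSE]^2 / n0[ok]) -
      3 * (n + 1)
  H <- sweep(H, 2, tiecorr, "/")
  H[!is.finite(H)] <- 0                          # all-tied column: tiecorr 0
  H[!ok, ] <- 0
  pmax(H, 0) / (2 * log(10))
}

.lod_matrix <- function(Y, X01, model = c("normal", "np")) {
  model <- match.arg(model)
  if (model == "normal") .lod_normal_matrix(Y, X01) else .lod_np_matrix(Y, X01)
}

# ---- scalar entry points ----------------------------------------------------

#' Normal-model LOD at a single marker
#'
#' `LOD = (n/2) log10(RSS0 / RSS1)` where RSS0 is the residual sum of
#' squares about the grand mean and RSS1 about the genotype-class means.
#' Segregants with a missing trait value are excluded pairwise; a constant
#' trait or an empty genotype class gives LOD 0 by convention.
#'
#' @param trait_values Numeric per-segregant trait values.
#' @param marker_calls Character calls (`"BY"`/`"RM"`) aligned with
#'   `trait_values`.
#' @return Nonnegative LOD score.
#' @export
lod_normal <- function(trait_values, marker_calls) {
  keep <- is.finite(trait_values) & !is.na(marker_calls)
  y <- trait_values[keep]
  x <- as.numeric(marker_calls[keep] == "RM")
  if (length(y) == 0) return(0)
  .lod_normal_matrix(matrix(y, ncol = 1), matrix(x, ncol = 1))[1, 1]
}

#' Nonparametric (Kruskal-Wallis) LOD at a single marker
#'
#' `LOD = H / (2 ln 10)` with `H` the ties-corrected Kruskal-Wallis
#' statistic over the two genotype classes. Invariant to monotone
#' transformations of the trait.
#'
#' @inheritParams lod_normal
#' @return Nonnegative LOD score.
#' @export
lod_np <- function(trait_values, marker_calls) {
  keep <- is.finite(trait_values) & !is.na(marker_calls)
  y <- trait_values[keep]
  x <- as.numeric(marker_calls[keep] == "RM")
  if (length(y) == 0) return(0)
  .lod_np_matrix(matrix(y, ncol = 1), matrix(x, ncol = 1))[1, 1]
}

# ---- genome scan ------------------------------------------------------------

#' Single-marker genome scan
#'
#' LOD at every marker for every trait. Traits and genotypes are joined on
#' segregant ids; segregants missing a trait are dropped per trait; traits
#' with fewer than `min_segregants` scored segregants are skipped with a
#' warning.
#'
#' @param traits A `trait_table`.
#' @param genos A `genotype_matrix` (no missing calls; see
#'   [impute_genotypes()]).
#' @param model `"normal"` or `"np"`.
#' @param min_segregants Minimum common segregants per trait (default 20).
#' @return An object of class `mqtl_scan`: markers, model, trait ids, the
#'   traits x markers LOD matrix, and the per-trait segregant count `n`.
#' @export
genome_scan <- function(traits, genos, model = c("normal", "np"),
                        min_segregants = 20) {
  model <- match.arg(model)
  stopifnot(inherits(traits, "trait_table"), inherits(genos, "genotype_matrix"))
  if (anyNA(genos$calls))
    stop("genotypes contain missing calls; run impute_genotypes() first")
  common <- intersect(traits$segregants, genos$segregants)
  if (length(common) == 0) stop("no common segregants")
  X <- t(genos$calls[, common, drop = FALSE] == "RM") * 1   # n x m
  V <- traits$values[, common, drop = FALSE]
  lod <- matrix(NA_real_, length(traits$compounds), nrow(genos$markers),
                dimnames = list(traits$compounds, genos$markers$id))
  nused <- stats::setNames(integer(length(traits$compounds)), traits$compounds)
  for (i in seq_along(traits$compounds)) {
    keep <- is.finite(V[i, ])
    nused[i] <- sum(keep)
    if (nused[i] < min_segregants) {
      warning("trait ", traits$compounds[i], " has fewer than ",
              min_segregants, " scored segregants; skipped")
      next
    }
    lod[i, ] <- .lod_matrix(matrix(V[i, keep], ncol = 1),
                            X[keep, , drop = FALSE], model)[, 1]
  }
  structure(list(markers = genos$markers, model = model,
                 traits = traits$compounds, lod = lod, n = nused),
            class = "mqtl_scan")
}

#' @export
print.mqtl_scan <- function(x, ...) {
  cat(sprintf("mqtl_scan (%s model): %d traits x %d markers, max LOD %.2f\n",
              x$model, nrow(x$lod), ncol(x$lod), max(x$lod, na.rm = TRUE)))
  invisible(x)
}

#' Permutation configuration
#'
#' @param n_perm Number of trait permutations (default 100; >= 20).
#' @param quantile Significance quantile of the permuted genome-wide
#'   maxima (default 0.90, the "top 10%" rule).
#' @param seed RNG seed.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_perm = 100, quantile = 0.90, seed = NULL) {
  stopifnot(n_perm >= 20, quantile > 0, quantile < 1)
  structure(list(n_perm = as.integer(n_perm), quantile = quantile, seed = seed),
            class = "perm_config")
}

#' Per-trait permutation threshold
#'
#' For each of `n_perm` permutations of the trait values across segregants,
#' the genome-wide maximum LOD is recorded; the threshold is the
#' `ceiling(n_perm * quantile)`-th smallest of these maxima (for 100
#' permutations at quantile 0.90, the 90th order statistic). Deterministic
#' given the seed.
#'
#' @param trait_values Named per-segregant trait values (names = segregant
#'   ids), or unnamed and aligned with `genos$segregants`.
#' @param genos A `genotype_matrix`.
#' @param config A [perm_config()].
#' @param model `"normal"` or `"np"`.
#' @return The threshold LOD, with the permuted maxima as attribute
#'   `"max_lods"`.
#' @export
permutation_threshold <- function(trait_values, genos,
                                  config = perm_config(),
                                  model = c("normal", "np")) {
  model <- match.arg(model)
  stopifnot(inherits(config, "perm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!is.null(names(trait_values))) {
    common <- intersect(names(trait_values), genos$segregants)
    y <- trait_values[common]
    X <- t(genos$calls[, common, drop = FALSE] == "RM") * 1
  } else {
    stopifnot(length(trait_values) == length(genos$segregants))
    y <- trait_values
    X <- t(genos$calls == "RM") * 1
  }
  keep <- is.finite(y)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  Y <- vapply(seq_len(config$n_perm), function(i) y[sample.int(n)],
              numeric(n))
  maxlod <- apply(.lod_matrix(Y, X, model), 2, max)
  k <- ceiling(config$n_perm * config$quantile)
  structure(sort(maxlod)[k], max_lods = maxlod)
}

#' Call QTL peaks from a LOD profile
#'
#' Per chromosome, if the maximum LOD meets the threshold, one peak is
#' emitted at the maximum-LOD marker (ties broken leftmost); a trait can
#' therefore have between 0 and one peak per chromosome.
#'
#' @param lod Per-marker LOD vector for one trait (aligned with `markers`).
#' @param markers A `marker_map`.
#' @param threshold Per-trait significance LOD.
#' @param prob Credible-interval probability (default 0.95).
#' @param trait,model Labels copied into the output.
#' @return A data.frame of peaks with credible-interval bounds (possibly
#'   zero rows).
#' @export
call_peaks <- function(lod, markers, threshold, prob = 0.95,
                       trait = NA_character_, model = "normal") {
  stopifnot(length(lod) == nrow(markers))
  out <- list()
  for (ch in unique(markers$chrom)) {
    rows <- which(markers$chrom == ch)
    peak <- rows[which.max(lod[rows])]          # which.max: leftmost tie
    if (lod[peak] >= threshold) {
      ci <- bayes_credible_interval(lod, markers, ch, prob = prob)
      out[[length(out) + 1L]] <- data.frame(
        trait = trait, model = model, chrom = ch,
        marker = markers$id[peak], peak_bp = markers$bp[peak],
        lod = lod[peak], threshold = threshold,
        ci_lo_bp = ci[["lo_bp"]], ci_hi_bp = ci[["hi_bp"]],
        ci_lo_marker = ci[["lo_marker"]], ci_hi_marker = ci[["hi_marker"]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else .empty_results_df(.peak_columns)
}

#' Bayesian credible interval for QTL location
#'
#' Posterior mass at marker i on the peak chromosome is proportional to
#' `10^LOD_i`. Markers are selected in decreasing posterior order until the
#' cumulative mass reaches `prob`; the interval spans the minimum to
#' maximum position of the selected markers, expanded outward by one
#' flanking marker on each side where available. The peak marker always
#' lies inside the interval.
#'
#' @param lod Per-marker LOD vector (whole genome, aligned with `markers`).
#' @param markers A `marker_map`.
#' @param chrom Chromosome to localize on.
#' @param prob Coverage probability (default 0.95).
#' @return Named list: `lo_bp`, `hi_bp`, `lo_marker`, `hi_marker`.
#' @export
bayes_credible_interval <- function(lod, markers, chrom, prob = 0.95) {
  rows <- which(markers$chrom == chrom)
  if (length(rows) == 0) stop("no markers on chromosome ", chrom)
  l <- lod[rows]
  w <- 10^(l - max(l))                          # stabilized posterior weights
  w <- w / sum(w)
  ord <- order(-w, markers$bp[rows])            # ties -> leftmost first
  k <- which(cumsum(w[ord]) >= prob)[1]
  if (is.na(k)) k <- length(ord)
  sel <- ord[seq_len(k)]
  lo <- max(1L, min(sel) - 1L)                  # one flanking marker each side
  hi <- min(length(rows), max(sel) + 1L)
  list(lo_bp = markers$bp[rows[lo]], hi_bp = markers$bp[rows[hi]],
       lo_marker = markers$id[rows[lo]], hi_marker = markers$id[rows[hi]])
}

#' Map QTL for all traits
#'
#' Runs the genome scan, computes a per-trait permutation threshold, and
#' calls peaks with credible intervals. Per-trait thresholds (not one
#' global threshold) follow from the permutation rule: the cutoff differs
#' for each trait.
#'
#' @param traits A `trait_table`.
#' @param genos A `genotype_matrix`.
#' @param model `"normal"` or `"np"` (default normal).
#' @param config A [perm_config()]; its seed governs all permutations.
#' @param prob Credible-interval probability (default 0.95).
#' @param min_segregants Minimum segregants per trait (default 20).
#' @return A list with `scan` (the `mqtl_scan`), `thresholds` (named
#'   per-trait LOD thresholds) and `peaks` (combined peak data.frame).
#' @export
map_qtl <- function(traits, genos, model = c("normal", "np"),
                    config = perm_config(), prob = 0.95,
                    min_segregants = 20) {
  model <- match.arg(model)
  if (!is.null(config$seed)) set.seed(config$seed)
  scan <- genome_scan(traits, genos, model, min_segregants)
  cfg_noseed <- perm_config(config$n_perm, config$quantile, seed = NULL)
  thresholds <- stats::setNames(rep(NA_real_, length(scan$traits)), scan$traits)
  peaks <- list()
  for (tr in scan$traits) {
    if (anyNA(scan$lod[tr, ])) next              # trait skipped by the scan
    y <- stats::setNames(traits$values[tr, ], traits$segregants)
    thresholds[tr] <- permutation_threshold(y, genos, cfg_noseed, model)
    pk <- call_peaks(scan$lod[tr, ], scan$markers, thresholds[tr],
                     prob = prob, trait = tr, model = model)
    if (nrow(pk)) peaks[[length(peaks) + 1L]] <- pk
  }
  peaks <- if (length(peaks)) do.call(rbind, peaks)
           else .empty_results_df(.peak_columns)
  list(scan = scan, thresholds = thresholds, peaks = peaks)
}
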