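# Broad-sense heritability from biological replicates, per-QTL variance
# partitioning on the replicate-level scale, percentile bootstrap, and the
# Poisson regression of QTL count on heritability.

#' Broad-sense heritability from replicate pairs
#'
#' `var_within` is the mean over segregants of the per-segregant sample
#' variance (n-1 denominator); `var_total` is the sample variance of all
#' replicate-level values pooled; `H2 = (var_total - var_within) /
#' var_total`. H2 is reported unclamped (it can be negative on noisy
#' traits) and is invariant under joint affine transformation of all
#' values.
#'
#' @param replicate_values Segregants x replicates numeric matrix (>= 2
#'   columns; rows with any missing value are excluded), or a list of
#'   per-segregant replicate vectors.
#' @param min_segregants Minimum complete segregants (default 10).
#' @return List of class `h2_record`: `h2`, `var_total`, `var_within`,
#'   `n_segregants`, `degenerate` (TRUE when `var_total` is 0).
#' @export
broad_sense_h2 <- function(replicate_values, min_segregants = 10) {
  if (is.list(replicate_values) && !is.data.frame(replicate_values)) {
    keep <- lengths(replicate_values) >= 2
    vals <- replicate_values[keep]
  } else {
    m <- as.matrix(replicate_values)
    if (ncol(m) < 2) stop("need >= 2 replicates per segregant")
    keep <- stats::complete.cases(m) & apply(is.finite(m), 1, all)
    vals <- lapply(which(keep), function(i) m[i, ])
  }
  if (length(vals) < min_segregants)
    stop("fewer than ", min_segregants, " segregants with complete replicates")
  var_within <- mean(vapply(vals, stats::var, numeric(1)))
  pooled <- unlist(vals)
  var_total <- stats::var(pooled)
  if (var_total == 0)
    return(structure(list(h2 = NA_real_, var_total = 0,
                          var_within = var_within,
                          n_segregants = length(vals), degenerate = TRUE),
                     class = "h2_record"))
  structure(list(h2 = (var_total - var_within) / var_total,
                 var_total = var_total, var_within = var_within,
                 n_segregants = length(vals), degenerate = FALSE),
            class = "h2_record")
}

#' Per-QTL variance partition (sequential attribution)
#'
#' Additive linear model of the trait on the peak markers' genotypes, with
#' per-QTL fractions computed as sequential sums of squares (peaks entered
#' in decreasing LOD order) divided by the total sum of squares. Fractions
#' therefore never sum above 1, and collinear peak genotypes are handled
#' naturally (the later peak is attributed only its residual contribution).
#' `type = "simultaneous"` uses drop-one (type-III-like) attribution
#' instead.
#'
#' Supply replicate-level trait values (names = segregant ids, repeated per
#' replicate) to make fractions share the denominator of the replicate-based
#' H2 estimate, so they stack under H2.
#'
#' @param trait_values Named numeric vector (names = segregant ids; names
#'   may repeat for replicate-level values).
#' @param peaks Peak data.frame for this trait (`marker`, `lod`).
#' @param genos A `genotype_matrix`.
#' @param type `"sequential"` (default) or `"simultaneous"`.
#' @return Named numeric vector of per-QTL variance fractions, in
#'   decreasing-LOD peak order.
#' @export
qtl_variance_partition <- function(trait_values, peaks, genos,
                                   type = c("sequential", "simultaneous")) {
  type <- match.arg(type)
  if (is.null(names(trait_values))) stop("trait_values must be named by segregant")
  if (!nrow(peaks)) return(stats::setNames(numeric(0), character(0)))
  keep <- is.finite(trait_values) & names(trait_values) %in% genos$segregants
  y <- trait_values[keep]
  ord <- order(-peaks$lod)
  mk <- peaks$marker[ord]
  bad <- setdiff(mk, genos$markers$id)
  if (length(bad)) stop("peak markers absent from genotypes: ",
                        paste(bad, collapse = ", "))
  X <- t(genos$calls[mk, names(y), drop = FALSE] == "RM") * 1
  colnames(X) <- paste0("q", seq_along(mk))
  dat <- data.frame(y = as.numeric(y), X)
  fit <- stats::lm(y ~ ., data = dat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(stats::setNames(rep(0, length(mk)), mk))
  an <- stats::anova(fit)
  if (type == "sequential") {
    ss <- an[colnames(X), "Sum Sq"]
    ss[is.na(ss)] <- 0                         # dropped collinear terms
  } else {
    ss <- vapply(colnames(X), function(v) {
      red <- stats::lm(stats::reformulate(setdiff(colnames(X), v), "y"),
                       data = dat)
      sum(stats::residuals(red)^2) - sum(stats::residuals(fit)^2)
    }, numeric(1))
  }
  stats::setNames(ss / ss_tot, mk)
}

#' Percentile bootstrap CI for the median
#'
#' Resample with replacement `n_boot` times, take medians, and return the
#' `(1 - prob)/2` and `1 - (1 - prob)/2` empirical quantiles. The interval
#' always contains the sample median of a constant sample.
#'
#' @param values Numeric vector (>= 5 values).
#' @param n_boot Bootstrap replicates (default 1,000).
#' @param prob Coverage probability (default 0.95).
#' @param seed RNG seed.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 1000, prob = 0.95,
                                seed = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need >= 5 values")
  if (!is.null(seed)) set.seed(seed)
  meds <- vapply(seq_len(n_boot), function(i)
    stats::median(sample(values, replace = TRUE)), numeric(1))
  unname(stats::quantile(meds, c((1 - prob) / 2, 1 - (1 - prob) / 2),
                         type = 7))
}

#' Poisson regression of QTL count on heritability
#'
#' Log-link Poisson regression of the number of detected QTLs per trait on
#' broad-sense heritability, with the Wald p-value for the slope.
#'
#' @param h2 Per-trait heritability estimates.
#' @param qtl_count Per-trait detected-QTL counts.
#' @param min_traits Minimum number of traits (default 20).
#' @return List: `slope`, `p_value`, `fit` (the `glm`), `degenerate`
#'   (TRUE when all counts are zero).
#' @export
qtlcount_h2_regression <- function(h2, qtl_count, min_traits = 20) {
  keep <- is.finite(h2) & is.finite(qtl_count)
  h2 <- h2[keep]; qtl_count <- qtl_count[keep]
  if (length(h2) < min_traits)
    stop("need >= ", min_traits, " traits for the QTL-count regression")
  if (all(qtl_count == 0))
    return(list(slope = NA_real_, p_value = NA_real_, fit = NULL,
                degenerate = TRUE))
  fit <- stats::glm(qtl_count ~ h2, family = stats::poisson())
  co <- summary(fit)$coefficients
  list(slope = co["h2", "Estimate"], p_value = co["h2", "Pr(>|z|)"],
       fit = fit, degenerate = FALSE)
}

#' Heritability records for all traits
#'
#' Combines [broad_sense_h2()] on replicate-level log-ratios with
#' [qtl_variance_partition()] (replicate-level, sequential) for the traits'
#' detected peaks.
#'
#' @param replicates Replicate-level log-ratios as returned in the
#'   `replicates` element of [preprocess_phenotypes()] (`values` matrix
#'   compounds x replicate samples, plus `segregant`).
#' @param peaks Peak data.frame across traits.
#' @param genos A `genotype_matrix`.
#' @param min_segregants Minimum complete segregants per trait (default 10).
#' @return A data.frame with one row per trait: `h2`, `var_total`,
#'   `var_within`, `n_qtl`, `qtl_fractions` (`;`-joined), `unexplained_h2`.
#' @export
heritability_records <- function(replicates, peaks, genos,
                                 min_segregants = 10) {
  cmpds <- rownames(replicates$values)
  seg <- replicates$segregant
  out <- lapply(cmpds, function(cc) {
    v <- replicates$values[cc, ]
    # only quantifiable (detected) replicates: a floored not-detected value
    # is a censoring artifact, not replicate disagreement
    if (!is.null(replicates$detected)) v[!replicates$detected[cc, ]] <- NA
    byseg <- split(as.numeric(v), seg)
    byseg <- lapply(byseg, function(x) x[is.finite(x)])
    rec <- tryCatch(broad_sense_h2(byseg, min_segregants),
                    error = function(e) NULL)
    pk <- peaks[peaks$trait == cc, , drop = FALSE]
    fr <- if (nrow(pk) && !is.null(rec) && !rec$degenerate) {
      yv <- stats::setNames(as.numeric(v), seg)
      qtl_variance_partition(yv, pk, genos)
    } else numeric(0)
    data.frame(
      trait = cc,
      h2 = if (is.null(rec)) NA_real_ else rec$h2,
      var_total = if (is.null(rec)) NA_real_ else rec$var_total,
      var_within = if (is.null(rec)) NA_real_ else rec$var_within,
      n_qtl = nrow(pk),
      qtl_fractions = paste(sprintf("%.6g", fr), collapse = ";"),
      unexplained_h2 = if (is.null(rec)) NA_real_ else rec$h2 - sum(fr),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
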