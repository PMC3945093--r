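# Parental-difference testing, FDR correction, mode-of-inheritance
# classification, and the media-contamination screen.

#' One-way strain ANOVA p-value
#'
#' F-test p-value for a strain effect between two groups of replicate
#' values (equivalent to a pooled-variance two-sided t-test for two
#' groups). Zero total variance returns p = 1 by convention; zero
#' within-group variance with distinct means returns the machine minimum.
#'
#' @param by_reps,rm_reps Numeric replicate values for the two strains
#'   (each of length >= 2).
#' @return A p-value in `[0, 1]`.
#' @export
strain_anova <- function(by_reps, rm_reps) {
  by_reps <- by_reps[is.finite(by_reps)]
  rm_reps <- rm_reps[is.finite(rm_reps)]
  if (length(by_reps) < 2 || length(rm_reps) < 2)
    stop("need >= 2 replicates per strain")
  y <- c(by_reps, rm_reps)
  n <- length(y)
  gm <- mean(y)
  ss_tot <- sum((y - gm)^2)
  if (ss_tot == 0) return(1)
  ss_between <- length(by_reps) * (mean(by_reps) - gm)^2 +
    length(rm_reps) * (mean(rm_reps) - gm)^2
  ss_within <- ss_tot - ss_between
  if (ss_within <= .Machine$double.eps * ss_tot)
    return(.Machine$double.xmin)
  f <- (ss_between / 1) / (ss_within / (n - 2))
  stats::pf(f, 1, n - 2, lower.tail = FALSE)
}

#' FDR adjustment (Storey q-values with BH fallback)
#'
#' Storey's procedure with `pi0` estimated at a fixed `lambda = 0.5`
#' (`pi0 = mean(p > 0.5) / 0.5`); when the estimate exceeds 1 (or the
#' input is degenerate) it falls back to Benjamini-Hochberg, i.e.
#' `pi0 = 1`. Monotone in p-rank and returned in input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param lambda Tuning point for the `pi0` estimate (default 0.5).
#' @return q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p, lambda = 0.5) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  pi0 <- mean(p > lambda, na.rm = TRUE) / (1 - lambda)
  if (!is.finite(pi0) || pi0 > 1 || pi0 <= 0) pi0 <- 1
  o <- order(p)
  q <- pi0 * p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))          # step-up: enforce monotonicity
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Classify mode of inheritance for a compound
#'
#' Operational rules: the compound is flagged *transgressive* when the
#' number of segregants lying beyond either parental mean by more than
#' `k` pooled parental standard deviations exceeds the count expected
#' under normal measurement noise (upper-tail binomial test against
#' `p0 = 2 * pnorm(-k)`); it is flagged *directional* when the segregant
#' mean lies between the parental means and the fraction of segregants
#' inside the closed parental-mean interval is significantly greater than
#' 0.5 (upper-tail binomial test). Both raw statistics are returned so the
#' transgressive p-values can be FDR-corrected across compounds (see
#' [parental_analysis()]). Flags are invariant under joint affine
#' transformations of all values.
#'
#' @param segregant_values Per-segregant trait values (>= 20 for stable
#'   classification; fewer triggers a warning).
#' @param by_reps,rm_reps Parental replicate values (>= 2 each; otherwise
#'   the label is withheld with an error).
#' @param k_sd Exceedance threshold in pooled parental SDs (default 2).
#' @param alpha Significance level for the directional test (default 0.05).
#' @return A list with `n_beyond`, `p_transgressive`, `frac_inside`,
#'   `p_directional`, `directional` (flag) and helper statistics. The
#'   transgressive flag itself is assigned by [parental_analysis()] after
#'   FDR correction.
#' @export
classify_inheritance <- function(segregant_values, by_reps, rm_reps,
                                 k_sd = 2, alpha = 0.05) {
  segregant_values <- segregant_values[is.finite(segregant_values)]
  by_reps <- by_reps[is.finite(by_reps)]
  rm_reps <- rm_reps[is.finite(rm_reps)]
  if (length(by_reps) < 2 || length(rm_reps) < 2)
    stop("cannot pool parental SD with fewer than 2 replicates per parent")
  if (length(segregant_values) < 20)
    warning("fewer than 20 segregants; inheritance classification unstable")
  n <- length(segregant_values)
  mby <- mean(by_reps); mrm <- mean(rm_reps)
  lo <- min(mby, mrm); hi <- max(mby, mrm)
  sd_pool <- sqrt(((length(by_reps) - 1) * stats::var(by_reps) +
                     (length(rm_reps) - 1) * stats::var(rm_reps)) /
                    (length(by_reps) + length(rm_reps) - 2))
  if (sd_pool == 0) sd_pool <- .Machine$double.eps
  n_beyond <- sum(segregant_values > hi + k_sd * sd_pool |
                    segregant_values < lo - k_sd * sd_pool)
  p0 <- 2 * stats::pnorm(-k_sd)
  p_trans <- stats::pbinom(n_beyond - 1L, n, p0, lower.tail = FALSE)
  n_inside <- sum(segregant_values >= lo & segregant_values <= hi)
  mean_between <- mean(segregant_values) >= lo && mean(segregant_values) <= hi
  p_dir <- stats::pbinom(n_inside - 1L, n, 0.5, lower.tail = FALSE)
  list(n_beyond = n_beyond, p_transgressive = p_trans,
       frac_inside = n_inside / n, mean_between = mean_between,
       p_directional = p_dir,
       directional = mean_between && p_dir < alpha,
       sd_pool = sd_pool, parental_means = c(BY = mby, RM = mrm))
}

#' Parental analysis across compounds
#'
#' Per compound: strain ANOVA on parental replicate log2 values, Storey/BH
#' FDR across compounds (significance at FDR 0.05), and mode-of-inheritance
#' classification with the transgressive binomial p-values FDR-corrected at
#' 5% across compounds.
#'
#' @param by_values,rm_values Compound x replicate matrices of parental
#'   log2 values (rownames = compounds).
#' @param segregant_values Compound x segregant matrix of trait values.
#' @param fdr Significance level on q-values (default 0.05).
#' @return A data.frame with one row per compound: means, p/q values,
#'   significance flag and inheritance label (`transgressive`,
#'   `directional`, `both`, or `neither`).
#' @export
parental_analysis <- function(by_values, rm_values, segregant_values,
                              fdr = 0.05) {
  cmpds <- rownames(by_values)
  stopifnot(!is.null(cmpds), identical(cmpds, rownames(rm_values)),
            identical(cmpds, rownames(segregant_values)))
  p <- vapply(cmpds, function(cc)
    strain_anova(by_values[cc, ], rm_values[cc, ]), numeric(1))
  q <- fdr_adjust(p)
  cls <- lapply(cmpds, function(cc)
    classify_inheritance(segregant_values[cc, ], by_values[cc, ], rm_values[cc, ]))
  p_trans <- vapply(cls, `[[`, numeric(1), "p_transgressive")
  q_trans <- fdr_adjust(p_trans)
  transgressive <- q_trans < fdr
  directional <- vapply(cls, `[[`, logical(1), "directional")
  inheritance <- ifelse(transgressive & directional, "both",
                        ifelse(transgressive, "transgressive",
                               ifelse(directional, "directional", "neither")))
  data.frame(compound = cmpds,
             BY_mean = rowMeans(by_values), RM_mean = rowMeans(rm_values),
             p_value = p, q_value = q, significant_at = q < fdr,
             p_transgressive = p_trans, q_transgressive = q_trans,
             p_directional = vapply(cls, `[[`, numeric(1), "p_directional"),
             inheritance = inheritance,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Media-contamination screen
#'
#' Per compound, a one-tailed two-sample (Welch) t-test of whether
#' biological (parental) levels exceed mock-extraction levels; compounds
#' failing to show a significant biological excess are flagged as
#' media-derived.
#'
#' @param mock_values Compound x sample matrix of mock-extraction log2
#'   values (>= 2 samples).
#' @param parental_values Compound x sample matrix of parental log2 values.
#' @param alpha One-tailed significance level (default 0.05).
#' @return A data.frame with per-compound p-values and a `media_derived`
#'   flag.
#' @export
media_contamination_screen <- function(mock_values, parental_values,
                                       alpha = 0.05) {
  stopifnot(ncol(mock_values) >= 2,
            identical(rownames(mock_values), rownames(parental_values)))
  p <- vapply(seq_len(nrow(mock_values)), function(i) {
    m <- mock_values[i, ]; b <- parental_values[i, ]
    if (stats::sd(m) == 0 && stats::sd(b) == 0)
      return(if (mean(b) > mean(m)) 0 else 1)
    stats::t.test(b, m, alternative = "greater")$p.value
  }, numeric(1))
  data.frame(compound = rownames(mock_values), p_excess = p,
             media_derived = p >= alpha, stringsAsFactors = FALSE,
             row.names = NULL)
}
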