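# Preprocessing of replicated ion counts into the per-segregant log2 trait
# matrix used for linkage. Fixed pipeline order: floor -> detection filter
# -> OD normalization -> replicate averaging -> same-day reference
# log-ratio. The floor guarantees positivity before the log, so trait
# values are always finite.

#' Preprocessing configuration
#'
#' @param floor Ion-count detection floor (default 32).
#' @param min_detect_frac Minimum detected fraction for a compound to be
#'   retained (default 0.25; the boundary is inclusive, detected fraction
#'   `>= min_detect_frac` is kept).
#' @param reference_role Sample role used for the same-day normalization
#'   (default `"rm_reference"`).
#' @param detect_roles Roles counted as "samples" by the detection filter
#'   (default: parents plus segregant replicates).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(floor = 32, min_detect_frac = 0.25,
                              reference_role = "rm_reference",
                              detect_roles = c("parent_BY", "parent_RM",
                                               "segregant")) {
  stopifnot(floor > 0, min_detect_frac > 0, min_detect_frac <= 1)
  structure(list(floor = floor, min_detect_frac = min_detect_frac,
                 reference_role = reference_role, detect_roles = detect_roles),
            class = "preprocess_config")
}

#' Floor ion counts at the detection limit
#'
#' Every measured value below the floor, and every not-detected entry, is
#' replaced by the floor. Detection flags are preserved separately so the
#' detection filter still sees the original mask.
#'
#' @param raw A `raw_phenotypes`.
#' @param floor The detection floor (default 32).
#' @return A `raw_phenotypes` with all counts `>= floor`.
#' @export
floor_counts <- function(raw, floor = 32) {
  stopifnot(inherits(raw, "raw_phenotypes"), floor > 0)
  cnt <- raw$counts
  cnt[is.na(cnt) | cnt < floor] <- floor
  raw$counts <- cnt
  raw
}

#' Drop compounds detected in too few samples
#'
#' Compounds whose detected fraction (over samples with the configured
#' roles) is below `min_detect_frac` are removed; survivor order is
#' preserved.
#'
#' @param raw A `raw_phenotypes` with detection flags.
#' @param min_detect_frac Minimum detected fraction (default 0.25,
#'   inclusive).
#' @param detect_roles Roles counted as samples for the filter.
#' @return A filtered `raw_phenotypes`.
#' @export
filter_detection <- function(raw, min_detect_frac = 0.25,
                             detect_roles = c("parent_BY", "parent_RM",
                                              "segregant")) {
  stopifnot(inherits(raw, "raw_phenotypes"))
  use <- raw$samples$role %in% detect_roles
  if (!any(use)) stop("no samples with the configured detection roles")
  frac <- rowMeans(raw$detected[, use, drop = FALSE])
  keep <- frac >= min_detect_frac
  raw$compounds <- raw$compounds[keep]
  raw$counts <- raw$counts[keep, , drop = FALSE]
  raw$detected <- raw$detected[keep, , drop = FALSE]
  raw
}

#' OD-normalize and average replicates
#'
#' Each biological sample's counts are divided by its optical density at
#' extraction; replicates of the same segregant are then averaged
#' (arithmetic mean on the normalized count scale).
#'
#' @param raw A floored `raw_phenotypes`.
#' @return A list with `normalized` (compound x sample matrix of
#'   OD-normalized counts, biological samples only), `segregant_means`
#'   (compound x segregant matrix), `segregant_day` (named day per
#'   segregant; errors if a segregant's replicates span days) and the
#'   sample metadata subset.
#' @export
normalize_and_average <- function(raw) {
  stopifnot(inherits(raw, "raw_phenotypes"))
  meta <- raw$samples
  bio <- meta$role %in% .biological_roles
  bad <- bio & (!is.finite(meta$od) | meta$od <= 0)
  if (any(bad))
    stop("missing OD for samples: ", paste(meta$sample_id[bad], collapse = ", "))
  norm <- sweep(raw$counts[, bio, drop = FALSE], 2, meta$od[bio], "/")
  det <- raw$detected[, bio, drop = FALSE]
  meta <- meta[bio, ]
  segs <- unique(meta$segregant_id[meta$role == "segregant"])
  means <- matrix(NA_real_, nrow(norm), length(segs),
                  dimnames = list(rownames(norm), segs))
  seg_day <- stats::setNames(character(length(segs)), segs)
  for (s in segs) {
    cols <- which(meta$role == "segregant" & meta$segregant_id == s)
    means[, s] <- rowMeans(norm[, cols, drop = FALSE])
    d <- unique(meta$day[cols])
    if (length(d) > 1)
      stop("replicates of segregant ", s, " span multiple days; ",
           "same-day reference normalization is ambiguous")
    seg_day[s] <- d
  }
  list(normalized = norm, detected = det, segregant_means = means,
       segregant_day = seg_day, meta = meta)
}

#' Log-ratio to the same-day reference
#'
#' Trait value = log2(segregant averaged intensity / arithmetic mean of the
#' same-day reference intensities), per compound. Errors if any day with
#' segregant samples lacks a reference sample.
#'
#' @param averaged The list returned by [normalize_and_average()].
#' @param reference_role Role of the reference samples (default
#'   `"rm_reference"`).
#' @return A `trait_table` (compounds x segregants).
#' @export
logratio_to_reference <- function(averaged, reference_role = "rm_reference") {
  meta <- averaged$meta
  ref <- meta$role == reference_role
  ref_days <- unique(meta$day[ref])
  need <- unique(averaged$segregant_day)
  missing_days <- setdiff(need, ref_days)
  if (length(missing_days))
    stop("no ", reference_role, " sample on day(s): ",
         paste(missing_days, collapse = ", "))
  ref_mean <- .reference_day_means(averaged, ref, need)
  vals <- log2(averaged$segregant_means /
                 ref_mean[, averaged$segregant_day, drop = FALSE])
  colnames(vals) <- colnames(averaged$segregant_means)
  trait_table(vals)
}

# Per-day reference means, per compound. Only detected (quantifiable)
# reference runs enter the mean: a floored not-detected reference would
# shift every log-ratio of its day by a large artifact. Days where no
# reference run detected a compound fall back to the floored values.
.reference_day_means <- function(averaged, ref, days) {
  ref_mean <- sapply(days, function(d) {
    cols <- which(ref & averaged$meta$day == d)
    vals <- averaged$normalized[, cols, drop = FALSE]
    det <- if (!is.null(averaged$detected))
      averaged$detected[, cols, drop = FALSE]
    else matrix(TRUE, nrow(vals), ncol(vals))
    out <- rowSums(vals * det) / rowSums(det)
    none <- rowSums(det) == 0
    out[none] <- rowMeans(vals[none, , drop = FALSE])
    out
  })
  matrix(ref_mean, nrow = nrow(averaged$normalized),
         dimnames = list(rownames(averaged$normalized), days))
}

# Replicate-level log-ratios (no averaging): one column per segregant
# replicate sample, used by the heritability module.
.replicate_logratios <- function(averaged, reference_role = "rm_reference") {
  meta <- averaged$meta
  ref <- meta$role == reference_role
  seg <- which(meta$role == "segregant")
  days <- meta$day[seg]
  missing_days <- setdiff(unique(days), unique(meta$day[ref]))
  if (length(missing_days))
    stop("no ", reference_role, " sample on day(s): ",
         paste(missing_days, collapse = ", "))
  ref_mean <- .reference_day_means(averaged, ref, unique(days))
  vals <- log2(averaged$normalized[, seg, drop = FALSE] /
                 ref_mean[, days, drop = FALSE])
  colnames(vals) <- meta$sample_id[seg]
  det <- averaged$detected[, seg, drop = FALSE]
  colnames(det) <- meta$sample_id[seg]
  list(values = vals, detected = det, segregant = meta$segregant_id[seg],
       replicate = meta$replicate[seg])
}

#' Run the full preprocessing pipeline
#'
#' floor -> detection filter -> OD normalize -> replicate average ->
#' same-day reference log-ratio.
#'
#' @param raw A `raw_phenotypes`.
#' @param config A [preprocess_config()].
#' @return A list with `traits` (a `trait_table` of averaged log-ratios),
#'   `replicates` (replicate-level log-ratios for heritability: `values`
#'   and `detected` matrices plus `segregant`/`replicate` vectors; the
#'   detection flags let the heritability module restrict itself to
#'   quantifiable replicates, where floored not-detected values would
#'   otherwise masquerade as huge replicate disagreement), and `qc`
#'   (per-compound detected and floored fractions, including dropped
#'   compounds).
#' @export
preprocess_phenotypes <- function(raw, config = preprocess_config()) {
  stopifnot(inherits(raw, "raw_phenotypes"), inherits(config, "preprocess_config"))
  use <- raw$samples$role %in% config$detect_roles
  qc <- data.frame(
    compound = raw$compounds,
    detected_frac = rowMeans(raw$detected[, use, drop = FALSE]),
    floored_frac = rowMeans(is.na(raw$counts[, use, drop = FALSE]) |
                              raw$counts[, use, drop = FALSE] < config$floor),
    stringsAsFactors = FALSE)
  qc$retained <- qc$detected_frac >= config$min_detect_frac
  flo <- floor_counts(raw, config$floor)
  flt <- filter_detection(flo, config$min_detect_frac, config$detect_roles)
  avg <- normalize_and_average(flt)
  traits <- logratio_to_reference(avg, config$reference_role)
  reps <- .replicate_logratios(avg, config$reference_role)
  list(traits = traits, replicates = reps, qc = qc, averaged = avg)
}
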