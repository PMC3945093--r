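# Synthetic-data generator emulating a densely genotyped haploid yeast
# cross phenotyped by LC-MS: a Haldane meiosis model over a fixed genome
# layout, planted additive QTLs, day batch effects, replicate noise
# calibrated to a target broad-sense heritability, OD scaling, a detection
# floor, and same-day reference samples for day normalization.

#' Define a simulation scenario
#'
#' Defaults emulate the study design of the cross: 16 chromosomes,
#' 2,820 markers, 114 segregants with 2 replicates each, 13 BY and 18 RM
#' parental replicates, a 32-count detection floor, and a 4,300 cM map.
#'
#' @param layout A `genome_layout` (default [yeast_genome_layout()]).
#' @param n_markers Total marker count (default 2,820).
#' @param n_segregants Number of segregants (default 114).
#' @param n_compounds Number of compounds (default 74).
#' @param planted_qtls data.frame with columns `compound` (index or id),
#'   `marker` (marker id or index) and `effect` (additive allele effect in
#'   log2 units; allele coding is +1 for BY, -1 for RM).
#' @param target_h2 Per-compound broad-sense heritability target in `[0,1]`
#'   (recycled; default 0.6).
#' @param n_replicates Replicates per segregant (default 2; both replicates
#'   of a segregant share a day, emulating duplicate filters from one
#'   culture).
#' @param parent_reps Named or unnamed pair: BY and RM replicate counts
#'   (default 13 and 18).
#' @param day_effect_sd SD of the per-day multiplicative batch effect on the
#'   log2 scale (default 0.3).
#' @param floor Ion-count detection floor (default 32); simulated counts
#'   below it are reported not-detected.
#' @param detect_prob Per-compound probability that a sample is detected,
#'   before floor censoring (recycled; default 0.98).
#' @param base_intensity Median ion-count scale (default 10,000), a fixture
#'   choice keeping floor censoring rare unless `detect_prob` stresses it.
#' @param null_noise_sd Replicate noise SD (log2) used when a compound has
#'   no genetic variance or `target_h2 = 0` (default 0.4).
#' @param ref_noise_sd Technical noise SD (log2) of same-day reference
#'   samples (default 0.1).
#' @param od_range Range of optical densities at extraction (default
#'   0.3-0.6).
#' @param segregants_per_day Segregants processed per batch day (default 6).
#' @param refs_per_day Same-day RM reference samples per day (default 2).
#' @param n_mock Mock-extraction (media-only) samples (default 0).
#' @param media_compounds Indices or ids of compounds present in the medium
#'   at biological levels (seen in mock extractions).
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(layout = yeast_genome_layout(),
                         n_markers = 2820L,
                         n_segregants = 114L,
                         n_compounds = 74L,
                         planted_qtls = NULL,
                         target_h2 = 0.6,
                         n_replicates = 2L,
                         parent_reps = c(BY = 13L, RM = 18L),
                         day_effect_sd = 0.3,
                         floor = 32,
                         detect_prob = 0.98,
                         base_intensity = 1e4,
                         null_noise_sd = 0.4,
                         ref_noise_sd = 0.1,
                         od_range = c(0.3, 0.6),
                         segregants_per_day = 6L,
                         refs_per_day = 2L,
                         n_mock = 0L,
                         media_compounds = integer(0)) {
  stopifnot(inherits(layout, "genome_layout"),
            n_markers >= 2 * length(layout$chrom),
            n_segregants >= 1, n_compounds >= 1, n_replicates >= 1,
            day_effect_sd >= 0, floor > 0, base_intensity > 0,
            null_noise_sd >= 0, ref_noise_sd >= 0,
            length(parent_reps) == 2, refs_per_day >= 1)
  target_h2 <- rep_len(target_h2, n_compounds)
  detect_prob <- rep_len(detect_prob, n_compounds)
  if (any(target_h2 < 0 | target_h2 > 1)) stop("target_h2 must lie in [0,1]")
  if (any(detect_prob < 0 | detect_prob > 1)) stop("detect_prob must lie in [0,1]")
  if (!is.null(planted_qtls)) {
    stopifnot(is.data.frame(planted_qtls),
              all(c("compound", "marker", "effect") %in% names(planted_qtls)),
              all(is.finite(planted_qtls$effect)))
  }
  structure(list(layout = layout, n_markers = as.integer(n_markers),
                 n_segregants = as.integer(n_segregants),
                 n_compounds = as.integer(n_compounds),
                 planted_qtls = planted_qtls, target_h2 = target_h2,
                 n_replicates = as.integer(n_replicates),
                 parent_reps = stats::setNames(as.integer(parent_reps), c("BY", "RM")),
                 day_effect_sd = day_effect_sd, floor = floor,
                 detect_prob = detect_prob, base_intensity = base_intensity,
                 null_noise_sd = null_noise_sd, ref_noise_sd = ref_noise_sd,
                 od_range = od_range,
                 segregants_per_day = as.integer(segregants_per_day),
                 refs_per_day = as.integer(refs_per_day),
                 n_mock = as.integer(n_mock),
                 media_compounds = media_compounds),
            class = "sim_scenario")
}

#' Scenario presets
#'
#' `"paper_design"` reproduces the study dimensions with 105 measured
#' compounds of which 74 are well-detected (detect_prob 0.95) and 31 are
#' poorly detected (detect_prob 0.10), so about 74 survive the 25%
#' detection filter.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
scenario_preset <- function(name = c("paper_design"), ...) {
  name <- match.arg(name)
  sim_scenario(n_compounds = 105L,
               detect_prob = c(rep(0.95, 74), rep(0.10, 31)),
               ...)
}

#' Haldane recombination fraction
#'
#' `r = (1 - exp(-2 d / 100)) / 2` for a map distance `d` in cM (no
#' crossover interference).
#'
#' @param d_cM Map distance in centimorgans.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Simulate a marker map
#'
#' Markers are allocated to chromosomes proportionally to genetic length
#' (largest-remainder rounding, at least 2 per chromosome) and placed
#' uniformly at random along each chromosome; genetic positions follow a
#' linear bp-to-cM map per chromosome, so bp and cM increase jointly.
#'
#' @param scenario A `sim_scenario`.
#' @param seed RNG seed.
#' @return A `marker_map`.
#' @export
simulate_map <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  lay <- scenario$layout
  cM_len <- lay$length_cM
  if (is.null(cM_len)) stop("layout needs genetic lengths to simulate a map")
  n <- scenario$n_markers
  quota <- n * cM_len / sum(cM_len)
  k <- pmax(2L, floor(quota))
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(quota - floor(quota), decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    ord <- order(k, decreasing = TRUE)
    for (i in seq_len(-rem)) k[ord[i]] <- k[ord[i]] - 1L
  }
  if (any(k > lay$length_bp)) stop("more markers than representable positions")
  pieces <- lapply(seq_along(lay$chrom), function(i) {
    ch <- lay$chrom[i]
    bp <- sort(sample.int(lay$length_bp[i], k[i]))
    data.frame(chrom = ch, bp = bp,
               cM = bp * cM_len[i] / lay$length_bp[i],
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, pieces)
  marker_map(sprintf("m%04d", seq_len(nrow(m))), m$chrom, m$bp, m$cM)
}

#' Simulate segregant genotypes under a Haldane meiosis model
#'
#' Per segregant and chromosome, the first marker's allele is
#' Bernoulli(0.5); between adjacent markers at distance `d` cM the allele
#' switches with probability [haldane_r()]`(d)`.
#'
#' @param markers A `marker_map` (sorted within chromosome).
#' @param n_segregants Number of segregants.
#' @param seed RNG seed.
#' @return A `genotype_matrix` with segregant ids `seg001`, ...
#' @export
simulate_genotypes <- function(markers, n_segregants, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(markers, "marker_map"), n_segregants >= 1)
  segs <- sprintf("seg%03d", seq_len(n_segregants))
  calls <- matrix(NA_character_, nrow(markers), n_segregants)
  for (ch in unique(markers$chrom)) {
    rows <- which(markers$chrom == ch)
    m <- length(rows)
    first <- stats::rbinom(n_segregants, 1L, 0.5)
    if (m > 1) {
      r <- haldane_r(diff(markers$cM[rows]))
      sw <- matrix(stats::rbinom((m - 1L) * n_segregants, 1L,
                                 rep(r, times = n_segregants)),
                   nrow = m - 1L)
      cs <- apply(sw, 2, cumsum)
      if (!is.matrix(cs)) cs <- matrix(cs, nrow = 1L)
      states <- rbind(first, sweep(cs, 2, first, "+")) %% 2L
    } else {
      states <- matrix(first, nrow = 1L)
    }
    calls[rows, ] <- .allele_levels[states + 1L]
  }
  genotype_matrix(markers, segs, calls)
}

# +1/-1 coding of calls: BY = +1, RM = -1 (markers x segregants).
.geno_pm1 <- function(genos) {
  x <- matrix(0, nrow(genos$calls), ncol(genos$calls),
              dimnames = dimnames(genos$calls))
  x[genos$calls == "BY"] <- 1
  x[genos$calls == "RM"] <- -1
  x
}

#' Simulate replicated phenotypes for a genotyped cross
#'
#' For each compound the latent segregant value is the additive genetic
#' value `g = sum(effect * allele)` with +1/-1 allele coding. Replicate
#' noise SD is set from the target heritability via
#' `sigma_e^2 = var(g) (1 - h2) / h2` so that the replicate-based estimator
#' of broad-sense heritability recovers `target_h2`; when a compound has no
#' genetic variance (or `target_h2 = 0`) the `null_noise_sd` is used. Each
#' batch day carries a Normal(0, `day_effect_sd`^2) multiplicative shift on
#' the log2 scale, shared by every sample run that day (including the
#' same-day RM references, so the reference log-ratio cancels it). Latent
#' log2 values are exponentiated around `base_intensity`, scaled by each
#' sample's OD, censored at the detection floor and masked not-detected
#' with probability `1 - detect_prob`.
#'
#' @param genos A `genotype_matrix`.
#' @param scenario A `sim_scenario`; planted QTL markers must exist in
#'   `genos`.
#' @param seed RNG seed.
#' @return A `raw_phenotypes` with a `truth` attribute (list with the
#'   genetic-value matrix, expected trait values, per-compound noise SD and
#'   planted effects) for use in parameter-recovery tests.
#' @export
simulate_phenotypes <- function(genos, scenario, seed = NULL) {
  stopifnot(inherits(genos, "genotype_matrix"), inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  sc <- scenario
  segs <- genos$segregants
  n_seg <- length(segs)
  n_cmp <- sc$n_compounds
  compounds <- sprintf("cmpd%03d", seq_len(n_cmp))

  # planted additive effects: compounds x markers (sparse in practice)
  effects <- vector("list", n_cmp)
  if (!is.null(sc$planted_qtls)) {
    pq <- sc$planted_qtls
    ci <- if (is.numeric(pq$compound)) as.integer(pq$compound)
          else match(as.character(pq$compound), compounds)
    mi <- if (is.numeric(pq$marker)) as.integer(pq$marker)
          else match(as.character(pq$marker), genos$markers$id)
    if (any(is.na(ci)) || any(ci < 1) || any(ci > n_cmp))
      stop("planted_qtls refers to unknown compounds")
    if (any(is.na(mi)) || any(mi < 1) || any(mi > nrow(genos$markers)))
      stop("planted_qtls refers to markers absent from the genotypes")
    for (r in seq_len(nrow(pq)))
      effects[[ci[r]]] <- rbind(effects[[ci[r]]],
                                c(marker = mi[r], effect = pq$effect[r]))
  }

  x <- .geno_pm1(genos)                    # markers x segregants, +1 BY / -1 RM
  g <- matrix(0, n_cmp, n_seg, dimnames = list(compounds, segs))
  g_BY <- g_RM <- numeric(n_cmp)
  for (c_i in seq_len(n_cmp)) {
    ef <- effects[[c_i]]
    if (!is.null(ef)) {
      g[c_i, ] <- colSums(x[ef[, "marker"], , drop = FALSE] * ef[, "effect"])
      g_BY[c_i] <- sum(ef[, "effect"])
      g_RM[c_i] <- -sum(ef[, "effect"])
    }
  }

  var_g <- apply(g, 1, stats::var)
  h2 <- sc$target_h2
  if (any(h2 == 1 & var_g == 0))
    stop("target_h2 = 1 with zero genetic variance is unattainable")
  sigma_e <- ifelse(var_g > 0 & h2 > 0,
                    ifelse(h2 == 1, 0, sqrt(var_g * (1 - h2) / h2)),
                    sc$null_noise_sd)

  # sample sheet: segregant replicates (shared day), parents, references, mocks
  n_days <- max(1L, ceiling(n_seg / sc$segregants_per_day))
  days <- sprintf("day%02d", seq_len(n_days))
  seg_day <- days[ceiling(seq_len(n_seg) / sc$segregants_per_day)]
  sheet <- list()
  for (r in seq_len(sc$n_replicates))
    sheet[[length(sheet) + 1L]] <- data.frame(
      sample_id = sprintf("%s_r%d", segs, r), role = "segregant",
      segregant_id = segs, replicate = r, day = seg_day,
      stringsAsFactors = FALSE)
  for (p in c("BY", "RM")) {
    np <- sc$parent_reps[[p]]
    sheet[[length(sheet) + 1L]] <- data.frame(
      sample_id = sprintf("%s_r%02d", p, seq_len(np)),
      role = paste0("parent_", p), segregant_id = NA_character_,
      replicate = seq_len(np), day = days[1 + (seq_len(np) - 1L) %% n_days],
      stringsAsFactors = FALSE)
  }
  sheet[[length(sheet) + 1L]] <- data.frame(
    sample_id = sprintf("ref_%s_r%d", rep(days, each = sc$refs_per_day),
                        rep(seq_len(sc$refs_per_day), times = n_days)),
    role = "rm_reference", segregant_id = NA_character_,
    replicate = rep(seq_len(sc$refs_per_day), times = n_days),
    day = rep(days, each = sc$refs_per_day), stringsAsFactors = FALSE)
  if (sc$n_mock > 0)
    sheet[[length(sheet) + 1L]] <- data.frame(
      sample_id = sprintf("mock_r%d", seq_len(sc$n_mock)),
      role = "mock_extraction", segregant_id = NA_character_,
      replicate = seq_len(sc$n_mock), day = days[1],
      stringsAsFactors = FALSE)
  sheet <- do.call(rbind, sheet)
  bio <- sheet$role %in% .biological_roles
  od <- ifelse(bio, stats::runif(nrow(sheet), sc$od_range[1], sc$od_range[2]),
               NA_real_)
  meta <- sample_meta(sheet$sample_id, sheet$role, sheet$segregant_id,
                      sheet$replicate, sheet$day, od)

  # latent log2 value per compound x sample (0 = the RM-parent baseline
  # would be g_RM; references are RM, so the processed trait is
  # log2 relative to RM, as in the assay design)
  latent <- matrix(NA_real_, n_cmp, nrow(meta),
                   dimnames = list(compounds, meta$sample_id))
  is_seg <- meta$role == "segregant"
  latent[, is_seg] <- g[, match(meta$segregant_id[is_seg], segs), drop = FALSE]
  latent[, meta$role == "parent_BY"] <- g_BY
  latent[, meta$role %in% c("parent_RM", "rm_reference")] <- g_RM
  media <- if (is.numeric(sc$media_compounds)) as.integer(sc$media_compounds)
           else match(as.character(sc$media_compounds), compounds)
  if (any(is.na(media))) stop("media_compounds refers to unknown compounds")
  is_mock <- meta$role == "mock_extraction"
  if (any(is_mock)) {
    latent[, is_mock] <- -12          # far below the detection floor
    latent[media, is_mock] <- g_RM[media]
  }

  day_eff <- matrix(stats::rnorm(n_cmp * n_days, 0, sc$day_effect_sd),
                    n_cmp, n_days, dimnames = list(compounds, days))
  noise_sd <- matrix(sigma_e, n_cmp, nrow(meta))
  noise_sd[, meta$role == "rm_reference"] <- sc$ref_noise_sd
  eps <- matrix(stats::rnorm(length(latent), 0, noise_sd), n_cmp,
                dimnames = dimnames(latent))
  log2val <- latent + day_eff[, match(meta$day, days), drop = FALSE] + eps
  scale <- ifelse(is.na(meta$od), 1, meta$od)
  counts <- sc$base_intensity * 2^log2val *
    matrix(scale, n_cmp, nrow(meta), byrow = TRUE)

  detected <- matrix(stats::runif(length(counts)) <
                       rep(sc$detect_prob, times = nrow(meta)),
                     n_cmp, dimnames = dimnames(counts))
  detected[counts < sc$floor] <- FALSE
  counts[!detected] <- NA_real_

  raw <- raw_phenotypes(compounds, meta, counts, detected)
  attr(raw, "truth") <- list(g = g, g_BY = g_BY, g_RM = g_RM,
                             trait_expected = sweep(g, 1, g_RM),
                             sigma_e = sigma_e, effects = effects,
                             day_effect = day_eff)
  raw
}

#' Simulate a gene annotation table
#'
#' Genes are placed uniformly: chromosome drawn with probability
#' proportional to length, start uniform such that the gene fits;
#' non-overlap is not enforced. A stated fraction is flagged metabolic, and
#' metabolic genes are assigned 1-3 random pathway ids. An optional
#' clustering knob relocates `cluster_n` metabolic genes near `cluster_at`
#' (a `(chrom, bp)` pair) to plant enrichment.
#'
#' @param layout A `genome_layout`.
#' @param n_genes Number of genes.
#' @param metabolic_fraction Fraction flagged metabolic.
#' @param seed RNG seed.
#' @param gene_length Gene length in bp (default 1,500).
#' @param n_pathways Number of pathway labels to draw from (default 20).
#' @param cluster_at Optional list/vector `(chrom, bp)` for planted
#'   clustering of metabolic genes.
#' @param cluster_n Number of metabolic genes to cluster (default 0).
#' @param cluster_span Span (bp) of the planted cluster (default 20,000).
#' @return A `gene_annotation`.
#' @export
simulate_annotation <- function(layout, n_genes, metabolic_fraction = 0.15,
                                seed = NULL, gene_length = 1500,
                                n_pathways = 20, cluster_at = NULL,
                                cluster_n = 0, cluster_span = 20000) {
  stopifnot(inherits(layout, "genome_layout"), n_genes >= 1,
            metabolic_fraction >= 0, metabolic_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  fits <- layout$length_bp >= gene_length
  if (!any(fits)) stop("gene_length exceeds every chromosome")
  ch_i <- sample(which(fits), n_genes, replace = TRUE,
                 prob = layout$length_bp[fits])
  start <- floor(stats::runif(n_genes, 1, layout$length_bp[ch_i] - gene_length + 2))
  n_met <- round(metabolic_fraction * n_genes)
  met <- seq_len(n_genes) %in% sample.int(n_genes, n_met)
  if (cluster_n > 0) {
    if (is.null(cluster_at)) stop("cluster_at required when cluster_n > 0")
    idx <- utils::head(which(met), cluster_n)
    ci <- match(as.character(cluster_at[[1]]), layout$chrom)
    center <- as.numeric(cluster_at[[2]])
    ch_i[idx] <- ci
    start[idx] <- pmax(1, pmin(layout$length_bp[ci] - gene_length + 1,
                               floor(center + stats::runif(length(idx),
                                                           -cluster_span / 2,
                                                           cluster_span / 2))))
  }
  pw <- character(n_genes)
  if (n_met > 0) {
    labels <- sprintf("PWY%03d", seq_len(n_pathways))
    pw[met] <- vapply(seq_len(sum(met)), function(i)
      paste(sample(labels, sample(1:3, 1)), collapse = ";"), character(1))
  }
  gene_annotation(sprintf("gene%04d", seq_len(n_genes)),
                  layout$chrom[ch_i], start, start + gene_length - 1,
                  is_metabolic = met, pathways = pw, layout = layout)
}

#' Simulate a full cross (map, genotypes, phenotypes)
#'
#' @param scenario A `sim_scenario`.
#' @param seed RNG seed covering all three stages.
#' @return List with `markers`, `genotypes`, `phenotypes` and the
#'   phenotype `truth` attribute lifted to `truth`.
#' @export
simulate_cross <- function(scenario = sim_scenario(), seed = 1) {
  set.seed(seed)
  markers <- simulate_map(scenario)
  genos <- simulate_genotypes(markers, scenario$n_segregants)
  pheno <- simulate_phenotypes(genos, scenario)
  list(markers = markers, genotypes = genos, phenotypes = pheno,
       truth = attr(pheno, "truth"))
}
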