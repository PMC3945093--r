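# End-to-end orchestration: simulate -> preprocess -> parental -> scan ->
# hotspots -> enrich -> herit, with a single JSON config, per-stage seeds,
# and a self-describing run directory.

#' Default pipeline configuration
#'
#' Stage toggles and the analysis defaults: floor 32, 25% detection filter,
#' 100 permutations with the top-10% rule, 0.95 credible intervals, 10-kb
#' bins at family-wise alpha 0.05, and 10,000 enrichment permutations.
#'
#' @param seed Master seed; per-stage seeds default to offsets from it.
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    stages = list(simulate = TRUE, preprocess = TRUE, parental = TRUE,
                  scan = TRUE, hotspots = TRUE, enrich = TRUE, herit = TRUE),
    simulate = list(n_markers = 2820, n_segregants = 114, n_compounds = 74,
                    target_h2 = 0.6, seed = seed),
    preprocess = list(floor = 32, min_detect_frac = 0.25),
    scan = list(model = "normal", n_perm = 100, quantile = 0.90,
                prob = 0.95, min_segregants = 20, seed = seed + 1),
    hotspots = list(bin_size = 10000, fw_alpha = 0.05, tail = "ge"),
    enrich = list(n_perm = 10000, seed = seed + 2, n_genes = 904,
                  metabolic_fraction = 1, anno_seed = seed + 3),
    herit = list(min_segregants = 10),
    inputs = list(genotypes = NULL, phenotypes = NULL, metadata = NULL,
                  annotation = NULL)),
    class = "run_config")
}

#' Read / write a pipeline configuration (JSON)
#'
#' @param path JSON file path.
#' @return For `read_config`, a `run_config`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  for (nm in names(cfg))
    base[[nm]] <- utils::modifyList(if (is.list(base[[nm]])) base[[nm]] else list(),
                                    as.list(cfg[[nm]]))
  base
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in fixed order and writes per-stage TSV/JSON
#' outputs plus a manifest to `outdir`. With the simulate stage enabled the
#' run is fully self-contained; otherwise genotype/phenotype/metadata (and
#' optionally annotation) paths must be set in `config$inputs`.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param outdir Output directory.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), outdir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir)
  say <- function(...) if (!quiet) message("[mqtlmap] ", sprintf(...))
  st <- config$stages
  res <- list()

  if (isTRUE(st$simulate)) {
    say("simulate: %d markers x %d segregants, %d compounds",
        config$simulate$n_markers, config$simulate$n_segregants,
        config$simulate$n_compounds)
    pq <- config$simulate$planted_qtls
    if (!is.null(pq)) pq <- as.data.frame(pq, stringsAsFactors = FALSE)
    sc <- sim_scenario(n_markers = config$simulate$n_markers,
                       n_segregants = config$simulate$n_segregants,
                       n_compounds = config$simulate$n_compounds,
                       target_h2 = config$simulate$target_h2,
                       planted_qtls = pq)
    sim <- simulate_cross(sc, seed = config$simulate$seed)
    res$genotypes <- sim$genotypes
    res$raw <- sim$phenotypes
    res$layout <- sc$layout
    write_genotypes(sim$genotypes, file.path(outdir, "genotypes.tsv"))
    write_phenotypes(sim$phenotypes, file.path(outdir, "phenotypes.tsv"),
                     file.path(outdir, "metadata.tsv"))
  } else {
    say("load inputs")
    res$genotypes <- impute_genotypes(read_genotypes(config$inputs$genotypes))
    res$raw <- read_phenotypes(config$inputs$phenotypes,
                               config$inputs$metadata)
    res$layout <- yeast_genome_layout(config$hotspots$bin_size)
  }

  if (isTRUE(st$preprocess)) {
    say("preprocess: floor %g, detection filter %.2f",
        config$preprocess$floor, config$preprocess$min_detect_frac)
    pp <- preprocess_phenotypes(res$raw,
                                preprocess_config(config$preprocess$floor,
                                                  config$preprocess$min_detect_frac))
    res$traits <- pp$traits
    res$replicates <- pp$replicates
    .write_tsv(pp$qc, file.path(outdir, "qc.tsv"))
    vals <- as.data.frame(pp$traits$values, check.names = FALSE)
    .write_tsv(cbind(data.frame(compound = rownames(vals)), vals),
               file.path(outdir, "traits.tsv"))
  }

  if (isTRUE(st$parental)) {
    say("parental analysis")
    meta <- res$raw$samples
    avg <- preprocess_phenotypes(res$raw,
                                 preprocess_config(config$preprocess$floor,
                                                   config$preprocess$min_detect_frac))$averaged
    ref <- avg$meta$role == "rm_reference"
    lr <- function(role) {
      cols <- which(avg$meta$role == role)
      sapply(cols, function(j) {
        d <- avg$meta$day[j]
        rj <- which(ref & avg$meta$day == d)
        if (!length(rj)) return(rep(NA_real_, nrow(avg$normalized)))
        log2(avg$normalized[, j] /
               rowMeans(avg$normalized[, rj, drop = FALSE]))
      })
    }
    byv <- lr("parent_BY"); rmv <- lr("parent_RM")
    rownames(byv) <- rownames(rmv) <- rownames(avg$normalized)
    if (ncol(byv) >= 2 && ncol(rmv) >= 2) {
      res$parental <- parental_analysis(byv, rmv, res$traits$values)
      .write_tsv(res$parental, file.path(outdir, "parental.tsv"))
    } else say("parental analysis skipped: fewer than 2 replicates per parent")
  }

  if (isTRUE(st$scan)) {
    say("scan: %s model, %d permutations", config$scan$model,
        config$scan$n_perm)
    mp <- map_qtl(res$traits, res$genotypes, model = config$scan$model,
                  config = perm_config(config$scan$n_perm,
                                       config$scan$quantile,
                                       seed = config$scan$seed),
                  prob = config$scan$prob,
                  min_segregants = config$scan$min_segregants)
    res$scan <- mp$scan
    res$thresholds <- mp$thresholds
    res$peaks <- mp$peaks
    say("scan: %d peaks for %d traits", nrow(mp$peaks),
        length(unique(mp$peaks$trait)))
  }

  if (isTRUE(st$hotspots) && !is.null(res$peaks)) {
    say("hotspots: %g bp bins", config$hotspots$bin_size)
    layout <- res$layout
    layout$bin_size <- config$hotspots$bin_size
    hs <- find_hotspots(res$peaks, layout, config$hotspots$fw_alpha,
                        config$hotspots$tail)
    res$hotspots <- hs
    jsonlite::write_json(list(lambda = hs$lambda, cutoff = hs$cutoff,
                              n_bins = hs$n_bins,
                              n_hotspots = nrow(hs$hotspots)),
                         file.path(outdir, "hotspots_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (isTRUE(st$enrich) && !is.null(res$peaks)) {
    say("enrichment: %d permutations", config$enrich$n_perm)
    genes <- if (!is.null(config$inputs$annotation))
      read_annotation(config$inputs$annotation, layout = res$layout)
    else simulate_annotation(res$layout, config$enrich$n_genes,
                             config$enrich$metabolic_fraction,
                             seed = config$enrich$anno_seed)
    res$annotation <- genes
    if (nrow(res$peaks)) {
      iv <- data.frame(chrom = res$peaks$chrom, lo_bp = res$peaks$ci_lo_bp,
                       hi_bp = res$peaks$ci_hi_bp, stringsAsFactors = FALSE)
      res$enrichment <- interval_enrichment(iv, res$layout, genes,
                                            n_perm = config$enrich$n_perm,
                                            seed = config$enrich$seed)
      jsonlite::write_json(list(observed = res$enrichment$observed_count,
                                p_value = res$enrichment$p_value,
                                null_mean = mean(res$enrichment$null_counts),
                                n_perm = res$enrichment$n_perm),
                           file.path(outdir, "enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
    } else say("enrichment skipped: no peaks")
  }

  if (isTRUE(st$herit) && !is.null(res$replicates)) {
    say("heritability")
    res$herit <- heritability_records(res$replicates,
                                      if (is.null(res$peaks))
                                        .empty_results_df(.peak_columns)
                                      else res$peaks,
                                      res$genotypes,
                                      config$herit$min_segregants)
    ok <- is.finite(res$herit$h2) & is.finite(res$herit$n_qtl)
    if (sum(ok) >= 20) {
      reg <- qtlcount_h2_regression(res$herit$h2[ok], res$herit$n_qtl[ok])
      jsonlite::write_json(list(slope = reg$slope, p_value = reg$p_value),
                           file.path(outdir, "herit_regression.json"),
                           auto_unbox = TRUE, digits = NA)
      res$herit_regression <- reg
    }
  }

  write_results(res$peaks, if (!is.null(res$hotspots)) res$hotspots$hotspots,
                res$herit, dir = outdir, config = unclass(config))
  say("done: %s", outdir)
  invisible(res)
}
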