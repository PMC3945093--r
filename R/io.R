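# Readers and writers for the TSV/BED/JSON interchange formats. All readers
# validate and reject malformed input rather than coercing; write->read is
# the identity on valid data. Outputs are UTF-8, LF, floats at 6 significant
# digits.

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    whole <- !is.na(x) & x == round(x) & abs(x) < 1e15
    out <- ifelse(is.na(x), "NA",
                  ifelse(whole, sprintf("%.0f", x), sprintf("%.6g", x)))
    out
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}

#' Read a genotype table
#'
#' Tab-separated file with columns `marker`, `chrom`, `bp`, `cM` followed by
#' one column of allele calls per segregant. Accepts the `{BY,RM}`, `{B,R}`
#' and `{0,1}` genotype dialects, normalized internally to `BY`/`RM`;
#' `NA`, `-` or empty cells are missing.
#'
#' @param path Path to the TSV file.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path) {
  d <- .read_tsv(path)
  need <- c("marker", "chrom", "bp", "cM")
  if (!all(need %in% names(d)[1:4]))
    stop("genotype file must start with columns marker, chrom, bp, cM")
  segs <- names(d)[-(1:4)]
  if (length(segs) == 0L) stop("genotype file has no segregant columns")
  calls <- vapply(d[segs], .normalize_calls,
                  character(nrow(d)))
  calls <- matrix(calls, nrow = nrow(d), dimnames = list(d$marker, segs))
  genotype_matrix(marker_map(d$marker, d$chrom, d$bp, d$cM), segs, calls)
}

#' Write a genotype table
#'
#' @param genos A `genotype_matrix`.
#' @param path Output TSV path.
#' @export
write_genotypes <- function(genos, path) {
  stopifnot(inherits(genos, "genotype_matrix"))
  df <- data.frame(marker = genos$markers$id, chrom = genos$markers$chrom,
                   bp = genos$markers$bp, cM = genos$markers$cM,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(genos$calls, stringsAsFactors = FALSE,
                                check.names = FALSE))
  .write_tsv(df, path)
}

#' Read raw phenotypes (counts plus sample metadata)
#'
#' The counts file has a `compound` column then one column per sample id;
#' `NA` encodes not-detected. The metadata file is keyed by `sample_id`
#' with columns `role`, `segregant_id`, `replicate`, `day`, `od`. Samples
#' present in the counts table but absent from the metadata are rejected.
#'
#' @param path Counts TSV path.
#' @param meta_path Sample metadata TSV path.
#' @return A `raw_phenotypes`.
#' @export
read_phenotypes <- function(path, meta_path) {
  d <- .read_tsv(path)
  if (names(d)[1] != "compound") stop("phenotype file must start with a compound column")
  md <- .read_tsv(meta_path)
  need <- c("sample_id", "role", "segregant_id", "replicate", "day", "od")
  if (!all(need %in% names(md)))
    stop("metadata file must have columns: ", paste(need, collapse = ", "))
  samples <- names(d)[-1]
  missing_meta <- setdiff(samples, md$sample_id)
  if (length(missing_meta))
    stop("samples lacking metadata: ", paste(missing_meta, collapse = ", "))
  md <- md[match(samples, md$sample_id), ]
  meta <- sample_meta(md$sample_id, md$role, md$segregant_id, md$replicate,
                      md$day, md$od)
  counts <- as.matrix(d[-1])
  if (!is.numeric(counts)) stop("non-numeric ion counts")
  rownames(counts) <- d$compound
  raw_phenotypes(d$compound, meta, counts)
}

#' Write raw phenotypes (counts plus sample metadata)
#'
#' @param raw A `raw_phenotypes`.
#' @param path Counts TSV path.
#' @param meta_path Metadata TSV path.
#' @export
write_phenotypes <- function(raw, path, meta_path) {
  stopifnot(inherits(raw, "raw_phenotypes"))
  df <- data.frame(compound = raw$compounds, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(raw$counts, stringsAsFactors = FALSE,
                                check.names = FALSE))
  .write_tsv(df, path)
  .write_tsv(as.data.frame(unclass(raw$samples), stringsAsFactors = FALSE),
             meta_path)
  invisible(c(path, meta_path))
}

#' Read a gene annotation table (native TSV or BED)
#'
#' Native format: TSV with columns `gene_id`, `chrom`, `start`, `end`,
#' `is_metabolic`, `pathways` in 1-based inclusive coordinates. BED format
#' (detected by the `.bed` extension or `format = "bed"`): 0-based
#' half-open `chrom start end name [score] [strand]`, converted on read;
#' all genes are flagged non-metabolic unless a 5th column holds 0/1 flags.
#'
#' @param path Input path.
#' @param format `"auto"`, `"tsv"` or `"bed"`.
#' @param layout Optional `genome_layout` for bounds checking.
#' @return A `gene_annotation`.
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "bed"),
                            layout = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    d <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
    if (ncol(d) < 4) stop("BED annotation needs chrom, start, end, name")
    gene_annotation(d[[4]], d[[1]], d[[2]] + 1L, d[[3]],
                    is_metabolic = if (ncol(d) >= 5) d[[5]] != 0 else FALSE,
                    pathways = "", layout = layout)
  } else {
    d <- .read_tsv(path)
    need <- c("gene_id", "chrom", "start", "end", "is_metabolic", "pathways")
    if (!all(need %in% names(d)))
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
    d$pathways[is.na(d$pathways)] <- ""
    gene_annotation(d$gene_id, d$chrom, d$start, d$end,
                    as.logical(d$is_metabolic), d$pathways, layout = layout)
  }
}

#' Write a gene annotation table (native TSV)
#'
#' @param genes A `gene_annotation`.
#' @param path Output TSV path.
#' @export
write_annotation <- function(genes, path) {
  .write_tsv(as.data.frame(unclass(genes), stringsAsFactors = FALSE), path)
}

.peak_columns <- c("trait", "model", "chrom", "marker", "peak_bp", "lod",
                   "threshold", "ci_lo_bp", "ci_hi_bp", "ci_lo_marker",
                   "ci_hi_marker")
.hotspot_columns <- c("chrom", "bin_lo", "bin_hi", "bp_lo", "bp_hi",
                      "n_linkages", "max_bin_count", "p_tail", "traits")
.herit_columns <- c("trait", "h2", "var_total", "var_within", "n_qtl",
                    "qtl_fractions", "unexplained_h2")

.empty_results_df <- function(cols) {
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

#' Write result tables and a run manifest
#'
#' Deterministic TSVs (fixed column order, floats at 6 significant digits)
#' for QTL peaks, hot spots, and heritability records, plus a JSON manifest
#' recording the configuration and seeds. Empty inputs yield headers-only
#' files.
#'
#' @param peaks QTL peak data.frame (or NULL).
#' @param hotspots Hot-spot data.frame (or NULL).
#' @param herit Heritability data.frame (or NULL).
#' @param dir Output directory (created if absent).
#' @param config List recorded verbatim in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(peaks = NULL, hotspots = NULL, herit = NULL,
                          dir, config = list()) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  if (is.null(peaks)) peaks <- .empty_results_df(.peak_columns)
  if (is.null(hotspots)) hotspots <- .empty_results_df(.hotspot_columns)
  if (is.null(herit)) herit <- .empty_results_df(.herit_columns)
  stopifnot(all(.peak_columns %in% names(peaks)),
            all(.hotspot_columns %in% names(hotspots)),
            all(.herit_columns %in% names(herit)))
  paths <- file.path(dir, c("peaks.tsv", "hotspots.tsv", "heritability.tsv",
                            "manifest.json"))
  .write_tsv(peaks[.peak_columns], paths[1])
  .write_tsv(hotspots[.hotspot_columns], paths[2])
  .write_tsv(herit[.herit_columns], paths[3])
  manifest <- list(package = "mqtlmap",
                   version = as.character(utils::packageVersion("mqtlmap")),
                   config = config,
                   rows = list(peaks = nrow(peaks), hotspots = nrow(hotspots),
                               heritability = nrow(herit)))
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}
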