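# Core typed containers. Plain S3 built on data.frames and matrices, in the
# style of cross-data containers used by linkage packages: a marker map,
# a calls matrix, replicated phenotypes with sample metadata, and a
# processed trait matrix. All genomic coordinates are 1-based inclusive;
# conversion happens only at BED boundaries (see read_annotation).

.allele_levels <- c("BY", "RM")
.sample_roles <- c("parent_BY", "parent_RM", "segregant", "rm_reference",
                   "mock_extraction")
.biological_roles <- c("parent_BY", "parent_RM", "segregant", "rm_reference")

#' Construct a marker map
#'
#' @param id Character marker ids (unique).
#' @param chrom Chromosome id per marker.
#' @param bp 1-based physical position.
#' @param cM Genetic position (cM), nondecreasing within chromosome.
#' @return A data.frame of class `marker_map`.
#' @export
marker_map <- function(id, chrom, bp, cM) {
  m <- data.frame(id = as.character(id), chrom = as.character(chrom),
                  bp = as.numeric(bp), cM = as.numeric(cM),
                  stringsAsFactors = FALSE)
  validate_marker_map(m)
  class(m) <- c("marker_map", "data.frame")
  m
}

validate_marker_map <- function(m) {
  if (anyDuplicated(m$id))
    stop("duplicate marker ids: ", paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  if (any(m$bp < 1)) stop("marker bp positions must be >= 1")
  if (any(m$cM < 0)) stop("marker cM positions must be >= 0")
  for (ch in unique(m$chrom)) {
    i <- which(m$chrom == ch)
    if (is.unsorted(m$bp[i], strictly = TRUE)) {
      bad <- m$id[i][which(diff(m$bp[i]) <= 0)[1] + 1L]
      stop("bp positions not strictly increasing on ", ch, " at marker ", bad)
    }
    if (is.unsorted(m$cM[i])) {
      bad <- m$id[i][which(diff(m$cM[i]) < 0)[1] + 1L]
      stop("cM positions decrease on ", ch, " at marker ", bad)
    }
  }
  invisible(m)
}

#' Construct a genotype matrix
#'
#' Biallelic calls for haploid segregants at mapped markers. Calls are
#' stored as a markers x segregants character matrix with values `"BY"`,
#' `"RM"` or `NA` (missing).
#'
#' @param markers A `marker_map` (or data.frame with id/chrom/bp/cM).
#' @param segregants Character vector of segregant ids.
#' @param calls Character matrix, `nrow(markers)` x `length(segregants)`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(markers, segregants, calls) {
  if (!inherits(markers, "marker_map"))
    markers <- marker_map(markers$id, markers$chrom, markers$bp, markers$cM)
  segregants <- as.character(segregants)
  calls <- as.matrix(calls)
  if (anyDuplicated(segregants)) stop("duplicate segregant ids")
  if (nrow(calls) != nrow(markers) || ncol(calls) != length(segregants))
    stop("calls dimensions do not match markers x segregants")
  bad <- !(calls %in% .allele_levels | is.na(calls))
  if (any(bad))
    stop("unknown allele codes: ", paste(unique(calls[bad]), collapse = ", "))
  if (any(colSums(!is.na(calls)) == 0))
    stop("segregant with no non-missing calls: ",
         paste(segregants[colSums(!is.na(calls)) == 0], collapse = ", "))
  dimnames(calls) <- list(markers$id, segregants)
  structure(list(markers = markers, segregants = segregants, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d segregants (%d chromosomes, %.1f%% missing)\n",
              nrow(x$markers), length(x$segregants),
              length(unique(x$markers$chrom)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

# Normalize common genotype-code dialects ({B,R}, {0,1}, {BY,RM}) to BY/RM.
.normalize_calls <- function(x, missing_codes = c("NA", "-", "")) {
  x <- as.character(x)
  x[x %in% missing_codes] <- NA_character_
  map <- c(B = "BY", R = "RM", "0" = "BY", "1" = "RM", BY = "BY", RM = "RM")
  out <- unname(map[x])
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop("unknown allele codes: ", paste(unique(x[bad]), collapse = ", "))
  out
}

#' Impute missing genotype calls from the nearest flanking marker
#'
#' Each missing call is replaced by the call at the nearest non-missing
#' marker on the same chromosome for that segregant (distance in bp; ties
#' go to the leftmost marker). Appropriate for dense maps where
#' nearest-marker imputation is near-lossless.
#'
#' @param genos A `genotype_matrix`.
#' @return A `genotype_matrix` with no missing calls (unless a segregant
#'   has no calls at all on a chromosome, which are left missing).
#' @export
impute_genotypes <- function(genos) {
  stopifnot(inherits(genos, "genotype_matrix"))
  calls <- genos$calls
  for (ch in unique(genos$markers$chrom)) {
    rows <- which(genos$markers$chrom == ch)
    bp <- genos$markers$bp[rows]
    sub <- calls[rows, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      miss <- which(is.na(sub[, j]))
      if (length(miss) == 0L) next
      obs <- which(!is.na(sub[, j]))
      if (length(obs) == 0L) next
      for (i in miss) {
        d <- abs(bp[obs] - bp[i])
        sub[i, j] <- sub[obs[which.min(d)], j]  # which.min: leftmost tie
      }
    }
    calls[rows, ] <- sub
  }
  genos$calls <- calls
  genos
}

#' Construct a sample metadata table
#'
#' @param sample_id Unique sample ids.
#' @param role One of `parent_BY`, `parent_RM`, `segregant`, `rm_reference`,
#'   `mock_extraction`.
#' @param segregant_id Segregant id (required for segregant samples).
#' @param replicate Small integer replicate index.
#' @param day Batch (day) label.
#' @param od Optical density at extraction; must be positive for
#'   biological samples.
#' @return A data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, role, segregant_id = NA, replicate = 1L,
                        day, od = NA_real_) {
  s <- data.frame(sample_id = as.character(sample_id),
                  role = as.character(role),
                  segregant_id = as.character(segregant_id),
                  replicate = as.integer(replicate),
                  day = as.character(day),
                  od = as.numeric(od), stringsAsFactors = FALSE)
  validate_sample_meta(s)
  class(s) <- c("sample_meta", "data.frame")
  s
}

validate_sample_meta <- function(s) {
  if (anyDuplicated(s$sample_id)) stop("duplicate sample ids")
  bad <- !(s$role %in% .sample_roles)
  if (any(bad)) stop("unknown sample roles: ", paste(unique(s$role[bad]), collapse = ", "))
  bio <- s$role %in% .biological_roles
  if (any(bio & (!is.finite(s$od) | s$od <= 0)))
    stop("missing or non-positive OD for biological samples: ",
         paste(s$sample_id[bio & (!is.finite(s$od) | s$od <= 0)], collapse = ", "))
  seg <- s$role == "segregant"
  if (any(seg & (is.na(s$segregant_id) | s$segregant_id == "")))
    stop("segregant samples without a segregant_id: ",
         paste(s$sample_id[seg & (is.na(s$segregant_id) | s$segregant_id == "")],
               collapse = ", "))
  invisible(s)
}

#' Construct a raw phenotype container
#'
#' Ion counts per compound x sample, with an explicit detection mask:
#' not-detected entries are `NA` in `counts` and `FALSE` in `detected`,
#' so they are distinguishable from measured values before flooring.
#'
#' @param compounds Character compound ids (may carry an ionization-mode tag).
#' @param samples A `sample_meta` table.
#' @param counts Numeric matrix, compounds x samples; nonnegative, `NA`
#'   where not detected.
#' @param detected Optional logical matrix; defaults to `!is.na(counts)`.
#' @return An object of class `raw_phenotypes`.
#' @export
raw_phenotypes <- function(compounds, samples, counts, detected = NULL) {
  compounds <- as.character(compounds)
  if (!inherits(samples, "sample_meta"))
    stop("samples must be a sample_meta table")
  counts <- as.matrix(counts)
  if (anyDuplicated(compounds)) stop("duplicate compound ids")
  if (nrow(counts) != length(compounds) || ncol(counts) != nrow(samples))
    stop("counts dimensions do not match compounds x samples")
  if (any(counts < 0, na.rm = TRUE)) stop("negative ion counts")
  if (is.null(detected)) detected <- !is.na(counts)
  detected <- as.matrix(detected)
  if (!all(dim(detected) == dim(counts))) stop("detected/counts dimension mismatch")
  dimnames(counts) <- dimnames(detected) <- list(compounds, samples$sample_id)
  structure(list(compounds = compounds, samples = samples,
                 counts = counts, detected = detected),
            class = "raw_phenotypes")
}

#' @export
print.raw_phenotypes <- function(x, ...) {
  cat(sprintf("raw_phenotypes: %d compounds x %d samples (%.1f%% detected)\n",
              length(x$compounds), nrow(x$samples), 100 * mean(x$detected)))
  invisible(x)
}

#' Construct a trait table
#'
#' Processed per-segregant trait values: log2(segregant / same-day RM
#' reference) abundance ratios, one value per compound x segregant.
#'
#' @param values Numeric matrix, compounds x segregants, with dimnames.
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("trait values need compound rownames and segregant colnames")
  if (any(is.infinite(values)))
    stop("trait values must be finite where present")
  structure(list(compounds = rownames(values), segregants = colnames(values),
                 values = values),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d compounds x %d segregants\n",
              length(x$compounds), length(x$segregants)))
  invisible(x)
}

#' Construct a gene annotation table
#'
#' @param gene_id Unique gene ids.
#' @param chrom Chromosome id.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param is_metabolic Logical flag (e.g. membership in a genome-scale
#'   metabolic model's gene set).
#' @param pathways Pathway memberships, `;`-separated string per gene
#'   (empty string for none).
#' @param layout Optional `genome_layout` used to check chromosome bounds.
#' @return A data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, is_metabolic = FALSE,
                            pathways = "", layout = NULL) {
  g <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  is_metabolic = as.logical(is_metabolic),
                  pathways = as.character(pathways), stringsAsFactors = FALSE)
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids")
  if (any(g$start < 1)) stop("gene start must be >= 1")
  if (any(g$start > g$end)) stop("gene start > end: ",
                                 paste(g$gene_id[g$start > g$end], collapse = ", "))
  if (!is.null(layout)) {
    len <- layout$length_bp[g$chrom]
    if (any(is.na(len))) stop("gene chromosome not in layout")
    if (any(g$end > len)) stop("gene extends beyond chromosome end: ",
                               paste(g$gene_id[g$end > len], collapse = ", "))
  }
  class(g) <- c("gene_annotation", "data.frame")
  g
}

# Split a ';'-separated pathway string into a character vector.
pathway_set <- function(x) {
  if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}
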