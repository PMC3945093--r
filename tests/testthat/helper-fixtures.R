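# Shared fixtures, all built in code.

small_layout <- function(bin_size = 10000) {
  genome_layout(c("c1", "c2", "c3"),
                c(1500000, 1000000, 500000),
                c(150, 100, 50), bin_size = bin_size)
}

# 4 markers on 2 chromosomes x 3 segregants, fully deterministic
tiny_genos <- function() {
  mk <- marker_map(c("mA", "mB", "mC", "mD"),
                   c("c1", "c1", "c2", "c2"),
                   c(100, 5000, 200, 9000),
                   c(0.5, 2.5, 0.1, 4.0))
  calls <- matrix(c("BY", "RM", "BY",
                    "BY", "RM", "RM",
                    "RM", "BY", "BY",
                    "RM", "RM", "BY"),
                  nrow = 4, byrow = TRUE)
  genotype_matrix(mk, c("s1", "s2", "s3"), calls)
}

small_scenario <- function(n_compounds = 4, ...) {
  sim_scenario(layout = small_layout(), n_markers = 90, n_segregants = 50,
               n_compounds = n_compounds, ...)
}

# minimal raw_phenotypes: one day, explicit counts matrix
make_raw <- function(counts, roles, segregant_id = NA, day = "d1", od = 1,
                     replicate = NULL, compounds = NULL) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  if (is.null(replicate)) replicate <- seq_len(n)
  if (is.null(compounds)) compounds <- sprintf("cmp%02d", seq_len(nrow(counts)))
  meta <- sample_meta(sprintf("smp%02d", seq_len(n)), rep_len(roles, n),
                      rep_len(segregant_id, n), rep_len(replicate, n),
                      rep_len(day, n), rep_len(od, n))
  raw_phenotypes(compounds, meta, counts)
}

# independent all-pairs interval/gene overlap counter
quad_overlap_oracle <- function(intervals, genes) {
  hit <- logical(nrow(genes))
  for (i in seq_len(nrow(intervals)))
    for (j in seq_len(nrow(genes)))
      if (intervals$chrom[i] == genes$chrom[j] &&
          intervals$lo_bp[i] <= genes$end[j] &&
          intervals$hi_bp[i] >= genes$start[j]) hit[j] <- TRUE
  sum(hit)
}

empty_peaks <- function() {
  data.frame(trait = character(0), model = character(0), chrom = character(0),
             marker = character(0), peak_bp = numeric(0), lod = numeric(0),
             threshold = numeric(0), ci_lo_bp = numeric(0),
             ci_hi_bp = numeric(0), ci_lo_marker = character(0),
             ci_hi_marker = character(0), stringsAsFactors = FALSE)
}
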