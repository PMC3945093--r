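# Data model validation and TSV/BED/JSON round trips.

test_that("marker map and genotype matrix validate their invariants", {
  expect_error(marker_map(c("a", "a"), c("c1", "c1"), c(1, 2), c(0, 1)),
               "duplicate marker ids")
  expect_error(marker_map(c("a", "b"), c("c1", "c1"), c(500, 200), c(0, 1)),
               "not strictly increasing.*b")
  expect_error(marker_map(c("a", "b"), c("c1", "c1"), c(100, 200), c(2, 1)),
               "cM positions decrease")
  g <- tiny_genos()
  expect_s3_class(g, "genotype_matrix")
  bad <- g$calls; bad[1, 1] <- "XX"
  expect_error(genotype_matrix(g$markers, g$segregants, bad),
               "unknown allele codes")
  allna <- g$calls; allna[, 2] <- NA
  expect_error(genotype_matrix(g$markers, g$segregants, allna),
               "no non-missing calls")
})

test_that("genotype read/write round-trips and normalizes dialects", {
  g <- tiny_genos()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path)
  expect_identical(g2$calls, g$calls)
  expect_equal(g2$markers$bp, g$markers$bp)
  expect_equal(g2$markers$cM, g$markers$cM, tolerance = 1e-5)

  # {B,R} and {0,1} dialects normalize to BY/RM
  lines <- c("marker\tchrom\tbp\tcM\ts1\ts2",
             "m1\tc1\t10\t0\tB\t0",
             "m2\tc1\t20\t1\tR\t1",
             "m3\tc1\t30\t2\tNA\t-")
  dial <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, dial)
  gd <- read_genotypes(dial)
  expect_equal(unname(gd$calls[, "s1"]), c("BY", "RM", NA))
  expect_equal(unname(gd$calls[, "s2"]), c("BY", "RM", NA))

  # malformed positions are rejected, naming the marker
  bad <- c("marker\tchrom\tbp\tcM\ts1", "m1\tc1\t50\t0\tB", "m2\tc1\t40\t1\tR")
  badf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(bad, badf)
  expect_error(read_genotypes(badf), "m2")
})

test_that("simulated full-size genotype matrix round-trips through TSV", {
  sc <- sim_scenario()
  set.seed(3)
  mk <- simulate_map(sc)
  g <- simulate_genotypes(mk, 114)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path)
  expect_identical(g2$calls, g$calls)
  expect_equal(g2$markers$bp, g$markers$bp)
  expect_identical(g2$segregants, g$segregants)
})

test_that("missing genotype calls impute from the nearest flanking marker", {
  mk <- marker_map(c("a", "b", "c", "d"), rep("c1", 4),
                   c(100, 200, 1000, 1100), c(0, 1, 2, 3))
  calls <- matrix(c("BY", NA, NA, "RM",
                    NA, "RM", "RM", NA), nrow = 4,
                  dimnames = list(mk$id, c("s1", "s2")))
  g <- genotype_matrix(mk, c("s1", "s2"), calls)
  gi <- impute_genotypes(g)
  expect_false(anyNA(gi$calls))
  expect_equal(unname(gi$calls[, "s1"]), c("BY", "BY", "RM", "RM"))
  expect_equal(unname(gi$calls[, "s2"]), c("RM", "RM", "RM", "RM"))
  # equidistant tie goes to the leftmost marker
  mk2 <- marker_map(c("a", "b", "c"), rep("c1", 3), c(100, 200, 300), 0:2)
  calls2 <- matrix(c("BY", NA, "RM"), 3, 1, dimnames = list(mk2$id, "s1"))
  gi2 <- impute_genotypes(genotype_matrix(mk2, "s1", calls2))
  expect_equal(unname(gi2$calls[2, 1]), "BY")
})

test_that("phenotype reader joins metadata and rejects malformed input", {
  raw <- make_raw(rbind(c(100, 250)), roles = "segregant",
                  segregant_id = c("s1", "s1"), replicate = c(1, 2))
  expect_equal(nrow(raw$samples), 2)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(raw, p1, p2)
  raw2 <- read_phenotypes(p1, p2)
  expect_equal(raw2$counts, raw$counts)
  expect_identical(raw2$samples$role, raw$samples$role)

  # a counts column without metadata is rejected
  writeLines(readLines(p2)[1:2], p2)  # drop second sample's metadata
  expect_error(read_phenotypes(p1, p2), "lacking metadata")

  expect_error(make_raw(rbind(c(-5, 10)), roles = "segregant",
                        segregant_id = "s1"), "negative")
  expect_error(make_raw(rbind(c(5, 10)), roles = "segregant",
                        segregant_id = "s1", od = NA), "OD")
})

test_that("phenotype round-trip preserves simulator output", {
  sim <- simulate_cross(small_scenario(), seed = 4)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(sim$phenotypes, p1, p2)
  raw2 <- read_phenotypes(p1, p2)
  expect_equal(raw2$counts, sim$phenotypes$counts, tolerance = 1e-5)
  expect_identical(is.na(raw2$counts), is.na(sim$phenotypes$counts))
  expect_equal(raw2$samples$od, sim$phenotypes$samples$od, tolerance = 1e-5)
})

test_that("annotation reads native TSV and converts BED coordinates", {
  genes <- gene_annotation(c("g1", "g2"), c("c1", "c2"), c(100, 5001),
                           c(1599, 6500), c(TRUE, FALSE), c("P1;P2", ""))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(genes, path)
  g2 <- read_annotation(path)
  expect_equal(g2$start, genes$start)
  expect_equal(g2$pathways, genes$pathways)
  expect_equal(pathway_set(g2$pathways[1]), c("P1", "P2"))

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t99\t1599\tg1\t1", "c2\t5000\t6500\tg2\t0"), bed)
  gb <- read_annotation(bed)
  expect_equal(gb$start, c(100, 5001))   # 0-based half-open -> 1-based inclusive
  expect_equal(gb$end, c(1599, 6500))
  expect_equal(gb$is_metabolic, c(TRUE, FALSE))
  expect_error(gene_annotation("g", "c1", 50, 10), "start > end")
})

test_that("genome layout counts bins with a per-chromosome ceiling", {
  expect_equal(n_bins(yeast_genome_layout()), 1216)
  lay <- genome_layout(c("a", "b"), c(10000, 10001))
  expect_equal(n_bins(lay), 3)  # 1 full bin + 1 full + 1 partial
  expect_error(genome_layout("a", -5), "positive")
})

test_that("write_results emits deterministic TSVs and a manifest", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  paths <- write_results(dir = d1, config = list(seed = 1))
  expect_true(all(file.exists(paths)))
  expect_equal(length(readLines(file.path(d1, "peaks.tsv"))), 1)  # header only

  pk <- data.frame(trait = "c1", model = "normal", chrom = "c2", marker = "m9",
                   peak_bp = 1234, lod = 5.4321, threshold = 3.1,
                   ci_lo_bp = 1000, ci_hi_bp = 2000, ci_lo_marker = "m8",
                   ci_hi_marker = "m10", stringsAsFactors = FALSE)
  write_results(peaks = pk, dir = d1, config = list(seed = 1))
  write_results(peaks = pk, dir = d2, config = list(seed = 1))
  expect_equal(length(readLines(file.path(d1, "peaks.tsv"))), 2)
  for (f in c("peaks.tsv", "hotspots.tsv", "heritability.tsv", "manifest.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})
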