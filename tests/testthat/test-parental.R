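# Parental differences, FDR, inheritance classification, media screen.

test_that("strain ANOVA matches hand computation and guards edge cases", {
  expect_equal(strain_anova(c(1, 1), c(1, 1)), 1)                 # no variance
  expect_equal(strain_anova(c(0, 0, 0), c(1, 1, 1)),
               .Machine$double.xmin)                              # perfect split
  # BY {1,2,3}, RM {2,3,4}: between SS 1.5, within SS 4 -> F = 1.5 on (1,4)
  expect_equal(strain_anova(c(1, 2, 3), c(2, 3, 4)),
               pf(1.5, 1, 4, lower.tail = FALSE))
  expect_equal(strain_anova(c(1, 2, 3), c(2, 3, 4)), 0.2879, tolerance = 1e-3)
  # agrees with aov for a random instance
  set.seed(1)
  a <- rnorm(6); b <- rnorm(8) + 0.5
  p_aov <- summary(stats::aov(c(a, b) ~ rep(c("BY", "RM"), c(6, 8))))[[1]][1, "Pr(>F)"]
  expect_equal(strain_anova(a, b), p_aov, tolerance = 1e-10)
  expect_error(strain_anova(1, c(1, 2)), ">= 2 replicates")
})

test_that("fdr_adjust reduces to BH when pi0 is degenerate", {
  # more than half the p-values above lambda -> pi0 estimate > 1 -> BH
  p <- c(0.01, 0.02, 0.03, 0.6, 0.8, 0.9, 0.95)
  expect_equal(fdr_adjust(p), p.adjust(p, "BH"))
  expect_equal(fdr_adjust(0.04), 0.04)           # n = 1
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
})

test_that("fdr_adjust applies the Storey pi0 shrinkage otherwise", {
  p <- c(0.01, 0.02, 0.03, 0.8)
  pi0 <- mean(p > 0.5) / 0.5                     # 0.5
  expect_equal(fdr_adjust(p), pmin(pi0 * p.adjust(p, "BH"), 1))
})

test_that("fdr_adjust is monotone and order-invariant", {
  set.seed(2)
  p <- runif(60)^1.5
  q <- fdr_adjust(p)
  o <- order(p)
  expect_false(is.unsorted(q[o]))                # monotone in p-rank
  perm <- sample(60)
  expect_equal(fdr_adjust(p[perm]), q[perm])     # returned in input order
  expect_true(all(q >= 0 & q <= 1))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("inheritance classification flags constructions correctly", {
  set.seed(3)
  by <- rnorm(10, 0, 0.05); rm <- rnorm(10, 1, 0.05)
  inside <- runif(50, 0.2, 0.8)
  cl <- classify_inheritance(inside, by, rm)
  expect_true(cl$directional)
  expect_equal(cl$n_beyond, 0)
  expect_equal(cl$p_transgressive, 1)

  beyond <- c(runif(35, 0.2, 0.8), rnorm(15, 1 + 5 * cl$sd_pool, 0.01))
  cl2 <- classify_inheritance(beyond, by, rm)
  expect_lt(cl2$p_transgressive, 1e-6)
  expect_gte(cl2$n_beyond, 15)

  expect_error(classify_inheritance(inside, 1, rm), "fewer than 2")
})

test_that("inheritance flags are invariant under joint affine transforms", {
  set.seed(4)
  by <- rnorm(8, 0, 0.1); rm <- rnorm(8, 2, 0.1)
  seg <- c(rnorm(40, 1, 0.3), rnorm(10, 4, 0.1))
  base <- classify_inheritance(seg, by, rm)
  for (ab in list(c(3, -5), c(-2, 1))) {
    tr <- classify_inheritance(ab[1] * seg + ab[2], ab[1] * by + ab[2],
                               ab[1] * rm + ab[2])
    expect_equal(tr$p_transgressive, base$p_transgressive)
    expect_equal(tr$p_directional, base$p_directional)
    expect_equal(tr$directional, base$directional)
  }
})

test_that("media screen flags media-level compounds, including the planted preset", {
  set.seed(6)
  mock <- rbind(rep(10, 3), rep(5, 3)) + matrix(rnorm(6, 0, 0.1), 2)
  bio <- rbind(rep(10, 6), rep(12, 6)) + matrix(rnorm(12, 0, 0.1), 2)
  rownames(mock) <- rownames(bio) <- c("media_like", "biological")
  scr <- media_contamination_screen(mock, bio)
  expect_true(scr$media_derived[scr$compound == "media_like"])
  expect_false(scr$media_derived[scr$compound == "biological"])

  # simulator preset planting exactly 6 media compounds
  sc <- small_scenario(n_compounds = 12, n_mock = 4, media_compounds = 1:6)
  sim <- simulate_cross(sc, seed = 30)
  fl <- floor_counts(sim$phenotypes)
  meta <- fl$samples
  lmock <- log2(fl$counts[, meta$role == "mock_extraction", drop = FALSE])
  lbio <- log2(sweep(fl$counts[, meta$role %in% c("parent_BY", "parent_RM"),
                               drop = FALSE], 2,
                     meta$od[meta$role %in% c("parent_BY", "parent_RM")], "/"))
  scr2 <- media_contamination_screen(lmock, lbio)
  expect_setequal(scr2$compound[scr2$media_derived], sprintf("cmpd%03d", 1:6))
})

test_that("parental_analysis integrates tests across compounds", {
  set.seed(5)
  n <- 30
  by <- matrix(rnorm(n * 5, 0, 0.2), n)
  rm <- matrix(rnorm(n * 6, rep(c(2, 0), c(10, 20)), 0.2), n)
  seg <- matrix(rnorm(n * 50, 0.5, 0.5), n)
  rownames(by) <- rownames(rm) <- rownames(seg) <- sprintf("c%02d", 1:n)
  pa <- parental_analysis(by, rm, seg)
  expect_equal(nrow(pa), n)
  expect_true(all(pa$significant_at[1:10]))       # planted 2-log2 difference
  expect_true(all(pa$q_value >= 0 & pa$q_value <= 1))
  expect_true(all(pa$inheritance %in%
                    c("transgressive", "directional", "both", "neither")))
})
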