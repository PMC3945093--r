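# Preprocessing: flooring, detection filter, OD normalization, replicate
# averaging, same-day reference log-ratios, and the pipeline invariants.

test_that("floor_counts replaces sub-floor and not-detected values", {
  raw <- make_raw(rbind(c(100, 31.9, NA)), roles = "segregant",
                  segregant_id = c("s1", "s2", "s3"), replicate = 1)
  fl <- floor_counts(raw, 32)
  expect_equal(unname(fl$counts[1, ]), c(100, 32, 32))
  expect_equal(unname(fl$detected[1, ]), c(TRUE, TRUE, FALSE))
})

test_that("detection filter applies the inclusive 25% boundary", {
  counts <- rbind(c(rep(NA, 8), 1000, 1000),   # 2/10 detected -> dropped
                  rep(1000, 10))               # kept
  raw <- make_raw(counts, roles = "segregant",
                  segregant_id = sprintf("s%d", 1:10), replicate = 1)
  flt <- filter_detection(raw, 0.25)
  expect_equal(flt$compounds, "cmp02")

  # exactly 25 of 100 detected is retained
  counts2 <- matrix(c(rep(NA, 75), rep(1000, 25)), 1)
  raw2 <- make_raw(counts2, roles = "segregant",
                   segregant_id = sprintf("s%d", 1:100), replicate = 1)
  expect_equal(nrow(filter_detection(raw2, 0.25)$counts), 1)
})

test_that("OD normalization and replicate averaging are arithmetic", {
  # same segregant at different ODs normalizes to a common value
  raw <- make_raw(rbind(c(500, 1000)), roles = "segregant",
                  segregant_id = "s1", replicate = c(1, 2), od = c(0.5, 1.0))
  avg <- normalize_and_average(raw)
  expect_equal(unname(avg$normalized[1, ]), c(1000, 1000))
  expect_equal(unname(avg$segregant_means[1, "s1"]), 1000)

  # replicates {100, 300} at od 1 average to 200
  raw2 <- make_raw(rbind(c(100, 300)), roles = "segregant",
                   segregant_id = "s1", replicate = c(1, 2))
  expect_equal(unname(normalize_and_average(raw2)$segregant_means[1, "s1"]), 200)

  raw3 <- make_raw(rbind(c(1, 2)), roles = "segregant",
                   segregant_id = c("s1", "s2"), replicate = 1)
  raw3$samples$od[2] <- NA
  expect_error(normalize_and_average(raw3), "smp02")
})

test_that("log-ratio to the same-day reference matches hand values", {
  # segregant 64 vs reference 32 -> log2 = 1; equality -> 0;
  # reference replicates {32, 64} (mean 48) with segregant 96 -> 1
  counts <- rbind(c(64, 32, 96, 32, 64))
  raw <- make_raw(counts,
                  roles = c("segregant", "segregant", "segregant",
                            "rm_reference", "rm_reference"),
                  segregant_id = c("sA", "sB", "sC", NA, NA),
                  replicate = c(1, 1, 1, 1, 2), day = "d1")
  # sA vs mean(32,64)=48: log2(64/48); construct per-day cases separately
  avg <- normalize_and_average(raw)
  tt <- logratio_to_reference(avg)
  expect_equal(unname(tt$values[1, "sC"]), 1)            # 96 / 48
  expect_equal(unname(tt$values[1, "sA"]), log2(64 / 48))

  one <- make_raw(rbind(c(64, 32)), roles = c("segregant", "rm_reference"),
                  segregant_id = c("sA", NA), replicate = 1, day = "d1")
  tt1 <- logratio_to_reference(normalize_and_average(one))
  expect_equal(unname(tt1$values[1, "sA"]), 1)

  same <- make_raw(rbind(c(32, 32)), roles = c("segregant", "rm_reference"),
                   segregant_id = c("sA", NA), replicate = 1, day = "d1")
  expect_equal(unname(logratio_to_reference(normalize_and_average(same))$values[1, "sA"]), 0)

  # a day without a reference is an error naming the day
  noref <- make_raw(rbind(c(64, 32)), roles = c("segregant", "rm_reference"),
                    segregant_id = c("sA", NA), replicate = 1,
                    day = c("d1", "d2"))
  expect_error(logratio_to_reference(normalize_and_average(noref)), "d1")
})

test_that("a common multiplicative day shift cancels in trait values", {
  # detect_prob 1 keeps the fixed floor constant out of play: a floored
  # value does not scale with its day, so exact cancellation needs
  # fully detected compounds
  sim <- simulate_cross(small_scenario(detect_prob = 1), seed = 20)
  raw <- sim$phenotypes
  pp1 <- preprocess_phenotypes(raw)
  day1 <- raw$samples$day == "day01"
  raw$counts[, day1] <- raw$counts[, day1] * 3.7
  pp2 <- preprocess_phenotypes(raw)
  expect_equal(pp2$traits$values, pp1$traits$values, tolerance = 1e-12)
})

test_that("normalize-then-average equals average-then-normalize at equal OD", {
  raw <- make_raw(rbind(c(120, 260), c(40, 44)), roles = "segregant",
                  segregant_id = "s1", replicate = c(1, 2), od = 0.4)
  avg <- normalize_and_average(raw)
  expect_equal(unname(avg$segregant_means[, "s1"]),
               c(mean(c(120, 260)), mean(c(40, 44))) / 0.4)
})

test_that("preprocessed trait values are finite and order-preserved", {
  sim <- simulate_cross(small_scenario(detect_prob = 0.9), seed = 21)
  pp <- preprocess_phenotypes(sim$phenotypes)
  expect_true(all(is.finite(pp$traits$values)))
  expect_identical(pp$traits$compounds,
                   intersect(sim$phenotypes$compounds, pp$traits$compounds))
  expect_true(all(pp$qc$detected_frac >= 0 & pp$qc$detected_frac <= 1))
})
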