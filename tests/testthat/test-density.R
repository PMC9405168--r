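test_that("segment densities match hand arithmetic", {
  seg <- data.frame(segment_id = "s1", stage = "glass", arc_length_um = 12.5)
  rec <- segment_density(seg, spines_from_counts("s1", M = 4, LT = 3, S = 1))
  expect_equal(rec$density_total, 6.4)
  expect_equal(rec$density_M, 3.2)
  expect_equal(rec$density_LT, 2.4)
  expect_equal(rec$density_S, 0.8)
  expect_equal(rec$density_F, 0)

  empty <- segment_density(data.frame(segment_id = "s0", stage = "glass",
                                      arc_length_um = 10),
                           spines_from_counts("s0"))
  expect_true(all(empty[grep("^density", names(empty))] == 0))

  # same counts on a doubled length: every density halves
  seg20 <- data.frame(segment_id = "s1", stage = "glass", arc_length_um = 25)
  rec20 <- segment_density(seg20, spines_from_counts("s1", M = 4, LT = 3, S = 1))
  expect_equal(rec20$density_total, rec$density_total / 2)
  expect_equal(rec20$density_M, rec$density_M / 2)
})

test_that("segment length rules and id checks are enforced", {
  seg <- data.frame(segment_id = "x", stage = "glass", arc_length_um = 8)
  expect_error(segment_density(seg, spines_from_counts("x", S = 1)),
               "at least")
  expect_silent(segment_density(seg, spines_from_counts("x", S = 1),
                                allow_short = TRUE))
  seg0 <- data.frame(segment_id = "x", stage = "glass", arc_length_um = 0)
  expect_error(segment_density(seg0, spines_from_counts("x"),
                               allow_short = TRUE), "positive")
  segok <- data.frame(segment_id = "x", stage = "glass", arc_length_um = 10)
  expect_error(segment_density(segok, spines_from_counts("y", M = 1)),
               "unknown segment")
})

test_that("class densities partition the total on generated data", {
  set.seed(5)
  ds <- generate_study(study_config(seed = 5, segments_per_stage = 25),
                       include_polylines = FALSE)
  rec <- segment_density(ds$segments, classify_spines(ds$spines))
  expect_equal(rec$density_M + rec$density_LT + rec$density_S + rec$density_F,
               rec$density_total)
  expect_true(all(rec$count_total ==
                    rec$count_M + rec$count_LT + rec$count_S + rec$count_F))
})

test_that("stage_summary reproduces n = 2 arithmetic and is order-invariant", {
  seg <- data.frame(segment_id = c("a", "b"), stage = "glass",
                    arc_length_um = 10)
  sp <- rbind(spines_from_counts("a", M = 6), spines_from_counts("b", M = 8))
  s <- stage_summary(segment_density(seg, sp))
  tot <- s[s$stage == "glass" & s$measure == "total", ]
  expect_equal(tot$mean, 7)
  expect_equal(tot$se, 1)
  expect_equal(tot$n, 2L)

  set.seed(9)
  ds <- generate_study(study_config(seed = 9, segments_per_stage = 15),
                       include_polylines = FALSE)
  rec <- segment_density(ds$segments, classify_spines(ds$spines))
  canon <- function(s) {
    s <- s[order(s$stage, s$measure), ]
    rownames(s) <- NULL
    s
  }
  s1 <- stage_summary(rec)
  s2 <- stage_summary(rec[sample(nrow(rec)), ])
  expect_equal(canon(s1), canon(s2))
})

test_that("pooled class means equal the stage-mean average in balanced designs", {
  set.seed(13)
  ds <- generate_study(study_config(seed = 13, segments_per_stage = 20),
                       include_polylines = FALSE)
  s <- stage_summary(segment_density(ds$segments, classify_spines(ds$spines)))
  for (m in c(SPINE_CLASSES, "total")) {
    pooled <- s$mean[s$stage == "pooled" & s$measure == m]
    stage_means <- s$mean[s$stage != "pooled" & s$measure == m]
    expect_equal(pooled, mean(stage_means))
  }
})

test_that("stages with fewer than 2 segments cannot be summarised", {
  seg <- data.frame(segment_id = c("a", "b", "c"),
                    stage = c("glass", "glass", "elver"),
                    arc_length_um = 10)
  rec <- segment_density(seg, spines_from_counts("a", M = 1))
  expect_error(stage_summary(rec), "fewer than 2")
})

test_that("biometric regressions recover exact and null relationships", {
  an <- data.frame(TL_cm = c(5, 10, 20, 40, 80),
                   TW_g = c(0.2, 1, 30, 100, 200),
                   BW_g = c(0.004, 0.01, 0.05, 0.1, 0.2))
  an$mean_density <- 2 + 3 * log10(an$TL_cm)  # exactly linear in log TL
  r <- suppressWarnings(biometric_regressions(an))
  expect_equal(r$r_squared[r$metric == "TL"], 1)
  expect_equal(r$slope[r$metric == "TL"], 3)

  an$mean_density <- rep(5, 5)  # constant response
  r0 <- biometric_regressions(an)
  expect_true(all(r0$r_squared == 0))
  expect_false(any(r0$significant))

  an$TL_cm[1] <- -1
  expect_error(biometric_regressions(an), "positive")
  expect_error(biometric_regressions(an[1:2, ]), "at least 3")
})
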