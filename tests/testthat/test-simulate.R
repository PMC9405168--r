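test_that("class-conditional geometries classify back to their class", {
  set.seed(51)
  for (cl in SPINE_CLASSES) {
    g <- classify_spines(sample_geometry(cl, 1000))
    expect_true(all(g$class == cl))
    expect_false(any(g$gap_flag))
  }
  set.seed(52)
  expect_true(all(sample_geometry("S", 500)$total_length_um < 1))
  expect_true(all(sample_geometry("F", 500)$total_length_um > 10))
  expect_error(sample_geometry("X", 1), "unknown")
})

test_that("per-class counts hit the requested mean under each dispersion", {
  set.seed(53)
  rt <- calibrate_rate_table()
  m_target <- rt$totals["glass"]
  counts <- sample_counts(rep(m_target, 10000), phi = 1)
  se <- sqrt(m_target / 10000)
  expect_lt(abs(mean(counts) - m_target), 3 * se)
  expect_lt(abs(stats::var(counts) - m_target), 0.2 * m_target)

  sub <- sample_counts(rep(4, 10000), phi = 0.5)
  expect_lt(abs(mean(sub) - 4), 0.1)
  expect_lt(stats::var(sub), 3)  # sub-Poisson spread

  over <- sample_counts(rep(4, 10000), phi = 3)
  expect_gt(stats::var(over), 8)  # over-dispersed
})

test_that("zero rates generate spineless segments", {
  rt0 <- as_rate_table(matrix(0, 1, 4,
                              dimnames = list("glass", SPINE_CLASSES)))
  set.seed(54)
  out <- sample_segments("glass", rt0, 20)
  expect_equal(nrow(out$spines), 0)
  expect_equal(nrow(out$segments), 20)
})

test_that("generation is a pure function of the seed", {
  cfg <- study_config(seed = 99, segments_per_stage = 8)
  d1 <- generate_study(cfg, include_polylines = TRUE)
  d2 <- generate_study(cfg, include_polylines = TRUE)
  expect_identical(d1, d2)
  d3 <- generate_study(study_config(seed = 100, segments_per_stage = 8),
                       include_polylines = FALSE)
  expect_false(identical(d1$spines, d3$spines))
})

test_that("the default design reproduces the published study shape", {
  cfg <- study_config(seed = 7)
  expect_equal(cfg$segments_per_stage, 77L)
  ds <- generate_study(cfg, include_polylines = FALSE)
  expect_equal(nrow(ds$segments), 308)
  expect_equal(nrow(ds$animals), 19)
  expect_equal(as.integer(table(ds$animals$stage)[c("glass", "elver",
                                                    "yellow", "silver")]),
               c(5L, 5L, 5L, 4L))
  # every segment's animal exists and stages agree
  idx <- match(ds$segments$animal_id, ds$animals$animal_id)
  expect_false(any(is.na(idx)))
  expect_equal(ds$segments$stage, ds$animals$stage[idx])
  expect_true(all(ds$segments$arc_length_um >= 10 &
                    ds$segments$arc_length_um <= 14))
  expect_true(all(ds$animals$TL_cm > 0 & ds$animals$TW_g > 0 &
                    ds$animals$BW_g > 0))
})

test_that("config validation rejects broken designs", {
  expect_error(study_config(), "seed")
  expect_error(study_config(seed = 1, segments_per_stage = 1), ">= 2")
  expect_error(study_config(seed = 1, segment_length_range = c(5, 14)),
               "minimum >= 10")
  expect_error(study_config(seed = 1, animals_per_stage = c(5, 5)),
               "one entry per stage")
  expect_error(study_config(seed = 1, phi = -1), "phi")
})

test_that("simulated polylines carry exactly the requested arc length", {
  set.seed(55)
  for (L in c(10, 12.7, 14)) {
    pl <- random_polyline(L)
    expect_equal(arc_length(pl), L, tolerance = 1e-9)
  }
  ds <- generate_study(study_config(seed = 56, segments_per_stage = 4),
                       include_polylines = TRUE)
  for (id in ds$segments$segment_id) {
    expect_equal(arc_length(ds$polylines[[id]]),
                 ds$segments$arc_length_um[ds$segments$segment_id == id],
                 tolerance = 1e-9)
  }
})

test_that("segments survive an SWC round trip through measurement", {
  set.seed(57)
  ds <- generate_study(study_config(seed = 57, segments_per_stage = 3),
                       include_polylines = TRUE)
  id <- ds$segments$segment_id[1]
  morph <- segment_morphology(ds, id)
  f <- tempfile(fileext = ".swc")
  write_swc(morph, f)
  back <- read_swc(f)
  expect_equal(unname(back$metadata["segment_id"]), id)
  # dendrite chain length equals the segment's arc length
  dend <- back$nodes[back$nodes$type == 3, c("x", "y", "z")]
  expect_equal(arc_length(as.matrix(dend)),
               ds$segments$arc_length_um[ds$segments$segment_id == id],
               tolerance = 1e-6)
  # re-measured spine branches classify back to their generating class
  profs <- spine_profiles(back)
  truth <- ds$spines[ds$spines$segment_id == id, ]
  expect_length(profs, nrow(truth))
  got <- vapply(profs, function(p) {
    m <- measure_spine(p, head_min_diameter = 0.12)
    classify_spine(m)$label
  }, character(1))
  expect_equal(sort(got), sort(truth$true_class))
})
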