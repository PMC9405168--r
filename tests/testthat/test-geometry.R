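test_that("arc length matches hand-computed polylines", {
  expect_equal(arc_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(arc_length(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 2)
  expect_error(arc_length(rbind(c(0, 0, 0))), "at least 2")
})

test_that("arc length is symmetric, additive and rigid-motion invariant", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_points(sample(3:12, 1))
    len <- arc_length(p)
    expect_equal(arc_length(p[nrow(p):1, ]), len)
    # additivity under concatenation at a shared joint
    ks <- 2:(nrow(p) - 1)
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(arc_length(p[1:k, , drop = FALSE]) +
                   arc_length(p[k:nrow(p), , drop = FALSE]), len)
    # rotation + translation
    q <- random_rotation()
    shift <- matrix(stats::runif(3), nrow(p), 3, byrow = TRUE)
    expect_equal(arc_length(p %*% t(q) + shift), len)
  }
})

test_that("protrusion profiles enforce their sampling invariants", {
  expect_error(protrusion_profile(c(0.1, 0.2), c(1, 1)), "start at 0")
  expect_error(protrusion_profile(c(0, 0.2, 0.2), c(1, 1, 1)),
               "strictly increasing")
  expect_error(protrusion_profile(c(0, 0.2), c(1, -1)), "positive")
  expect_error(protrusion_profile(0, 1), "at least 2")
})

test_that("measure_spine extracts head and neck from a bulbous profile", {
  p <- protrusion_profile(seq(0, 1, by = 0.2),
                          c(0.40, 0.25, 0.20, 0.70, 0.80, 0.60))
  m <- measure_spine(p, head_min_diameter = 0.3, head_prominence_ratio = 1.2)
  expect_true(m$has_head)
  expect_equal(m$total_length, 1.0)
  expect_equal(m$head_diameter, 0.80)
  expect_equal(m$neck_max_diameter, 0.40)
  expect_equal(m$neck_length, 0.40)
})

test_that("measure_spine calls tapering and uniform profiles headless", {
  taper <- protrusion_profile(c(0, 0.3, 0.6, 0.9), c(0.4, 0.3, 0.2, 0.1))
  m <- measure_spine(taper)
  expect_false(m$has_head)
  expect_equal(m$head_diameter, 0)
  expect_equal(m$neck_max_diameter, 0)
  expect_equal(m$neck_length, 0)

  filo <- protrusion_profile(c(0, 6, 12), c(0.2, 0.2, 0.2))
  m2 <- measure_spine(filo)
  expect_false(m2$has_head)
  expect_equal(m2$total_length, 12)
})

test_that("measure_spine never reports a head thinner than the neck", {
  # bulbous base, small distal bump: prominence passes but the 'head'
  # would be thinner than the neck region's maximum -> headless
  p <- protrusion_profile(c(0, 0.3, 0.6), c(0.9, 0.2, 0.5))
  expect_false(measure_spine(p)$has_head)
})

test_that("measure_spine is scale-consistent in the diameters", {
  set.seed(7)
  for (i in 1:25) {
    arc <- cumsum(c(0, stats::runif(sample(3:9, 1), 0.05, 0.5)))
    d <- stats::runif(length(arc), 0.1, 1)
    m1 <- measure_spine(protrusion_profile(arc, d))
    for (c in c(0.5, 3)) {
      m2 <- measure_spine(protrusion_profile(arc, c * d),
                          head_min_diameter = 0.3 * c)
      expect_equal(m2$has_head, m1$has_head)
      expect_equal(m2$total_length, m1$total_length)
      expect_equal(m2$head_diameter, c * m1$head_diameter)
      expect_equal(m2$neck_max_diameter, c * m1$neck_max_diameter)
      expect_equal(m2$neck_length, m1$neck_length)
    }
  }
})

test_that("spine_metrics rejects inconsistent geometry", {
  expect_error(spine_metrics(-1, FALSE), "positive")
  expect_error(spine_metrics(1, TRUE, head_diameter = 0.3,
                             neck_max_diameter = 0.4, neck_length = 0.2),
               "head_diameter > neck_max_diameter")
  expect_error(spine_metrics(1, TRUE, head_diameter = 0.5,
                             neck_max_diameter = 0.3, neck_length = 1.2),
               "neck_length")
  expect_error(spine_metrics(1, FALSE, head_diameter = 0.2), "zero")
})
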