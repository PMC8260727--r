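straight_base <- function(lo = -50, hi = 50)
  capsule_baseline(rbind(c(lo, 0), c(hi, 0)))

test_that("constructed protrusions are measured exactly", {
  base <- straight_base()
  rect <- rbind(c(0, 0), c(0, 1.2), c(3, 1.2), c(3, 0))
  m <- measure_focus(rect, base)
  expect_equal(m$radial_mm, 1.2, tolerance = 1e-12)
  expect_equal(m$width_mm, 3.0, tolerance = 1e-12)
  expect_equal(m$area_mm2, 3.6, tolerance = 1e-12)
  tri <- rbind(c(0, 0), c(0.5, 2.5), c(1, 0))
  m2 <- measure_focus(tri, base)
  expect_equal(m2$radial_mm, 2.5, tolerance = 1e-12)
  expect_equal(m2$width_mm, 1.0, tolerance = 1e-12)
  expect_equal(m2$area_mm2, 2.5, tolerance = 1e-12)
})

test_that("randomized fixtures recover ground truth within 1e-6", {
  for (btype in c("straight", "arc")) {
    fx <- generate_geometry_fixture(25, baseline_type = btype, seed = 11)
    m <- measure_fixture(fx)
    truth_r <- vapply(fx$foci, `[[`, numeric(1), "true_r")
    truth_w <- vapply(fx$foci, `[[`, numeric(1), "true_w")
    expect_lt(max(abs(m$r_mm - truth_r)), 1e-6)
    expect_lt(max(abs(m$w_mm - truth_w)), 1e-6)
    expect_identical(m$area_mm2, m$r_mm * m$w_mm)  # exact product identity
  }
})

test_that("measurements agree with the vertex oracle on small polygons", {
  set.seed(21)
  base <- straight_base()
  for (i in 1:50) {
    poly <- random_protrusion(x0 = runif(1, -20, 10),
                              height = runif(1, 0.1, 5),
                              width = runif(1, 0.3, 8))
    m <- measure_focus(poly, base, outward = "left")
    o <- oracle_measure_straight(poly)
    expect_equal(m$radial_mm, o$r, tolerance = 1e-9)
    expect_equal(m$width_mm, o$w, tolerance = 1e-9)
  }
})

test_that("measurement is invariant under rigid motion", {
  set.seed(31)
  poly <- random_protrusion(height = 2.2, width = 4.1)
  base_pts <- rbind(c(-30, 0), c(-10, 0), c(15, 0), c(40, 0))
  ref <- measure_focus(poly, capsule_baseline(base_pts))
  for (i in 1:10) {
    ang <- runif(1, 0, 2 * pi); shift <- runif(2, -50, 50)
    m <- measure_focus(rigid_transform(poly, ang, shift),
                       capsule_baseline(rigid_transform(base_pts, ang, shift)))
    expect_equal(m$radial_mm, ref$radial_mm, tolerance = 1e-9)
    expect_equal(m$width_mm, ref$width_mm, tolerance = 1e-9)
    expect_equal(m$area_mm2, ref$area_mm2, tolerance = 1e-9)
  }
})

test_that("outward enlargement never decreases the radial distance", {
  set.seed(41)
  base <- straight_base()
  for (i in 1:20) {
    h <- runif(1, 0.5, 3); w <- runif(1, 1, 6)
    poly <- rbind(c(0, 0), c(w / 3, h), c(2 * w / 3, h * 0.8), c(w, 0))
    grow <- runif(1, 1, 2)
    bigger <- poly
    bigger[, 2] <- bigger[, 2] * grow  # superset on the outward side
    r1 <- measure_focus(poly, base)$radial_mm
    r2 <- measure_focus(bigger, base)$radial_mm
    expect_gte(r2, r1 - 1e-12)
  }
})

test_that("a polygon inside the capsule yields the no-EPE signal", {
  base <- straight_base()
  inside <- rbind(c(0, -1), c(2, -1), c(2, -3), c(0, -3))
  m <- measure_focus(inside, base, outward = "left")
  expect_true(m$no_epe)
  expect_identical(m$radial_mm, 0)
  # malformed input stays an error, distinct from the no-EPE signal
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(measure_focus(bowtie, base), "self-intersecting")
})

test_that("baseline gaps are imputed as straight chords", {
  b0 <- capsule_baseline(rbind(c(0, 0), c(4, 0)))
  expect_identical(impute_baseline(b0), b0)  # no gaps: unchanged
  # collinear chord across a gap
  b1 <- capsule_baseline(rbind(c(0, 0), c(1, 0), c(3, 0), c(4, 0)),
                         gap_spans = list(c(2, 3)))
  ib1 <- impute_baseline(b1)
  expect_null(ib1$gap_spans)
  expect_equal(ib1$points, rbind(c(0, 0), c(1, 0), c(3, 0), c(4, 0)))
  # curved capsule: points inside the gap are dropped, flanking endpoints
  # joined by the straight segment
  th <- seq(0, pi, length.out = 7)
  arc <- cbind(cos(th), sin(th))
  b2 <- capsule_baseline(arc, gap_spans = list(c(2, 6)))
  ib2 <- impute_baseline(b2)
  expect_equal(nrow(ib2$points), 4)
  expect_equal(ib2$points[2, ], arc[2, ])
  expect_equal(ib2$points[3, ], arc[6, ])
  expect_error(impute_baseline(
    capsule_baseline(rbind(c(0, 0), c(1, 0)), gap_spans = list(c(1, 2)))),
    "whole capsule")
  # measurement over an imputed gap works end to end
  fx <- generate_geometry_fixture(5, baseline_type = "gap", seed = 3)
  m <- measure_fixture(fx)
  truth_r <- vapply(fx$foci, `[[`, numeric(1), "true_r")
  expect_lt(max(abs(m$r_mm - truth_r)), 1e-6)
})

test_that("contour shape classification follows the two-type rule", {
  expect_identical(classify_shape(2.1, 1.0), "church_spire")
  expect_identical(classify_shape(2.0, 1.0), "broad_sessile")  # strict boundary
  # flat, wide extension: short radial distance, long footprint
  expect_identical(classify_shape(0.4, 6.5), "broad_sessile")
  expect_identical(classify_shape(c(5, 0.1), c(1, 1)),
                   c("church_spire", "broad_sessile"))
  expect_error(classify_shape(-1, 2), "domain error")
  expect_error(classify_shape(1, 0), "domain error")
})

test_that("focus counting merges by nodule identity", {
  expect_identical(count_epe_foci(c("A", "A")), 1L)
  expect_identical(count_epe_foci(c("A", "B")), 2L)
  expect_identical(count_epe_foci(c("A", "A", "B", "C", "C", "C")), 3L)
  expect_identical(count_epe_foci(data.frame(nodule_id = c("x", "y", "x"))), 2L)
  expect_error(count_epe_foci(c("A", NA)), "nodule_id")
  expect_error(count_epe_foci(data.frame(r_mm = 1)), "nodule_id")
})

test_that("EPE index selection takes the longest radial distance", {
  f <- data.frame(r_mm = c(0.5, 2.41), area_mm2 = c(5, 1))
  expect_equal(select_epe_index(f)$r_mm, 2.41)
  single <- data.frame(r_mm = 1.1, area_mm2 = 3)
  expect_equal(select_epe_index(single), single)
  tie <- data.frame(r_mm = c(1.0, 1.0), area_mm2 = c(2.0, 3.0))
  expect_equal(select_epe_index(tie)$area_mm2, 3.0)
  expect_error(select_epe_index(data.frame(r_mm = numeric(0))), "non-empty")
})

test_that("fixtures round-trip through WKT with manifest intact", {
  fx <- generate_geometry_fixture(6, seed = 8, duplicate_nodule_prob = 0.5)
  d <- tempfile()
  write_geometry_fixture(fx, d)
  fx2 <- read_geometry_fixture(d)
  expect_equal(fx2$expected_focus_count, fx$expected_focus_count)
  expect_equal(fx2$baseline$points, fx$baseline$points)
  m1 <- measure_fixture(fx); m2 <- measure_fixture(fx2)
  expect_equal(m2$r_mm, m1$r_mm, tolerance = 1e-12)
  expect_equal(m2$nodule_id, m1$nodule_id)
  # same-nodule tagging drives the expected focus count below n_foci
  expect_lt(fx$expected_focus_count, 6)
  # a church-spire ground truth is labelled as such
  spire <- generate_geometry_fixture(1, heights = c(2.5, 2.5),
                                     widths = c(1, 1), seed = 2)
  expect_identical(spire$foci[[1]]$true_shape, "church_spire")
  expect_error(generate_geometry_fixture(2, heights = c(-1, 2)), "fixture error")
})
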