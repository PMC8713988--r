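# outline_detection: polar DP segmentation, tracking, polygon area.

test_that("detector recovers a bright disk to within a pixel", {
  d <- make_disk(80)
  o <- detect_outline(d$img, d$centre, r_min = 40, r_max = 110)
  expect_lt(abs(mean(o$radii_px) - 80), 1)
  expect_lt(max(abs(o$centre - d$centre)), 0.5)
  expect_gte(nrow(o$boundary), 36)
})

test_that("detector recovers an ellipse area within 2 percent", {
  e <- make_ellipse(90, 70)
  o <- detect_outline(e$img, e$centre, r_min = 40, r_max = 110)
  expect_lt(abs(polygon_area(o, 1) / (pi * 90 * 70) - 1), 0.02)
})

test_that("centre equals the shoelace centroid of the boundary", {
  d <- make_disk(60)
  o <- detect_outline(d$img, d$centre, r_min = 30, r_max = 90)
  expect_equal(o$centre, zygoflow:::polygon_centroid(o$boundary),
               tolerance = 1e-6)
})

test_that("infinite temporal weight reproduces the previous outline", {
  d <- make_disk(80)
  prev <- outline_from_radius(function(a) 75 + 3 * sin(zygoflow:::deg2rad(2 * a)),
                              centre = d$centre)
  o <- detect_outline(d$img, d$centre, r_min = 40, r_max = 110, prev = prev,
                      temporal_weight = 1e9)
  expect_lt(max(abs(o$radii_px - prev$radii_px)), 0.51)
})

test_that("DP objective matches exhaustive enumeration on small grids", {
  set.seed(42)
  for (rep in 1:4) {
    A <- sample(6:10, 1)
    R <- sample(4:6, 1)
    E <- matrix(runif(A * R), A, R)
    sm <- runif(1, 0, 0.5)
    sol <- polar_dp(E, smoothing = sm, max_step = 1, coarse_step = 1)
    expect_equal(sol$objective, brute_force_dp(E, smoothing = sm),
                 tolerance = 1e-10)
  }
})

test_that("DP with temporal bias matches enumeration", {
  set.seed(7)
  A <- 8; R <- 5
  E <- matrix(runif(A * R), A, R)
  r_prev <- sample(2:4, A, replace = TRUE)
  sol <- polar_dp(E, smoothing = 0.2, temporal_weight = 0.3, r_prev = r_prev,
                  max_step = 1, coarse_step = 1)
  expect_equal(sol$objective,
               brute_force_dp(E, 0.2, 0.3, r_prev), tolerance = 1e-10)
})

test_that("radial roughness is non-increasing in the smoothing factor", {
  set.seed(5)
  d <- make_disk(60)
  img <- d$img + matrix(rnorm(length(d$img), 0, 0.05), nrow(d$img))
  rough <- vapply(c(0, 0.05, 0.2, 1, 5), function(sm) {
    o <- detect_outline(img, d$centre, r_min = 30, r_max = 90, smoothing = sm,
                        coarse_step = 1)
    sum(diff(c(o$radii_px, o$radii_px[1]))^2)
  }, numeric(1))
  expect_true(all(diff(rough) <= 1e-9))
})

test_that("outline is invariant to positive intensity scaling", {
  set.seed(9)
  d <- make_disk(70)
  img <- d$img + matrix(rnorm(length(d$img), 0, 0.02), nrow(d$img))
  o1 <- detect_outline(img, d$centre, r_min = 35, r_max = 100)
  o2 <- detect_outline(img * 7.3, d$centre, r_min = 35, r_max = 100)
  expect_identical(o1$radii_px, o2$radii_px)
})

test_that("segmentation failure is signalled on flat images", {
  flat <- matrix(0.5, 101, 101)
  expect_error(detect_outline(flat, c(51, 51), r_min = 10, r_max = 40),
               "segmentation failure")
  expect_error(detect_outline(flat, c(500, 51), r_min = 10, r_max = 40),
               "outside")
})

test_that("tracking a static scene yields self-consistent outlines", {
  d <- make_disk(60, margin = 25)
  st <- frame_stack(rep(list(d$img), 10), 0.5, 2)
  outl <- track_outlines(st, d$centre, r_min = 30, r_max = 80)
  base <- outl[[1]]$radii_px
  for (o in outl) expect_lt(mean(abs(o$radii_px - base)), 1)
})

test_that("tracking follows a rigid translation of 2 px per frame", {
  H <- 201
  rows <- matrix(1:H, H, H); cols <- t(rows)
  frames <- lapply(0:5, function(k) {
    ctr <- c(70 + 2 * k, 70 + 2 * k)
    r <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
    ifelse(r <= 50, 0.7, 0.3)
  })
  st <- frame_stack(frames, 0.5, 2)
  outl <- track_outlines(st, c(70, 70), r_min = 25, r_max = 70)
  centres <- t(vapply(outl, function(o) o$centre, numeric(2)))
  steps <- diff(centres)
  expect_lt(max(abs(steps - 2)), 0.5)
})

test_that("a noise frame is interpolated and flagged", {
  set.seed(1)
  d <- make_disk(60, margin = 25)
  frames <- rep(list(d$img), 5)
  frames[[3]] <- matrix(0.5, nrow(d$img), ncol(d$img))  # featureless
  st <- frame_stack(frames, 0.5, 2)
  outl <- track_outlines(st, d$centre, r_min = 30, r_max = 80)
  expect_true(outl[[3]]$interpolated)
  expect_false(outl[[2]]$interpolated)
  expect_lt(mean(abs(outl[[3]]$radii_px - outl[[2]]$radii_px)), 1)
})

test_that("tracking aborts when most frames fail", {
  d <- make_disk(60, margin = 25)
  frames <- c(list(d$img), rep(list(matrix(0.5, nrow(d$img), ncol(d$img))), 4))
  st <- frame_stack(frames, 0.5, 2)
  expect_error(track_outlines(st, d$centre, r_min = 30, r_max = 80), "failed")
})

test_that("polygon_area matches analytic areas and ignores orientation", {
  sq <- cbind(row = c(1, 1, 101, 101), col = c(1, 101, 101, 1))
  expect_equal(polygon_area(sq, 0.5), 2500)
  expect_equal(polygon_area(sq[4:1, ], 0.5), 2500)

  ang <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- cbind(row = 100 + 80 * sin(ang), col = 100 + 80 * cos(ang))
  expect_lt(abs(polygon_area(circ, 0.26) / (pi * 80^2 * 0.26^2) - 1), 0.01)

  tiny <- cbind(row = c(1, 1, 2), col = c(1, 2, 1))
  expect_error(polygon_area(tiny, 1), "degenerate")
})
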