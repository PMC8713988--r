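# piv: multi-pass NCC displacement recovery, validation, summaries.

test_that("rigid integer translation is recovered within 0.2 px", {
  p <- translated_pair(256, dr = 3, dc = -2)
  # pattern displaced by (3, -2): b(x) = a(x - d) with d = (3, -2)
  f <- piv_pair(p$a, p$b, 64, 32)
  expect_gt(mean(f$valid), 0.9)
  err <- sqrt((f$d_row[f$valid] - 3)^2 + (f$d_col[f$valid] + 2)^2)
  expect_lt(sqrt(mean(err^2)), 0.2)
})

test_that("sub-pixel translation is recovered by the Gaussian peak fit", {
  # synthesize a 1.5 px row displacement by sampling a smooth texture
  base <- make_texture(300, seed = 4)
  rows <- matrix(1:256, 256, 256); cols <- t(rows)
  a <- base[21:276, 21:276]
  b <- matrix(bilinear_sample(base, as.vector(rows + 20 - 1.5),
                              as.vector(cols + 20)), 256)
  f <- piv_pair(a, b, 64, 32)
  v <- c(mean(f$d_row[f$valid]), mean(f$d_col[f$valid]))
  expect_lt(abs(v[1] - 1.5), 0.1)
  expect_lt(abs(v[2]), 0.1)
})

test_that("identical frames give zero vectors", {
  a <- make_texture(192, seed = 2)
  f <- piv_pair(a, a, 64, 32)
  expect_true(all(abs(f$d_row[f$valid]) < 0.05))
  expect_true(all(abs(f$d_col[f$valid]) < 0.05))
})

test_that("uniform frames yield no valid vectors, not an error", {
  a <- matrix(0.5, 192, 192)
  f <- piv_pair(a, a, 64, 32)
  expect_false(any(f$valid))
})

test_that("recovered displacement is linear in the true displacement", {
  for (d in list(c(1, 0), c(2, 0), c(4, 0), c(0, 3))) {
    p <- translated_pair(256, dr = d[1], dc = d[2], seed = 5)
    f <- piv_pair(p$a, p$b, 64, 32)
    expect_lt(abs(mean(f$d_row[f$valid]) - d[1]), 0.2)
    expect_lt(abs(mean(f$d_col[f$valid]) - d[2]), 0.2)
  }
})

test_that("reversing the frame order negates the field", {
  p <- translated_pair(256, dr = 4, dc = -3, seed = 6)
  f1 <- piv_pair(p$a, p$b, 64, 32)
  f2 <- piv_pair(p$b, p$a, 64, 32)
  sel <- f1$valid & f2$valid
  expect_gt(sum(sel), 50)
  expect_lt(sqrt(mean((f1$d_row[sel] + f2$d_row[sel])^2)), 0.2)
  expect_lt(sqrt(mean((f1$d_col[sel] + f2$d_col[sel])^2)), 0.2)
})

test_that("the multi-pass schedule beats a single coarse pass on shear", {
  # horizontal shear: column displacement proportional to row
  base <- make_texture(300, seed = 8)
  n <- 256
  rows <- matrix(1:n, n, n); cols <- t(rows)
  shear <- 16 * (rows - n / 2) / n  # +-8 px across the frame
  a <- base[21:(20 + n), 21:(20 + n)]
  b <- matrix(bilinear_sample(base, as.vector(rows + 20),
                              as.vector(cols + 20 - shear)), n)
  rms_for <- function(f) {
    true_dc <- 16 * (f$grid_rows - n / 2) / n
    err2 <- (sweep(f$d_col, 1, true_dc))^2 + f$d_row^2
    sqrt(mean(err2[f$valid]))
  }
  multi <- piv_pair(a, b, 64, 32)
  single <- piv_pair(a, b, 64, 64)
  expect_lte(rms_for(multi), rms_for(single))
})

test_that("vectors are capped at the search-range bound and masked", {
  p <- translated_pair(256, dr = 2, dc = 0, seed = 9)
  mask <- matrix(FALSE, 256, 256)
  mask[1:128, ] <- TRUE
  f <- piv_pair(p$a, p$b, 64, 32, mask = mask)
  ngr <- length(f$grid_rows)
  below <- matrix(rep(f$grid_rows > 130, times = length(f$grid_cols)), ngr)
  expect_false(any(f$valid & below))
  expect_true(all(sqrt(f$d_row[f$valid]^2 + f$d_col[f$valid]^2) <= 32))
})

test_that("mean_vector averages valid in-region vectors in um/min", {
  f <- uniform_field(2, -1, frame_interval = 2, pixel_size = 0.5)
  mv <- mean_vector(f)
  expect_equal(as.numeric(mv), c(2, -1) * 0.5 / 2, tolerance = 1e-12)

  # antisymmetric rotation field: means cancel
  fr <- rotation_field(0.05)
  expect_lt(max(abs(mean_vector(fr))), 1e-10)

  # masking halves the averaging set
  fh <- uniform_field(1, 0)
  fh$d_row[1:7, ] <- 5
  fh$valid[1:7, ] <- FALSE
  mvh <- mean_vector(fh)
  expect_equal(as.numeric(mvh)[1], 1)
  expect_equal(attr(mvh, "n"), sum(fh$valid))

  fn <- uniform_field(1, 0)
  fn$valid[] <- FALSE
  expect_error(mean_vector(fn), "no valid vectors")
})

test_that("mean_magnitude matches the solid-body speed profile", {
  f <- uniform_field(3, 4, pixel_size = 0.5, frame_interval = 2)
  expect_equal(as.numeric(mean_magnitude(f, c(0, 1000, 0, 1000))),
               5 * 0.5 / 2, tolerance = 1e-12)

  om <- 0.05
  fr <- rotation_field(om)
  ctr <- mean(fr$grid_rows)
  # annulus as a thin rectangle at radius band around [r1, r2] on one side
  r1 <- 32; r2 <- 64
  rect <- c(ctr - 8, ctr + 8, ctr + r1, ctr + r2)
  got <- as.numeric(mean_magnitude(fr, rect))
  rr <- rep(fr$grid_rows, times = length(fr$grid_cols))
  cc <- rep(fr$grid_cols, each = length(fr$grid_rows))
  sel <- rr >= rect[1] & rr <= rect[2] & cc >= rect[3] & cc <= rect[4]
  expected <- om * mean(sqrt((rr[sel] - ctr)^2 + (cc[sel] - ctr)^2))
  expect_equal(got, expected, tolerance = 0.02)

  fr$valid[] <- FALSE
  expect_error(mean_magnitude(fr, rect), "no valid grid point")
})

test_that("field export carries units and validity", {
  f <- uniform_field(1, 1, pixel_size = 0.5, frame_interval = 2)
  df <- field_to_df(f)
  expect_true(all(c("row", "col", "d_row_px", "d_col_px", "speed_um_min",
                    "valid") %in% names(df)))
  expect_equal(df$speed_um_min[1], sqrt(2) * 0.5 / 2, tolerance = 1e-12)
})
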