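# vorticity: least-squares curl on masked fields, half-cell splitting,
# chi-squared sign comparisons.

test_that("solid-body rotation yields vorticity 2*omega within 10 percent", {
  om <- 0.05
  vf <- vorticity_field(rotation_field(om))
  expect_lt(abs(mean(vf$vorticity, na.rm = TRUE) / (2 * om) - 1), 0.10)
})

test_that("vorticity survives 40 percent random invalidation within 15 percent", {
  om <- 0.05
  f <- rotation_field(om)
  set.seed(21)
  f$valid[sample(length(f$valid), round(0.4 * length(f$valid)))] <- FALSE
  vf <- vorticity_field(f)
  expect_lt(abs(mean(vf$vorticity, na.rm = TRUE) / (2 * om) - 1), 0.15)
})

test_that("uniform translation is curl-free", {
  vf <- vorticity_field(uniform_field(2, 1))
  expect_lt(max(abs(vf$vorticity), na.rm = TRUE), 0.005)
})

test_that("least-squares curl equals central differences on linear fields", {
  # random linear velocity field: gradients are constant, so the 3x3
  # least-squares fit and central differences must agree to round-off
  set.seed(31)
  g <- rotation_field(0)
  a <- rnorm(6, 0, 0.05)
  dy <- outer(g$grid_rows - mean(g$grid_rows), rep(1, length(g$grid_cols)))
  dx <- outer(rep(1, length(g$grid_rows)), g$grid_cols - mean(g$grid_cols))
  g$d_col <- a[1] + a[2] * dx + a[3] * dy
  g$d_row <- a[4] + a[5] * dx + a[6] * dy
  vf <- vorticity_field(g)
  h <- diff(g$grid_rows)[1]
  cd <- function(i, j) {
    du_dy <- (g$d_col[i + 1, j] - g$d_col[i - 1, j]) / (2 * h)
    dv_dx <- (g$d_row[i, j + 1] - g$d_row[i, j - 1]) / (2 * h)
    du_dy - dv_dx
  }
  for (i in c(3, 8)) for (j in c(4, 11)) {
    expect_equal(vf$vorticity[i, j], cd(i, j), tolerance = 1e-6)
  }
})

test_that("negating the field flips every vorticity sign", {
  f <- rotation_field(0.04)
  neg <- f
  neg$d_row <- -f$d_row; neg$d_col <- -f$d_col
  v1 <- vorticity_field(f)$vorticity
  v2 <- vorticity_field(neg)$vorticity
  expect_equal(v2, -v1, tolerance = 1e-12)
})

test_that("a 90 degree rigid rotation preserves mean vorticity", {
  set.seed(41)
  f <- rotation_field(0.05)
  f$d_row <- f$d_row + matrix(rnorm(length(f$d_row), 0, 0.1), nrow(f$d_row))
  f$d_col <- f$d_col + matrix(rnorm(length(f$d_col), 0, 0.1), nrow(f$d_col))
  # rotate grid and vectors by 90 deg clockwise on screen:
  # (row, col) -> (col, N - row); (d_row, d_col) -> (d_col, -d_row)
  g <- f
  g$d_row <- t(f$d_col)[, rev(seq_len(nrow(f$d_col)))]
  g$d_col <- -t(f$d_row)[, rev(seq_len(nrow(f$d_row)))]
  g$valid <- t(f$valid)[, rev(seq_len(nrow(f$valid)))]
  v1 <- mean(vorticity_field(f)$vorticity, na.rm = TRUE)
  v2 <- mean(vorticity_field(g)$vorticity, na.rm = TRUE)
  expect_lt(abs(v2 / v1 - 1), 0.05)
})

test_that("region series assigns signs with a noise floor and support rule", {
  f <- rotation_field(0.05)
  s <- region_vorticity_series(list(f, f, f), NULL, "cell")
  expect_equal(s$sign, c(1L, 1L, 1L))
  expect_true(all(s$n_valid >= 4))

  # pure noise stays at sign 0 under the default floor
  set.seed(51)
  noise_fields <- lapply(1:6, function(k) {
    g <- rotation_field(0)
    g$d_row <- matrix(rnorm(length(g$d_row), 0, 0.02), nrow(g$d_row))
    g$d_col <- matrix(rnorm(length(g$d_col), 0, 0.02), nrow(g$d_col))
    g
  })
  sn <- region_vorticity_series(noise_fields, NULL, "cell")
  expect_gte(mean(sn$sign == 0), 0.5)
})

test_that("mirrored vortices give opposite per-cell signs", {
  f <- rotation_field(0.05, ngrid = 16)
  g <- f
  g$d_row <- -f$d_row; g$d_col <- -f$d_col
  s1 <- region_vorticity_series(rep(list(f), 8), NULL, "cell-1")
  s2 <- region_vorticity_series(rep(list(g), 8), NULL, "cell-2")
  expect_true(all(s1$sign == 1))
  expect_true(all(s2$sign == -1))
})

test_that("split_cell_halves bisects an ellipse into equal disjoint halves", {
  H <- 201
  rows <- matrix(1:H, H, H); cols <- t(rows)
  mask <- ((rows - 101) / 80)^2 + ((cols - 101) / 50)^2 <= 1
  sp <- split_cell_halves(mask)
  expect_false(any(sp$half_a & sp$half_b))
  expect_identical(sp$half_a | sp$half_b, mask)
  expect_lt(abs(sum(sp$half_a) / sum(sp$half_b) - 1), 0.02)
  # the computed longest axis is the ellipse major axis (vertical)
  axis_dir <- abs(sp$axis[2, ] - sp$axis[1, ])
  expect_gt(axis_dir[1], axis_dir[2])
})

test_that("an annotated axis overrides the computed one", {
  H <- 101
  rows <- matrix(1:H, H, H); cols <- t(rows)
  mask <- (rows - 51)^2 + (cols - 51)^2 <= 40^2
  ax <- rbind(c(51, 11), c(51, 91))  # horizontal
  sp <- split_cell_halves(mask, axis = ax)
  expect_identical(sp$axis, ax)
  # halves split left/right of the vertical bisector
  expect_true(all(which(sp$half_a, arr.ind = TRUE)[, 2] >= 51))
})

test_that("an L-shaped mask still splits disjointly and exhaustively", {
  mask <- matrix(FALSE, 120, 120)
  mask[10:110, 10:40] <- TRUE
  mask[80:110, 10:110] <- TRUE
  sp <- split_cell_halves(mask)
  expect_false(any(sp$half_a & sp$half_b))
  expect_identical(sp$half_a | sp$half_b, mask)
  expect_equal(sum(sp$half_a) + sum(sp$half_b), sum(mask))
})

test_that("erode_mask shrinks a disc by the requested number of pixels", {
  H <- 101
  rows <- matrix(1:H, H, H); cols <- t(rows)
  mask <- (rows - 51)^2 + (cols - 51)^2 <= 30^2
  er <- erode_mask(mask, 5)
  r_er <- sqrt(sum(er) / pi)
  expect_lt(abs(r_er - 25), 1.5)
  expect_true(all(mask[er]))
})

make_sign_series <- function(signs, interval = 2) {
  structure(
    data.frame(pair = seq_along(signs),
               time_min = (seq_along(signs) - 1) * interval,
               mean_vorticity = signs * 0.01, n_valid = 20,
               sign = as.integer(signs)),
    region_id = "x", noise_floor = 0.005,
    class = c("zf_vort_series", "data.frame")
  )
}

test_that("fully opposed signs give the closed-form chi-square", {
  a <- make_sign_series(rep(1, 20), interval = 5)
  b <- make_sign_series(rep(-1, 20), interval = 5)
  cmp <- compare_signs(a, b, window = 100)
  expect_equal(nrow(cmp), 1)
  # 20/0 vs 0/20: expected counts are all 10 (>= 5), so no Yates: X^2 = 40
  oracle <- stats::chisq.test(rbind(c(20, 0), c(0, 20)), correct = FALSE)
  expect_equal(cmp$chi_square, unname(oracle$statistic))
  expect_equal(cmp$chi_square, 40)
  expect_lt(cmp$p_value, 0.001)
})

test_that("identical sign series give chi-square 0 and p 1", {
  a <- make_sign_series(rep(c(1, -1), 10), interval = 5)
  cmp <- compare_signs(a, a, window = 100)
  expect_equal(cmp$chi_square, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("windows with undefined signs are untestable", {
  a <- make_sign_series(rep(1, 20), interval = 5)
  z <- make_sign_series(rep(0, 20), interval = 5)
  cmp <- compare_signs(a, z, window = 100)
  expect_false(cmp$testable[1])
  expect_true(is.na(cmp$chi_square[1]))
})

test_that("Yates correction is applied when expected counts are small", {
  a <- make_sign_series(rep(1, 4), interval = 30)
  b <- make_sign_series(rep(-1, 4), interval = 30)
  cmp <- compare_signs(a, b, window = 130, min_defined = 4)
  oracle <- suppressWarnings(
    stats::chisq.test(rbind(c(4, 0), c(0, 4)), correct = TRUE)
  )
  expect_true(cmp$yates[1])
  expect_equal(cmp$chi_square[1], unname(oracle$statistic))
})
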