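# Shared geometry and sampling helpers.

deg2rad <- function(deg) deg * pi / 180

#' Unit direction of an image angle
#'
#' Angles are measured from image "up" (decreasing row), increasing toward
#' image-right (clockwise as displayed). Returns the `(row, col)` unit vector.
#'
#' @param angle_deg angle in degrees.
#' @return numeric length-2 vector `(d_row, d_col)`.
#' @keywords internal
angle_dir <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  c(-cos(a), sin(a))
}

# Angle (deg, in the package convention) of the vector from `from` to `to`,
# both (row, col). Result in [0, 360).
point_angle <- function(from, to) {
  d_row <- to[1] - from[1]
  d_col <- to[2] - from[2]
  (atan2(d_col, -d_row) * 180 / pi) %% 360
}

#' Bilinear image sampling
#'
#' Samples `img` at fractional `(row, col)` positions. Positions outside the
#' image return `fill`.
#'
#' @param img numeric matrix.
#' @param rows,cols numeric vectors of equal length, fractional positions.
#' @param fill value for out-of-bounds samples.
#' @return numeric vector of sampled intensities.
#' @keywords internal
bilinear_sample <- function(img, rows, cols, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0;   fc <- cols - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  # Points exactly on the last row/col still sample cleanly
  edge <- (rows >= 1 & rows <= nr & cols >= 1 & cols <= nc) & !ok
  out <- rep(fill, length(rows))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i01 <- cbind(r0[ok], c0[ok] + 1)
    i10 <- cbind(r0[ok] + 1, c0[ok]); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i11] * fr[ok] * fc[ok]
  }
  if (any(edge)) {
    out[edge] <- img[cbind(pmin(pmax(round(rows[edge]), 1), nr),
                           pmin(pmax(round(cols[edge]), 1), nc))]
  }
  out
}

# Shift a matrix by (dr, dc) with edge replication; used by the Sobel filter.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1), nc)
  m[ri, ci, drop = FALSE]
}

#' Sobel gradient magnitude
#'
#' 3x3 Sobel filter with edge replication at the borders.
#'
#' @param img numeric matrix.
#' @return matrix of gradient magnitudes, same shape as `img`.
#' @export
sobel_magnitude <- function(img) {
  stopifnot(is.matrix(img))
  # Gradient along columns (image x)
  gx <- (shift_mat(img, -1, -1) + 2 * shift_mat(img, 0, -1) + shift_mat(img, 1, -1)) -
    (shift_mat(img, -1, 1) + 2 * shift_mat(img, 0, 1) + shift_mat(img, 1, 1))
  # Gradient along rows (image y)
  gy <- (shift_mat(img, -1, -1) + 2 * shift_mat(img, -1, 0) + shift_mat(img, -1, 1)) -
    (shift_mat(img, 1, -1) + 2 * shift_mat(img, 1, 0) + shift_mat(img, 1, 1))
  sqrt(gx^2 + gy^2)
}

#' Test points against a closed polygon
#'
#' Even-odd (ray casting) rule; points on an edge may fall on either side.
#'
#' @param rows,cols point coordinates.
#' @param poly two-column matrix `(row, col)` of polygon vertices (closed
#'   implicitly, last vertex joins the first).
#' @return logical vector.
#' @export
points_in_polygon <- function(rows, cols, poly) {
  n <- nrow(poly)
  px <- poly[, 2]; py <- poly[, 1]
  inside <- rep(FALSE, length(rows))
  j <- n
  for (i in seq_len(n)) {
    yi <- py[i]; yj <- py[j]; xi <- px[i]; xj <- px[j]
    cross <- ((yi > rows) != (yj > rows)) &
      (cols < (xj - xi) * (rows - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

# Shoelace signed area of an open-listed closed polygon (row, col), px^2.
shoelace_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Area centroid (row, col) of a closed polygon via the shoelace formula.
polygon_centroid <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) {
    return(c(mean(y), mean(x)))
  }
  cx <- sum((x[j] + x) * cr) / (6 * a)
  cy <- sum((y[j] + y) * cr) / (6 * a)
  c(cy, cx)
}

# Centered moving average, window w (odd); shorter windows at the ends.
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  h <- floor(w / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
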