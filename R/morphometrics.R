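# Radial shape descriptors about the centre of area: 36 radii and 18
# diameters at 10 degree steps, diameter SD, axis ratios, 2PB diameters.

#' Radial profile of an outline
#'
#' Measures 36 radii at 10 degree steps from the outline's centre of area
#' (CoA) to the boundary polygon, and the 18 diameters
#' `d(theta) = r(theta) + r(theta + 180)` for `theta = 0..170`. Every
#' diameter passes through the CoA. When a ray crosses a concave boundary
#' more than once the farthest crossing is used by default, so diameters
#' grow monotonically under elongation; `intersection = "first"` selects the
#' nearest crossing instead.
#'
#' @param outline a `zf_outline` with the CoA inside the polygon.
#' @param pixel_size micrometres per pixel.
#' @param intersection `"farthest"` (default) or `"first"`.
#' @return object of class `zf_radial_profile` with fields `frame_index`,
#'   `angles_deg` (0, 10, ..., 350), `radii_um`, `diam_angles_deg`
#'   (0, ..., 170), `diameters_um` and `coa` (px).
#' @export
radial_profile <- function(outline, pixel_size,
                           intersection = c("farthest", "first")) {
  intersection <- match.arg(intersection)
  stopifnot(inherits(outline, "zf_outline"))
  poly <- outline$boundary
  coa <- outline$centre
  if (!points_in_polygon(coa[1], coa[2], poly)) {
    stop("centre of area lies outside the outline polygon")
  }
  angles <- seq(0, 350, by = 10)
  radii_px <- vapply(angles, function(a) {
    ray_polygon_radius(coa, angle_dir(a), poly, farthest = intersection == "farthest")
  }, numeric(1))
  if (any(!is.finite(radii_px))) {
    stop("a measurement ray failed to intersect the outline")
  }
  radii_um <- radii_px * pixel_size
  diam <- radii_um[1:18] + radii_um[19:36]
  structure(
    list(
      frame_index = outline$frame_index,
      angles_deg = angles,
      radii_um = radii_um,
      diam_angles_deg = angles[1:18],
      diameters_um = diam,
      coa = coa,
      pixel_size = pixel_size
    ),
    class = "zf_radial_profile"
  )
}

#' @export
print.zf_radial_profile <- function(x, ...) {
  cat(sprintf(
    "<zf_radial_profile> frame %s | mean diameter %.2f um | SD %.3f um\n",
    x$frame_index, mean(x$diameters_um), stats::sd(x$diameters_um)
  ))
  invisible(x)
}

# Distance from origin o along unit direction d to the boundary polygon.
ray_polygon_radius <- function(o, d, poly, farthest = TRUE) {
  p1r <- poly[, 1]; p1c <- poly[, 2]
  n <- nrow(poly)
  nxt <- c(seq_len(n)[-1], 1)
  er <- poly[nxt, 1] - p1r
  ec <- poly[nxt, 2] - p1c
  qr <- p1r - o[1]; qc <- p1c - o[2]
  cross2 <- function(ar, ac, br, bc) ac * br - ar * bc
  denom <- cross2(d[1], d[2], er, ec)
  t <- cross2(qr, qc, er, ec) / denom
  u <- cross2(qr, qc, d[1], d[2]) / denom
  # small slack on u: rays through a shared vertex must hit one of the
  # two incident edges despite round-off
  hit <- is.finite(t) & t > 1e-9 & u >= -1e-9 & u < 1
  if (!any(hit)) return(NA_real_)
  if (farthest) max(t[hit]) else min(t[hit])
}

#' Standard deviation of the 18 diameters
#'
#' Sample SD (n - 1 denominator) of the 18 diameter lengths; zero only when
#' all diameters are equal. Used as the per-frame shape index whose peaks
#' and troughs delimit shape sequences.
#'
#' @param profile a `zf_radial_profile`.
#' @return SD in micrometres.
#' @export
diameter_sd <- function(profile) {
  stopifnot(inherits(profile, "zf_radial_profile"))
  stats::sd(profile$diameters_um)
}

#' Ratio of a diameter to its perpendicular
#'
#' `diameter(angle) / diameter(angle + 90)`, both through the CoA. Angles
#' are snapped to the nearest 10 degree measurement ray; the snapped angle
#' is recorded in the `"angle_used"` attribute.
#'
#' @param profile a `zf_radial_profile`.
#' @param angle degrees.
#' @return dimensionless ratio.
#' @export
axis_ratio <- function(profile, angle) {
  stopifnot(inherits(profile, "zf_radial_profile"))
  snap <- (round(angle / 10) * 10) %% 180
  perp <- (snap + 90) %% 180
  d1 <- profile$diameters_um[match(snap, profile$diam_angles_deg)]
  d2 <- profile$diameters_um[match(perp, profile$diam_angles_deg)]
  if (!is.finite(d2) || d2 <= 0) stop("degenerate perpendicular diameter")
  structure(d1 / d2, angle_used = snap)
}

#' Zygote diameter through the second polar body
#'
#' The diameter at the 10 degree measurement angle nearest the CoA-to-2PB
#' direction. With `include_pb2_width` the measurement is extended along the
#' same ray to the far edge of the annotated 2PB disc (taken as tangent to
#' the membrane): `r(theta + 180) + |CoA -> 2PB centre| + 2PB radius`.
#'
#' @param profile a `zf_radial_profile`.
#' @param pb2_position `(row, col)` 2PB centre in pixels.
#' @param include_pb2_width logical.
#' @param pb2_radius_px 2PB disc radius in pixels (required when
#'   `include_pb2_width`).
#' @return diameter in micrometres; attributes `angle_used` (snapped
#'   measurement angle) and `angle_raw` (exact CoA-to-2PB angle).
#' @export
pb2_diameter <- function(profile, pb2_position, include_pb2_width = FALSE,
                         pb2_radius_px = NULL) {
  stopifnot(inherits(profile, "zf_radial_profile"))
  if (is.null(pb2_position)) stop("2PB annotation missing")
  raw <- point_angle(profile$coa, pb2_position)
  snap <- (round(raw / 10) * 10) %% 360
  px <- profile$pixel_size
  if (!include_pb2_width) {
    val <- profile$diameters_um[match(snap %% 180, profile$diam_angles_deg)]
  } else {
    if (is.null(pb2_radius_px)) stop("`pb2_radius_px` required with include_pb2_width")
    opp <- (snap + 180) %% 360
    r_opp <- profile$radii_um[match(opp, profile$angles_deg)]
    dist_pb2 <- sqrt(sum((pb2_position - profile$coa)^2)) * px
    val <- r_opp + dist_pb2 + pb2_radius_px * px
  }
  structure(val, angle_used = snap, angle_raw = raw)
}

#' Radial profiles for a tracked sequence
#'
#' @param outlines list of `zf_outline` (e.g. from [track_outlines()]).
#' @param pixel_size micrometres per pixel.
#' @param ... passed to [radial_profile()].
#' @return list of `zf_radial_profile`.
#' @export
profile_series <- function(outlines, pixel_size, ...) {
  lapply(outlines, radial_profile, pixel_size = pixel_size, ...)
}

#' Diameter time series matrix
#'
#' @param profiles list of `zf_radial_profile`.
#' @return numeric matrix, frames x 18 angles; column names are the
#'   diameter angles in degrees.
#' @export
diameter_matrix <- function(profiles) {
  m <- t(vapply(profiles, function(p) p$diameters_um, numeric(18)))
  colnames(m) <- profiles[[1]]$diam_angles_deg
  m
}

#' Per-frame shape metrics table
#'
#' @param outlines list of `zf_outline`.
#' @param stack the `zf_stack` they were measured on (for calibration).
#' @return data frame with `frame`, `time_min`, `area_um2`,
#'   `diameter_sd_um`, the 36 radii (`r<angle>_um`) and 18 diameters
#'   (`d<angle>_um`).
#' @export
shape_metrics <- function(outlines, stack) {
  px <- stack$pixel_size
  profiles <- profile_series(outlines, px)
  radii <- t(vapply(profiles, function(p) p$radii_um, numeric(36)))
  colnames(radii) <- sprintf("r%03d_um", profiles[[1]]$angles_deg)
  diam <- diameter_matrix(profiles)
  colnames(diam) <- sprintf("d%03d_um", profiles[[1]]$diam_angles_deg)
  data.frame(
    frame = vapply(outlines, function(o) as.integer(o$frame_index), integer(1)),
    time_min = stack$timestamps[seq_along(outlines)],
    area_um2 = vapply(outlines, polygon_area, numeric(1), pixel_size = px),
    diameter_sd_um = vapply(profiles, diameter_sd, numeric(1)),
    interpolated = vapply(outlines, function(o) isTRUE(o$interpolated), logical(1)),
    radii, diam,
    check.names = FALSE
  )
}
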