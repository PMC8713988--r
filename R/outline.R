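# Cell / zona outline extraction: Sobel edge map sampled on a polar unwrap
# about a seed centre, then a circular dynamic program over the radius
# function r(theta).

#' Polar unwrap of an image about a centre
#'
#' Samples `img` bilinearly along rays from `centre` at `n_angles` equally
#' spaced angles and unit-pixel radial steps in `[r_min, r_max]`.
#'
#' @param img numeric matrix.
#' @param centre `(row, col)` centre.
#' @param r_min,r_max radial band in pixels.
#' @param n_angles number of angular bins (angle of bin k is
#'   `(k - 1) * 360 / n_angles` degrees).
#' @return matrix of `n_angles` rows and `r_max - r_min + 1` columns.
#' @export
polar_unwrap <- function(img, centre, r_min, r_max, n_angles = 360) {
  stopifnot(r_min >= 1, r_min < r_max)
  angles <- (seq_len(n_angles) - 1) * 360 / n_angles
  radii <- seq(r_min, r_max)
  a <- deg2rad(angles)
  dr <- -cos(a); dc <- sin(a)
  rows <- centre[1] + outer(dr, radii)
  cols <- centre[2] + outer(dc, radii)
  vals <- bilinear_sample(img, as.vector(rows), as.vector(cols), fill = 0)
  matrix(vals, nrow = n_angles)
}

#' Circular dynamic program over a polar energy map
#'
#' Finds the radius index path `j(theta)` over the angular bins maximizing
#'
#' `sum E[theta, j] - smoothing * sum (j(theta+1) - j(theta))^2 -
#'  temporal_weight * sum (j(theta) - r_prev(theta))^2`
#'
#' subject to circular closure (`j` after the last bin returns to the first)
#' and a per-step transition bound `|delta j| <= max_step`. Closure is
#' enforced by solving the DP once per candidate start radius on a coarse
#' grid (every `coarse_step`-th radius) and refining around the best.
#'
#' @param energy matrix (`n_angles` x `n_radii`) of edge energies; `-Inf`
#'   marks inadmissible nodes.
#' @param smoothing nonnegative weight on squared radial steps.
#' @param temporal_weight nonnegative weight on squared deviation from
#'   `r_prev`.
#' @param r_prev optional numeric vector (length `n_angles`) of reference
#'   radius indices.
#' @param max_step maximum radial index change per angular step.
#' @param coarse_step start-radius stride for the closure search; 1 solves
#'   every start exactly.
#' @return list with `path` (radius indices, length `n_angles`) and
#'   `objective`.
#' @export
polar_dp <- function(energy, smoothing = 0, temporal_weight = 0,
                     r_prev = NULL, max_step = 2L, coarse_step = 4L) {
  A <- nrow(energy); R <- ncol(energy)
  stopifnot(A >= 3, R >= 1)
  node <- -energy
  if (temporal_weight > 0) {
    if (is.null(r_prev) || length(r_prev) != A) {
      stop("`r_prev` of length n_angles required when temporal_weight > 0")
    }
    node <- node + temporal_weight *
      (matrix(seq_len(R), A, R, byrow = TRUE) - r_prev)^2
  }
  node[!is.finite(node)] <- Inf
  steps <- seq.int(-max_step, max_step)
  step_cost <- smoothing * steps^2

  solve_start <- function(s) {
    if (!is.finite(node[1, s])) return(NULL)
    D <- rep(Inf, R); D[s] <- node[1, s]
    P <- matrix(0L, A, R)
    for (th in 2:A) {
      best <- rep(Inf, R); arg <- integer(R)
      for (k in seq_along(steps)) {
        d <- steps[k]
        cand <- if (d > 0) {
          c(rep(Inf, d), D[seq_len(R - d)])
        } else if (d < 0) {
          c(D[seq.int(1 - d, R)], rep(Inf, -d))
        } else D
        cand <- cand + step_cost[k]
        upd <- cand < best
        best[upd] <- cand[upd]
        arg[upd] <- d
      }
      D <- best + node[th, ]
      P[th, ] <- arg
    }
    close_cost <- smoothing * (seq_len(R) - s)^2
    close_cost[abs(seq_len(R) - s) > max_step] <- Inf
    tot <- D + close_cost
    j <- which.min(tot)
    if (!is.finite(tot[j])) return(NULL)
    path <- integer(A)
    path[A] <- j
    for (th in A:2) path[th - 1] <- path[th] - P[th, path[th]]
    list(path = path, objective = -tot[j])
  }

  starts <- unique(c(seq.int(1, R, by = max(1L, coarse_step)), R))
  best <- NULL
  for (s in starts) {
    res <- solve_start(s)
    if (!is.null(res) && (is.null(best) || res$objective > best$objective)) {
      best <- res
    }
  }
  if (is.null(best)) stop("no admissible closed path in the polar DP")
  if (coarse_step > 1) {
    s0 <- best$path[1]
    refine <- setdiff(
      seq.int(max(1L, s0 - coarse_step + 1L), min(R, s0 + coarse_step - 1L)),
      starts
    )
    for (s in refine) {
      res <- solve_start(s)
      if (!is.null(res) && res$objective > best$objective) best <- res
    }
  }
  best
}

new_outline <- function(boundary, radii_px, angles_deg, frame_index, target,
                        objective = NA_real_, interpolated = FALSE) {
  structure(
    list(
      boundary = boundary,
      centre = polygon_centroid(boundary),
      radii_px = radii_px,
      angles_deg = angles_deg,
      frame_index = frame_index,
      target = target,
      objective = objective,
      interpolated = interpolated
    ),
    class = "zf_outline"
  )
}

#' @export
print.zf_outline <- function(x, ...) {
  cat(sprintf(
    "<zf_outline> frame %s | %s | %d vertices | centre (%.1f, %.1f) px | mean r %.1f px%s\n",
    x$frame_index, x$target, nrow(x$boundary), x$centre[1], x$centre[2],
    mean(x$radii_px), if (isTRUE(x$interpolated)) " | interpolated" else ""
  ))
  invisible(x)
}

#' Detect a closed cell (or zona) outline in one frame
#'
#' Runs Sobel edge detection, unwraps the edge map about `seed_centre` into
#' polar coordinates, and finds the closed radius path `r(theta)` maximizing
#' edge energy minus quadratic smoothing and temporal-bias penalties (see
#' [polar_dp()]). The edge map is normalized to maximum 1 before the DP so
#' the result is invariant to positive scaling of image intensities.
#'
#' @param frame numeric matrix (one grayscale frame, intensities `[0, 1]`).
#' @param seed_centre `(row, col)` point inside the cell.
#' @param r_min,r_max admissible radial band (pixels).
#' @param prev optional `zf_outline` from the previous frame; required when
#'   `temporal_weight > 0`.
#' @param temporal_weight nonnegative weight biasing `r(theta)` toward the
#'   previous frame's outline (per px^2).
#' @param smoothing nonnegative weight on squared radial roughness of the
#'   outline (per px^2).
#' @param n_angles angular resolution (default 360 bins of 1 degree).
#' @param max_step maximum change of r (px) per angular bin.
#' @param edge_polarity `"any"`, `"rising"` (intensity increases outward at
#'   the boundary) or `"falling"`; used to pick the inner vs outer zona edge.
#' @param r_max_per_angle optional numeric vector (length `n_angles`) of
#'   per-angle upper radius bounds, e.g. a band dilated around an annotated
#'   second polar body (`include_pb2` convention).
#' @param frame_index frame label carried in the result.
#' @param target `"cell"` or `"zona"`.
#' @param coarse_step closure search stride passed to [polar_dp()].
#' @return a `zf_outline`: closed boundary polygon (`boundary`, one
#'   `(row, col)` vertex per angular bin), area centroid `centre` (CoA),
#'   radius function `radii_px` and the DP `objective`.
#' @export
detect_outline <- function(frame, seed_centre, r_min, r_max, prev = NULL,
                           temporal_weight = 0, smoothing = 0.1,
                           n_angles = 360L, max_step = 2L,
                           edge_polarity = c("any", "rising", "falling"),
                           r_max_per_angle = NULL,
                           frame_index = NA_integer_, target = "cell",
                           coarse_step = 4L) {
  edge_polarity <- match.arg(edge_polarity)
  nr <- nrow(frame); nc <- ncol(frame)
  if (seed_centre[1] < 1 || seed_centre[1] > nr ||
      seed_centre[2] < 1 || seed_centre[2] > nc) {
    stop("seed centre lies outside the image")
  }
  stopifnot(r_min >= 1, r_min < r_max)
  edge <- sobel_magnitude(frame)
  E <- polar_unwrap(edge, seed_centre, r_min, r_max, n_angles)
  if (edge_polarity != "any") {
    I <- polar_unwrap(frame, seed_centre, r_min, r_max, n_angles)
    grad <- cbind(I[, 2] - I[, 1], (I[, -(1:2), drop = FALSE] -
                                      I[, seq_len(ncol(I) - 2), drop = FALSE]) / 2,
                  I[, ncol(I)] - I[, ncol(I) - 1])
    keep <- if (edge_polarity == "rising") grad > 0 else grad < 0
    E <- E * keep
  }
  mx <- max(E)
  if (mx <= 0) stop("segmentation failure: no edge energy in the radial band")
  E <- E / mx
  if (!is.null(r_max_per_angle)) {
    stopifnot(length(r_max_per_angle) == n_angles)
    radii <- seq(r_min, r_max)
    bad <- outer(r_max_per_angle, radii, function(rm, r) r > rm)
    E[bad] <- -Inf
  }
  r_prev <- NULL
  if (!is.null(prev)) {
    r_prev_px <- prev_radii_at(prev, (seq_len(n_angles) - 1) * 360 / n_angles)
    r_prev <- r_prev_px - r_min + 1
  } else if (temporal_weight > 0) {
    stop("`prev` outline required when temporal_weight > 0")
  }
  sol <- polar_dp(E, smoothing = smoothing, temporal_weight = temporal_weight,
                  r_prev = r_prev, max_step = max_step,
                  coarse_step = coarse_step)
  radii_px <- r_min + sol$path - 1
  angles <- (seq_len(n_angles) - 1) * 360 / n_angles
  dirs <- vapply(angles, angle_dir, numeric(2))
  boundary <- cbind(
    row = seed_centre[1] + radii_px * dirs[1, ],
    col = seed_centre[2] + radii_px * dirs[2, ]
  )
  new_outline(boundary, radii_px, angles, frame_index, target,
              objective = sol$objective)
}

# Radius function of an existing outline sampled at given angles (px),
# relative to the outline's own polar parameterization.
prev_radii_at <- function(outline, angles_deg) {
  if (length(outline$angles_deg) == length(angles_deg) &&
      all(outline$angles_deg == angles_deg)) {
    return(outline$radii_px)
  }
  ang <- c(outline$angles_deg, 360)
  rad <- c(outline$radii_px, outline$radii_px[1])
  stats::approx(ang, rad, xout = angles_deg %% 360, rule = 2)$y
}

#' Track outlines across a stack
#'
#' Frame 1 is detected without temporal bias; each later frame is biased
#' toward the previous successful outline (weight `temporal_weight`) and
#' seeded at its centre of area, so the detector follows a drifting cell.
#' Frames where segmentation fails are interpolated linearly in `r(theta)`
#' per angular bin between flanking successes and flagged `interpolated`.
#'
#' @param stack a `zf_stack`.
#' @param seed_centre `(row, col)` seed for the first frame.
#' @param r_min,r_max radial band (px).
#' @param temporal_weight bias toward the previous outline for frames > 1.
#' @param max_fail_frac abort when more than this fraction of frames fail.
#' @param ... further arguments to [detect_outline()].
#' @return list of `zf_outline`, one per frame.
#' @export
track_outlines <- function(stack, seed_centre, r_min, r_max,
                           temporal_weight = 0.02, max_fail_frac = 0.5, ...) {
  stopifnot(inherits(stack, "zf_stack"))
  n <- length(stack$frames)
  outlines <- vector("list", n)
  prev <- NULL
  seed <- seed_centre
  for (i in seq_len(n)) {
    res <- tryCatch(
      detect_outline(stack$frames[[i]], seed, r_min, r_max, prev = prev,
                     temporal_weight = if (is.null(prev)) 0 else temporal_weight,
                     frame_index = i, ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      outlines[i] <- list(NULL)
    } else {
      outlines[[i]] <- res
      prev <- res
      seed <- res$centre
    }
  }
  failed <- which(vapply(outlines, is.null, logical(1)))
  if (length(failed) > n * max_fail_frac) {
    stop(sprintf("outline tracking failed on %d of %d frames", length(failed), n))
  }
  if (length(failed) > 0) {
    good <- setdiff(seq_len(n), failed)
    for (i in failed) {
      lo <- max(good[good < i], -Inf)
      hi <- min(good[good > i], Inf)
      if (is.finite(lo) && is.finite(hi)) {
        w <- (i - lo) / (hi - lo)
        radii <- (1 - w) * outlines[[lo]]$radii_px + w * outlines[[hi]]$radii_px
        ctr <- (1 - w) * outlines[[lo]]$centre + w * outlines[[hi]]$centre
        ang <- outlines[[lo]]$angles_deg
      } else {
        src <- outlines[[if (is.finite(lo)) lo else hi]]
        radii <- src$radii_px; ctr <- src$centre; ang <- src$angles_deg
      }
      dirs <- vapply(ang, angle_dir, numeric(2))
      boundary <- cbind(row = ctr[1] + radii * dirs[1, ],
                        col = ctr[2] + radii * dirs[2, ])
      outlines[[i]] <- new_outline(boundary, radii, ang, i,
                                   target = "cell", interpolated = TRUE)
    }
  }
  outlines
}

#' Polygon area of an outline
#'
#' Shoelace area of the boundary polygon, converted to square micrometres.
#' Positive regardless of vertex orientation.
#'
#' @param outline a `zf_outline` (or a two-column `(row, col)` matrix).
#' @param pixel_size micrometres per pixel.
#' @return area in um^2.
#' @export
polygon_area <- function(outline, pixel_size) {
  poly <- if (inherits(outline, "zf_outline")) outline$boundary else outline
  a_px <- abs(shoelace_area(poly))
  if (a_px < 10) stop("degenerate polygon: area below 10 px^2")
  a_px * pixel_size^2
}

#' Outline radii as a data frame
#'
#' @param outline a `zf_outline`.
#' @param pixel_size micrometres per pixel.
#' @return data frame with columns `frame`, `theta_deg`, `r_um`.
#' @export
outline_radii_df <- function(outline, pixel_size) {
  data.frame(
    frame = outline$frame_index,
    theta_deg = outline$angles_deg,
    r_um = outline$radii_px * pixel_size
  )
}
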