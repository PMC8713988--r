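# Shape-sequence (rounder-distorted-rounder) detection on diameter series,
# cytokinetic elongation axis, "first step" detection and indent finding.

# Strict local extrema of a series; flat troughs/peaks take their widest
# extent (first and last index of the flat run are both candidates, the
# extremum index reported is the run midpoint).
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  # run-length compress flats so plateaus count once
  r <- rle(x)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(v)
  is_max <- is_min <- rep(FALSE, k)
  if (k >= 3) {
    for (i in 2:(k - 1)) {
      if (v[i] > v[i - 1] && v[i] > v[i + 1]) is_max[i] <- TRUE
      if (v[i] < v[i - 1] && v[i] < v[i + 1]) is_min[i] <- TRUE
    }
  }
  mid <- floor((starts + ends) / 2)
  list(max = mid[is_max], min = mid[is_min],
       start = starts, end = ends,
       max_runs = which(is_max), min_runs = which(is_min))
}

# Topographic prominence of peak at index i relative to the higher of the
# two flanking minima reachable without crossing a higher peak.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left <- x[seq_len(p)]
    right <- x[seq.int(p, length(x))]
    higher_l <- which(left > x[p])
    base_l <- if (length(higher_l)) min(left[seq.int(max(higher_l), p)]) else min(left)
    higher_r <- which(right > x[p])
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
    x[p] - max(base_l, base_r)
  }, numeric(1))
}

#' Detect rounder-distorted-rounder shape sequences
#'
#' Candidate (trough, peak, trough) triplets are located on the smoothed
#' diameter-SD trace; for each triplet every one of the 18 diameters is
#' tested for an extension of at least `min_extension` from the first trough
#' to the peak followed by a retraction of at least `retraction_floor`
#' toward the second trough. A sequence is emitted per qualifying triplet,
#' carrying the angle of the diameter with the maximal in-out-in change
#' (`min(extension, retraction)`; ties broken toward the smaller angle).
#'
#' @param diam_series frames x 18 matrix of diameters (um), columns named
#'   by angle as from [diameter_matrix()].
#' @param sd_series per-frame diameter SD (um); computed from
#'   `diam_series` when omitted.
#' @param frame_interval minutes per frame (for durations).
#' @param min_extension minimum first-half extension (um); default 1.5.
#' @param smooth_window moving-average window (frames) on the SD trace.
#' @param min_prominence minimum SD peak prominence (um) for a candidate
#'   triplet.
#' @param retraction_floor minimum second-half retraction (um) above
#'   measurement noise.
#' @return data frame, one row per sequence: `angle_deg`, `start_frame`,
#'   `peak_frame`, `end_frame`, `out_amplitude_um`, `in_amplitude_um`,
#'   `max_inoutin_um`, `duration_min`, `n_qualifying`.
#' @export
detect_sequences <- function(diam_series, sd_series = NULL,
                             frame_interval = 1, min_extension = 1.5,
                             smooth_window = 3, min_prominence = 0.3,
                             retraction_floor = 0.5) {
  diam_series <- as.matrix(diam_series)
  n <- nrow(diam_series)
  if (n < 3) stop("need at least 3 frames to detect sequences")
  if (n < smooth_window) stop("series shorter than the smoothing window")
  if (is.null(sd_series)) sd_series <- apply(diam_series, 1, stats::sd)
  angles <- as.numeric(colnames(diam_series))
  if (anyNA(angles)) angles <- seq(0, 170, by = 10)

  s <- moving_average(sd_series, smooth_window)
  ex <- local_extrema(s)
  empty <- data.frame(
    angle_deg = numeric(0), start_frame = integer(0), peak_frame = integer(0),
    end_frame = integer(0), out_amplitude_um = numeric(0),
    in_amplitude_um = numeric(0), max_inoutin_um = numeric(0),
    duration_min = numeric(0), n_qualifying = integer(0)
  )
  if (length(ex$max) == 0) return(empty)
  prom <- peak_prominence(s, ex$max)
  peaks <- ex$max[prom >= min_prominence]
  if (length(peaks) == 0) return(empty)

  # troughs = SD minima plus the series ends, widest extent on flats
  trough_runs <- ex$min_runs
  trough_pos <- ex$min
  # widest-extent convention: a sequence starts at the beginning of the
  # trough plateau before the peak and ends at the end of the plateau after
  trough_start <- ex$start[trough_runs]
  trough_end <- ex$end[trough_runs]
  cand_starts <- c(1, trough_start)
  cand_ends <- c(trough_end, n)

  out <- empty
  for (p in peaks) {
    st <- max(cand_starts[cand_starts < p])
    en <- min(cand_ends[cand_ends > p])
    ext <- diam_series[p, ] - diam_series[st, ]
    retr <- diam_series[p, ] - diam_series[en, ]
    qual <- ext >= min_extension & retr >= retraction_floor
    if (!any(qual)) next
    inout <- pmin(ext, retr)
    inout[!qual] <- -Inf
    best <- which.max(inout)  # which.max takes the first (smallest angle) tie
    out <- rbind(out, data.frame(
      angle_deg = angles[best], start_frame = st, peak_frame = p,
      end_frame = en, out_amplitude_um = ext[best],
      in_amplitude_um = retr[best], max_inoutin_um = inout[best],
      duration_min = (en - st) * frame_interval,
      n_qualifying = sum(qual)
    ))
  }
  out
}

#' Cytokinetic elongation axis
#'
#' The diameter angle with the greatest extension between an earlier frame
#' `t0` and the frame `t1` at which the first cytokinetic furrow is seen.
#'
#' @param profiles list of `zf_radial_profile` (or a diameter matrix).
#' @param t0,t1 frame indices, `t0 < t1`.
#' @return list with `angle_deg`, `extension_um`, `indeterminate` (no
#'   diameter grew) and `tie` (multiple angles within 1e-9 um; the smallest
#'   angle is returned).
#' @export
find_elongation_axis <- function(profiles, t0, t1) {
  stopifnot(t0 < t1)
  dm <- if (is.matrix(profiles)) profiles else diameter_matrix(profiles)
  if (t1 > nrow(dm)) stop("profile missing in the requested range")
  angles <- as.numeric(colnames(dm))
  if (anyNA(angles)) angles <- seq(0, 170, by = 10)
  ext <- dm[t1, ] - dm[t0, ]
  best <- which.max(ext)
  tie <- sum(abs(ext - ext[best]) < 1e-9) > 1
  list(
    angle_deg = if (max(ext) <= 0) NA_real_ else angles[best],
    extension_um = max(ext),
    indeterminate = max(ext) <= 0,
    tie = tie
  )
}

#' First step of rapid elongation
#'
#' Earliest frame at which the elongation diameter increases by at least
#' `threshold` micrometres within a `window`-minute interval.
#'
#' @param diam elongation-diameter time series (um).
#' @param frame_interval minutes per frame.
#' @param threshold minimum increase (um); default 1.
#' @param window interval length (min); default 2. When `frame_interval`
#'   does not divide `window` the nearest whole-frame window is used and
#'   recorded in the `"window_frames"` attribute.
#' @return earliest qualifying frame index, or `NA` if none.
#' @export
detect_first_step <- function(diam, frame_interval, threshold = 1, window = 2) {
  w <- max(1L, as.integer(round(window / frame_interval)))
  n <- length(diam)
  if (n <= w) stop("series too short for the requested window")
  inc <- diam[seq.int(1 + w, n)] - diam[seq_len(n - w)]
  hit <- which(inc >= threshold & inc > 0)
  structure(if (length(hit)) hit[1] else NA_integer_, window_frames = w)
}

#' Detect surface indents on an outline
#'
#' Local concavities of the radius function: angular local maxima of the
#' depth below the convex-hull radius, reported when at least `min_depth`
#' micrometres deep. Supports automatic cytokinesis staging (one-indent /
#' two-indents) when manual annotations are absent.
#'
#' @param outline a `zf_outline`.
#' @param min_depth minimum depth (um).
#' @param pixel_size micrometres per pixel.
#' @return data frame with `angle_deg` and `depth_um`, deepest first.
#' @export
detect_indents <- function(outline, min_depth, pixel_size) {
  stopifnot(inherits(outline, "zf_outline"))
  hull_idx <- grDevices::chull(outline$boundary[, 2], outline$boundary[, 1])
  hull <- outline$boundary[hull_idx, , drop = FALSE]
  ctr <- outline$centre
  hull_r <- vapply(outline$angles_deg, function(a) {
    ray_polygon_radius(ctr, angle_dir(a), hull, farthest = TRUE)
  }, numeric(1))
  r <- vapply(outline$angles_deg, function(a) {
    ray_polygon_radius(ctr, angle_dir(a), outline$boundary, farthest = TRUE)
  }, numeric(1))
  depth <- (hull_r - r) * pixel_size
  depth[!is.finite(depth)] <- 0
  n <- length(depth)
  prv <- c(depth[n], depth[-n]); nxt <- c(depth[-1], depth[1])
  is_peak <- depth >= prv & depth > nxt & depth >= min_depth
  out <- data.frame(angle_deg = outline$angles_deg[is_peak],
                    depth_um = depth[is_peak])
  out[order(-out$depth_um), , drop = FALSE]
}
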