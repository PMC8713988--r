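# Vorticity of masked PIV fields, tolerant of incomplete vector patterns,
# half-cell partitioning and chi-squared comparison of vorticity signs.

#' Vorticity of a PIV vector field
#'
#' At every grid point a local linear velocity model
#' `u = a0 + a1 x + a2 y`, `v = b0 + b1 x + b2 y` is fitted by least squares
#' over the valid vectors in the surrounding 3x3 neighbourhood, and the curl
#' is taken from the fitted gradients. Because the fit only needs 4 valid
#' supports (with full rank), intermittent or incomplete vector patterns --
#' partial rings of vectors, masked-out regions -- still yield estimates;
#' points with fewer than 4 valid neighbours are undefined (`NA`).
#'
#' Sign convention: positive vorticity is counter-clockwise on the displayed
#' image. Units are reciprocal minutes.
#'
#' @param field a `zf_vector_field`.
#' @return object of class `zf_vorticity_field`: `grid_rows`, `grid_cols`,
#'   matrix `vorticity` (1/min, `NA` where undefined) and `n_support`.
#' @export
vorticity_field <- function(field) {
  stopifnot(inherits(field, "zf_vector_field"))
  ngr <- length(field$grid_rows); ngc <- length(field$grid_cols)
  vort <- matrix(NA_real_, ngr, ngc)
  nsup <- matrix(0L, ngr, ngc)
  if (sum(field$valid) >= 4) {
    h_r <- if (ngr > 1) diff(field$grid_rows)[1] else 1
    h_c <- if (ngc > 1) diff(field$grid_cols)[1] else 1
    for (i in seq_len(ngr)) {
      for (j in seq_len(ngc)) {
        ii <- max(1, i - 1):min(ngr, i + 1)
        jj <- max(1, j - 1):min(ngc, j + 1)
        sub <- field$valid[ii, jj, drop = FALSE]
        n_ok <- sum(sub)
        nsup[i, j] <- n_ok
        if (n_ok < 4) next
        di <- rep(ii - i, times = length(jj))[as.vector(sub)]
        dj <- rep(jj - j, each = length(ii))[as.vector(sub)]
        x <- dj * h_c; y <- di * h_r
        X <- cbind(1, x, y)
        XtX <- crossprod(X)
        if (abs(det(XtX)) < 1e-9) next
        XtXi <- solve(XtX)
        u <- field$d_col[ii, jj, drop = FALSE][as.vector(sub)]
        v <- field$d_row[ii, jj, drop = FALSE][as.vector(sub)]
        cu <- XtXi %*% crossprod(X, u)
        cv <- XtXi %*% crossprod(X, v)
        # counter-clockwise positive on screen (y = row points down)
        vort[i, j] <- (cu[3] - cv[2]) / field$frame_interval
      }
    }
  }
  structure(
    list(grid_rows = field$grid_rows, grid_cols = field$grid_cols,
         vorticity = vort, n_support = nsup,
         frame_pair = field$frame_pair),
    class = "zf_vorticity_field"
  )
}

#' Per-region vorticity time series
#'
#' Mean of the defined vorticity values inside a region mask for every
#' frame pair, with a sign (`+1`, `-1`, or `0`) thresholded at a noise
#' floor. Frames with fewer than `min_support` defined grid points get
#' sign 0 and are excluded from sign tests.
#'
#' @param fields list of `zf_vector_field` (consecutive frame pairs).
#' @param region_masks one logical mask, one `zf_outline`, or a list of
#'   them (one per frame pair).
#' @param region_id label for the series.
#' @param noise_floor `|mean vorticity|` below which the sign is 0 (1/min).
#' @param min_support minimum defined grid points for a defined sign.
#' @return object of class `zf_vort_series`: data frame with `pair`,
#'   `time_min`, `mean_vorticity`, `n_valid`, `sign`; attributes
#'   `region_id` and `noise_floor`.
#' @export
region_vorticity_series <- function(fields, region_masks, region_id = "cell",
                                    noise_floor = 0.005, min_support = 4) {
  n <- length(fields)
  if (!is.list(region_masks) || inherits(region_masks, "zf_outline")) {
    region_masks <- rep(list(region_masks), n)
  }
  stopifnot(length(region_masks) == n)
  rows <- lapply(seq_len(n), function(k) {
    f <- fields[[k]]
    vf <- vorticity_field(f)
    inside <- grid_in_region(f$grid_rows, f$grid_cols, region_masks[[k]])
    vals <- vf$vorticity[inside & !is.na(vf$vorticity)]
    mv <- if (length(vals)) mean(vals) else NA_real_
    sgn <- if (length(vals) < min_support || is.na(mv) ||
               abs(mv) < noise_floor) 0L else as.integer(sign(mv))
    t0 <- if (is.na(f$frame_pair[1])) (k - 1) * f$frame_interval else
      (f$frame_pair[1] - 1) * f$frame_interval
    data.frame(pair = k, time_min = t0, mean_vorticity = mv,
               n_valid = length(vals), sign = sgn)
  })
  out <- do.call(rbind, rows)
  if (all(out$n_valid == 0)) stop("region contains no defined vorticity in any frame")
  structure(out, region_id = region_id, noise_floor = noise_floor,
            class = c("zf_vort_series", "data.frame"))
}

#' Noise floor from a quiescent interval
#'
#' Twice the SD of the per-frame mean vorticity over the first `n_pairs`
#' frame pairs of a user-designated quiescent interval.
#'
#' @param fields list of `zf_vector_field` from the quiescent interval.
#' @param region_mask region as in [region_vorticity_series()].
#' @param n_pairs number of leading pairs to use (default 5).
#' @return noise floor in 1/min.
#' @export
estimate_noise_floor <- function(fields, region_mask, n_pairs = 5) {
  fields <- fields[seq_len(min(n_pairs, length(fields)))]
  s <- region_vorticity_series(fields, region_mask, noise_floor = 0)
  2 * stats::sd(s$mean_vorticity)
}

#' Erode a binary mask
#'
#' Repeated 3x3 binary erosion, shrinking the region by roughly `px`
#' pixels. Used to keep vorticity measurements away from the cell membrane,
#' where interrogation windows straddle the static boundary.
#'
#' @param mask logical matrix.
#' @param px number of erosion passes (approximate shrink in pixels).
#' @return eroded logical matrix.
#' @export
erode_mask <- function(mask, px = 8) {
  for (k in seq_len(px)) {
    mask <- mask & shift_mat(mask, 1, 0) & shift_mat(mask, -1, 0) &
      shift_mat(mask, 0, 1) & shift_mat(mask, 0, -1)
  }
  mask
}

#' Split a cell mask into halves across its longest axis
#'
#' The longest axis is the maximal-distance chord between convex-hull
#' points of the mask (or a user-annotated line, which takes precedence);
#' the mask is divided by the perpendicular bisector of that axis. The
#' halves are disjoint and their union is the mask.
#'
#' @param cell_mask logical matrix.
#' @param axis optional 2x2 matrix, rows `(row, col)` of the two axis
#'   endpoints (annotation override).
#' @return list with logical matrices `half_a`, `half_b` and the `axis`
#'   used.
#' @export
split_cell_halves <- function(cell_mask, axis = NULL) {
  stopifnot(is.matrix(cell_mask), is.logical(cell_mask))
  pix <- which(cell_mask, arr.ind = TRUE)
  if (nrow(pix) < 2) stop("degenerate mask")
  if (is.null(axis)) {
    hull <- pix[grDevices::chull(pix[, 2], pix[, 1]), , drop = FALSE]
    d2 <- as.matrix(stats::dist(hull))
    idx <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    axis <- hull[idx, , drop = FALSE]
  }
  stopifnot(nrow(axis) == 2)
  mid <- colMeans(axis)
  dvec <- axis[2, ] - axis[1, ]
  dvec <- dvec / sqrt(sum(dvec^2))
  proj <- (pix[, 1] - mid[1]) * dvec[1] + (pix[, 2] - mid[2]) * dvec[2]
  half_a <- half_b <- matrix(FALSE, nrow(cell_mask), ncol(cell_mask))
  half_a[pix[proj >= 0, , drop = FALSE]] <- TRUE
  half_b[pix[proj < 0, , drop = FALSE]] <- TRUE
  list(half_a = half_a, half_b = half_b, axis = axis)
}

#' Chi-squared comparison of vorticity signs between two regions
#'
#' Signs are compared in consecutive time windows (default 100 minutes,
#' with the first window conventionally starting 30-99 minutes after the
#' two-indents stage). Per window a 2x2 table of (+, -) sign counts for the
#' two regions is tested with Pearson's chi-squared (1 df; Yates'
#' continuity correction when any expected count is below 5). Sign-0 frames
#' are excluded; a window in which either region has fewer than
#' `min_defined` defined signs is reported untestable.
#'
#' @param series_a,series_b `zf_vort_series` for the two regions.
#' @param window window length in minutes (default 100).
#' @param start_time start of the first window (min); default the first
#'   time common to both series.
#' @param min_defined minimum defined-sign frames per region per window.
#' @return data frame, one row per window: `window_start_min`,
#'   `window_end_min`, sign counts `a_pos`, `a_neg`, `b_pos`, `b_neg`,
#'   `chi_square`, `p_value`, `yates`, `testable`.
#' @export
compare_signs <- function(series_a, series_b, window = 100,
                          start_time = NULL, min_defined = 5) {
  t_lo <- max(min(series_a$time_min), min(series_b$time_min))
  t_hi <- min(max(series_a$time_min), max(series_b$time_min))
  if (t_lo > t_hi) stop("series have no overlapping frame range")
  if (is.null(start_time)) start_time <- t_lo
  starts <- seq(start_time, t_hi, by = window)
  rows <- lapply(starts, function(w0) {
    w1 <- w0 + window
    sa <- series_a$sign[series_a$time_min >= w0 & series_a$time_min < w1]
    sb <- series_b$sign[series_b$time_min >= w0 & series_b$time_min < w1]
    a_pos <- sum(sa == 1); a_neg <- sum(sa == -1)
    b_pos <- sum(sb == 1); b_neg <- sum(sb == -1)
    res <- data.frame(window_start_min = w0, window_end_min = w1,
                      a_pos = a_pos, a_neg = a_neg,
                      b_pos = b_pos, b_neg = b_neg,
                      chi_square = NA_real_, p_value = NA_real_,
                      yates = NA, testable = FALSE)
    if (a_pos + a_neg < min_defined || b_pos + b_neg < min_defined) return(res)
    tab <- rbind(c(a_pos, a_neg), c(b_pos, b_neg))
    res$testable <- TRUE
    if (any(colSums(tab) == 0)) {
      # both regions share one sign entirely: no detectable difference
      res$chi_square <- 0; res$p_value <- 1; res$yates <- FALSE
      return(res)
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_yates <- any(expected < 5)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = use_yates))
    res$chi_square <- unname(ct$statistic)
    res$p_value <- ct$p.value
    res$yates <- use_yates
    res
  })
  do.call(rbind, rows)
}
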