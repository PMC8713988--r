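# Particle image velocimetry: multi-pass normalized cross-correlation of
# square interrogation windows between consecutive frames, with sub-pixel
# peak localisation and peak-quality validation.

# Regular-grid bilinear interpolation with nearest-edge extrapolation.
interp2_reg <- function(grid_rows, grid_cols, Z, r, c) {
  fr <- stats::approx(grid_rows, seq_along(grid_rows), xout = r, rule = 2)$y
  fc <- stats::approx(grid_cols, seq_along(grid_cols), xout = c, rule = 2)$y
  r0 <- pmin(floor(fr), length(grid_rows) - 1); r0 <- pmax(r0, 1)
  c0 <- pmin(floor(fc), length(grid_cols) - 1); c0 <- pmax(c0, 1)
  if (length(grid_rows) == 1) { r0 <- 1; fr <- 1 }
  if (length(grid_cols) == 1) { c0 <- 1; fc <- 1 }
  ar <- fr - r0; ac <- fc - c0
  r1 <- pmin(r0 + 1, length(grid_rows)); c1 <- pmin(c0 + 1, length(grid_cols))
  Z[cbind(r0, c0)] * (1 - ar) * (1 - ac) + Z[cbind(r0, c1)] * (1 - ar) * ac +
    Z[cbind(r1, c0)] * ar * (1 - ac) + Z[cbind(r1, c1)] * ar * ac
}

# One interrogation of an a-window against a shifted b-window of equal size.
# Returns c(d_row, d_col, peak, ratio) relative to the applied shift, or NA.
interrogate_window <- function(a_win, b_win, search) {
  W <- nrow(a_win)
  a_win <- a_win - mean(a_win)
  b_win <- b_win - mean(b_win)
  na <- sqrt(sum(a_win^2)); nb <- sqrt(sum(b_win^2))
  if (na < 1e-9 || nb < 1e-9) return(NULL)  # textureless
  C <- Re(stats::fft(Conj(stats::fft(a_win)) * stats::fft(b_win),
                     inverse = TRUE)) / (W * W)
  C <- C / (na * nb)
  half <- W %/% 2
  ord <- c((half + 1):W, 1:half)  # displacement -half .. half-1, centre at half+1
  Cs <- C[ord, ord]
  ctr <- half + 1
  lo <- ctr - search; hi <- ctr + search
  box <- Cs[lo:hi, lo:hi, drop = FALSE]
  pk <- which(box == max(box), arr.ind = TRUE)[1, ]
  peak <- box[pk[1], pk[2]]
  # second-highest peak outside the 3x3 neighbourhood of the first
  masked <- box
  masked[max(1, pk[1] - 1):min(nrow(box), pk[1] + 1),
         max(1, pk[2] - 1):min(ncol(box), pk[2] + 1)] <- -Inf
  second <- suppressWarnings(max(masked))
  ratio <- peak / max(second, 1e-12)
  pi <- lo + pk[1] - 1; pj <- lo + pk[2] - 1
  subpix <- function(cm, c0, cp) {
    if (cm > 0 && cp > 0 && c0 > cm && c0 > cp) {
      0.5 * (log(cm) - log(cp)) / (log(cm) + log(cp) - 2 * log(c0))
    } else {
      den <- cm - 2 * c0 + cp
      if (abs(den) < 1e-12) 0 else {
        d <- (cm - cp) / (2 * den)
        max(min(d, 0.5), -0.5)
      }
    }
  }
  dr <- pi - ctr; dc <- pj - ctr
  if (pi > 1 && pi < W) dr <- dr + subpix(Cs[pi - 1, pj], Cs[pi, pj], Cs[pi + 1, pj])
  if (pj > 1 && pj < W) dc <- dc + subpix(Cs[pi, pj - 1], Cs[pi, pj], Cs[pi, pj + 1])
  c(dr, dc, peak, ratio)
}

#' PIV between one pair of frames
#'
#' Multi-pass normalized cross-correlation: pass 1 matches square
#' interrogation windows of `initial_window` pixels; each subsequent pass
#' halves the window down to `final_window` (the customary schedules are
#' 64:32 and, for low-noise recordings, 64:16), shifting the second frame's
#' window by the bilinearly interpolated coarse displacement before
#' correlating. Correlation peaks are located to sub-pixel precision by a
#' three-point Gaussian fit (parabolic fallback) and validated by the
#' peak-to-second-peak ratio.
#'
#' @param frame_a,frame_b numeric matrices of identical shape.
#' @param initial_window,final_window first- and last-pass interrogation
#'   window sizes (px, powers of two, `final <= initial`, both >= 8).
#' @param overlap window overlap fraction in `[0, 0.75]` (default 0.5).
#' @param mask optional region restricting valid vectors: a logical matrix
#'   of the frame shape or a `zf_outline`.
#' @param pixel_size,frame_interval calibration used when summarizing in
#'   physical units (stored with the field; vectors are kept in px/frame).
#' @param peak_ratio_min minimum peak-to-second-peak ratio.
#' @param search_frac search radius per pass as a fraction of the window.
#' @param frame_pair labels of the two frames.
#' @return object of class `zf_vector_field`: `grid_rows`, `grid_cols`
#'   (window-centre coordinates, px), matrices `d_row`, `d_col` (px/frame),
#'   `valid`, `peak_corr`, plus calibration and the window schedule.
#' @export
piv_pair <- function(frame_a, frame_b, initial_window = 64L,
                     final_window = 32L, overlap = 0.5, mask = NULL,
                     pixel_size = 1, frame_interval = 1,
                     peak_ratio_min = 1.2, search_frac = 0.25,
                     frame_pair = c(NA_integer_, NA_integer_)) {
  stopifnot(all(dim(frame_a) == dim(frame_b)),
            final_window <= initial_window, final_window >= 8,
            overlap >= 0, overlap <= 0.75)
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  schedule <- initial_window
  while (schedule[length(schedule)] > final_window) {
    schedule <- c(schedule, schedule[length(schedule)] %/% 2L)
  }
  if (schedule[length(schedule)] != final_window) {
    stop("`final_window` must be `initial_window` / 2^k")
  }

  prev <- NULL
  for (W in schedule) {
    spacing <- max(1L, as.integer(round(W * (1 - overlap))))
    r0s <- seq.int(1L, nr - W + 1L, by = spacing)
    c0s <- seq.int(1L, nc - W + 1L, by = spacing)
    g_rows <- r0s + (W - 1) / 2
    g_cols <- c0s + (W - 1) / 2
    ngr <- length(r0s); ngc <- length(c0s)
    d_row <- matrix(NA_real_, ngr, ngc)
    d_col <- matrix(NA_real_, ngr, ngc)
    peak_corr <- matrix(NA_real_, ngr, ngc)
    valid <- matrix(FALSE, ngr, ngc)
    # predicted displacement from the previous (coarser) pass
    if (!is.null(prev)) {
      pr <- prev$d_row; pc <- prev$d_col
      if (any(prev$valid)) {
        pr[!prev$valid] <- stats::median(pr[prev$valid])
        pc[!prev$valid] <- stats::median(pc[prev$valid])
      } else {
        pr[] <- 0; pc[] <- 0
      }
      pred_r <- outer(seq_len(ngr), seq_len(ngc), function(i, j) {
        interp2_reg(prev$grid_rows, prev$grid_cols, pr, g_rows[i], g_cols[j])
      })
      pred_c <- outer(seq_len(ngr), seq_len(ngc), function(i, j) {
        interp2_reg(prev$grid_rows, prev$grid_cols, pc, g_rows[i], g_cols[j])
      })
    } else {
      pred_r <- matrix(0, ngr, ngc); pred_c <- matrix(0, ngr, ngc)
    }
    search <- max(2L, as.integer(floor(W * search_frac)))
    for (i in seq_len(ngr)) {
      r0 <- r0s[i]
      for (j in seq_len(ngc)) {
        c0 <- c0s[j]
        sh_r <- as.integer(round(pred_r[i, j]))
        sh_c <- as.integer(round(pred_c[i, j]))
        sh_r <- min(max(sh_r, 1L - r0), nr - W + 1L - r0)
        sh_c <- min(max(sh_c, 1L - c0), nc - W + 1L - c0)
        a_win <- frame_a[r0:(r0 + W - 1L), c0:(c0 + W - 1L)]
        b_win <- frame_b[(r0 + sh_r):(r0 + sh_r + W - 1L),
                         (c0 + sh_c):(c0 + sh_c + W - 1L)]
        res <- interrogate_window(a_win, b_win, search)
        if (is.null(res)) next
        d_row[i, j] <- sh_r + res[1]
        d_col[i, j] <- sh_c + res[2]
        peak_corr[i, j] <- res[3]
        valid[i, j] <- res[3] > 0 && res[4] >= peak_ratio_min
      }
    }
    prev <- list(grid_rows = g_rows, grid_cols = g_cols,
                 d_row = d_row, d_col = d_col, valid = valid,
                 peak_corr = peak_corr)
  }

  # search-range bound and region mask apply to the final field
  mag <- sqrt(prev$d_row^2 + prev$d_col^2)
  prev$valid <- prev$valid & !is.na(mag) & mag <= initial_window / 2
  if (!is.null(mask)) {
    inside <- grid_in_region(prev$grid_rows, prev$grid_cols, mask)
    prev$valid <- prev$valid & inside
  }
  structure(
    c(prev, list(frame_pair = frame_pair, window_schedule = schedule,
                 overlap = overlap, pixel_size = pixel_size,
                 frame_interval = frame_interval)),
    class = "zf_vector_field"
  )
}

#' @export
print.zf_vector_field <- function(x, ...) {
  cat(sprintf(
    "<zf_vector_field> %d x %d grid | windows %s px | %d/%d valid | frames (%s, %s)\n",
    length(x$grid_rows), length(x$grid_cols),
    paste(x$window_schedule, collapse = ">"),
    sum(x$valid), length(x$valid), x$frame_pair[1], x$frame_pair[2]
  ))
  invisible(x)
}

# Membership of grid points in a region (logical mask matrix, zf_outline,
# or NULL = everywhere).
grid_in_region <- function(grid_rows, grid_cols, region) {
  ngr <- length(grid_rows); ngc <- length(grid_cols)
  if (is.null(region)) return(matrix(TRUE, ngr, ngc))
  rr <- rep(grid_rows, times = ngc)
  cc <- rep(grid_cols, each = ngr)
  if (inherits(region, "zf_outline")) {
    inside <- points_in_polygon(rr, cc, region$boundary)
  } else if (is.matrix(region) && is.logical(region)) {
    ri <- pmin(pmax(round(rr), 1), nrow(region))
    ci <- pmin(pmax(round(cc), 1), ncol(region))
    inside <- region[cbind(ri, ci)]
  } else {
    stop("unsupported region type")
  }
  matrix(inside, ngr, ngc)
}

#' Mean movement vector inside a region
#'
#' Arithmetic mean of all valid displacement vectors inside the region
#' (typically the computed cell outline), in micrometres per minute.
#'
#' @param field a `zf_vector_field`.
#' @param region `zf_outline`, logical mask, or `NULL` for the whole field.
#' @return named numeric `(d_row, d_col)` in um/min, with attribute `n`.
#' @export
mean_vector <- function(field, region = NULL) {
  sel <- field$valid & grid_in_region(field$grid_rows, field$grid_cols, region)
  if (!any(sel)) stop("no valid vectors inside the region")
  k <- field$pixel_size / field$frame_interval
  structure(
    c(d_row = mean(field$d_row[sel]) * k, d_col = mean(field$d_col[sel]) * k),
    n = sum(sel)
  )
}

#' Mean movement magnitude in a rectangle
#'
#' Mean vector magnitude over valid grid points inside a rectangle placed
#' in the cytoplasm, in micrometres per minute.
#'
#' @param field a `zf_vector_field`.
#' @param rect numeric `(row_min, row_max, col_min, col_max)` in pixels.
#' @return mean speed in um/min, with attribute `n`.
#' @export
mean_magnitude <- function(field, rect) {
  stopifnot(length(rect) == 4)
  rr <- rep(field$grid_rows, times = length(field$grid_cols))
  cc <- rep(field$grid_cols, each = length(field$grid_rows))
  sel <- field$valid & rr >= rect[1] & rr <= rect[2] &
    cc >= rect[3] & cc <= rect[4]
  if (!any(sel)) stop("rectangle contains no valid grid point")
  k <- field$pixel_size / field$frame_interval
  structure(mean(sqrt(field$d_row[sel]^2 + field$d_col[sel]^2)) * k,
            n = sum(sel))
}

#' Vector field as a data frame
#'
#' @param field a `zf_vector_field`.
#' @return data frame with `row`, `col` (px), `d_row_px`, `d_col_px`
#'   (px/frame), `speed_um_min`, `valid`, `peak_corr`.
#' @export
field_to_df <- function(field) {
  ngr <- length(field$grid_rows); ngc <- length(field$grid_cols)
  k <- field$pixel_size / field$frame_interval
  data.frame(
    frame_a = field$frame_pair[1], frame_b = field$frame_pair[2],
    row = rep(field$grid_rows, times = ngc),
    col = rep(field$grid_cols, each = ngr),
    d_row_px = as.vector(field$d_row),
    d_col_px = as.vector(field$d_col),
    speed_um_min = as.vector(sqrt(field$d_row^2 + field$d_col^2)) * k,
    valid = as.vector(field$valid),
    peak_corr = as.vector(field$peak_corr)
  )
}

#' Quiver overlay PNG
#'
#' Draws the frame with the valid PIV vectors as dark arrows and the mean
#' vector as a red arrow from the region centroid.
#'
#' @param field a `zf_vector_field`.
#' @param frame background frame.
#' @param path output PNG path.
#' @param region optional region for the mean vector.
#' @param arrow_scale display magnification of the vectors.
#' @return `path`, invisibly.
#' @export
plot_vector_field <- function(field, frame, path, region = NULL,
                              arrow_scale = 5) {
  grDevices::png(path, width = ncol(frame), height = nrow(frame))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot(NA, xlim = c(1, ncol(frame)), ylim = c(nrow(frame), 1),
                 asp = 1, axes = FALSE, xlab = "", ylab = "")
  graphics::rasterImage(grDevices::as.raster(pmin(pmax(frame, 0), 1)),
                        1, nrow(frame), ncol(frame), 1)
  sel <- which(field$valid, arr.ind = TRUE)
  if (nrow(sel) > 0) {
    x0 <- field$grid_cols[sel[, 2]]; y0 <- field$grid_rows[sel[, 1]]
    dx <- field$d_col[sel] * arrow_scale; dy <- field$d_row[sel] * arrow_scale
    graphics::arrows(x0, y0, x0 + dx, y0 + dy, length = 0.03, col = "grey20")
  }
  mv <- tryCatch(mean_vector(field, region), error = function(e) NULL)
  if (!is.null(mv)) {
    k <- field$pixel_size / field$frame_interval
    ctr <- if (inherits(region, "zf_outline")) region$centre else
      c(mean(field$grid_rows), mean(field$grid_cols))
    graphics::arrows(ctr[2], ctr[1],
                     ctr[2] + mv["d_col"] / k * arrow_scale * 2,
                     ctr[1] + mv["d_row"] / k * arrow_scale * 2,
                     length = 0.08, col = "red", lwd = 2)
  }
  invisible(path)
}
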