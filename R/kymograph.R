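# Space-time intensity images along a chosen diameter.

#' Extract a kymograph along a diameter
#'
#' Samples intensity bilinearly at 1 px steps along a line of fixed length
#' through an anchor point, for every frame. Rows are positions along the
#' line (from the bottom end at `-length/2` to the top end at `+length/2`
#' of the direction `angle`), columns are frames. The anchor is either the
#' per-frame centre of area (the line then tracks the cell) or a fixed
#' point (e.g. for zona-referenced views).
#'
#' @param stack a `zf_stack`.
#' @param angle line angle in degrees (0 = image vertical).
#' @param length_um line length in micrometres.
#' @param anchor `"coa"` (requires `outlines`) or a fixed `(row, col)`
#'   point.
#' @param outlines list of `zf_outline`, needed when `anchor = "coa"`.
#' @param segment `"full"` or `"end"`: `"end"` keeps only a window of
#'   `end_window_um` at the bottom end of the diameter.
#' @param end_window_um sub-segment length for `segment = "end"`.
#' @return object of class `zf_kymograph`: `image` (positions x frames),
#'   `positions_um` (signed, along the line), `angle`, `length_um`.
#' @export
extract_kymograph <- function(stack, angle, length_um, anchor = "coa",
                              outlines = NULL,
                              segment = c("full", "end"),
                              end_window_um = 25) {
  segment <- match.arg(segment)
  stopifnot(inherits(stack, "zf_stack"))
  px <- stack$pixel_size
  n_steps <- max(2L, round(length_um / px))
  # 1 px steps, bottom end to top end of the diameter
  s <- seq(-floor(n_steps / 2), length.out = n_steps)
  d <- angle_dir(angle)
  n <- length(stack$frames)
  if (identical(anchor, "coa")) {
    if (is.null(outlines) || length(outlines) < n) {
      stop("`outlines` (one per frame) required for anchor = \"coa\"")
    }
    centres <- t(vapply(outlines, function(o) o$centre, numeric(2)))
  } else {
    centres <- matrix(rep(as.numeric(anchor), each = n), nrow = n)
  }
  nr <- nrow(stack$frames[[1]]); nc <- ncol(stack$frames[[1]])
  img <- matrix(NA_real_, length(s), n)
  for (i in seq_len(n)) {
    rows <- centres[i, 1] + s * d[1]
    cols <- centres[i, 2] + s * d[2]
    if (any(rows < 1 | rows > nr | cols < 1 | cols > nc)) {
      stop(sprintf("sampling line exits the image at frame %d", i))
    }
    img[, i] <- bilinear_sample(stack$frames[[i]], rows, cols)
  }
  positions_um <- s * px
  if (segment == "end") {
    keep <- positions_um <= (min(positions_um) + end_window_um)
    img <- img[keep, , drop = FALSE]
    positions_um <- positions_um[keep]
  }
  structure(
    list(image = img, positions_um = positions_um, angle = angle,
         length_um = length_um, frame_interval = stack$frame_interval,
         anchor = anchor, segment = segment),
    class = "zf_kymograph"
  )
}

#' @export
print.zf_kymograph <- function(x, ...) {
  cat(sprintf(
    "<zf_kymograph> %d positions x %d frames | %g deg | %.1f um span\n",
    nrow(x$image), ncol(x$image), x$angle, diff(range(x$positions_um))
  ))
  invisible(x)
}

#' Write a kymograph to PNG (and optionally CSV)
#'
#' @param kymo a `zf_kymograph`.
#' @param path PNG output path.
#' @param csv_path optional CSV of the raw intensity matrix.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path, csv_path = NULL) {
  img <- kymo$image
  rng <- range(img, finite = TRUE)
  if (diff(rng) > 0) img <- (img - rng[1]) / diff(rng)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  if (!is.null(csv_path)) {
    df <- as.data.frame(kymo$image)
    names(df) <- sprintf("frame%03d", seq_len(ncol(kymo$image)))
    utils::write.csv(cbind(position_um = kymo$positions_um, df), csv_path,
                     row.names = FALSE)
  }
  invisible(path)
}
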