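# Calibrated image stacks, annotations, metric tables and run configuration.

#' Construct a calibrated frame stack
#'
#' A `zf_stack` holds an ordered list of 2-D grayscale frames together with
#' the spatial calibration (micrometres per pixel) and the temporal
#' calibration (minutes per frame). Intensities are normalized to `[0, 1]`.
#'
#' @param frames list of numeric matrices, all of identical dimensions.
#' @param pixel_size micrometres per pixel, > 0.
#' @param frame_interval minutes per frame, > 0.
#' @param normalize if `TRUE` (default), frames are rescaled to `[0, 1]`
#'   assuming 8- or 16-bit integer data when values exceed 1.
#' @return object of class `zf_stack` with elements `frames`, `pixel_size`,
#'   `frame_interval` and `timestamps` (minutes, `(i - 1) * frame_interval`).
#' @export
frame_stack <- function(frames, pixel_size, frame_interval, normalize = TRUE) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("`frames` must be a non-empty list of matrices")
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    stop("all frames must be 2-D matrices")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("frames have unequal shapes")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("`pixel_size` must be a positive scalar (um/px)")
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      frame_interval <= 0) {
    stop("`frame_interval` must be a positive scalar (min/frame)")
  }
  if (normalize) frames <- lapply(frames, normalize_intensity)
  structure(
    list(
      frames = frames,
      pixel_size = pixel_size,
      frame_interval = frame_interval,
      timestamps = (seq_along(frames) - 1) * frame_interval
    ),
    class = "zf_stack"
  )
}

#' @export
print.zf_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<zf_stack> %d frames of %d x %d px | %.4g um/px | %.4g min/frame (%.4g min total)\n",
    length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval,
    max(x$timestamps)
  ))
  invisible(x)
}

#' @export
length.zf_stack <- function(x) length(x$frames)

#' Normalize grayscale intensities to [0, 1]
#'
#' Values already in `[0, 1]` are returned unchanged (the operation is
#' idempotent). Larger values are assumed to be 8- or 16-bit integer data and
#' divided by `255` or `65535` accordingly.
#'
#' @param img numeric matrix.
#' @return numeric matrix in `[0, 1]`.
#' @export
normalize_intensity <- function(img) {
  mx <- max(img, na.rm = TRUE)
  if (mx <= 1) return(img)
  denom <- if (mx <= 255) 255 else 65535
  img / denom
}

#' Load an image stack from disk
#'
#' Reads either a multi-page TIFF or a directory of single-frame images
#' (TIFF or PNG, ordered lexically by file name) into a calibrated
#' [frame_stack()]. Colour frames are averaged to grayscale.
#'
#' @param path multi-page TIFF file or a directory of frames.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes per frame.
#' @param min_frames minimum frame count (default 2: motion analysis needs
#'   at least one frame pair).
#' @return a `zf_stack`.
#' @export
load_stack <- function(path, pixel_size, frame_interval, min_frames = 2) {
  if (!file.exists(path)) stop("input path does not exist: ", path)
  to_gray <- function(a) {
    if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
    as.matrix(a)
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no TIFF/PNG frames found in ", path)
    frames <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        to_gray(png::readPNG(f))
      } else {
        to_gray(tiff::readTIFF(f))
      }
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_gray)
  }
  if (length(frames) < min_frames) {
    stop(sprintf("stack has %d frame(s); at least %d required",
                 length(frames), min_frames))
  }
  frame_stack(frames, pixel_size, frame_interval)
}

#' Write a stack to a multi-page TIFF
#'
#' @param stack a `zf_stack`.
#' @param path output file path.
#' @param bits 8 or 16 bit output.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16) {
  stopifnot(inherits(stack, "zf_stack"), bits %in% c(8, 16))
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Per-frame annotations
#'
#' Optional manual annotations accompanying a stack: the second polar body
#' position, named stage events (e.g. `one_indent`, `two_indents`, `pnebd`)
#' and a dividing line between daughter cells at the two-cell stage.
#'
#' @param n_frames frame count of the annotated stack.
#' @param pb2_position optional data frame with columns `frame`, `row`,
#'   `col` (and optionally `radius_px`) giving the 2PB centre per frame.
#' @param stage_frames optional named list/vector mapping event names to
#'   frame indices (1-based).
#' @param cell_split optional data frame with columns `frame`, `row1`,
#'   `col1`, `row2`, `col2`: a line dividing the two-cell image.
#' @return object of class `zf_annotations`.
#' @export
annotations <- function(n_frames, pb2_position = NULL, stage_frames = NULL,
                        cell_split = NULL) {
  chk <- function(idx, what) {
    if (any(idx < 1 | idx > n_frames)) {
      stop(what, " references frame outside the stack (1..", n_frames, ")")
    }
  }
  if (!is.null(pb2_position)) chk(pb2_position$frame, "pb2_position")
  if (!is.null(stage_frames)) {
    stage_frames <- unlist(stage_frames)
    chk(stage_frames, "stage_frames")
  }
  if (!is.null(cell_split)) chk(cell_split$frame, "cell_split")
  structure(
    list(n_frames = n_frames, pb2_position = pb2_position,
         stage_frames = stage_frames, cell_split = cell_split),
    class = "zf_annotations"
  )
}

#' Write a metrics table to CSV
#'
#' One row per frame or event; physical units are embedded in the column
#' names (e.g. `area_um2`, `diameter_sd_um`, `speed_um_min`).
#'
#' @param records data frame, non-empty.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("`records` is empty; nothing to write")
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Declarative YAML configuration naming the input (or synthetic preset),
#' calibration and per-stage algorithm parameters. Values supplied in
#' `overrides` (e.g. from CLI flags) replace config values key by key.
#'
#' @param path YAML file.
#' @param overrides optional named list of overrides; nested keys via
#'   sub-lists.
#' @return named list.
#' @export
load_config <- function(path, overrides = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(overrides)) cfg <- modify_list(cfg, overrides)
  cfg
}

modify_list <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}
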