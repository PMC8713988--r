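# End-to-end orchestration: outline -> morphometrics -> sequences -> PIV ->
# vorticity -> kymograph, with validated config and deterministic outputs.

#' Validate a pipeline configuration
#'
#' Checks structure and calibration before any computation. A config names
#' either an input stack (`input$path` plus `pixel_size` and
#' `frame_interval`) or a synthetic preset (`input$preset`, `input$seed`).
#'
#' @param config named list (e.g. from [load_config()]).
#' @return the config, with defaults filled in.
#' @export
validate_config <- function(config) {
  inp <- config$input
  if (is.null(inp)) stop("config validation: missing `input` section")
  if (is.null(inp$preset)) {
    if (is.null(inp$path)) {
      stop("config validation: `input` needs `path` or `preset`")
    }
    if (is.null(inp$pixel_size) || inp$pixel_size <= 0) {
      stop("config validation: missing or non-positive `input$pixel_size`")
    }
    if (is.null(inp$frame_interval) || inp$frame_interval <= 0) {
      stop("config validation: missing or non-positive `input$frame_interval`")
    }
  } else {
    if (is.null(inp$seed)) config$input$seed <- 1L
  }
  if (is.null(config$output_dir)) stop("config validation: missing `output_dir`")
  defaults <- list(
    outline = list(r_min_um = 15, r_max_um = 48, smoothing = 0.1,
                   temporal_weight = 0.02, n_angles = 360),
    sequences = list(min_extension_um = 1.5, smooth_window = 3,
                     min_prominence = 0.3),
    piv = list(enabled = TRUE, initial_window = 64, final_window = 32,
               overlap = 0.5, cache = FALSE),
    vorticity = list(enabled = FALSE, window_min = 100, noise_floor = 0.005,
                     erode_px = 8),
    kymograph = list(enabled = FALSE, angle_deg = 20, length_um = 100)
  )
  for (nm in names(defaults)) {
    config[[nm]] <- modify_list(defaults[[nm]], config[[nm]])
  }
  config
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes outline tracking, radial morphometrics, shape-sequence
#' detection, PIV, (optionally) vorticity sign comparison and a kymograph,
#' writing per-frame metrics CSV, an events JSON, per-pair vector-field
#' CSVs, sign-test tables and a run log into `output_dir`. Runs are
#' deterministic given the config (and seed, for synthetic input): a rerun
#' produces byte-identical CSV/JSON outputs.
#'
#' @param config config list or path to a YAML config.
#' @return invisible list with the computed objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("zygoflow run", "config:")

  truth <- NULL
  stack <- pipeline_stage("input", {
    if (!is.null(config$input$preset)) {
      spec <- preset_library(config$input$preset, seed = config$input$seed)
      if (!is.null(config$input$n_frames)) {
        spec$n_frames <- min(spec$n_frames, config$input$n_frames)
      }
      sc <- render_scenario(spec)
      truth <- sc$truth
      sc$stack
    } else {
      load_stack(config$input$path, config$input$pixel_size,
                 config$input$frame_interval)
    }
  })
  px <- stack$pixel_size
  two_cell <- !is.null(truth) && truth$spec$geometry == "two_cell"

  outlines <- profiles <- metrics <- seqs <- NULL
  if (!two_cell) {
    outlines <- pipeline_stage("outline", {
      d <- dim(stack$frames[[1]])
      seed_ctr <- config$outline$seed_centre
      if (is.null(seed_ctr)) seed_ctr <- c(d[1] / 2, d[2] / 2)
      track_outlines(stack, seed_ctr,
                     r_min = max(2, round(config$outline$r_min_um / px)),
                     r_max = round(config$outline$r_max_um / px),
                     temporal_weight = config$outline$temporal_weight,
                     smoothing = config$outline$smoothing,
                     n_angles = config$outline$n_angles)
    })
    metrics <- pipeline_stage("morphometrics", shape_metrics(outlines, stack))
    write_metrics(metrics, file.path(out_dir, "metrics.csv"))
    seqs <- pipeline_stage("sequences", {
      profiles <- profile_series(outlines, px)
      detect_sequences(diameter_matrix(profiles),
                       sd_series = metrics$diameter_sd_um,
                       frame_interval = stack$frame_interval,
                       min_extension = config$sequences$min_extension_um,
                       smooth_window = config$sequences$smooth_window,
                       min_prominence = config$sequences$min_prominence)
    })
    jsonlite::write_json(
      list(sequences = seqs),
      file.path(out_dir, "events.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  fields <- NULL
  if (isTRUE(config$piv$enabled) && length(stack$frames) >= 2) {
    fields <- pipeline_stage("piv", {
      cache_dir <- file.path(out_dir, "cache")
      key <- NULL
      if (isTRUE(config$piv$cache)) {
        dir.create(cache_dir, showWarnings = FALSE)
        tf <- tempfile()
        saveRDS(list(config$input, config$piv), tf)
        key <- unname(tools::md5sum(tf))
        unlink(tf)
        cache_file <- file.path(cache_dir, paste0(key, ".rds"))
        if (file.exists(cache_file)) {
          log_lines <- c(log_lines, "piv: cache hit")
        }
      }
      if (isTRUE(config$piv$cache) && file.exists(file.path(cache_dir, paste0(key, ".rds")))) {
        readRDS(file.path(cache_dir, paste0(key, ".rds")))
      } else {
        fl <- lapply(seq_len(length(stack$frames) - 1), function(i) {
          region <- if (!two_cell && !is.null(outlines)) outlines[[i]] else NULL
          piv_pair(stack$frames[[i]], stack$frames[[i + 1]],
                   initial_window = config$piv$initial_window,
                   final_window = config$piv$final_window,
                   overlap = config$piv$overlap, mask = region,
                   pixel_size = px, frame_interval = stack$frame_interval,
                   frame_pair = c(i, i + 1))
        })
        if (isTRUE(config$piv$cache)) {
          saveRDS(fl, file.path(cache_dir, paste0(key, ".rds")))
        }
        fl
      }
    })
    piv_df <- do.call(rbind, lapply(fields, field_to_df))
    write_metrics(piv_df, file.path(out_dir, "vector_fields.csv"))
  }

  signs <- NULL
  if (isTRUE(config$vorticity$enabled) && !is.null(fields)) {
    signs <- pipeline_stage("vorticity", {
      if (two_cell) {
        ep <- config$vorticity$erode_px
        masks_1 <- lapply(seq_along(fields), function(i)
          erode_mask(truth$cell_masks[[i]][[1]], ep))
        masks_2 <- lapply(seq_along(fields), function(i)
          erode_mask(truth$cell_masks[[i]][[2]], ep))
        s1 <- region_vorticity_series(fields, masks_1, "cell-1",
                                      noise_floor = config$vorticity$noise_floor)
        s2 <- region_vorticity_series(fields, masks_2, "cell-2",
                                      noise_floor = config$vorticity$noise_floor)
        cmp <- compare_signs(s1, s2, window = config$vorticity$window_min)
        write_metrics(rbind(cbind(region = "cell-1", s1),
                            cbind(region = "cell-2", s2)),
                      file.path(out_dir, "vorticity_series.csv"))
        write_metrics(cmp, file.path(out_dir, "sign_tests.csv"))
        list(series = list(s1, s2), comparison = cmp)
      } else {
        s <- region_vorticity_series(fields,
                                     lapply(seq_along(fields), function(i) outlines[[i]]),
                                     "cell",
                                     noise_floor = config$vorticity$noise_floor)
        write_metrics(s, file.path(out_dir, "vorticity_series.csv"))
        list(series = list(s), comparison = NULL)
      }
    })
  }

  kymo <- NULL
  if (isTRUE(config$kymograph$enabled) && !two_cell && !is.null(outlines)) {
    kymo <- pipeline_stage("kymograph", {
      k <- extract_kymograph(stack, config$kymograph$angle_deg,
                             config$kymograph$length_um,
                             anchor = "coa", outlines = outlines)
      write_kymograph(k, file.path(out_dir, "kymograph.png"),
                      csv_path = file.path(out_dir, "kymograph.csv"))
      k
    })
  }

  log_lines <- c(log_lines,
                 yaml::as.yaml(config[c("input", "outline", "sequences",
                                        "piv", "vorticity", "kymograph")]))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(stack = stack, outlines = outlines, metrics = metrics,
                 sequences = seqs, fields = fields, signs = signs,
                 kymograph = kymo, truth = truth, output_dir = out_dir))
}
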