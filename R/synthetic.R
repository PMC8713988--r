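# Synthetic calibrated time-lapse generator with analytic ground truth:
# a textured cell inside a static elliptical zona ring, per-diameter shape
# modulation, cytokinetic elongation/indentation into two lobes, and
# internal flow fields (translation, solid-body rotation, vortex pairs)
# that advect the cytoplasmic texture.

#' Build a synthetic scenario specification
#'
#' All geometry is in micrometres; conversion to pixels happens at render
#' time. With a fixed `seed` the rendered stack is bit-identical across
#' runs.
#'
#' @param n_frames number of frames.
#' @param pixel_size micrometres per pixel (default 0.5, typical of
#'   bright-field embryo recordings; 0.26 is a common high-resolution
#'   calibration).
#' @param frame_interval minutes per frame (recordings are typically taken
#'   every 1-2 minutes).
#' @param base_radius_um cell radius (default 38, a mouse zygote scale).
#' @param zona_inner_um,zona_outer_um zona pellucida ring radii.
#' @param zona_axis_ratio mild ellipticity of the zona (its long over short
#'   axis; embryonic zonae are slightly oval, ~1.05-1.09).
#' @param zona_angle_deg orientation of the zona long axis.
#' @param modulations list of per-diameter shape modulations, each a list
#'   with `angle_deg`, `amplitude_um` (peak diameter increase),
#'   `t_start_min`, `period_min`, `n_cycles`.
#' @param flow one of the flow models made by [flow_none()],
#'   [flow_translation()], [flow_rotation()], [flow_vortex_pair()].
#' @param cytokinesis optional list with `t_first_step_min`,
#'   `elongation_um`, `axis_deg`, `duration_min`, `indent_depth_um`,
#'   `t_one_indent_min`, `t_two_indents_min`.
#' @param geometry `"one_cell"` or `"two_cell"` (two circular lobes along
#'   `two_cell_axis_deg`, used with mirrored vortex flows).
#' @param two_cell_axis_deg,two_cell_radius_um,two_cell_offset_um two-cell
#'   lobe geometry.
#' @param n_granules,granule_sigma_px,texture_contrast cytoplasm texture.
#' @param noise_sd additive Gaussian intensity noise (default 0.01, low
#'   enough that PIV validity stays above 90 percent, as in usable real
#'   footage).
#' @param spots optional list of rendered moving spots (for kymograph
#'   ground truth), each a list `start_um` (offset from centre, row/col),
#'   `velocity_um_min` (row/col), `sigma_px`, `amplitude`.
#' @param seed RNG seed.
#' @return object of class `zf_scenario`.
#' @export
scenario_spec <- function(n_frames = 40, pixel_size = 0.5, frame_interval = 2,
                          base_radius_um = 38,
                          zona_inner_um = 46, zona_outer_um = 53,
                          zona_axis_ratio = 1.07, zona_angle_deg = 30,
                          modulations = list(),
                          flow = flow_none(),
                          cytokinesis = NULL,
                          geometry = c("one_cell", "two_cell"),
                          two_cell_axis_deg = 20, two_cell_radius_um = 27,
                          two_cell_offset_um = 24,
                          n_granules = 250, granule_sigma_px = 1.4,
                          texture_contrast = 0.35, membrane_intensity = 0.25,
                          noise_sd = 0.01,
                          spots = list(), seed = 1L) {
  geometry <- match.arg(geometry)
  spec <- list(
    n_frames = n_frames, pixel_size = pixel_size,
    frame_interval = frame_interval, base_radius_um = base_radius_um,
    zona_inner_um = zona_inner_um, zona_outer_um = zona_outer_um,
    zona_axis_ratio = zona_axis_ratio, zona_angle_deg = zona_angle_deg,
    modulations = modulations, flow = flow, cytokinesis = cytokinesis,
    geometry = geometry, two_cell_axis_deg = two_cell_axis_deg,
    two_cell_radius_um = two_cell_radius_um,
    two_cell_offset_um = two_cell_offset_um,
    n_granules = n_granules, granule_sigma_px = granule_sigma_px,
    texture_contrast = texture_contrast,
    membrane_intensity = membrane_intensity, noise_sd = noise_sd,
    spots = spots, seed = as.integer(seed)
  )
  class(spec) <- "zf_scenario"
  spec
}

#' Flow models for synthetic scenarios
#'
#' Velocities are in micrometres per minute, positions relative to the cell
#' centre in pixels. `flow_rotation` rotates counter-clockwise on the
#' displayed image for positive `omega` (vorticity `+2 omega`).
#' `flow_vortex_pair` places two Rankine vortices (solid-body core,
#' irrotational far field) at offsets from the centre.
#'
#' @param v_row,v_col translation speed (um/min).
#' @param omega angular speed (rad/min).
#' @param centres_um list of `(row, col)` offsets of the vortex centres
#'   from the cell centre (um).
#' @param omegas peak angular speeds of each vortex (rad/min, sign =
#'   direction).
#' @param core_um solid-body core radius (um).
#' @return a flow-model object used by [render_scenario()].
#' @name flow_models
NULL

#' @rdname flow_models
#' @export
flow_none <- function() structure(list(type = "none"), class = "zf_flow")

#' @rdname flow_models
#' @export
flow_translation <- function(v_row, v_col) {
  structure(list(type = "translation", v_row = v_row, v_col = v_col),
            class = "zf_flow")
}

#' @rdname flow_models
#' @param burst optional speed burst: list `t_min`, `duration_min`,
#'   `factor` multiplying `omega` within the burst.
#' @export
flow_rotation <- function(omega, burst = NULL) {
  structure(list(type = "rotation", omega = omega, burst = burst),
            class = "zf_flow")
}

#' @rdname flow_models
#' @export
flow_vortex_pair <- function(centres_um, omegas, core_um = 12) {
  stopifnot(length(centres_um) == length(omegas))
  structure(list(type = "vortex_pair", centres_um = centres_um,
                 omegas = omegas, core_um = core_um),
            class = "zf_flow")
}

#' @rdname flow_models
#' @export
#' @details `flow_mirror_rotation` rotates each point rigidly about the
#'   nearest of the listed centres (piecewise solid-body rotation), the
#'   idealized "one vortex dominates each whole cell" regime: the signed
#'   vorticity is exactly `2 omega_k` throughout cell `k` and the texture
#'   never shears, so counter-rotation persists indefinitely.
flow_mirror_rotation <- function(centres_um, omegas) {
  stopifnot(length(centres_um) == length(omegas))
  structure(list(type = "mirror_rotation", centres_um = centres_um,
                 omegas = omegas),
            class = "zf_flow")
}

# Velocity of a flow model in um/min at offsets (d_row_um, d_col_um) from
# the cell centre, at time t (min). Returns list(u = d_col, v = d_row).
flow_velocity_um <- function(flow, d_row_um, d_col_um, t) {
  z <- rep(0, length(d_row_um))
  switch(flow$type,
    none = list(v = z, u = z),
    translation = list(v = z + flow$v_row, u = z + flow$v_col),
    rotation = {
      om <- flow$omega
      if (!is.null(flow$burst) &&
          t >= flow$burst$t_min && t < flow$burst$t_min + flow$burst$duration_min) {
        om <- om * flow$burst$factor
      }
      # counter-clockwise on screen: u = omega * y, v = -omega * x
      list(v = -om * d_col_um, u = om * d_row_um)
    },
    mirror_rotation = {
      d2 <- vapply(flow$centres_um, function(ctr) {
        (d_row_um - ctr[1])^2 + (d_col_um - ctr[2])^2
      }, numeric(length(d_row_um)))
      d2 <- matrix(d2, ncol = length(flow$centres_um))
      nearest <- max.col(-d2, ties.method = "first")
      v <- z; u <- z
      for (k in seq_along(flow$omegas)) {
        sel <- nearest == k
        ctr <- flow$centres_um[[k]]; om <- flow$omegas[k]
        u[sel] <- om * (d_row_um[sel] - ctr[1])
        v[sel] <- -om * (d_col_um[sel] - ctr[2])
      }
      list(v = v, u = u)
    },
    vortex_pair = {
      v <- z; u <- z
      for (k in seq_along(flow$omegas)) {
        ctr <- flow$centres_um[[k]]
        dy <- d_row_um - ctr[1]; dx <- d_col_um - ctr[2]
        r2 <- dy^2 + dx^2
        f <- ifelse(r2 <= flow$core_um^2, 1, flow$core_um^2 / pmax(r2, 1e-9))
        om <- flow$omegas[k]
        u <- u + om * dy * f
        v <- v - om * dx * f
      }
      list(v = v, u = u)
    },
    stop("unknown flow model: ", flow$type)
  )
}

# Wrapped angular bump of unit height and ~`width_deg` half-width.
angular_bump <- function(theta_deg, centre_deg, width_deg = 18) {
  d <- ((theta_deg - centre_deg + 180) %% 360) - 180
  exp(-0.5 * (d / (width_deg / 2))^2)
}

# Cell radius function R(theta, t) in um for a one-cell scenario.
cell_radius_um <- function(spec, theta_deg, t) {
  r <- rep(spec$base_radius_um, length(theta_deg))
  for (m in spec$modulations) {
    dt <- t - m$t_start_min
    total <- m$period_min * m$n_cycles
    if (dt >= 0 && dt < total) {
      mt <- sin(pi * (dt %% m$period_min) / m$period_min)^2
      amp_r <- 0.5 * m$amplitude_um * mt
      r <- r + amp_r * (angular_bump(theta_deg, m$angle_deg) +
                          angular_bump(theta_deg, m$angle_deg + 180))
    }
  }
  ck <- spec$cytokinesis
  if (!is.null(ck)) {
    ramp <- function(t0, dur) min(max((t - t0) / dur, 0), 1)
    e <- ck$elongation_um * ramp(ck$t_first_step_min, ck$duration_min)
    if (e > 0) {
      a <- deg2rad(theta_deg - ck$axis_deg)
      r <- r + 0.5 * e * cos(a)^2 - 0.25 * e * sin(a)^2
    }
    for (side in c(90, -90)) {
      t_ind <- if (side == 90) ck$t_one_indent_min else ck$t_two_indents_min
      depth <- ck$indent_depth_um * ramp(t_ind, 4)
      if (depth > 0) {
        r <- r - depth * angular_bump(theta_deg, ck$axis_deg + side, 24)
      }
    }
  }
  r
}

# Light separable box blur, used to give the texture a PIV-friendly
# correlation length.
box_blur <- function(m, passes = 2) {
  for (k in seq_len(passes)) {
    m <- (shift_mat(m, 1, 0) + m + shift_mat(m, -1, 0)) / 3
    m <- (shift_mat(m, 0, 1) + m + shift_mat(m, 0, -1)) / 3
  }
  m
}

#' Render a synthetic scenario
#'
#' Draws every frame and returns the stack together with the analytic
#' ground truth: per-frame outline polygons, the flow velocity sampled at
#' PIV grid points (written from the model, never re-estimated), per-cell
#' masks for two-cell geometries, and the list of injected shape events.
#' The cytoplasm texture is advected frame-to-frame by backward bilinear
#' warping of the flow field.
#'
#' @param spec a `zf_scenario`.
#' @param grid_spacing_px spacing of the ground-truth flow grid.
#' @return list with `stack` (a `zf_stack`), and `truth`: `outlines`
#'   (list of `(row, col)` polygon matrices, px), `centre` (px),
#'   `cell_masks` (two-cell geometries), `flow_at` (function
#'   `(t, rows, cols) -> list(d_row, d_col)` in px/frame), `flow_grid`
#'   (data frame of ground-truth vectors per frame pair), `events`.
#' @export
render_scenario <- function(spec, grid_spacing_px = 16) {
  stopifnot(inherits(spec, "zf_scenario"))
  px <- spec$pixel_size
  extent_um <- spec$zona_outer_um * max(spec$zona_axis_ratio, 1)
  half <- ceiling(extent_um / px) + 14
  H <- W <- 2L * half + 1L
  ctr <- c(half + 1, half + 1)

  set.seed(spec$seed)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  d_row <- rows - ctr[1]; d_col <- cols - ctr[2]
  r_px <- sqrt(d_row^2 + d_col^2)
  theta <- (atan2(d_col, -d_row) * 180 / pi) %% 360

  # static zona ring (ellipse): radius of the ring at each pixel's angle
  za <- deg2rad(theta - spec$zona_angle_deg)
  shape <- sqrt(cos(za)^2 / spec$zona_axis_ratio^2 + sin(za)^2)
  zr_in <- (spec$zona_inner_um / px) / shape
  zr_out <- (spec$zona_outer_um / px) / shape
  zona_band <- r_px >= zr_in & r_px <= zr_out
  zona_edges <- abs(r_px - zr_in) < 1.2 | abs(r_px - zr_out) < 1.2

  # initial cytoplasm texture: blurred noise plus dark granules
  tex <- box_blur(matrix(stats::runif(H * W), H, W), passes = 2)
  tex <- (tex - min(tex)) / diff(range(tex))
  gran_r <- spec$base_radius_um / px * sqrt(stats::runif(spec$n_granules)) * 0.95
  gran_a <- stats::runif(spec$n_granules, 0, 2 * pi)
  gr <- ctr[1] - gran_r * cos(gran_a)
  gc <- ctr[2] + gran_r * sin(gran_a)
  for (g in seq_len(spec$n_granules)) {
    rr <- max(1, floor(gr[g] - 4)):min(H, ceiling(gr[g] + 4))
    cc <- max(1, floor(gc[g] - 4)):min(W, ceiling(gc[g] + 4))
    d2 <- outer((rr - gr[g])^2, (cc - gc[g])^2, "+")
    tex[rr, cc] <- tex[rr, cc] - 0.6 * exp(-d2 / (2 * spec$granule_sigma_px^2))
  }

  two_cell <- spec$geometry == "two_cell"
  ax <- angle_dir(spec$two_cell_axis_deg)
  lobe_ctrs <- list(
    ctr + ax * spec$two_cell_offset_um / px,
    ctr - ax * spec$two_cell_offset_um / px
  )

  flow_px_frame <- function(t, rr, cc) {
    vel <- flow_velocity_um(spec$flow, (rr - ctr[1]) * px, (cc - ctr[2]) * px, t)
    list(d_row = vel$v / px * spec$frame_interval,
         d_col = vel$u / px * spec$frame_interval)
  }

  cell_mask_at <- function(t) {
    if (two_cell) {
      m1 <- sqrt((rows - lobe_ctrs[[1]][1])^2 + (cols - lobe_ctrs[[1]][2])^2) <=
        spec$two_cell_radius_um / px
      m2 <- sqrt((rows - lobe_ctrs[[2]][1])^2 + (cols - lobe_ctrs[[2]][2])^2) <=
        spec$two_cell_radius_um / px
      list(mask = m1 | m2, masks = list(m1, m2))
    } else {
      R <- matrix(cell_radius_um(spec, as.vector(theta), t) / px, H, W)
      list(mask = r_px <= R, edge = abs(r_px - R) < 1.2)
    }
  }

  frames <- vector("list", spec$n_frames)
  outlines <- vector("list", spec$n_frames)
  cell_masks <- vector("list", spec$n_frames)
  noise <- function() matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)

  # backward coordinate map composed across frames, so each frame samples
  # the original texture once (no cumulative interpolation blur)
  tex0 <- tex
  map_r <- rows; map_c <- cols
  fine_theta <- seq(0, 359, by = 1)
  for (f in seq_len(spec$n_frames)) {
    t <- (f - 1) * spec$frame_interval
    if (f > 1) {
      # advect texture by the flow over the previous interval
      fl <- flow_px_frame(t - spec$frame_interval, rows, cols)
      src_r <- as.vector(rows - fl$d_row)
      src_c <- as.vector(cols - fl$d_col)
      map_r <- matrix(bilinear_sample(map_r, src_r, src_c, fill = NA), H, W)
      map_c <- matrix(bilinear_sample(map_c, src_r, src_c, fill = NA), H, W)
      oob <- is.na(map_r) | is.na(map_c)
      map_r[oob] <- rows[oob]; map_c[oob] <- cols[oob]
      tex <- matrix(bilinear_sample(tex0, as.vector(map_r), as.vector(map_c),
                                    fill = 0.5), H, W)
    }
    cm <- cell_mask_at(t)
    img <- matrix(0.62, H, W)
    img[zona_band] <- 0.5
    img[zona_edges] <- 0.28
    inside <- cm$mask
    img[inside] <- 0.55 + spec$texture_contrast * (tex[inside] - 0.5)
    if (two_cell) {
      b1 <- abs(sqrt((rows - lobe_ctrs[[1]][1])^2 + (cols - lobe_ctrs[[1]][2])^2) -
                  spec$two_cell_radius_um / px) < 1.2
      b2 <- abs(sqrt((rows - lobe_ctrs[[2]][1])^2 + (cols - lobe_ctrs[[2]][2])^2) -
                  spec$two_cell_radius_um / px) < 1.2
      img[b1 | b2] <- spec$membrane_intensity
    } else {
      img[cm$edge] <- spec$membrane_intensity
    }
    for (sp in spec$spots) {
      pos <- ctr + (sp$start_um + sp$velocity_um_min * t) / px
      rr <- max(1, floor(pos[1] - 5)):min(H, ceiling(pos[1] + 5))
      cc <- max(1, floor(pos[2] - 5)):min(W, ceiling(pos[2] + 5))
      d2 <- outer((rr - pos[1])^2, (cc - pos[2])^2, "+")
      img[rr, cc] <- img[rr, cc] + sp$amplitude * exp(-d2 / (2 * sp$sigma_px^2))
    }
    img <- pmin(pmax(img + noise(), 0), 1)
    frames[[f]] <- img

    if (two_cell) {
      cell_masks[[f]] <- cm$masks
      outlines[[f]] <- NULL
    } else {
      Rf <- cell_radius_um(spec, fine_theta, t) / px
      dirs <- vapply(fine_theta, angle_dir, numeric(2))
      outlines[[f]] <- cbind(row = ctr[1] + Rf * dirs[1, ],
                             col = ctr[2] + Rf * dirs[2, ])
      cell_masks[[f]] <- list(cm$mask)
    }
  }

  stack <- frame_stack(frames, px, spec$frame_interval, normalize = FALSE)

  # ground-truth flow at PIV-like grid points, px/frame, per frame pair
  g_rows <- seq(grid_spacing_px, H - grid_spacing_px, by = grid_spacing_px)
  g_cols <- seq(grid_spacing_px, W - grid_spacing_px, by = grid_spacing_px)
  gg <- expand.grid(row = g_rows, col = g_cols)
  flow_grid <- do.call(rbind, lapply(seq_len(spec$n_frames - 1), function(f) {
    t <- (f - 1) * spec$frame_interval
    fl <- flow_px_frame(t, gg$row, gg$col)
    inside <- if (two_cell) {
      Reduce(`|`, lapply(cell_masks[[f]], function(m) m[cbind(gg$row, gg$col)]))
    } else {
      cell_masks[[f]][[1]][cbind(gg$row, gg$col)]
    }
    data.frame(pair = f, row = gg$row, col = gg$col,
               d_row_px = fl$d_row, d_col_px = fl$d_col, in_cell = inside)
  }))

  events <- list()
  for (m in spec$modulations) {
    for (k in seq_len(m$n_cycles)) {
      t0 <- m$t_start_min + (k - 1) * m$period_min
      events[[length(events) + 1]] <- list(
        type = "shape_sequence", angle_deg = m$angle_deg,
        amplitude_um = m$amplitude_um,
        start_frame = floor(t0 / spec$frame_interval) + 1,
        peak_frame = round((t0 + m$period_min / 2) / spec$frame_interval) + 1,
        end_frame = ceiling((t0 + m$period_min) / spec$frame_interval) + 1
      )
    }
  }
  if (!is.null(spec$cytokinesis)) {
    events[[length(events) + 1]] <- list(
      type = "first_step",
      frame = floor(spec$cytokinesis$t_first_step_min / spec$frame_interval) + 1,
      axis_deg = spec$cytokinesis$axis_deg
    )
  }

  list(
    stack = stack,
    truth = list(
      centre = ctr, outlines = outlines, cell_masks = cell_masks,
      flow_at = flow_px_frame, flow_grid = flow_grid, events = events,
      spec = spec
    )
  )
}

#' Library of named scenario presets
#'
#' * `interphase_cycles`: a static cell with two injected in-out-in shape
#'   cycles of 3 um amplitude on the 140 degree diameter.
#' * `pnebd_burst`: slow solid-body cytoplasm rotation with a brief
#'   four-fold speed spike mid-recording.
#' * `cytokinesis_vortices`: a two-cell geometry with mirrored
#'   counter-rotating Rankine vortices, one per nascent cell (61 frames =
#'   60 frame pairs).
#' * `two_cell_persistence`: the same mirrored vortices sampled every 10
#'   minutes for 560 minutes of simulated time, so the opposed vorticity
#'   signs persist across all 100-minute windows.
#'
#' @param name preset name; omit to list available names.
#' @param seed RNG seed for the returned spec.
#' @return a `zf_scenario`, or a character vector of names.
#' @export
preset_library <- function(name = NULL, seed = 1L) {
  build <- list(
    interphase_cycles = function() scenario_spec(
      n_frames = 50, frame_interval = 2,
      modulations = list(list(angle_deg = 140, amplitude_um = 3,
                              t_start_min = 10, period_min = 30, n_cycles = 2)),
      seed = seed
    ),
    pnebd_burst = function() scenario_spec(
      n_frames = 40, frame_interval = 2,
      flow = flow_rotation(0.004, burst = list(t_min = 36, duration_min = 8,
                                               factor = 4)),
      seed = seed
    ),
    cytokinesis_vortices = function() {
      ax <- angle_dir(20)
      off <- 24
      scenario_spec(
        n_frames = 61, frame_interval = 2, geometry = "two_cell",
        two_cell_axis_deg = 20,
        flow = flow_vortex_pair(
          centres_um = list(ax * off, -ax * off),
          omegas = c(0.05, -0.05), core_um = 14
        ),
        texture_contrast = 0.5, membrane_intensity = 0.42,
        seed = seed
      )
    },
    two_cell_persistence = function() {
      ax <- angle_dir(20)
      off <- 24
      scenario_spec(
        n_frames = 57, frame_interval = 10, geometry = "two_cell",
        two_cell_axis_deg = 20,
        flow = flow_mirror_rotation(
          centres_um = list(ax * off, -ax * off),
          omegas = c(0.012, -0.012)
        ),
        texture_contrast = 0.5, membrane_intensity = 0.42,
        seed = seed
      )
    }
  )
  if (is.null(name)) return(names(build))
  if (!name %in% names(build)) {
    stop("unknown preset: ", name, " (available: ",
         paste(names(build), collapse = ", "), ")")
  }
  build[[name]]()
}
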