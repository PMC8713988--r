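# Programmatic fixtures shared across tests.

# Binary disk / ellipse images with given intensities.
make_disk <- function(radius_px, margin = 30, fg = 0.7, bg = 0.3) {
  H <- 2 * (radius_px + margin) + 1
  ctr <- c(radius_px + margin + 1, radius_px + margin + 1)
  rows <- matrix(seq_len(H), H, H)
  cols <- t(rows)
  r <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  list(img = ifelse(r <= radius_px, fg, bg), centre = ctr, radius = radius_px)
}

# Ellipse with semi-axis `a` along the image vertical (angle 0) and `b`
# horizontal.
make_ellipse <- function(a_px, b_px, margin = 30, fg = 0.7, bg = 0.3) {
  H <- 2 * (ceiling(max(a_px, b_px)) + margin) + 1
  ctr <- c((H + 1) / 2, (H + 1) / 2)
  rows <- matrix(seq_len(H), H, H)
  cols <- t(rows)
  e <- ((rows - ctr[1]) / a_px)^2 + ((cols - ctr[2]) / b_px)^2
  list(img = ifelse(e <= 1, fg, bg), centre = ctr, a = a_px, b = b_px)
}

# Smooth random texture with ~2 px correlation length, good for PIV.
make_texture <- function(n, seed = 1, pad = 0) {
  set.seed(seed)
  m <- matrix(stats::runif((n + 2 * pad)^2), n + 2 * pad)
  for (k in 1:2) {
    m <- (rbind(m[1, ], m[-nrow(m), ]) + m + rbind(m[-1, ], m[nrow(m), ])) / 3
    m <- (cbind(m[, 1], m[, -ncol(m)]) + m + cbind(m[, -1], m[, ncol(m)])) / 3
  }
  m
}

# A texture pair where frame b equals frame a displaced by integer (dr, dc).
translated_pair <- function(n = 256, dr = 3, dc = -2, seed = 1) {
  pad <- max(abs(dr), abs(dc)) + 5
  base <- make_texture(n, seed = seed, pad = pad)
  a <- base[(pad + 1):(pad + n), (pad + 1):(pad + n)]
  b <- base[(pad + 1 - dr):(pad + n - dr), (pad + 1 - dc):(pad + n - dc)]
  list(a = a, b = b)
}

# Hand-built vector field (solid-body rotation, CCW on screen for omega > 0).
rotation_field <- function(omega, ngrid = 15, spacing = 16,
                           frame_interval = 1) {
  gr <- seq(spacing, ngrid * spacing, by = spacing)
  ctr <- mean(gr)
  dy <- matrix(rep(gr - ctr, times = ngrid), ngrid)
  dx <- t(dy)
  structure(
    list(grid_rows = gr, grid_cols = gr,
         d_row = -omega * dx * frame_interval,
         d_col = omega * dy * frame_interval,
         valid = matrix(TRUE, ngrid, ngrid),
         peak_corr = matrix(1, ngrid, ngrid),
         frame_pair = c(1L, 2L), window_schedule = c(64L, 32L),
         overlap = 0.5, pixel_size = 1, frame_interval = frame_interval),
    class = "zf_vector_field"
  )
}

# Constant-vector field on the same grid.
uniform_field <- function(d_row, d_col, ngrid = 15, spacing = 16,
                          frame_interval = 1, pixel_size = 1) {
  f <- rotation_field(0, ngrid, spacing, frame_interval)
  f$d_row[] <- d_row
  f$d_col[] <- d_col
  f$pixel_size <- pixel_size
  f
}

# Synthetic zf_outline from a radius function r(theta_deg) in px.
outline_from_radius <- function(r_fun, centre = c(150, 150), n_angles = 360,
                                frame_index = 1L) {
  angles <- (seq_len(n_angles) - 1) * 360 / n_angles
  radii <- vapply(angles, r_fun, numeric(1))
  pts <- t(vapply(seq_along(angles), function(i) {
    centre + radii[i] * zygoflow:::angle_dir(angles[i])
  }, numeric(2)))
  colnames(pts) <- c("row", "col")
  structure(
    list(boundary = pts, centre = zygoflow:::polygon_centroid(pts),
         radii_px = radii, angles_deg = angles, frame_index = frame_index,
         target = "cell", objective = NA_real_, interpolated = FALSE),
    class = "zf_outline"
  )
}

# Brute-force circular-DP objective by exhaustive enumeration over closed
# paths with |delta r| <= 1 (independent oracle for polar_dp).
brute_force_dp <- function(energy, smoothing = 0, temporal_weight = 0,
                           r_prev = NULL) {
  A <- nrow(energy); R <- ncol(energy)
  best <- -Inf
  steps <- expand.grid(rep(list(-1:1), A - 1))
  for (s in seq_len(R)) {
    paths <- cbind(s, s + t(apply(as.matrix(steps), 1, cumsum)))
    ok <- apply(paths >= 1 & paths <= R, 1, all) &
      abs(paths[, A] - s) <= 1
    if (!any(ok)) next
    paths <- paths[ok, , drop = FALSE]
    obj <- apply(paths, 1, function(p) {
      e <- sum(energy[cbind(seq_len(A), p)])
      rough <- sum(diff(c(p, p[1]))^2)
      temp <- if (temporal_weight > 0) sum((p - r_prev)^2) else 0
      e - smoothing * rough - temporal_weight * temp
    })
    best <- max(best, max(obj))
  }
  best
}
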