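# synthetic_data: scenario rendering, ground truth, determinism, presets.

test_that("same spec and seed render bit-identical stacks", {
  spec <- scenario_spec(n_frames = 4, seed = 42)
  s1 <- render_scenario(spec)
  s2 <- render_scenario(spec)
  for (i in 1:4) expect_identical(s1$stack$frames[[i]], s2$stack$frames[[i]])
})

test_that("zero flow and zero noise give identical frames and zero truth", {
  spec <- scenario_spec(n_frames = 5, noise_sd = 0, seed = 42)
  sc <- render_scenario(spec)
  for (i in 2:5) {
    expect_identical(sc$stack$frames[[i]], sc$stack$frames[[1]])
  }
  expect_true(all(sc$truth$flow_grid$d_row_px == 0))
  expect_true(all(sc$truth$flow_grid$d_col_px == 0))
})

test_that("ground-truth flow equals the analytic model at grid points", {
  spec <- scenario_spec(n_frames = 3, flow = flow_rotation(0.01), seed = 7)
  sc <- render_scenario(spec)
  g <- sc$truth$flow_grid[sc$truth$flow_grid$pair == 1, ]
  ctr <- sc$truth$centre
  px <- spec$pixel_size
  # u = omega * dy, v = -omega * dx (um/min), converted to px/frame
  k <- spec$frame_interval
  expect_equal(g$d_col_px, 0.01 * (g$row - ctr[1]) * k, tolerance = 1e-12)
  expect_equal(g$d_row_px, -0.01 * (g$col - ctr[2]) * k, tolerance = 1e-12)
})

test_that("an injected diameter modulation appears in the event list", {
  spec <- scenario_spec(
    n_frames = 30,
    modulations = list(list(angle_deg = 140, amplitude_um = 3,
                            t_start_min = 10, period_min = 30, n_cycles = 1)),
    seed = 3
  )
  sc <- render_scenario(spec)
  ev <- Filter(function(e) e$type == "shape_sequence", sc$truth$events)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$angle_deg, 140)
  # the rendered outline polygon really bulges by ~3 um on that diameter
  peak_poly <- sc$truth$outlines[[ev[[1]]$peak_frame]]
  base_poly <- sc$truth$outlines[[1]]
  px <- spec$pixel_size
  ctr <- sc$truth$centre
  rad_at <- function(poly, ang) {
    i <- ang + 1  # fine outline sampled at 1 degree steps from 0
    sqrt(sum((poly[i, ] - ctr)^2)) * px
  }
  d_peak <- rad_at(peak_poly, 140) + rad_at(peak_poly, 320)
  d_base <- rad_at(base_poly, 140) + rad_at(base_poly, 320)
  expect_equal(d_peak - d_base, 3, tolerance = 0.2)
})

test_that("counter-rotating vortex truth has opposite signs per cell", {
  spec <- preset_library("cytokinesis_vortices", seed = 5)
  sc <- render_scenario(spec)
  g <- sc$truth$flow_grid[sc$truth$flow_grid$pair == 1, ]
  ctr <- sc$truth$centre
  px <- spec$pixel_size
  ax <- zygoflow:::angle_dir(20)
  c1 <- ctr + ax * 24 / px
  # analytic curl sign at each lobe centre neighbourhood: use the model
  near1 <- g$in_cell & sqrt((g$row - c1[1])^2 + (g$col - c1[2])^2) < 20
  c2 <- ctr - ax * 24 / px
  near2 <- g$in_cell & sqrt((g$row - c2[1])^2 + (g$col - c2[2])^2) < 20
  curl_sign <- function(sel) {
    # crude discrete curl from the sampled truth vectors
    sub <- g[sel, ]
    fit_u <- stats::lm(d_col_px ~ row + col, data = sub)
    fit_v <- stats::lm(d_row_px ~ row + col, data = sub)
    sign(stats::coef(fit_u)["row"] - stats::coef(fit_v)["col"])
  }
  expect_equal(unname(curl_sign(near1)), 1)
  expect_equal(unname(curl_sign(near2)), -1)
})

test_that("texture intensity inside the cell is conserved under rotation", {
  spec <- scenario_spec(n_frames = 10, flow = flow_rotation(0.02),
                        noise_sd = 0, seed = 11)
  sc <- render_scenario(spec)
  totals <- vapply(sc$stack$frames, function(f) {
    ctr <- sc$truth$centre
    H <- nrow(f)
    rows <- matrix(1:H, H, H); cols <- t(rows)
    r <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
    mean(f[r < spec$base_radius_um / spec$pixel_size - 3])
  }, numeric(1))
  expect_lt(max(abs(diff(totals)) / totals[-length(totals)]), 0.01)
})

test_that("presets are listed, render, and reject unknown names", {
  nms <- preset_library()
  expect_true(all(c("interphase_cycles", "pnebd_burst",
                    "cytokinesis_vortices", "two_cell_persistence") %in% nms))
  expect_error(preset_library("no_such_preset"), "unknown preset")
  spec <- preset_library("pnebd_burst", seed = 2)
  sc <- render_scenario(spec)
  expect_length(sc$stack$frames, spec$n_frames)
})

test_that("the cytokinesis preset renders 60 frame pairs quickly", {
  spec <- preset_library("cytokinesis_vortices", seed = 1)
  elapsed <- system.time(sc <- render_scenario(spec))["elapsed"]
  expect_equal(length(sc$stack$frames), 61)
  expect_lt(elapsed, 60)
})

test_that("the speed burst raises PIV-measured cytoplasm speed", {
  spec <- preset_library("pnebd_burst", seed = 6)
  sc <- render_scenario(spec)
  st <- sc$stack
  ctr <- sc$truth$centre
  rect <- c(ctr[1] - 30, ctr[1] + 30, ctr[2] - 30, ctr[2] + 30)
  speed_at <- function(i) {
    f <- piv_pair(st$frames[[i]], st$frames[[i + 1]], 64, 16,
                  pixel_size = st$pixel_size, frame_interval = st$frame_interval)
    as.numeric(mean_magnitude(f, rect))
  }
  quiet <- speed_at(5)
  burst <- speed_at(20)  # t = 38 min, inside the 36-44 min burst
  expect_gt(burst, 2 * quiet)
})
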