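test_that("forward model matches the closed-form quadrature oracle", {
  times <- 0:80
  aif <- aif_ramp(times)
  # trapezoid is exact on the piecewise-linear ramp, so the closed-form
  # integral is an independent oracle for the cumulative quadrature
  expect_equal(cumtrapz(times, aif), ramp_integral(times), tolerance = 1e-12)
  ct <- patlak_forward(0.24, 0.116, times, aif)
  oracle <- (0.24 / 60) * ramp_integral(times) + 0.116 * aif
  expect_lt(max(abs(ct - oracle) / pmax(oracle, 1e-12)), 1e-3)  # < 0.1%

  # zero-slope case: pure vascular signal
  ct0 <- patlak_forward(0, 0.116, times, aif)
  expect_equal(ct0, 0.116 * aif, tolerance = 1e-12)

  # on the AIF plateau with Ktrans > 0, tissue C_I keeps strictly increasing
  plateau_idx <- which(times > 20)
  expect_true(all(diff(ct[plateau_idx]) > 0))
})

test_that("patlak_transform linearizes exactly and guards the AIF", {
  times <- 0:80
  aif_c <- tcc(times, rep(4, 81), "lv")           # constant AIF from t = 0
  tis <- tcc(times, 0.116 * rep(4, 81), "tumor")
  pts <- patlak_transform(tis, aif_c)
  expect_equal(pts$x_s, as.numeric(times), tolerance = 1e-12)  # x(t) = t
  expect_equal(pts$y, rep(0.116, 81), tolerance = 1e-12)

  # forward-model points are exactly collinear: residual of exact line is 0
  aif <- tcc(times, aif_ramp(times), "lv")
  ct <- tcc(times, patlak_forward(0.3, 0.2, times, aif$ci_mg_ml), "tumor")
  p <- patlak_transform(ct, aif, window = patlak_window(30, 80))
  line <- (0.3 / 60) * p$x_s + 0.2
  expect_lt(max(abs(p$y - line)), 1e-12)

  # AIF <= 0 at an evaluated sample is an error naming the time
  bad <- tcc(times, c(0, aif_ramp(times)[-1]), "lv")
  expect_error(patlak_transform(ct, bad), "t = 0")
  # but windowing past the zero makes it usable
  expect_silent(patlak_transform(ct, bad, window = patlak_window(30, 80)))
  off_grid <- tcc(seq(0, 160, by = 2), rep(1, 81), "lv")
  expect_error(patlak_transform(ct, off_grid), "time grid")
})

test_that("patlak_fit recovers parameters, converts units, needs 3 points", {
  times <- 0:80
  aif <- tcc(times, aif_ramp(times), "lv")
  ct <- tcc(times, patlak_forward(0.24, 0.116, times, aif$ci_mg_ml), "tumor")
  fit <- patlak_analyze(ct, aif)
  expect_equal(fit$ktrans_per_min, 0.24, tolerance = 1e-9)
  expect_equal(fit$rbv_percent, 11.6, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_identical(fit$n, 51L)

  # tissue = c * aif: zero slope, intercept 100c
  prop <- tcc(times, 0.116 * aif$ci_mg_ml, "muscle")
  fitp <- patlak_analyze(prop, aif)
  expect_equal(fitp$ktrans_per_min, 0, tolerance = 1e-12)
  expect_equal(fitp$rbv_percent, 11.6, tolerance = 1e-9)

  pts <- patlak_transform(ct, aif, window = patlak_window(30, 80))
  expect_error(patlak_fit(pts, patlak_window(79.2, 80)), ">= 3")
  expect_error(patlak_window(50, 50))
})

test_that("fit is invariant to global AIF scaling and to sub-windowing", {
  times <- 0:80
  aif_v <- aif_ramp(times)
  ct_v <- patlak_forward(0.18, 0.25, times, aif_v)
  ref <- patlak_analyze(tcc(times, ct_v, "tumor"), tcc(times, aif_v, "lv"))
  for (k in c(0.2, 5)) {
    f <- patlak_analyze(tcc(times, k * ct_v, "tumor"),
                        tcc(times, k * aif_v, "lv"))
    expect_equal(f$ktrans_per_min, ref$ktrans_per_min, tolerance = 1e-9)
    expect_equal(f$rbv_percent, ref$rbv_percent, tolerance = 1e-9)
  }
  # any sub-window with >= 3 points gives the same fit on exact data
  for (w in list(c(30, 40), c(45, 55), c(70, 80))) {
    f <- patlak_analyze(tcc(times, ct_v, "tumor"), tcc(times, aif_v, "lv"),
                        patlak_window(w[1], w[2]))
    expect_equal(f$ktrans_per_min, 0.18, tolerance = 1e-9)
    expect_equal(f$rbv_percent, 25, tolerance = 1e-9)
  }
})

test_that("smooth_curve: identity window, constant curves, variance reduction", {
  times <- 0:80
  curve <- tcc(times, aif_ramp(times), "lv")
  expect_equal(smooth_curve(curve, 1)$ci_mg_ml, curve$ci_mg_ml)
  const <- tcc(times, rep(3, 81), "lv")
  expect_equal(smooth_curve(const, 5)$ci_mg_ml, rep(3, 81))
  expect_error(smooth_curve(tcc(0:3, rep(1, 4), "lv"), 50), "window")

  # white noise, window 5: interior variance drops by ~5
  noise <- cemct:::with_seed(21, rnorm(5000))
  nc <- tcc(seq_len(5000), noise, "custom")
  sm <- smooth_curve(nc, 5)
  interior <- 3:4998
  ratio <- var(sm$ci_mg_ml[interior]) / var(noise[interior])
  expect_equal(ratio, 1 / 5, tolerance = 0.15)
  expect_match(sm$smoothing, "ma:5")
})

test_that("curve extraction from a generated planar series", {
  spec <- dce_spec()
  truth <- dce_truth()
  series <- make_dce_series(spec, truth)
  # pipeline: baseline subtraction + calibration to projected C_I
  cal <- new_calibration(1 / spec$hu_per_mgml, 0, protocol = "DCE")
  ci_series <- series_apply_calibration(series_subtract_baseline(series), cal)

  tumor_voi <- spec$organs[[3]]$voi
  curve <- extract_curve(ci_series, tumor_voi$center[1:2],
                         tumor_voi$semi_axes[1:2], label = "tumor")
  forward <- patlak_forward(0.24, 0.116, truth$times_s,
                            aif_ramp(truth$times_s))
  # projected curve equals the generating curve up to one scale factor:
  # the ratio is constant across time (< 0.5% spread)
  nz <- forward > 1e-9
  ratio <- curve$ci_mg_ml[nz] / forward[nz]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.005)

  # thickness normalization recovers absolute concentrations approximately
  curve_n <- extract_curve(ci_series, tumor_voi$center[1:2],
                           tumor_voi$semi_axes[1:2], label = "tumor",
                           thickness_mm = voi_effective_thickness(tumor_voi))
  expect_equal(curve_n$ci_mg_ml[60], forward[60], tolerance = 0.05)

  # constant frames give a flat curve
  flat <- planar_series(array(2.5, dim = c(8, 8, 5)), 0:4, c(1, 1))
  fc <- extract_curve(flat, c(3, 3), c(2, 2))
  expect_equal(fc$ci_mg_ml, rep(2.5, 5))
  expect_error(extract_curve(flat, c(100, 100), c(1, 1)), "no pixels")
})

test_that("planar superimposition biases the tumor curve upward", {
  spec <- dce_spec()
  truth <- kinetic_truth(list(
    tumor = list(ktrans_per_min = 0.24, rbv = 0.116),
    lv = list(ktrans_per_min = 0, rbv = 1),
    liver = list(ktrans_per_min = 0.1, rbv = 0.3)))
  clean <- make_dce_series(spec, truth)
  overlapped <- make_dce_series(spec, truth, overlap_labels = "liver")
  cal <- new_calibration(1 / spec$hu_per_mgml, 0, protocol = "DCE")
  tumor_voi <- spec$organs[[3]]$voi
  get_curve <- function(s) {
    extract_curve(series_apply_calibration(series_subtract_baseline(s), cal),
                  tumor_voi$center[1:2], tumor_voi$semi_axes[1:2], "tumor")
  }
  c_clean <- get_curve(clean); c_over <- get_curve(overlapped)
  expect_true(all(c_over$ci_mg_ml[-1] > c_clean$ci_mg_ml[-1]))
})

test_that("projection conserves total signal and errors name missing regions", {
  spec <- dce_spec()
  truth <- dce_truth()
  series <- make_dce_series(spec, truth)
  # linearity of parallel projection: frame sum * pixel area equals
  # voxel-volume-weighted sum of the projected 3D map
  enh <- series_subtract_baseline(series)
  k <- 41L  # frame at t = 40 s
  aif <- aif_ramp(truth$times_s)
  vol3d <- array(0, dim = spec$shape)
  for (lab in names(truth$regions)) {
    r <- truth$regions[[lab]]
    org <- Filter(function(o) o$voi$label == lab, spec$organs)[[1]]
    m <- cemct:::voi_mask(org$voi, spec$shape, spec$spacing)
    ctk <- patlak_forward(r$ktrans_per_min, r$rbv, truth$times_s, aif)[k]
    vol3d[m] <- vol3d[m] + spec$hu_per_mgml * ctk
  }
  lhs <- sum(enh$frames[, , k]) * prod(enh$spacing)
  rhs <- sum(vol3d) * prod(spec$spacing)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  bad_truth <- kinetic_truth(list(kidney = list(ktrans_per_min = 0.1, rbv = 0.1)))
  expect_error(make_dce_series(spec, bad_truth), "kidney")
})

test_that("DCE planar pipeline recovers kinetics end to end (thickness-corrected)", {
  spec <- dce_spec()
  truth <- dce_truth()
  series <- make_dce_series(spec, truth)
  cal <- new_calibration(1 / spec$hu_per_mgml, 0, protocol = "DCE")
  ci_series <- series_apply_calibration(series_subtract_baseline(series), cal)
  get <- function(lab) {
    voi <- Filter(function(o) o$voi$label == lab, spec$organs)[[1]]$voi
    extract_curve(ci_series, voi$center[1:2], voi$semi_axes[1:2], lab,
                  thickness_mm = voi_effective_thickness(voi))
  }
  fit <- patlak_analyze(get("tumor"), get("lv"))
  # voxelized projection geometry costs a few percent of accuracy
  expect_equal(fit$ktrans_per_min, 0.24, tolerance = 0.1)
  expect_equal(fit$rbv_percent, 11.6, tolerance = 0.12)
  expect_gt(fit$r_squared, 0.999)
})

test_that("series and curve I/O round trips", {
  spec <- dce_spec()
  series <- make_dce_series(spec, dce_truth())
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dce.nii")
  write_series(series, path)
  back <- read_series(path)
  expect_equal(back$frames, series$frames, tolerance = 1e-12)
  expect_equal(back$times_s, series$times_s)
  expect_equal(back$baseline, series$baseline, tolerance = 1e-12)
  expect_identical(back$kind, series$kind)

  curve <- tcc(0:10, (0:10) / 10, "muscle")
  cpath <- file.path(dir, "muscle.csv")
  write_curve_csv(curve, cpath)
  cback <- read_curve_csv(cpath)
  expect_equal(cback$ci_mg_ml, curve$ci_mg_ml)
  expect_identical(cback$label, "muscle")
})
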