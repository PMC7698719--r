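#' Time-concentration curve
#'
#' Iodine concentration over time for one region (left ventricle = AIF,
#' muscle, or tumor), extracted from a calibrated dynamic planar series or
#' produced directly by the forward model.
#'
#' @param times_s Sample times, s, strictly increasing.
#' @param ci_mg_ml Concentrations, mg I/mL, same length.
#' @param label Region label (`"lv"` marks the arterial input function).
#' @param smoothing Smoothing descriptor (`"none"` or e.g. `"ma:5s"`).
#' @return Object of class `cemct_tcc`.
#' @export
tcc <- function(times_s, ci_mg_ml, label = "custom", smoothing = "none") {
  times_s <- as.numeric(times_s); ci_mg_ml <- as.numeric(ci_mg_ml)
  if (length(times_s) != length(ci_mg_ml)) abort("times/concentrations length mismatch")
  if (length(times_s) > 1L && any(diff(times_s) <= 0)) {
    abort("times must be strictly increasing")
  }
  structure(list(times_s = times_s, ci_mg_ml = ci_mg_ml,
                 label = as.character(label), smoothing = smoothing),
            class = "cemct_tcc")
}

#' @export
print.cemct_tcc <- function(x, ...) {
  cat(sprintf("<cemct_tcc> %s: %d samples, t = %g..%g s, C_I range [%.3g, %.3g] mg I/mL (%s)\n",
              x$label, length(x$times_s), min(x$times_s), max(x$times_s),
              min(x$ci_mg_ml), max(x$ci_mg_ml), x$smoothing))
  invisible(x)
}

#' Effective path length of an ellipsoid along a projection axis
#'
#' Mean chord length over the projected footprint, `volume / footprint area
#' = (4/3) * semi_axis`. Dividing a projected ROI mean by this thickness
#' converts projected concentration (mg I/mL * mm) back to concentration for
#' a homogeneous ellipsoidal organ.
#'
#' @param voi A `cemct_voi`.
#' @param axis Projection axis (1-3).
#' @return Thickness, mm.
#' @export
voi_effective_thickness <- function(voi, axis = 3L) {
  stopifnot(inherits(voi, "cemct_voi"))
  4 / 3 * voi$semi_axes[axis]
}

#' Extract a time-concentration curve from a planar series
#'
#' Per-frame mean over an elliptical ROI (pixel-center membership).
#' Projection images hold line integrals, so the ROI mean carries a path
#' length in mm; supply `thickness_mm` (e.g.
#' [voi_effective_thickness()]) to divide it out and obtain a concentration
#' curve, or leave `NULL` to keep the projected units.
#'
#' @param series A `cemct_planar_series` (calibrated:
#'   `"proj_iodine_mg_ml_mm"`, or any kind if you only need shapes).
#' @param center Ellipse center, mm, length 2.
#' @param semi_axes Ellipse semi-axes, mm, length 2.
#' @param label Region label for the curve.
#' @param thickness_mm Optional path-length normalization, mm.
#' @return A `cemct_tcc`.
#' @export
extract_curve <- function(series, center, semi_axes, label = "custom",
                          thickness_mm = NULL) {
  stopifnot(inherits(series, "cemct_planar_series"))
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  stopifnot(length(center) == 2L, length(semi_axes) == 2L, all(semi_axes > 0))
  d <- dim(series$frames)
  ux <- ((axis_coords(d[1], series$spacing[1]) - center[1]) / semi_axes[1])^2
  uy <- ((axis_coords(d[2], series$spacing[2]) - center[2]) / semi_axes[2])^2
  m <- outer(ux, uy, "+") <= 1
  if (!any(m)) abort("ROI '%s' contains no pixels", label)
  vals <- apply(series$frames, 3, function(f) mean(f[m]))
  if (!is.null(thickness_mm)) {
    check_scalar(thickness_mm, "thickness_mm")
    if (thickness_mm <= 0) abort("`thickness_mm` must be > 0")
    vals <- vals / thickness_mm
  }
  tcc(series$times_s, vals, label)
}

#' Moving-average smoothing of a time-concentration curve
#'
#' Centered moving average; at the edges the window is truncated to the
#' available samples. `window_s` is converted to an odd number of samples
#' from the median sampling interval. A window of one sample is the
#' identity.
#'
#' @param curve A `cemct_tcc`.
#' @param window_s Smoothing window, s (>= one sampling interval).
#' @return A `cemct_tcc` with the smoothing recorded in its descriptor.
#' @export
smooth_curve <- function(curve, window_s = 5) {
  stopifnot(inherits(curve, "cemct_tcc"))
  check_scalar(window_s, "window_s")
  dt <- stats::median(diff(curve$times_s))
  k <- max(1L, round(window_s / dt))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(curve$ci_mg_ml)
  if (k > n) abort("smoothing window (%d samples) exceeds curve length (%d)", k, n)
  h <- (k - 1L) %/% 2L
  y <- curve$ci_mg_ml
  sm <- vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
  tcc(curve$times_s, sm, curve$label, smoothing = sprintf("ma:%gs", window_s))
}

#' Patlak window
#'
#' Time interval over which the irreversible-compartment assumption holds and
#' the Patlak plot is fitted. Default 30-80 s for the standard
#' continuous-infusion protocol.
#'
#' @param t1_s,t2_s Window bounds, s, `t1_s < t2_s`.
#' @return Object of class `cemct_patlak_window`.
#' @export
patlak_window <- function(t1_s = 30, t2_s = 80) {
  check_scalar(t1_s, "t1_s"); check_scalar(t2_s, "t2_s")
  if (t1_s >= t2_s) abort("need t1_s < t2_s")
  structure(list(t1_s = t1_s, t2_s = t2_s), class = "cemct_patlak_window")
}

#' Patlak transformation
#'
#' Linearizes the irreversible two-compartment model: for each sample,
#' `x(t) = int_0^t C_AIF dtau / C_AIF(t)` (units s, cumulative trapezoid from
#' the start of the grid) and `y(t) = C_tissue(t) / C_AIF(t)`
#' (dimensionless). On data generated by the forward model the points are
#' exactly collinear with slope K^trans (s^-1) and intercept rBV.
#'
#' @param tissue,aif `cemct_tcc`s on an identical time grid.
#' @param window Optional [patlak_window()]; when supplied, only samples with
#'   `t` in the window are evaluated (the AIF integral still starts at the
#'   grid origin). The AIF must be > 0 at every evaluated sample.
#' @return A data.frame with columns `t_s`, `x_s`, `y`.
#' @export
patlak_transform <- function(tissue, aif, window = NULL) {
  stopifnot(inherits(tissue, "cemct_tcc"), inherits(aif, "cemct_tcc"))
  if (length(tissue$times_s) != length(aif$times_s) ||
      max(abs(tissue$times_s - aif$times_s)) > 1e-9) {
    abort("tissue and AIF curves must share one time grid")
  }
  t <- tissue$times_s
  integ <- cumtrapz(t, aif$ci_mg_ml)
  keep <- if (is.null(window)) {
    rep(TRUE, length(t))
  } else {
    stopifnot(inherits(window, "cemct_patlak_window"))
    t >= window$t1_s & t <= window$t2_s
  }
  bad <- keep & aif$ci_mg_ml <= 0
  if (any(bad)) {
    abort("AIF is not positive at t = %g s; cannot form the Patlak plot",
          t[which(bad)[1]])
  }
  data.frame(t_s = t[keep],
             x_s = integ[keep] / aif$ci_mg_ml[keep],
             y = tissue$ci_mg_ml[keep] / aif$ci_mg_ml[keep])
}

#' Patlak linear regression
#'
#' Ordinary least squares of `y` on `x` over the points whose time lies in
#' the fit window. The slope (s^-1) is reported as K^trans in min^-1 (x60);
#' the intercept, a vascular volume fraction, is reported as rBV in percent
#' (x100).
#'
#' @param points Data.frame from [patlak_transform()] (columns `t_s`, `x_s`,
#'   `y`).
#' @param window A [patlak_window()]; at least 3 points must fall inside.
#' @return Object of class `cemct_kinetic_fit`: list with `ktrans_per_min`,
#'   `rbv_percent`, `r_squared`, `n`, `window`.
#' @export
patlak_fit <- function(points, window = patlak_window()) {
  stopifnot(is.data.frame(points), all(c("t_s", "x_s", "y") %in% names(points)),
            inherits(window, "cemct_patlak_window"))
  inw <- points$t_s >= window$t1_s & points$t_s <= window$t2_s
  n <- sum(inw)
  if (n < 3L) abort("only %d points in the %g-%g s window; need >= 3", n,
                    window$t1_s, window$t2_s)
  x <- points$x_s[inw]; y <- points$y[inw]
  fit <- stats::lm(y ~ x)
  r2 <- r_squared_of(fit, y)
  structure(list(ktrans_per_min = unname(stats::coef(fit)[2]) * 60,
                 rbv_percent = unname(stats::coef(fit)[1]) * 100,
                 r_squared = r2, n = n, window = window),
            class = "cemct_kinetic_fit")
}

#' @export
print.cemct_kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> K^trans = %.4g min^-1, rBV = %.4g %%  (R^2 = %.5f, n = %d, %g-%g s)\n",
    x$ktrans_per_min, x$rbv_percent, x$r_squared, x$n,
    x$window$t1_s, x$window$t2_s))
  invisible(x)
}

#' Full Patlak analysis of a tissue/AIF curve pair
#'
#' Convenience wrapper: [patlak_transform()] restricted to the window
#' followed by [patlak_fit()].
#'
#' @inheritParams patlak_transform
#' @param window A [patlak_window()].
#' @return A `cemct_kinetic_fit`.
#' @export
patlak_analyze <- function(tissue, aif, window = patlak_window()) {
  patlak_fit(patlak_transform(tissue, aif, window = window), window = window)
}

#' Curve CSV I/O (`t_s`, `ci_mg_ml`, `label`)
#' @param curve A `cemct_tcc`.
#' @param path File path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "cemct_tcc"))
  utils::write.csv(data.frame(t_s = curve$times_s, ci_mg_ml = curve$ci_mg_ml,
                              label = curve$label),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  x <- utils::read.csv(path)
  tcc(x$t_s, x$ci_mg_ml, label = as.character(x$label[1]))
}

#' Kinetic-fit JSON serialization
#' @param fit A `cemct_kinetic_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cemct_kinetic_fit"))
  jsonlite::write_json(list(ktrans_per_min = fit$ktrans_per_min,
                            rbv_percent = fit$rbv_percent,
                            r2 = fit$r_squared, t1_s = fit$window$t1_s,
                            t2_s = fit$window$t2_s, n = fit$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
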