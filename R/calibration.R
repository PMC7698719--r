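#' Subtraction configuration
#'
#' Temporal mode computes the enhancement image `E = CE - baseline`; weighted
#' dual-energy mode computes `E = HE - alpha * LE`. The default weighting
#' factor `alpha = 0.55` cancels unenhanced soft tissue between the two beam
#' qualities (it is chosen to null tissue, not bone), leaving the
#' iodine-specific signal.
#'
#' @param mode `"temporal"` or `"weighted_de"`.
#' @param alpha Dual-energy weighting factor, in (0, 1]. Ignored in temporal
#'   mode.
#' @return An object of class `cemct_subtraction_config`.
#' @export
subtraction_config <- function(mode = c("temporal", "weighted_de"), alpha = 0.55) {
  mode <- match.arg(mode)
  check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1]")
  structure(list(mode = mode, alpha = alpha), class = "cemct_subtraction_config")
}

#' Temporal or weighted dual-energy subtraction
#'
#' Produces an enhancement image in HU. Temporal mode: `a` is the
#' contrast-enhanced image and `b` the registered baseline, `E = a - b`.
#' Weighted mode: `a` is the high-energy image and `b` the registered
#' low-energy image, `E = a - alpha * b`.
#'
#' Both inputs must be HU volumes in the same frame; a frame mismatch is an
#' error instructing registration first.
#'
#' @param a,b `cemct_volume`s of kind `"hu"`, same shape/spacing/frame.
#' @param cfg A [subtraction_config()].
#' @return A `cemct_volume` of kind `"enhancement_hu"`.
#' @export
subtract <- function(a, b, cfg = subtraction_config()) {
  stopifnot(inherits(cfg, "cemct_subtraction_config"))
  check_compatible(a, b)
  if (a$kind != "hu" || b$kind != "hu") {
    abort("subtract() expects HU volumes (got '%s' and '%s')", a$kind, b$kind)
  }
  out <- a
  out$data <- if (cfg$mode == "temporal") a$data - b$data else a$data - cfg$alpha * b$data
  out$kind <- "enhancement_hu"
  out
}

#' Iodine calibration curve
#'
#' Straight-line map from enhancement (HU) to iodine concentration
#' (mg I/mL), fitted per imaging protocol against an iodinated calibration
#' phantom. The intercept is left free (whether the physical line passes
#' through the origin is protocol-dependent); the fit R-squared is carried
#' along so that degenerate calibrations can be flagged downstream.
#'
#' @param slope (mg I/mL) per HU, must be > 0 for a physical calibration.
#' @param intercept mg I/mL.
#' @param r_squared Fit R-squared in [0, 1].
#' @param protocol `"SE"`, `"DE"` or `"DCE"`.
#' @param n Number of calibration points used.
#' @return Object of class `cemct_calibration`.
#' @export
new_calibration <- function(slope, intercept, r_squared = 1,
                            protocol = c("SE", "DE", "DCE"), n = NA_integer_) {
  protocol <- match.arg(protocol)
  check_scalar(slope, "slope"); check_scalar(intercept, "intercept")
  check_scalar(r_squared, "r_squared")
  if (r_squared < 0 || r_squared > 1 + 1e-12) abort("`r_squared` must be in [0, 1]")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = min(r_squared, 1), protocol = protocol,
                 n = as.integer(n)),
            class = "cemct_calibration")
}

#' @export
print.cemct_calibration <- function(x, ...) {
  cat(sprintf("<cemct_calibration> %s: C_I = %.6g * E %+.6g  (R^2 = %.4f, n = %d)\n",
              x$protocol, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Fit an iodine calibration curve from phantom measurements
#'
#' Ordinary least squares of known iodine concentration on measured VOI-mean
#' enhancement. Replicate points count with their multiplicity (no implicit
#' weighting). At least 3 points over at least 3 distinct concentrations are
#' required, and the enhancement values must not be all equal.
#'
#' @param enhancement_hu Numeric vector of VOI-mean enhancements (HU).
#' @param concentration_mg_ml Known iodine concentrations (mg I/mL), same
#'   length.
#' @param protocol Protocol tag for the resulting curve.
#' @return A `cemct_calibration`.
#' @export
fit_calibration <- function(enhancement_hu, concentration_mg_ml,
                            protocol = c("SE", "DE", "DCE")) {
  protocol <- match.arg(protocol)
  e <- as.numeric(enhancement_hu); ci <- as.numeric(concentration_mg_ml)
  if (length(e) != length(ci)) abort("input lengths differ")
  if (length(e) < 3L) abort("need at least 3 calibration points, got %d", length(e))
  if (length(unique(ci)) < 3L) abort("need at least 3 distinct concentrations")
  if (any(ci < 0)) abort("concentrations must be >= 0")
  if (stats::sd(e) < 1e-12) abort("degenerate calibration: all enhancements equal")
  fit <- stats::lm(ci ~ e)
  r2 <- r_squared_of(fit, ci)
  new_calibration(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  r_squared = r2, protocol = protocol, n = length(e))
}

#' Convert an enhancement image to an iodine-concentration image
#'
#' Applies the protocol-specific calibration voxelwise:
#' `C_I = slope * E + intercept`. Negative concentrations are retained by
#' default so that VOI means stay unbiased; pass `floor_mg_ml = 0` to clamp.
#'
#' @param e A `cemct_volume` of kind `"enhancement_hu"`.
#' @param cal A `cemct_calibration` whose protocol matches the image's
#'   protocol tag (untagged images are accepted).
#' @param floor_mg_ml Optional lower clamp (mg I/mL); `NULL` retains
#'   negatives.
#' @return A `cemct_volume` of kind `"iodine_mg_ml"`.
#' @export
apply_calibration <- function(e, cal, floor_mg_ml = NULL) {
  stopifnot(is_volume(e), inherits(cal, "cemct_calibration"))
  if (e$kind != "enhancement_hu") {
    abort("apply_calibration() expects an enhancement_hu volume, got '%s'", e$kind)
  }
  if (!is.null(e$protocol) && e$protocol != cal$protocol) {
    abort("calibration protocol '%s' does not match image protocol '%s'",
          cal$protocol, e$protocol)
  }
  out <- e
  out$data <- cal$slope * e$data + cal$intercept
  if (!is.null(floor_mg_ml)) out$data <- pmax(out$data, floor_mg_ml)
  out$kind <- "iodine_mg_ml"
  out
}

#' Serialize / restore a calibration curve as YAML
#' @param cal A `cemct_calibration`.
#' @param path File path.
#' @export
write_calibration_yaml <- function(cal, path) {
  stopifnot(inherits(cal, "cemct_calibration"))
  yaml::write_yaml(unclass(cal), path)
  invisible(path)
}

#' @rdname write_calibration_yaml
#' @export
read_calibration_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  new_calibration(x$slope, x$intercept, x$r_squared, x$protocol,
                  n = if (is.null(x$n)) NA_integer_ else x$n)
}
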