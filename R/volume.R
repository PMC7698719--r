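#' 3D image volume
#'
#' The basic container of the static (single- and dual-energy) pipeline: a 3D
#' scalar array with voxel spacing in mm, a frame-of-reference id, a value-kind
#' tag and an optional imaging-protocol tag. The value kind records where the
#' image sits in the processing chain (`attenuation_mu` -> `hu` ->
#' `enhancement_hu` -> `iodine_mg_ml`); operations check and update it so that,
#' e.g., a calibration curve cannot be applied to a raw attenuation image.
#'
#' World coordinates are `(index - 1) * spacing` per axis (0-based voxel
#' indices, origin at the corner voxel center).
#'
#' @param data Numeric 3D array.
#' @param spacing Voxel spacing in mm, length 3, all > 0.
#' @param frame Frame-of-reference id (character scalar). Two volumes can only
#'   be combined voxelwise when their frames match.
#' @param kind Value-kind tag, one of `"attenuation_mu"`, `"hu"`,
#'   `"enhancement_hu"`, `"iodine_mg_ml"`.
#' @param protocol Optional imaging-protocol tag (`"SE"`, `"DE"`, `"DCE"`) used
#'   to guard calibration application. `NULL` means unspecified.
#' @return An object of class `cemct_volume`.
#' @export
new_volume <- function(data, spacing, frame = "ref", kind = "hu",
                       protocol = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive values (mm)")
  }
  kind <- match.arg(kind, volume_kinds())
  if (!is.null(protocol)) protocol <- match.arg(protocol, c("SE", "DE", "DCE"))
  structure(
    list(data = data, spacing = spacing, frame = as.character(frame),
         kind = kind, protocol = protocol),
    class = "cemct_volume"
  )
}

volume_kinds <- function() c("attenuation_mu", "hu", "enhancement_hu", "iodine_mg_ml")

#' @export
print.cemct_volume <- function(x, ...) {
  cat(sprintf("<cemct_volume> %s  %s\n", paste(dim(x$data), collapse = "x"), x$kind))
  cat(sprintf("  spacing (mm): %s   frame: %s   protocol: %s\n",
              paste(format(x$spacing), collapse = " x "), x$frame,
              if (is.null(x$protocol)) "<unset>" else x$protocol))
  cat(sprintf("  range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.cemct_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "cemct_volume")

# guard for voxelwise arithmetic between two volumes
check_compatible <- function(a, b, require_frame = TRUE) {
  stopifnot(is_volume(a), is_volume(b))
  if (!identical(dim(a$data), dim(b$data))) {
    abort("volumes have different shapes (%s vs %s)",
          paste(dim(a$data), collapse = "x"), paste(dim(b$data), collapse = "x"))
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-9) {
    abort("volumes have different voxel spacing")
  }
  if (require_frame && !identical(a$frame, b$frame)) {
    abort("volumes are in different frames ('%s' vs '%s'); run register_affine() first",
          a$frame, b$frame)
  }
  invisible(TRUE)
}

# world coordinates of voxel centers along one axis (mm)
axis_coords <- function(n, spacing) (seq_len(n) - 1) * spacing

#' Calibrate a raw attenuation volume to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`, using the measured linear
#' attenuation coefficient of water for the imaging protocol at hand. Water
#' maps to 0 HU and vacuum/air to -1000 HU.
#'
#' @param vol A `cemct_volume` with kind `"attenuation_mu"`.
#' @param mu_water Linear attenuation coefficient of water (same units as the
#'   volume values), > 0. Protocol-specific: each beam quality has its own.
#' @return A `cemct_volume` with kind `"hu"`; shape, spacing, frame preserved.
#' @export
hu_calibrate <- function(vol, mu_water) {
  stopifnot(is_volume(vol))
  if (vol$kind != "attenuation_mu") {
    abort("hu_calibrate() expects an attenuation_mu volume, got '%s'", vol$kind)
  }
  check_scalar(mu_water, "mu_water")
  if (mu_water <= 0) abort("`mu_water` must be > 0")
  out <- vol
  out$data <- 1000 * (vol$data - mu_water) / mu_water
  out$kind <- "hu"
  out
}
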