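#' Kinetic ground truth for the dynamic forward model
#'
#' Parameters of the irreversible two-compartment (Patlak) model under
#' continuous contrast infusion: per-region volume transfer constant K^trans
#' (min^-1) and vascular volume fraction rBV (dimensionless, in [0, 1]), plus
#' the arterial input function. The AIF follows the shape observed in a large
#' blood pool during continuous infusion: a linear ramp from zero reaching a
#' constant plateau, after which the concentration stays flat.
#'
#' @param regions Named list, one entry per tissue region (names are VOI
#'   labels, e.g. `"tumor"`, `"muscle"`), each
#'   `list(ktrans_per_min = , rbv = )` with `ktrans_per_min >= 0` and
#'   `rbv` in `[0, 1]`.
#' @param ramp_end_s AIF ramp duration, s (> 0). Default 20 s.
#' @param plateau_mg_ml AIF plateau concentration, mg I/mL (> 0). Default 6.
#' @param times_s Sampling grid, s, strictly increasing. Default `0:80`
#'   (one frame per second over the standard 0-80 s protocol).
#' @return Object of class `cemct_kinetic_truth`.
#' @export
kinetic_truth <- function(regions, ramp_end_s = 20, plateau_mg_ml = 6,
                          times_s = 0:80) {
  stopifnot(is.list(regions), length(regions) >= 1L,
            !is.null(names(regions)), all(nzchar(names(regions))))
  for (nm in names(regions)) {
    r <- regions[[nm]]
    check_scalar(r$ktrans_per_min, paste0(nm, "$ktrans_per_min"))
    check_scalar(r$rbv, paste0(nm, "$rbv"))
    if (r$ktrans_per_min < 0) abort("region '%s': K^trans must be >= 0", nm)
    if (r$rbv < 0 || r$rbv > 1) abort("region '%s': rbv must be in [0, 1]", nm)
  }
  check_scalar(ramp_end_s, "ramp_end_s"); check_scalar(plateau_mg_ml, "plateau_mg_ml")
  if (ramp_end_s <= 0) abort("`ramp_end_s` must be > 0")
  if (plateau_mg_ml <= 0) abort("`plateau_mg_ml` must be > 0")
  times_s <- as.numeric(times_s)
  if (length(times_s) < 2L || any(diff(times_s) <= 0)) {
    abort("`times_s` must be strictly increasing")
  }
  structure(list(regions = regions, ramp_end_s = ramp_end_s,
                 plateau_mg_ml = plateau_mg_ml, times_s = times_s),
            class = "cemct_kinetic_truth")
}

#' Continuous-infusion arterial input function
#'
#' Piecewise-linear ramp from 0 at `t = 0` to the plateau concentration at
#' `t = ramp_end_s`, constant afterwards.
#'
#' @param times_s Sample times, s.
#' @param ramp_end_s Ramp duration, s.
#' @param plateau_mg_ml Plateau concentration, mg I/mL.
#' @return Numeric vector of concentrations (mg I/mL).
#' @export
aif_ramp <- function(times_s, ramp_end_s = 20, plateau_mg_ml = 6) {
  pmin(pmax(times_s, 0) / ramp_end_s, 1) * plateau_mg_ml
}

#' Patlak forward model
#'
#' Tissue concentration of an irreversible two-compartment system:
#' `C_tissue(t) = (Ktrans/60) * int_0^t C_AIF(tau) dtau + rBV * C_AIF(t)`,
#' with the integral computed by cumulative trapezoid on the sampling grid —
#' the same quadrature the Patlak inversion uses, making the round trip
#' exact on noise-free data.
#'
#' @param ktrans_per_min Volume transfer constant, min^-1 (converted
#'   internally to s^-1).
#' @param rbv Vascular volume fraction, dimensionless.
#' @param times_s Sample times, s, strictly increasing.
#' @param aif_mg_ml AIF concentrations at `times_s`, mg I/mL.
#' @return Tissue concentrations at `times_s`, mg I/mL.
#' @export
patlak_forward <- function(ktrans_per_min, rbv, times_s, aif_mg_ml) {
  check_scalar(ktrans_per_min, "ktrans_per_min"); check_scalar(rbv, "rbv")
  (ktrans_per_min / 60) * cumtrapz(times_s, aif_mg_ml) + rbv * aif_mg_ml
}

#' Planar projection time series
#'
#' Time-ordered 2D projections (one frame per time point) with timestamps,
#' the substrate of the dynamic contrast-enhanced stage. Frames are stored as
#' a 3D array `[x, y, t]`; `baseline` is the pre-contrast projection of the
#' static anatomy.
#'
#' @param frames 3D array `[nx, ny, nt]`.
#' @param times_s Timestamps, s, length `nt`, strictly increasing.
#' @param spacing In-plane pixel spacing, mm, length 2.
#' @param kind Value-kind tag of the frames (projected quantities carry a
#'   `proj_` prefix: `"proj_hu_mm"`, `"proj_enhancement_hu_mm"`,
#'   `"proj_iodine_mg_ml_mm"`).
#' @param baseline Optional pre-contrast frame (matrix `nx x ny`).
#' @return Object of class `cemct_planar_series`.
#' @export
planar_series <- function(frames, times_s, spacing, kind = "proj_hu_mm",
                          baseline = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  times_s <- as.numeric(times_s)
  if (dim(frames)[3] != length(times_s)) abort("frames/timestamps length mismatch")
  if (length(times_s) > 1L && any(diff(times_s) <= 0)) {
    abort("timestamps must be strictly increasing")
  }
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 2L, all(spacing > 0))
  if (!is.null(baseline)) {
    stopifnot(is.matrix(baseline), all(dim(baseline) == dim(frames)[1:2]))
  }
  structure(list(frames = frames, times_s = times_s, spacing = spacing,
                 kind = kind, baseline = baseline),
            class = "cemct_planar_series")
}

#' @export
print.cemct_planar_series <- function(x, ...) {
  cat(sprintf("<cemct_planar_series> %dx%d pixels, %d frames (t = %g..%g s), %s\n",
              dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
              min(x$times_s), max(x$times_s), x$kind))
  invisible(x)
}

# parallel projection of a 3D array along one axis, scaled by the voxel size
# along that axis (a line integral in mm units)
project_volume <- function(a, spacing, axis = 3L) {
  apply(a, setdiff(1:3, axis), sum) * spacing[axis]
}

#' Generate a dynamic contrast-enhanced planar series
#'
#' Forward-simulates the DCE acquisition: each region of `truth` follows the
#' Patlak forward model on the sampling grid; at every time point the 3D
#' iodine-concentration map (regions painted into the phantom geometry) is
#' projected along `axis` as a fixed-angle parallel projection (sum times
#' voxel size, mm), the static anatomy projection is added in HU*mm, and
#' optional Gaussian noise is applied per frame. An organ listed in
#' `overlap_labels` is shifted so that its projection superimposes on the
#' tumor's, emulating the planar-superimposition bias of projection imaging.
#'
#' @param spec A [phantom_spec()]; every region named in `truth` must exist
#'   as an organ label.
#' @param truth A [kinetic_truth()]; its sampling grid must cover 0-80 s for
#'   the standard protocol.
#' @param axis Projection axis (default 3).
#' @param overlap_labels Organ labels to superimpose onto the tumor
#'   projection (default none).
#' @return A `cemct_planar_series` of kind `"proj_hu_mm"` whose `baseline`
#'   holds the pre-contrast anatomy projection.
#' @export
make_dce_series <- function(spec, truth, axis = 3L, overlap_labels = character()) {
  stopifnot(inherits(spec, "cemct_phantom_spec"),
            inherits(truth, "cemct_kinetic_truth"))
  organ_labels <- vapply(spec$organs, function(o) o$voi$label, "")
  missing <- setdiff(names(truth$regions), organ_labels)
  if (length(missing)) {
    abort("truth region(s) not present in the phantom spec: %s",
          paste(missing, collapse = ", "))
  }
  times <- truth$times_s
  aif <- aif_ramp(times, truth$ramp_end_s, truth$plateau_mg_ml)
  curves <- lapply(truth$regions, function(r) {
    patlak_forward(r$ktrans_per_min, r$rbv, times, aif)
  })
  sp <- spec$spacing
  anat <- paint_organs(spec, function(o) o$hu, spec$background_hu)
  base_proj <- project_volume(anat, sp, axis)
  # per-region masks (overlap organs shifted onto the tumor's projection)
  masks <- list()
  for (org in spec$organs) {
    lab <- org$voi$label
    if (!lab %in% names(truth$regions)) next
    voi <- org$voi
    if (lab %in% overlap_labels) {
      tumor_idx <- which(organ_labels == "tumor")
      if (!length(tumor_idx)) abort("overlap requested but no tumor organ present")
      tumor_c <- spec$organs[[tumor_idx[1]]]$voi$center
      ctr <- voi$center
      inplane <- setdiff(1:3, axis)
      ctr[inplane] <- tumor_c[inplane]
      voi <- ellipsoid_voi(ctr, voi$semi_axes, voi$label)
    }
    masks[[lab]] <- voi_mask(voi, spec$shape, sp)
  }
  nt <- length(times)
  d2 <- dim(base_proj)
  frames <- array(0, dim = c(d2[1], d2[2], nt))
  region_proj <- lapply(masks, function(m) {
    project_volume(array(as.numeric(m), dim = spec$shape), sp, axis)
  })
  with_seed(spec$seed, {
    for (k in seq_len(nt)) {
      f <- base_proj
      for (lab in names(masks)) {
        f <- f + spec$hu_per_mgml * curves[[lab]][k] * region_proj[[lab]]
      }
      if (spec$noise_sigma > 0) {
        f <- f + matrix(stats::rnorm(length(f), sd = spec$noise_sigma), d2[1], d2[2])
      }
      frames[, , k] <- f
    }
  })
  planar_series(frames, times, sp[setdiff(1:3, axis)], kind = "proj_hu_mm",
                baseline = base_proj)
}

#' Baseline subtraction and calibration for planar series
#'
#' `series_subtract_baseline()` subtracts the pre-contrast anatomy projection
#' from every frame (temporal subtraction, frame by frame);
#' `series_apply_calibration()` converts the subtracted frames to projected
#' iodine concentration using a calibration curve (slope applied per mm of
#' path, intercept ignored for projections fitted with intercept 0).
#'
#' @param series A `cemct_planar_series`.
#' @return A `cemct_planar_series` with updated frames and kind.
#' @export
series_subtract_baseline <- function(series) {
  stopifnot(inherits(series, "cemct_planar_series"))
  if (is.null(series$baseline)) abort("series carries no baseline frame")
  out <- series
  out$frames <- sweep(series$frames, c(1, 2), series$baseline, "-")
  out$kind <- "proj_enhancement_hu_mm"
  out
}

#' @rdname series_subtract_baseline
#' @param cal A `cemct_calibration`.
#' @export
series_apply_calibration <- function(series, cal) {
  stopifnot(inherits(series, "cemct_planar_series"),
            inherits(cal, "cemct_calibration"))
  if (series$kind != "proj_enhancement_hu_mm") {
    abort("calibrate subtracted series only (kind '%s')", series$kind)
  }
  out <- series
  out$frames <- cal$slope * series$frames
  out$kind <- "proj_iodine_mg_ml_mm"
  out
}

#' Planar-series I/O: NIfTI stack + CSV timestamp sidecar
#'
#' Frames are stored as a 3D NIfTI (third axis = time); timestamps and
#' metadata go to `<path>.times.csv` / `<path>.meta.yaml`; the baseline frame
#' (if any) to `<path>.baseline.nii`.
#'
#' @param series A `cemct_planar_series`.
#' @param path `.nii` output path.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "cemct_planar_series"))
  vol <- new_volume(series$frames, c(series$spacing, 1), frame = "planar",
                    kind = "hu")
  write_nifti(vol, path)
  utils::write.csv(data.frame(frame = seq_along(series$times_s),
                              t_s = series$times_s),
                   paste0(path, ".times.csv"), row.names = FALSE)
  yaml::write_yaml(list(kind = series$kind, spacing = as.list(series$spacing),
                        has_baseline = !is.null(series$baseline)),
                   paste0(path, ".meta.yaml"))
  if (!is.null(series$baseline)) {
    b <- array(series$baseline, dim = c(dim(series$baseline), 1L))
    write_nifti(new_volume(b, c(series$spacing, 1), frame = "planar",
                           kind = "hu"),
                paste0(path, ".baseline.nii"))
  }
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  vol <- read_nifti(path)
  times <- utils::read.csv(paste0(path, ".times.csv"))$t_s
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  baseline <- NULL
  if (isTRUE(meta$has_baseline)) {
    b <- read_nifti(paste0(path, ".baseline.nii"))
    baseline <- b$data[, , 1]
  }
  planar_series(vol$data, times, unlist(meta$spacing), kind = meta$kind,
                baseline = baseline)
}

#' Kinetic-truth YAML serialization
#' @param truth A `cemct_kinetic_truth`.
#' @param path File path.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "cemct_kinetic_truth"))
  yaml::write_yaml(list(regions = truth$regions, ramp_end_s = truth$ramp_end_s,
                        plateau_mg_ml = truth$plateau_mg_ml,
                        times_s = as.list(truth$times_s)), path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  kinetic_truth(x$regions, ramp_end_s = x$ramp_end_s,
                plateau_mg_ml = x$plateau_mg_ml, times_s = unlist(x$times_s))
}
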