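#' Digital phantom specification
#'
#' Describes a synthetic small-animal phantom as a set of ellipsoidal organs
#' painted into a uniform background: each organ has a baseline attenuation
#' (HU) and an iodine concentration (mg I/mL) for the contrast-bearing member
#' of an image pair. Iodine converts to enhancement through a single linear
#' gain `hu_per_mgml` (default 50 HU per mg I/mL, i.e. a calibration slope of
#' 0.02 (mg I/mL)/HU), the same line the pipeline's calibration stage is meant
#' to recover. Gaussian noise (HU, per-voxel, independent) and an optional
#' affine misalignment of the first member of each pair emulate acquisition
#' imperfections.
#'
#' @param shape Volume shape in voxels, length 3.
#' @param spacing Voxel spacing, mm, length 3.
#' @param organs List of organs, each `list(voi = ellipsoid_voi(...), hu = ,
#'   ci = )` with `hu` the baseline attenuation (HU) and `ci` the iodine
#'   concentration (mg I/mL, >= 0).
#' @param background_hu Background attenuation (HU).
#' @param hu_per_mgml Iodine-to-enhancement gain (HU per mg I/mL), > 0.
#' @param noise_sigma Gaussian noise SD in HU, >= 0.
#' @param misalign Optional `cemct_affine` pose change of the baseline/LE
#'   member of a pair: the anatomy is repainted analytically at the mapped
#'   coordinates (no interpolation) before noise, and the misaligned member
#'   gets a distinct frame id so registration is exercised downstream.
#' @param seed RNG seed; a fixed seed makes every generator bit-reproducible.
#' @return Object of class `cemct_phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing, organs, background_hu = 0,
                         hu_per_mgml = 50, noise_sigma = 0, misalign = NULL,
                         seed = 1L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape >= 2L), length(spacing) == 3L,
            all(spacing > 0))
  check_scalar(noise_sigma, "noise_sigma")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0")
  check_scalar(hu_per_mgml, "hu_per_mgml")
  if (hu_per_mgml <= 0) abort("`hu_per_mgml` must be > 0")
  if (!is.null(misalign)) stopifnot(inherits(misalign, "cemct_affine"))
  extent <- (shape - 1) * spacing
  for (org in organs) {
    stopifnot(inherits(org$voi, "cemct_voi"), is.numeric(org$hu))
    if (is.null(org$ci)) org$ci <- 0
    if (any(org$ci < 0)) abort("organ '%s': iodine concentration < 0", org$voi$label)
    lo <- org$voi$center - org$voi$semi_axes
    hi <- org$voi$center + org$voi$semi_axes
    if (any(lo < -1e-9) || any(hi > extent + 1e-9)) {
      abort("organ '%s' extends outside the volume bounds", org$voi$label)
    }
  }
  structure(list(shape = shape, spacing = spacing, organs = organs,
                 background_hu = background_hu, hu_per_mgml = hu_per_mgml,
                 noise_sigma = noise_sigma, misalign = misalign,
                 seed = as.integer(seed)),
            class = "cemct_phantom_spec")
}

organ_ci <- function(org) if (is.null(org$ci)) 0 else org$ci

# paint organs into a background; `value_fun(org)` gives the painted value,
# painting overwrites (later organs on top) unless add = TRUE. `tf` paints
# the anatomy as seen through an affine pose change, analytically (no
# interpolation), which is how the misaligned member of an image pair is
# produced.
paint_organs <- function(spec, value_fun, background = 0, add = FALSE,
                         tf = NULL) {
  a <- array(background, dim = spec$shape)
  for (org in spec$organs) {
    m <- voi_mask(org$voi, spec$shape, spec$spacing, tf = tf)
    v <- value_fun(org)
    if (add) a[m] <- a[m] + v else a[m] <- v
  }
  a
}

add_noise <- function(a, sigma) {
  if (sigma <= 0) return(a)
  a + array(stats::rnorm(length(a), sd = sigma), dim = dim(a))
}

#' Generate a single-energy baseline / contrast-enhanced volume pair
#'
#' The baseline image is the organ map at baseline attenuation; the CE image
#' adds `ci * hu_per_mgml` HU inside every iodinated organ (enhancement linear
#' in concentration). Noise is drawn independently per volume; if the spec
#' carries a misalignment, it is applied to the baseline member, which then
#' receives a distinct frame id so the pipeline's registration step is
#' exercised.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `baseline` and `ce` (`cemct_volume`s, kind
#'   `"hu"`, protocol `"SE"`).
#' @export
make_se_pair <- function(spec) {
  stopifnot(inherits(spec, "cemct_phantom_spec"))
  base <- paint_organs(spec, function(o) o$hu, spec$background_hu)
  enh <- paint_organs(spec, function(o) organ_ci(o) * spec$hu_per_mgml)
  with_seed(spec$seed, {
    if (is.null(spec$misalign)) {
      baseline <- new_volume(base, spec$spacing, frame = "animal",
                             kind = "hu", protocol = "SE")
    } else {
      moved <- paint_organs(spec, function(o) o$hu, spec$background_hu,
                            tf = spec$misalign)
      baseline <- new_volume(moved, spec$spacing, frame = "animal-moving",
                             kind = "hu", protocol = "SE")
    }
    baseline$data <- add_noise(baseline$data, spec$noise_sigma)
    ce <- new_volume(add_noise(base + enh, spec$noise_sigma), spec$spacing,
                     frame = "animal", kind = "hu", protocol = "SE")
    list(baseline = baseline, ce = ce)
  })
}

#' Generate a dual-energy low-/high-energy volume pair
#'
#' Constructed so that weighted subtraction with the default factor
#' `alpha = 0.55` cancels unenhanced tissue exactly (before noise): the LE
#' image carries the organ attenuations, the HE image is `alpha * LE` plus an
#' HE-only iodine term `ci * hu_per_mgml`. This phenomenological model (no
#' tabulated attenuation coefficients) is all the downstream weighted
#' subtraction needs: a signal that survives `HE - alpha*LE` only where
#' iodine is.
#'
#' @param spec A [phantom_spec()].
#' @param alpha Tissue-cancellation weighting factor (default 0.55).
#' @return List with elements `le` and `he` (`cemct_volume`s, kind `"hu"`,
#'   protocol `"DE"`).
#' @export
make_de_pair <- function(spec, alpha = 0.55) {
  stopifnot(inherits(spec, "cemct_phantom_spec"))
  le_a <- paint_organs(spec, function(o) o$hu, spec$background_hu)
  iod <- paint_organs(spec, function(o) organ_ci(o) * spec$hu_per_mgml)
  he_a <- alpha * le_a + iod
  with_seed(spec$seed, {
    if (is.null(spec$misalign)) {
      le <- new_volume(le_a, spec$spacing, frame = "animal", kind = "hu",
                       protocol = "DE")
    } else {
      moved <- paint_organs(spec, function(o) o$hu, spec$background_hu,
                            tf = spec$misalign)
      le <- new_volume(moved, spec$spacing, frame = "animal-moving",
                       kind = "hu", protocol = "DE")
    }
    le$data <- add_noise(le$data, spec$noise_sigma)
    he <- new_volume(add_noise(he_a, spec$noise_sigma), spec$spacing,
                     frame = "animal", kind = "hu", protocol = "DE")
    list(le = le, he = he)
  })
}

#' Generate an iodinated calibration phantom
#'
#' One ellipsoidal insert per known concentration, laid out along the x axis
#' of a dedicated volume, with enhancement `slope_hu_per_mgml * C_I +
#' intercept_hu` (so the pipeline's [fit_calibration()] should recover
#' `1/slope_hu_per_mgml` as its (mg I/mL)/HU slope for `intercept_hu = 0`).
#'
#' @param concentrations Known iodine concentrations, mg I/mL, >= 0, at least
#'   3 distinct (a shorter list makes the downstream fit degenerate).
#' @param slope_hu_per_mgml Enhancement per concentration, HU/(mg I/mL).
#' @param intercept_hu Enhancement offset, HU.
#' @param noise_sigma Gaussian noise SD, HU.
#' @param insert_radius_mm Insert semi-axis, mm.
#' @param spacing Voxel spacing, mm.
#' @param seed RNG seed.
#' @return List with `volume` (a `cemct_volume`, kind `"enhancement_hu"`,
#'   protocol `"SE"`) and `vois` (list of `cemct_voi`, one per concentration,
#'   in input order).
#' @export
make_calibration_phantom <- function(concentrations, slope_hu_per_mgml = 50,
                                     intercept_hu = 0, noise_sigma = 0,
                                     insert_radius_mm = 2, spacing = c(0.5, 0.5, 0.5),
                                     seed = 1L) {
  conc <- as.numeric(concentrations)
  if (any(conc < 0)) abort("concentrations must be >= 0")
  if (length(unique(conc)) < 3L) {
    abort("need at least 3 distinct concentrations, got %d", length(unique(conc)))
  }
  r <- insert_radius_mm
  pitch <- 3 * r
  n <- length(conc)
  extent_x <- pitch * (n + 1)
  shape <- c(ceiling(extent_x / spacing[1]) + 1L,
             ceiling(6 * r / spacing[2]) + 1L,
             ceiling(6 * r / spacing[3]) + 1L)
  cy <- (shape[2] - 1) * spacing[2] / 2
  cz <- (shape[3] - 1) * spacing[3] / 2
  vois <- lapply(seq_len(n), function(i) {
    ellipsoid_voi(c(pitch * i, cy, cz), rep(r, 3), "custom")
  })
  a <- array(0, dim = shape)
  for (i in seq_len(n)) {
    m <- voi_mask(vois[[i]], shape, spacing)
    a[m] <- slope_hu_per_mgml * conc[i] + intercept_hu
  }
  a <- with_seed(seed, add_noise(a, noise_sigma))
  list(volume = new_volume(a, spacing, frame = "phantom",
                           kind = "enhancement_hu", protocol = "SE"),
       vois = vois)
}

#' Phantom spec YAML serialization
#' @param spec A `cemct_phantom_spec`.
#' @param path File path.
#' @export
write_phantom_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "cemct_phantom_spec"))
  x <- list(shape = as.list(spec$shape), spacing = as.list(spec$spacing),
            background_hu = spec$background_hu, hu_per_mgml = spec$hu_per_mgml,
            noise_sigma = spec$noise_sigma, seed = spec$seed,
            organs = lapply(spec$organs, function(o) {
              list(label = o$voi$label, center = as.list(o$voi$center),
                   semi_axes = as.list(o$voi$semi_axes), hu = o$hu,
                   ci = organ_ci(o))
            }))
  if (!is.null(spec$misalign)) {
    x$misalign <- list(A = as.list(as.vector(spec$misalign$A)),
                       t = as.list(spec$misalign$t))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  organs <- lapply(x$organs, function(o) {
    list(voi = ellipsoid_voi(unlist(o$center), unlist(o$semi_axes), o$label),
         hu = o$hu, ci = o$ci)
  })
  misalign <- if (!is.null(x$misalign)) {
    new_affine(matrix(unlist(x$misalign$A), 3, 3), unlist(x$misalign$t))
  }
  phantom_spec(unlist(x$shape), unlist(x$spacing), organs,
               background_hu = x$background_hu, hu_per_mgml = x$hu_per_mgml,
               noise_sigma = x$noise_sigma, misalign = misalign,
               seed = x$seed)
}
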