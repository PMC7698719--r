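# Shared fixtures: all synthetic, built in code at test time.

# Small rat-like phantom for the static (SE/DE) pipeline. Iodine
# concentrations follow the single-energy tumor/muscle/aorta working point
# (aorta 6.2, tumor 1.55, muscle 0.72 mg I/mL), so pipeline rBV truth is
# 100 * 1.55 / 6.2 = 25% for tumor.
rat_spec <- function(noise_sigma = 0, misalign = NULL, seed = 1L,
                     shape = c(48L, 48L, 48L), spacing = c(0.5, 0.5, 0.5)) {
  phantom_spec(
    shape, spacing,
    organs = list(
      list(voi = ellipsoid_voi(c(6, 6, 12), c(1.5, 1.5, 4), "aorta"),
           hu = 50, ci = 6.2),
      list(voi = ellipsoid_voi(c(6, 17, 12), c(2.5, 2, 4), "muscle"),
           hu = 45, ci = 0.72),
      list(voi = ellipsoid_voi(c(16, 12, 12), c(5, 4, 3), "tumor"),
           hu = 35, ci = 1.55),
      list(voi = ellipsoid_voi(c(16, 4, 6), c(2, 1.5, 1.5), "liver"),
           hu = 55, ci = 2)),
    background_hu = 20, hu_per_mgml = 50, noise_sigma = noise_sigma,
    misalign = misalign, seed = seed)
}

# Phantom for the dynamic planar stage: lv / muscle / tumor separated in the
# x-y plane so their z projections do not overlap; the liver sits above the
# tumor in z to act as the optional superimposing organ.
dce_spec <- function(noise_sigma = 0, seed = 1L) {
  phantom_spec(
    c(44L, 44L, 24L), c(0.5, 0.5, 0.5),
    organs = list(
      list(voi = ellipsoid_voi(c(5, 5, 6), c(3, 3, 3), "lv"), hu = 50, ci = 0),
      list(voi = ellipsoid_voi(c(16, 5, 6), c(3, 2.5, 2.5), "muscle"),
           hu = 45, ci = 0),
      list(voi = ellipsoid_voi(c(9, 16, 5), c(4, 3.5, 3), "tumor"),
           hu = 35, ci = 0),
      list(voi = ellipsoid_voi(c(18, 16, 9), c(2, 2, 1.5), "liver"),
           hu = 55, ci = 0)),
    background_hu = 20, hu_per_mgml = 50, noise_sigma = noise_sigma,
    seed = seed)
}

# Default dynamic ground truth: DCE working point (tumor Ktrans 0.24 min^-1,
# rBV 11.6%; muscle 0.13 min^-1, 12.2%), continuous-infusion AIF ramping to
# 6 mg I/mL over 20 s, 1 s sampling over 0-80 s.
dce_truth <- function(tumor = list(ktrans_per_min = 0.24, rbv = 0.116),
                      muscle = list(ktrans_per_min = 0.13, rbv = 0.122)) {
  kinetic_truth(list(tumor = tumor, muscle = muscle, lv = list(
    ktrans_per_min = 0, rbv = 1)))
}

# closed-form integral of the ramp AIF (piecewise-linear, so the trapezoid
# rule is exact on it): independent oracle for the forward model
ramp_integral <- function(t, ramp_end = 20, plateau = 6) {
  ifelse(t <= ramp_end,
         plateau * t^2 / (2 * ramp_end),
         plateau * (ramp_end / 2 + (t - ramp_end)))
}
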