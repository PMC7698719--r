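#' Affine transform in world (mm) coordinates
#'
#' Maps a point `x` in the output (fixed) frame to `A %*% x + t` in the input
#' (moving) frame; resampling evaluates the moving volume at the mapped
#' locations by trilinear interpolation.
#'
#' @param A 3x3 linear part (must be invertible).
#' @param t Translation, length 3, mm.
#' @return An object of class `cemct_affine`.
#' @export
new_affine <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3L)
  if (abs(det(A)) < 1e-12) abort("affine linear part is singular")
  structure(list(A = A, t = t), class = "cemct_affine")
}

#' @export
print.cemct_affine <- function(x, ...) {
  cat("<cemct_affine>\n")
  m <- cbind(x$A, x$t)
  dimnames(m) <- list(NULL, c("", "", "", "t (mm)"))
  print(round(m, 5))
  invisible(x)
}

#' @rdname new_affine
#' @param theta_deg Rotation angle about `axis`, degrees.
#' @param axis Rotation axis (1, 2 or 3).
#' @export
affine_rotation <- function(theta_deg, axis = 3L, t = c(0, 0, 0)) {
  th <- theta_deg * pi / 180
  R <- diag(3)
  ax <- setdiff(1:3, axis)
  R[ax[1], ax[1]] <- cos(th); R[ax[2], ax[2]] <- cos(th)
  R[ax[1], ax[2]] <- -sin(th); R[ax[2], ax[1]] <- sin(th)
  new_affine(R, t)
}

#' Invert an affine transform
#' @param tf A `cemct_affine`.
#' @export
affine_invert <- function(tf) {
  Ai <- solve(tf$A)
  new_affine(Ai, -Ai %*% tf$t)
}

# Trilinear interpolation of a 3D array at fractional (1-based) voxel indices.
# Out-of-support locations return NA.
trilinear <- function(arr, xi, yi, zi) {
  d <- dim(arr)
  ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
  out <- rep(NA_real_, length(xi))
  if (!any(ok)) return(out)
  xi <- xi[ok]; yi <- yi[ok]; zi <- zi[ok]
  x0 <- pmin(floor(xi), d[1] - 1L); y0 <- pmin(floor(yi), d[2] - 1L)
  z0 <- pmin(floor(zi), d[3] - 1L)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- x0 + (y0 - 1) * nx + (z0 - 1) * nxy
  v000 <- arr[base];            v100 <- arr[base + 1]
  v010 <- arr[base + nx];       v110 <- arr[base + nx + 1]
  v001 <- arr[base + nxy];      v101 <- arr[base + nxy + 1]
  v011 <- arr[base + nx + nxy]; v111 <- arr[base + nx + nxy + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Resample a volume through an affine transform
#'
#' Evaluates `vol` at `A %*% x + t` for every voxel-center world coordinate
#' `x` of the output grid (same geometry as `vol`), with trilinear
#' interpolation. Voxels mapped outside the input support are filled with
#' `fill`.
#'
#' @param vol A `cemct_volume`.
#' @param tf A `cemct_affine` (fixed-frame to moving-frame mapping).
#' @param fill Value for out-of-support voxels (default 0).
#' @param frame Frame id of the output (defaults to the input frame).
#' @return A `cemct_volume` with an attribute `"valid"`: logical array marking
#'   voxels interpolated from data (not fill).
#' @export
affine_resample <- function(vol, tf, fill = 0, frame = vol$frame) {
  stopifnot(is_volume(vol), inherits(tf, "cemct_affine"))
  d <- dim(vol$data)
  sp <- vol$spacing
  xs <- axis_coords(d[1], sp[1]); ys <- axis_coords(d[2], sp[2])
  zs <- axis_coords(d[3], sp[3])
  # world coordinates of every output voxel center, recycled in array order
  wx <- rep(xs, times = d[2] * d[3])
  wy <- rep(rep(ys, each = d[1]), times = d[3])
  wz <- rep(zs, each = d[1] * d[2])
  mx <- tf$A[1, 1] * wx + tf$A[1, 2] * wy + tf$A[1, 3] * wz + tf$t[1]
  my <- tf$A[2, 1] * wx + tf$A[2, 2] * wy + tf$A[2, 3] * wz + tf$t[2]
  mz <- tf$A[3, 1] * wx + tf$A[3, 2] * wy + tf$A[3, 3] * wz + tf$t[3]
  vals <- trilinear(vol$data, mx / sp[1] + 1, my / sp[2] + 1, mz / sp[3] + 1)
  valid <- !is.na(vals)
  vals[!valid] <- fill
  out <- vol
  out$data <- array(vals, dim = d)
  out$frame <- frame
  attr(out$data, "valid") <- NULL
  attr(out, "valid") <- array(valid, dim = d)
  out
}

# Separable [1,2,1]/4 smoothing, `passes` times per axis. Used to regularize
# the similarity metric before registration (sharp-edged images make the NCC
# landscape ragged under linear interpolation).
smooth_volume3 <- function(vol, passes = 2L) {
  a <- vol$data
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      n <- dim(a)[ax]
      lo <- pmax(seq_len(n) - 1L, 1L)
      hi <- pmin(seq_len(n) + 1L, n)
      a <- switch(ax,
                  (a[lo, , , drop = FALSE] + 2 * a + a[hi, , , drop = FALSE]) / 4,
                  (a[, lo, , drop = FALSE] + 2 * a + a[, hi, , drop = FALSE]) / 4,
                  (a[, , lo, drop = FALSE] + 2 * a + a[, , hi, drop = FALSE]) / 4)
    }
  }
  out <- vol
  out$data <- a
  out
}

# Block-average downsampling by integer factor f (crops to a multiple of f).
downsample_volume <- function(vol, f) {
  if (f == 1L) return(vol)
  d <- dim(vol$data)
  nd <- d %/% f
  if (any(nd < 2L)) return(vol)
  a <- vol$data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f), drop = FALSE]
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(f^3, prod(nd))
  m <- array(colMeans(a), dim = nd)
  out <- vol
  out$data <- m
  out$spacing <- vol$spacing * f
  out
}

# 1 - normalized cross-correlation between fixed and transformed moving,
# over voxels with valid interpolation. Large penalty when overlap collapses.
ncc_cost <- function(params, moving, fixed, mode) {
  tf <- params_to_affine(params, mode)
  res <- affine_resample(moving, tf)
  v <- attr(res, "valid")
  n <- sum(v)
  if (n < 32L) return(2)
  f <- fixed$data[v]; m <- res$data[v]
  sf <- stats::sd(f); sm <- stats::sd(m)
  if (sf < 1e-12 || sm < 1e-12) return(2)
  1 - stats::cor(f, m)
}

params_to_affine <- function(params, mode) {
  if (mode == "translation") {
    new_affine(diag(3), params)
  } else {
    new_affine(diag(3) + matrix(params[1:9], 3, 3), params[10:12])
  }
}

affine_to_params <- function(tf, mode) {
  if (mode == "translation") tf$t else c(as.vector(tf$A - diag(3)), tf$t)
}

#' Intensity-based affine registration
#'
#' Registers `moving` to `fixed` by maximizing normalized cross-correlation
#' over a multi-resolution pyramid (block-averaged volumes), using
#' derivative-free Nelder-Mead optimization. A translation-only stage seeds
#' the full 12-parameter affine stage. The returned transform maps fixed-frame
#' world coordinates to moving-frame coordinates, i.e. resampling `moving`
#' through it aligns it onto `fixed`.
#'
#' When the two volumes already share a frame id, the identity transform is
#' returned without optimization unless `force = TRUE`.
#'
#' @param moving,fixed `cemct_volume`s with identical spacing.
#' @param mode `"affine"` (default) or `"translation"`.
#' @param levels Integer downsampling factors, coarse to fine.
#' @param force Optimize even if the frame ids already match.
#' @param maxit Nelder-Mead iteration cap per stage.
#' @param smooth_passes Pre-smoothing passes applied to both inputs before
#'   the metric is evaluated (0 disables).
#' @param restarts Nelder-Mead restarts per pyramid level (restarting from
#'   the previous optimum rebuilds the simplex and escapes premature
#'   convergence).
#' @return A list with `transform` (`cemct_affine`), `resampled`
#'   (`cemct_volume` in the fixed frame), and `metric` (final NCC).
#' @export
register_affine <- function(moving, fixed, mode = c("affine", "translation"),
                            levels = c(4L, 2L, 1L), force = FALSE,
                            maxit = 2000L, smooth_passes = 2L, restarts = 2L) {
  mode <- match.arg(mode)
  check_compatible(moving, fixed, require_frame = FALSE)
  if (!force && identical(moving$frame, fixed$frame)) {
    res <- moving
    res$frame <- fixed$frame
    return(list(transform = new_affine(), resampled = res,
                metric = 1 - ncc_cost(c(0, 0, 0), moving, fixed, "translation")))
  }
  mv_s <- if (smooth_passes > 0) smooth_volume3(moving, smooth_passes) else moving
  fx_s <- if (smooth_passes > 0) smooth_volume3(fixed, smooth_passes) else fixed
  p_tr <- c(0, 0, 0)
  p_af <- rep(0, 12)
  for (f in sort(unique(as.integer(levels)), decreasing = TRUE)) {
    mv <- downsample_volume(mv_s, f)
    fx <- downsample_volume(fx_s, f)
    sp <- max(mv$spacing)
    # full resolution is a refinement stage: metric evaluations there are
    # ~f^3 more expensive, so its iteration budget is capped
    mi <- if (f == 1L) min(maxit, 300L) else maxit
    for (r in seq_len(max(1L, restarts))) {
      o <- stats::optim(p_tr, ncc_cost, moving = mv, fixed = fx,
                        mode = "translation", method = "Nelder-Mead",
                        control = list(maxit = mi, reltol = 1e-12,
                                       parscale = rep(sp / 2, 3)))
      p_tr <- o$par
    }
    if (mode == "affine") {
      if (all(p_af == 0)) p_af[10:12] <- p_tr
      for (r in seq_len(max(1L, restarts))) {
        o <- stats::optim(p_af, ncc_cost, moving = mv, fixed = fx,
                          mode = "affine", method = "Nelder-Mead",
                          control = list(maxit = 2L * mi, reltol = 1e-12,
                                         parscale = c(rep(0.02, 9), rep(sp / 2, 3))))
        p_af <- o$par
      }
      p_tr <- p_af[10:12]
    }
  }
  final_p <- if (mode == "affine") p_af else p_tr
  cost <- ncc_cost(final_p, mv_s, fx_s, mode)
  if (!is.finite(cost) || cost >= 2) {
    abort("registration failed to find overlapping support (final metric %.3f)", 1 - cost)
  }
  tf <- params_to_affine(final_p, mode)
  res <- affine_resample(moving, tf, frame = fixed$frame)
  list(transform = tf, resampled = res, metric = 1 - cost)
}
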