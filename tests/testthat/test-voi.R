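test_that("derive_core halves dimensions, preserves center, composes", {
  tumor <- ellipsoid_voi(c(10, 11, 12), c(8, 6, 4), "tumor")
  core <- derive_core(tumor)
  expect_identical(core$label, "core")
  expect_equal(core$center, tumor$center)
  expect_equal(core$semi_axes, c(4, 3, 2))
  expect_equal(voi_volume_mm3(core) / voi_volume_mm3(tumor), 1 / 8)
  # composition quarters the dimensions; labels guard misuse, not geometry
  expect_equal(derive_core(core)$semi_axes, tumor$semi_axes / 4)
  expect_error(derive_core(ellipsoid_voi(c(0, 0, 0), c(1, 1, 1), "muscle")),
               "tumor")
})

test_that("derive_periphery builds 4 disjoint VOIs inside tumor, outside core", {
  tumor <- ellipsoid_voi(c(12, 12, 12), c(8, 6, 4), "tumor")
  core <- derive_core(tumor)
  per <- derive_periphery(tumor, core)
  expect_length(per, 4)
  expect_identical(vapply(per, `[[`, "", "label"), paste0("periphery_", 1:4))
  # geometric checks in tumor-normalized coordinates: map each periphery
  # ellipsoid to u-space where tumor = unit ball
  for (i in seq_along(per)) {
    u_c <- (per[[i]]$center - tumor$center) / tumor$semi_axes
    u_r <- per[[i]]$semi_axes / tumor$semi_axes   # = 0.2 each axis
    expect_lte(sqrt(sum(u_c^2)) + max(u_r), 1)            # inside tumor
    expect_gte(sqrt(sum(u_c^2)) - max(u_r),
               max(core$semi_axes / tumor$semi_axes))     # outside core
    for (j in seq_len(i - 1)) {
      u_cj <- (per[[j]]$center - tumor$center) / tumor$semi_axes
      expect_gt(sqrt(sum((u_c - u_cj)^2)), 2 * max(u_r))  # pairwise disjoint
    }
  }
  # infeasible placements are rejected with the failing constraint
  expect_error(derive_periphery(tumor, core, offset_frac = 0.9, scale_frac = 0.2),
               "leave the tumor")
  expect_error(derive_periphery(tumor, core, offset_frac = 0.6, scale_frac = 0.2),
               "core")
  off_center <- ellipsoid_voi(tumor$center + 1, core$semi_axes, "core")
  expect_error(derive_periphery(tumor, off_center), "concentric")
})

test_that("sample_voi matches a brute-force voxel loop and handles truncation", {
  vol <- new_volume(array(rnorm(16^3, 100, 20), dim = c(16, 16, 16)),
                    c(0.5, 0.5, 0.5))
  voi <- ellipsoid_voi(c(3.2, 4.1, 3.7), c(1.4, 1.1, 0.9), "custom")
  st <- sample_voi(vol, voi)
  # exhaustive triple loop over voxel centers
  vals <- c()
  for (i in 1:16) for (j in 1:16) for (k in 1:16) {
    x <- (c(i, j, k) - 1) * 0.5
    if (sum(((x - voi$center) / voi$semi_axes)^2) <= 1) {
      vals <- c(vals, vol$data[i, j, k])
    }
  }
  expect_identical(st$n_voxels, length(vals))
  expect_equal(st$mean, mean(vals), tolerance = 1e-12)
  expect_equal(st$sd, sd(vals), tolerance = 1e-12)

  # constant volume: mean v, SD 0
  cvol <- new_volume(array(7, dim = c(8, 8, 8)), c(1, 1, 1))
  cst <- sample_voi(cvol, ellipsoid_voi(c(3, 3, 3), c(2, 2, 2), "custom"))
  expect_equal(cst$mean, 7)
  expect_equal(cst$sd, 0)

  # VOI reaching past the volume edge: only in-bounds voxels counted
  edge <- ellipsoid_voi(c(0, 3, 3), c(2, 2, 2), "custom")
  est <- sample_voi(cvol, edge)
  full <- sample_voi(cvol, ellipsoid_voi(c(3, 3, 3), c(2, 2, 2), "custom"))
  expect_lt(est$n_voxels, full$n_voxels)
  # and entirely-outside VOIs error
  expect_error(sample_voi(cvol, ellipsoid_voi(c(30, 30, 30), c(1, 1, 1), "custom")),
               "intersect")
})

test_that("sampling is invariant to padding with out-of-VOI voxels", {
  a <- array(rnorm(8^3), dim = c(8, 8, 8))
  voi <- ellipsoid_voi(c(2, 2, 2), c(1.4, 1.4, 1.4), "custom")
  st1 <- sample_voi(new_volume(a, c(0.5, 0.5, 0.5)), voi)
  padded <- array(999, dim = c(12, 12, 12)); padded[1:8, 1:8, 1:8] <- a
  st2 <- sample_voi(new_volume(padded, c(0.5, 0.5, 0.5)), voi)
  expect_equal(st1$mean, st2$mean)
  expect_equal(st1$n_voxels, st2$n_voxels)
})

test_that("periphery pooling vs mean-of-means; outward gradient ranks regions", {
  # radially increasing iodine map around the tumor center
  d <- c(32, 32, 32); sp <- c(0.5, 0.5, 0.5)
  ctr <- c(8, 8, 8)
  g <- array(0, dim = d)
  for (k in 1:d[3]) {
    z2 <- (((k - 1) * sp[3]) - ctr[3])^2
    xy <- outer((((1:d[1]) - 1) * sp[1] - ctr[1])^2,
                (((1:d[2]) - 1) * sp[2] - ctr[2])^2, "+")
    g[, , k] <- sqrt(xy + z2)
  }
  vol <- new_volume(g, sp, kind = "iodine_mg_ml")
  tumor <- ellipsoid_voi(ctr, c(6, 5, 4), "tumor")
  core <- derive_core(tumor)
  per <- derive_periphery(tumor, core)
  core_m <- sample_voi(vol, core)$mean
  pool <- sample_voi(vol, per)
  mom <- sample_voi(vol, per, aggregate = "mean_of_means")
  expect_gt(pool$mean, core_m)   # C_I increases outward
  expect_identical(pool$label, "periphery")
  # pooled vs mean-of-means agree closely for equal-size VOIs
  expect_equal(pool$mean, mom$mean, tolerance = 0.02)
})

test_that("rbv_from_ci implements 100*C_I/C_I,aorta with guards", {
  t_st <- cemct:::new_region_stats("tumor", 100, 1.55, 0.1, kind = "iodine_mg_ml")
  a_st <- cemct:::new_region_stats("aorta", 50, 6.2, 0.2, kind = "iodine_mg_ml")
  rbv <- rbv_from_ci(t_st, a_st)
  expect_equal(rbv$mean, 25)
  expect_identical(rbv$kind, "rbv_percent")
  expect_equal(rbv_from_ci(a_st, a_st)$mean, 100)  # self-ratio
  z_st <- cemct:::new_region_stats("tumor", 100, 0, 0, kind = "iodine_mg_ml")
  expect_equal(rbv_from_ci(z_st, a_st)$mean, 0)
  bad <- cemct:::new_region_stats("aorta", 50, 0, 0.2, kind = "iodine_mg_ml")
  expect_error(rbv_from_ci(t_st, bad), "aorta mean")
  hu_st <- cemct:::new_region_stats("tumor", 100, 50, 5, kind = "hu")
  expect_error(rbv_from_ci(hu_st, a_st), "iodine_mg_ml")
})

test_that("rBV is invariant to global scaling of the C_I image", {
  spec <- rat_spec()
  pair <- make_se_pair(spec)
  e <- subtract(pair$ce, pair$baseline)
  cal <- new_calibration(1 / spec$hu_per_mgml, 0, protocol = "SE")
  ci <- apply_calibration(e, cal)
  vois <- lapply(spec$organs, `[[`, "voi")
  tumor <- vois[[3]]; aorta <- vois[[1]]
  r1 <- rbv_from_ci(sample_voi(ci, tumor), sample_voi(ci, aorta))
  for (k in c(0.5, 3)) {
    ci_k <- ci; ci_k$data <- k * ci$data
    rk <- rbv_from_ci(sample_voi(ci_k, tumor), sample_voi(ci_k, aorta))
    expect_equal(rk$mean, r1$mean, tolerance = 1e-12)
  }
})

test_that("VOI YAML round trip preserves geometry and labels", {
  vois <- list(ellipsoid_voi(c(1, 2, 3), c(4, 5, 6), "tumor"),
               ellipsoid_voi(c(0.5, 0.5, 0.5), c(1, 1, 1), "aorta"))
  path <- file.path(withr::local_tempdir(), "vois.yaml")
  write_vois_yaml(vois, path)
  back <- read_vois_yaml(path)
  expect_equal(back[[1]]$semi_axes, c(4, 5, 6))
  expect_identical(back[[2]]$label, "aorta")
})
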