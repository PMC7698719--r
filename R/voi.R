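VOI_LABELS <- c("aorta", "ivc", "kidney", "liver", "spleen", "muscle",
                "tumor", "core", paste0("periphery_", 1:4), "lv", "custom")

#' Axis-aligned ellipsoid volume of interest
#'
#' All quantification in the static pipeline happens over ellipsoidal VOIs
#' (vascular structures, paraspinal muscle, and the tumor regions: complete
#' tumor, central core and four peripheral sub-VOIs). A voxel belongs to the
#' VOI iff its center satisfies `sum(((x - center) / semi_axes)^2) <= 1` in
#' world (mm) coordinates.
#'
#' @param center Length-3 center, mm.
#' @param semi_axes Length-3 semi-axes, mm, all > 0.
#' @param label One of the anatomical labels (`"aorta"`, `"ivc"`, `"kidney"`,
#'   `"liver"`, `"spleen"`, `"muscle"`, `"tumor"`, `"core"`,
#'   `"periphery_1"`..`"periphery_4"`, `"lv"`, `"custom"`).
#' @return Object of class `cemct_voi`.
#' @export
ellipsoid_voi <- function(center, semi_axes, label = "custom") {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0)) {
    abort("semi-axes must be positive")
  }
  label <- match.arg(label, VOI_LABELS)
  structure(list(center = center, semi_axes = semi_axes, label = label),
            class = "cemct_voi")
}

#' @export
print.cemct_voi <- function(x, ...) {
  cat(sprintf("<cemct_voi> %s  center (%s) mm  semi-axes (%s) mm\n", x$label,
              paste(format(x$center), collapse = ", "),
              paste(format(x$semi_axes), collapse = ", ")))
  invisible(x)
}

#' Ellipsoid volume in mm^3
#' @param voi A `cemct_voi`.
#' @export
voi_volume_mm3 <- function(voi) 4 / 3 * pi * prod(voi$semi_axes)

# logical mask of voxel centers inside the VOI, for a grid of dims d and
# spacing sp (world coord of voxel i = (i-1)*sp). With `tf` the membership is
# evaluated at the affinely mapped coordinates (analytic painting of a moved
# pose, no interpolation).
voi_mask <- function(voi, d, sp, tf = NULL) {
  if (is.null(tf)) {
    ux <- ((axis_coords(d[1], sp[1]) - voi$center[1]) / voi$semi_axes[1])^2
    uy <- ((axis_coords(d[2], sp[2]) - voi$center[2]) / voi$semi_axes[2])^2
    uz <- ((axis_coords(d[3], sp[3]) - voi$center[3]) / voi$semi_axes[3])^2
    return(outer(outer(ux, uy, "+"), uz, "+") <= 1)
  }
  xs <- axis_coords(d[1], sp[1]); ys <- axis_coords(d[2], sp[2])
  zs <- axis_coords(d[3], sp[3])
  wx <- rep(xs, times = d[2] * d[3])
  wy <- rep(rep(ys, each = d[1]), times = d[3])
  wz <- rep(zs, each = d[1] * d[2])
  mx <- tf$A[1, 1] * wx + tf$A[1, 2] * wy + tf$A[1, 3] * wz + tf$t[1]
  my <- tf$A[2, 1] * wx + tf$A[2, 2] * wy + tf$A[2, 3] * wz + tf$t[2]
  mz <- tf$A[3, 1] * wx + tf$A[3, 2] * wy + tf$A[3, 3] * wz + tf$t[3]
  q <- ((mx - voi$center[1]) / voi$semi_axes[1])^2 +
    ((my - voi$center[2]) / voi$semi_axes[2])^2 +
    ((mz - voi$center[3]) / voi$semi_axes[3])^2
  array(q <= 1, dim = d)
}

#' Derive the central-tumor VOI
#'
#' The tumor core is the concentric ellipsoid with half the dimensions of the
#' complete tumor (so an eighth of its volume).
#'
#' @param tumor A `cemct_voi` labelled `"tumor"` (or `"core"`, allowing
#'   composition; labels guard against misuse elsewhere).
#' @return A `cemct_voi` labelled `"core"`, same center, semi-axes halved.
#' @export
derive_core <- function(tumor) {
  stopifnot(inherits(tumor, "cemct_voi"))
  if (!tumor$label %in% c("tumor", "core")) {
    abort("derive_core() expects a tumor (or core) VOI, got '%s'", tumor$label)
  }
  ellipsoid_voi(tumor$center, tumor$semi_axes / 2, "core")
}

#' Derive the four peripheral-tumor VOIs
#'
#' Places four equal ellipsoidal VOIs in the tumor volume outside the central
#' core, at offsets of `offset_frac` times the tumor semi-axis along +x, -x,
#' +y, -y from the tumor center, each with semi-axes `scale_frac` times the
#' tumor's. The defaults (0.75, 0.2) guarantee, in tumor-normalized
#' coordinates, containment in the tumor (0.75 + 0.2 <= 1), exclusion from a
#' concentric half-size core (0.75 - 0.2 >= 0.5) and pairwise disjointness;
#' all three are re-verified for the actual core passed in.
#'
#' @param tumor A `cemct_voi` labelled `"tumor"`.
#' @param core The central-tumor VOI (concentric with `tumor`).
#' @param offset_frac Center offset as a fraction of the tumor semi-axis.
#' @param scale_frac Sub-VOI semi-axes as a fraction of the tumor's.
#' @return List of four `cemct_voi`s labelled `"periphery_1"`..`"periphery_4"`.
#' @export
derive_periphery <- function(tumor, core = derive_core(tumor),
                             offset_frac = 0.75, scale_frac = 0.2) {
  stopifnot(inherits(tumor, "cemct_voi"), inherits(core, "cemct_voi"))
  if (tumor$label != "tumor") abort("`tumor` must be labelled 'tumor'")
  if (max(abs(core$center - tumor$center)) > 1e-9) {
    abort("periphery placement requires a core concentric with the tumor")
  }
  if (offset_frac + scale_frac > 1 + 1e-12) {
    abort("periphery VOIs leave the tumor: offset_frac + scale_frac = %.3f > 1",
          offset_frac + scale_frac)
  }
  core_frac <- max(core$semi_axes / tumor$semi_axes)
  if (offset_frac - scale_frac < core_frac - 1e-12) {
    abort("periphery VOIs intersect the core: offset - scale = %.3f < core fraction %.3f",
          offset_frac - scale_frac, core_frac)
  }
  if (2 * offset_frac^2 < (2 * scale_frac)^2) {  # adjacent centers sqrt(2)*offset apart
    abort("periphery VOIs overlap each other")
  }
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  lapply(seq_along(dirs), function(i) {
    ellipsoid_voi(tumor$center + offset_frac * tumor$semi_axes * dirs[[i]],
                  scale_frac * tumor$semi_axes, paste0("periphery_", i))
  })
}

#' Region statistics over a VOI
#'
#' Mean and SD of the volume values over all voxels whose centers fall inside
#' the ellipsoid (center-point membership, no partial-volume weighting).
#' Passing a list of VOIs (e.g. the four peripheral sub-VOIs) pools their
#' voxels into one region; `aggregate = "mean_of_means"` instead averages the
#' per-VOI means (sensitivity-check alternative).
#'
#' Voxels outside the volume bounds are simply absent from the grid, so a VOI
#' reaching past the edge is truncated and `n_voxels` reflects that.
#'
#' @param vol A `cemct_volume`.
#' @param voi A `cemct_voi` or a list of them.
#' @param label Region label for the output (defaults to the VOI's; pooled
#'   periphery lists default to `"periphery"`).
#' @param aggregate `"pool"` (default) or `"mean_of_means"` for VOI lists.
#' @return A `cemct_region_stats`: list with `label`, `n_voxels`, `mean`,
#'   `sd`, `kind`, `protocol`.
#' @export
sample_voi <- function(vol, voi, label = NULL,
                       aggregate = c("pool", "mean_of_means")) {
  stopifnot(is_volume(vol))
  aggregate <- match.arg(aggregate)
  vois <- if (inherits(voi, "cemct_voi")) list(voi) else voi
  stopifnot(all(vapply(vois, inherits, TRUE, "cemct_voi")))
  if (is.null(label)) {
    label <- if (length(vois) == 1L) {
      vois[[1]]$label
    } else if (all(grepl("^periphery_", vapply(vois, `[[`, "", "label")))) {
      "periphery"
    } else {
      "custom"
    }
  }
  d <- dim(vol$data); sp <- vol$spacing
  masks <- lapply(vois, voi_mask, d = d, sp = sp)
  if (aggregate == "mean_of_means" && length(masks) > 1L) {
    per <- vapply(masks, function(m) {
      if (!any(m)) abort("VOI does not intersect the volume")
      mean(vol$data[m])
    }, numeric(1))
    return(new_region_stats(label, sum(vapply(masks, sum, 0L)),
                            mean(per), stats::sd(per), vol))
  }
  m <- Reduce(`|`, masks)
  n <- sum(m)
  if (n == 0L) abort("VOI '%s' does not intersect the volume", label)
  vals <- vol$data[m]
  new_region_stats(label, n, mean(vals), if (n > 1L) stats::sd(vals) else 0, vol)
}

new_region_stats <- function(label, n, mean, sd, vol = NULL, kind = NULL,
                             protocol = NULL) {
  structure(list(label = label, n_voxels = as.integer(n), mean = mean,
                 sd = sd,
                 kind = if (is.null(kind)) vol$kind else kind,
                 protocol = if (is.null(protocol)) vol$protocol else protocol),
            class = "cemct_region_stats")
}

#' @export
print.cemct_region_stats <- function(x, ...) {
  cat(sprintf("<region_stats> %-12s %s: %.4g +/- %.4g  (n = %d voxels)\n",
              x$label, x$kind, x$mean, x$sd, x$n_voxels))
  invisible(x)
}

#' Relative blood volume from iodine-concentration statistics
#'
#' `rBV(%) = 100 * C_I,tissue / C_I,aorta`, normalizing the tissue iodine
#' concentration by the arterial one so inter-animal variability in contrast
#' delivery cancels. The SD is propagated with the first-order ratio rule
#' `sd_r = rBV * sqrt((sd_t/mean_t)^2 + (sd_a/mean_a)^2)` (independence
#' assumed; reported for orientation only).
#'
#' @param tissue,aorta `cemct_region_stats` of kind `"iodine_mg_ml"` from the
#'   same animal/protocol. The aorta mean must be > 0.
#' @return A `cemct_region_stats` with kind `"rbv_percent"`.
#' @export
rbv_from_ci <- function(tissue, aorta) {
  stopifnot(inherits(tissue, "cemct_region_stats"),
            inherits(aorta, "cemct_region_stats"))
  for (s in list(tissue, aorta)) {
    if (s$kind != "iodine_mg_ml") {
      abort("rbv_from_ci() expects iodine_mg_ml statistics, got '%s'", s$kind)
    }
  }
  if (!is.null(tissue$protocol) && !is.null(aorta$protocol) &&
      tissue$protocol != aorta$protocol) {
    abort("tissue and aorta statistics come from different protocols")
  }
  if (!is.finite(aorta$mean) || aorta$mean <= 0) {
    abort("invalid arterial reference: aorta mean C_I = %.4g <= 0", aorta$mean)
  }
  rbv <- 100 * tissue$mean / aorta$mean
  sd <- if (tissue$mean == 0) 0 else {
    abs(rbv) * sqrt((tissue$sd / tissue$mean)^2 + (aorta$sd / aorta$mean)^2)
  }
  new_region_stats(tissue$label, tissue$n_voxels, rbv, sd,
                   kind = "rbv_percent", protocol = tissue$protocol)
}

#' Quantify a standard VOI set over a volume
#'
#' Convenience driver producing one table row per region: samples every VOI,
#' derives core and periphery from the tumor VOI when present, and (for
#' iodine images with an AIF label present) appends rBV rows.
#'
#' @param vol A `cemct_volume`.
#' @param vois Named list of `cemct_voi`s.
#' @param aif_label Label of the arterial reference region for rBV (default
#'   `"aorta"`); set `NULL` to skip rBV.
#' @param animal Animal/tumor identifier carried into the table.
#' @return A data.frame with columns `protocol`, `animal`, `region`,
#'   `n_voxels`, `mean`, `sd`, `units`.
#' @export
quantify_volume <- function(vol, vois, aif_label = "aorta", animal = NA) {
  stopifnot(is_volume(vol))
  vois <- expand_tumor_vois(vois)
  stats_list <- lapply(vois, function(v) sample_voi(vol, v))
  if (vol$kind == "iodine_mg_ml" && !is.null(aif_label)) {
    labs <- vapply(stats_list, `[[`, "", "label")
    ai <- which(labs == aif_label)
    if (length(ai) == 1L) {
      for (s in stats_list[labs != aif_label]) {
        stats_list[[length(stats_list) + 1L]] <- rbv_from_ci(s, stats_list[[ai]])
      }
    }
  }
  do.call(rbind, lapply(stats_list, function(s) {
    data.frame(protocol = if (is.null(s$protocol)) NA_character_ else s$protocol,
               animal = animal, region = s$label, n_voxels = s$n_voxels,
               mean = s$mean, sd = s$sd, units = stats_units(s$kind),
               stringsAsFactors = FALSE)
  }))
}

# add core + pooled periphery entries whenever a tumor VOI is present
expand_tumor_vois <- function(vois) {
  labs <- vapply(vois, `[[`, "", "label")
  if ("tumor" %in% labs && !"core" %in% labs) {
    tumor <- vois[[which(labs == "tumor")[1]]]
    core <- derive_core(tumor)
    vois <- c(vois, list(core), list(derive_periphery(tumor, core)))
  }
  vois
}

stats_units <- function(kind) {
  switch(kind,
         hu = "HU", attenuation_mu = "1/mm", enhancement_hu = "HU",
         iodine_mg_ml = "mg I/mL", rbv_percent = "%", kind)
}

#' Aggregate per-animal quantification rows across animals
#'
#' Table-style summaries report mean +/- standard error of the mean across
#' animals (scatter-plot-level data keep per-animal SD).
#'
#' @param quant A data.frame as produced by [quantify_volume()] (rows from
#'   several animals).
#' @return A data.frame with columns `protocol`, `region`, `units`, `n`,
#'   `mean`, `sem`.
#' @export
aggregate_quant <- function(quant) {
  key <- interaction(quant$protocol, quant$region, quant$units, drop = TRUE)
  out <- do.call(rbind, lapply(split(quant, key), function(g) {
    data.frame(protocol = g$protocol[1], region = g$region[1],
               units = g$units[1], n = nrow(g), mean = mean(g$mean),
               sem = stats::sd(g$mean) / sqrt(nrow(g)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' VOI YAML serialization
#'
#' VOIs are written in world coordinates (mm) as a named YAML list with
#' `center`, `semi_axes` and `label` per entry.
#'
#' @param vois A `cemct_voi` or (named) list of them.
#' @param path File path.
#' @export
write_vois_yaml <- function(vois, path) {
  if (inherits(vois, "cemct_voi")) vois <- list(vois)
  yaml::write_yaml(lapply(vois, function(v) {
    list(label = v$label, center = as.list(v$center),
         semi_axes = as.list(v$semi_axes))
  }), path)
  invisible(path)
}

#' @rdname write_vois_yaml
#' @export
read_vois_yaml <- function(path) {
  lapply(yaml::read_yaml(path), function(v) {
    ellipsoid_voi(unlist(v$center), unlist(v$semi_axes), v$label)
  })
}
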