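#' Histology simulation specification
#'
#' Controls the synthetic histology table paired with generated tumors:
#' percent necrosis (PN, % of necrotic tissue), proliferation index (PI, %
#' PCNA-positive cells in viable tumor) and microvessel density (MVD, mean
#' vessel count over 10 high-power fields of hot spots). Each variable is
#' generated with a target Pearson correlation against a supplied per-tumor
#' imaging parameter, with specified marginal mean/SD; PN and PI are clipped
#' to [0, 100] and MVD to >= 0 (clipping can shrink the realized correlation
#' when marginals push against the bounds).
#'
#' Marginal defaults follow the histological characterization of the
#' subcutaneous C6 glioma model (8-tumor group: PN 38.1, PI 68.7 %, MVD 6.9
#' vessels/HPF; SDs reconstructed from the reported standard errors).
#'
#' @param n_tumors Number of tumors (>= 3; correlation is undefined below).
#' @param rho Named numeric, target correlations for `pn`, `pi`, `mvd`, each
#'   in [-1, 1].
#' @param means,sds Named numeric marginals for `pn`, `pi`, `mvd`; SDs > 0.
#' @param seed RNG seed.
#' @return Object of class `cemct_histology_spec`.
#' @export
histology_spec <- function(n_tumors,
                           rho = c(pn = 0.75, pi = 0, mvd = 0.8),
                           means = c(pn = 38.1, pi = 68.7, mvd = 6.9),
                           sds = c(pn = 15, pi = 8, mvd = 2.5),
                           seed = 1L) {
  n_tumors <- as.integer(n_tumors)
  if (n_tumors < 3L) abort("need at least 3 tumors (correlation undefined below)")
  vars <- c("pn", "pi", "mvd")
  for (x in list(rho = rho, means = means, sds = sds)) {
    if (!all(vars %in% names(x))) abort("rho/means/sds must name pn, pi, mvd")
  }
  if (any(abs(rho[vars]) > 1)) abort("|rho| must be <= 1")
  if (any(sds[vars] <= 0)) abort("SDs must be > 0")
  structure(list(n_tumors = n_tumors, rho = rho[vars], means = means[vars],
                 sds = sds[vars], seed = as.integer(seed)),
            class = "cemct_histology_spec")
}

#' Generate a synthetic histology table paired with imaging values
#'
#' For each histology variable `v` with target correlation `rho_v`, draws
#' `v = mean_v + sd_v * (rho_v * z + sqrt(1 - rho_v^2) * eps)` where `z` is
#' the standardized imaging parameter and `eps` independent standard normal,
#' then applies the range constraints (PN, PI in [0, 100]; MVD >= 0). With
#' `|rho| = 1` the dependence is exactly linear, so the sample correlation is
#' exactly +/-1 when no clipping occurs.
#'
#' @param sim A [histology_spec()].
#' @param imaging_values Per-tumor scalar imaging parameter (length
#'   `n_tumors`, nonzero variance).
#' @return A data.frame with columns `tumor_id`, `pn_percent`, `pi_percent`,
#'   `mvd_vessels_per_hpf`.
#' @export
make_histology_table <- function(sim, imaging_values) {
  stopifnot(inherits(sim, "cemct_histology_spec"))
  x <- as.numeric(imaging_values)
  if (length(x) != sim$n_tumors) {
    abort("imaging_values length %d != n_tumors %d", length(x), sim$n_tumors)
  }
  if (stats::sd(x) < 1e-12) abort("imaging_values must have nonzero variance")
  z <- (x - mean(x)) / stats::sd(x)
  with_seed(sim$seed, {
    draw <- function(v) {
      rho <- sim$rho[[v]]
      raw <- sim$means[[v]] + sim$sds[[v]] *
        (rho * z + sqrt(1 - rho^2) * stats::rnorm(sim$n_tumors))
      raw
    }
    pn <- pmin(pmax(draw("pn"), 0), 100)
    pi_ <- pmin(pmax(draw("pi"), 0), 100)
    mvd <- pmax(draw("mvd"), 0)
    data.frame(tumor_id = seq_len(sim$n_tumors), pn_percent = pn,
               pi_percent = pi_, mvd_vessels_per_hpf = mvd)
  })
}

#' Histology CSV I/O
#' @param histology Data.frame as produced by [make_histology_table()].
#' @param path File path.
#' @export
write_histology_csv <- function(histology, path) {
  cols <- c("tumor_id", "pn_percent", "pi_percent", "mvd_vessels_per_hpf")
  stopifnot(all(cols %in% names(histology)))
  utils::write.csv(histology[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histology_csv
#' @export
read_histology_csv <- function(path) {
  x <- utils::read.csv(path)
  cols <- c("tumor_id", "pn_percent", "pi_percent", "mvd_vessels_per_hpf")
  if (!all(cols %in% names(x))) {
    abort("histology CSV must have columns %s", paste(cols, collapse = ", "))
  }
  bad <- x$pn_percent < 0 | x$pn_percent > 100 | x$pi_percent < 0 |
    x$pi_percent > 100 | x$mvd_vessels_per_hpf < 0
  if (any(bad)) abort("histology values out of range in %d row(s)", sum(bad))
  x[cols]
}
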