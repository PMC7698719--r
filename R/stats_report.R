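#' Pearson correlation with Fisher confidence interval
#'
#' Sample Pearson r with a two-sided p-value from the t distribution on
#' `n - 2` degrees of freedom and a confidence interval from the Fisher z
#' transform (`atanh(r) +/- z * 1/sqrt(n - 3)`). With `n = 3` the Fisher
#' standard error is infinite and the CI degenerates to [-1, 1]; with
#' `|r| = 1` the p-value is reported as 0.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, finite, nonzero variance.
#' @param conf_level Confidence level (default 0.95).
#' @param parameter,histology_variable Optional names carried into the
#'   result (imaging parameter/region and histology variable).
#' @return Object of class `cemct_correlation`: list with `parameter`,
#'   `histology_variable`, `n`, `r`, `p_value`, `conf_low`, `conf_high`,
#'   `significant` (at 0.05).
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95, parameter = NA_character_,
                            histology_variable = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) abort("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3L) abort("need n >= 3 pairs, got %d", n)
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("non-finite values in input")
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) {
    abort("zero variance in input; correlation undefined")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  if (n > 3L) {
    z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  } else {
    ci <- c(-1, 1)
  }
  structure(list(parameter = parameter, histology_variable = histology_variable,
                 n = n, r = r, p_value = p, conf_low = ci[1], conf_high = ci[2],
                 significant = p < 0.05),
            class = "cemct_correlation")
}

#' @export
print.cemct_correlation <- function(x, ...) {
  cat(sprintf("<correlation> %s vs %s: r = %.3f (95%% CI %.3f..%.3f), p = %.3g, n = %d%s\n",
              x$parameter, x$histology_variable, x$r, x$conf_low, x$conf_high,
              x$p_value, x$n, if (x$significant) " *" else ""))
  invisible(x)
}

#' Group comparisons for quantification tables
#'
#' Statistical comparisons matching the reporting conventions of the
#' pipeline: two-way ANOVA with Bonferroni-adjusted pairwise contrasts of
#' one factor within each level of the other (used for attenuation, E, C_I
#' and rBV across protocols and regions), one-way ANOVA with Tukey HSD (used
#' for histology variables across groups), and a two-sided pooled-variance t
#' test (used for the K^trans muscle-vs-tumor contrast).
#'
#' @param data Data.frame in long format.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names: two for
#'   `"two_way_bonferroni"` (pairwise contrasts run over the first factor
#'   within levels of the second), one for the other methods.
#' @param method `"two_way_bonferroni"`, `"one_way_tukey"` or `"t_test"`.
#' @param var_equal For `"t_test"`: pooled variance (default TRUE).
#' @return A list with `method`, `anova` (data.frame of F tests; `NULL` for
#'   t test) and `pairwise` (data.frame with `contrast`, optional `within`,
#'   `estimate`, `p_adj`, `significant`).
#' @export
compare_groups <- function(data, response, factors,
                           method = c("two_way_bonferroni", "one_way_tukey",
                                      "t_test"),
                           var_equal = TRUE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)))
  y <- data[[response]]
  if (!is.numeric(y)) abort("response must be numeric")

  if (method == "t_test") {
    f <- factor(data[[factors[1]]])
    if (nlevels(f) != 2L) abort("t_test needs exactly 2 groups, got %d", nlevels(f))
    tt <- stats::t.test(y ~ f, var.equal = var_equal)
    pw <- data.frame(contrast = paste(levels(f), collapse = " - "),
                     estimate = unname(diff(rev(tt$estimate))),
                     statistic = unname(tt$statistic),
                     p_adj = tt$p.value,
                     significant = tt$p.value < 0.05,
                     stringsAsFactors = FALSE)
    return(list(method = method, anova = NULL, pairwise = pw))
  }

  if (method == "one_way_tukey") {
    if (length(factors) != 1L) abort("one_way_tukey needs exactly one factor")
    g <- factor(data[[factors[1]]])
    check_cells(y, list(g))
    fit <- stats::aov(y ~ g)
    an <- as.data.frame(summary(fit)[[1]])
    rownames(an) <- trimws(rownames(an))
    rownames(an)[rownames(an) == "g"] <- factors[1]
    tk <- stats::TukeyHSD(fit)$g
    pw <- data.frame(contrast = rownames(tk), estimate = tk[, "diff"],
                     p_adj = tk[, "p adj"], significant = tk[, "p adj"] < 0.05,
                     stringsAsFactors = FALSE, row.names = NULL)
    return(list(method = method, anova = an, pairwise = pw))
  }

  # two-way ANOVA + Bonferroni pairwise contrasts of factor 1 within factor 2
  if (length(factors) != 2L) abort("two_way_bonferroni needs two factors")
  fa <- factor(data[[factors[1]]]); fb <- factor(data[[factors[2]]])
  check_cells(y, list(fa, fb))
  fit <- stats::aov(y ~ fa * fb)
  an <- as.data.frame(summary(fit)[[1]])
  rownames(an) <- c(factors, paste(factors, collapse = ":"), "Residuals")
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]
  combos <- utils::combn(levels(fa), 2, simplify = FALSE)
  rows <- list()
  for (b in levels(fb)) {
    for (cb in combos) {
      i1 <- fa == cb[1] & fb == b
      i2 <- fa == cb[2] & fb == b
      est <- mean(y[i1]) - mean(y[i2])
      se <- sqrt(mse * (1 / sum(i1) + 1 / sum(i2)))
      p <- 2 * stats::pt(-abs(est / se), df = df_res)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = paste(cb, collapse = " - "), within = b, estimate = est,
        p_raw = p, stringsAsFactors = FALSE)
    }
  }
  pw <- do.call(rbind, rows)
  pw$p_adj <- pmin(pw$p_raw * nrow(pw), 1)
  pw$significant <- pw$p_adj < 0.05
  list(method = method, anova = an, pairwise = pw)
}

check_cells <- function(y, fs) {
  cell <- interaction(fs, drop = FALSE)
  counts <- table(cell)
  if (any(counts < 2L)) {
    abort("ANOVA needs >= 2 observations per cell; empty/singleton cell(s): %s",
          paste(names(counts)[counts < 2L], collapse = ", "))
  }
  invisible(TRUE)
}

#' Imaging-versus-histology correlation screen
#'
#' Evaluates the Pearson correlation of every imaging parameter x region
#' column against every histology variable, joined on `tumor_id`. No
#' multiplicity adjustment is applied by default (each pair is reported with
#' its raw p-value, significance flagged at 0.05); `p_adjust = "BH"` enables
#' Benjamini-Hochberg for sensitivity analyses. Pairs with fewer than 3
#' joined tumors or zero variance are skipped with a warning.
#'
#' @param imaging Data.frame in long format with columns `tumor_id`,
#'   `parameter` (e.g. `"ci"`), `region` (e.g. `"periphery"`), `value`.
#' @param histology Data.frame with columns `tumor_id`, `pn_percent`,
#'   `pi_percent`, `mvd_vessels_per_hpf`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data.frame sorted by p-value with columns `parameter`, `region`,
#'   `histology_variable`, `n`, `r`, `conf_low`, `conf_high`, `p_value`,
#'   `significant`.
#' @export
correlation_screen <- function(imaging, histology, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(c("tumor_id", "parameter", "region", "value") %in% names(imaging)))
  hvars <- c(pn = "pn_percent", pi = "pi_percent", mvd = "mvd_vessels_per_hpf")
  stopifnot("tumor_id" %in% names(histology), all(hvars %in% names(histology)))
  out <- list()
  for (key in split(imaging,
                    interaction(imaging$parameter, imaging$region, drop = TRUE))) {
    merged <- merge(key, histology, by = "tumor_id")
    for (h in names(hvars)) {
      pair <- sprintf("%s[%s] vs %s", key$parameter[1], key$region[1], h)
      xv <- merged$value; yv <- merged[[hvars[[h]]]]
      ok <- is.finite(xv) & is.finite(yv)
      if (sum(ok) < 3L) {
        warning(sprintf("skipping %s: only %d joined tumors", pair, sum(ok)),
                call. = FALSE)
        next
      }
      if (stats::sd(xv[ok]) < 1e-12 || stats::sd(yv[ok]) < 1e-12) {
        warning(sprintf("skipping %s: zero variance", pair), call. = FALSE)
        next
      }
      res <- pearson_with_ci(xv[ok], yv[ok],
                             parameter = sprintf("%s[%s]", key$parameter[1],
                                                 key$region[1]),
                             histology_variable = h)
      out[[length(out) + 1L]] <- data.frame(
        parameter = key$parameter[1], region = key$region[1],
        histology_variable = h, n = res$n, r = res$r,
        conf_low = res$conf_low, conf_high = res$conf_high,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame())
  df <- do.call(rbind, out)
  if (p_adjust == "BH") df$p_value <- stats::p.adjust(df$p_value, method = "BH")
  df$significant <- df$p_value < 0.05
  df[order(df$p_value), , drop = FALSE]
}
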