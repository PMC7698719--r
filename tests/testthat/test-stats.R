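test_that("pearson_with_ci matches the hand-expanded covariance formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  res <- pearson_with_ci(x, y)
  # closed-form oracle written out from sums
  dx <- x - mean(x); dy <- y - mean(y)
  r_hand <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df = 3), tolerance = 1e-12)
  z <- atanh(r_hand); se <- 1 / sqrt(2)
  expect_equal(res$conf_low, tanh(z - qnorm(0.975) * se), tolerance = 1e-12)
  expect_true(res$conf_low <= res$r && res$r <= res$conf_high)
})

test_that("pearson_with_ci: perfect fits, degenerate input, n = 3 CI", {
  x <- 1:10
  expect_equal(pearson_with_ci(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_with_ci(x, 2 * x + 1)$p_value, 0)
  expect_equal(pearson_with_ci(x, -x)$r, -1)
  expect_error(pearson_with_ci(1:2, 1:2), "n >= 3")
  expect_error(pearson_with_ci(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_with_ci(c(1, NA, 3), c(1, 2, 3)), "finite")
  res3 <- pearson_with_ci(c(1, 2, 3), c(1, 3, 2))
  expect_equal(c(res3$conf_low, res3$conf_high), c(-1, 1))
})

test_that("pearson is invariant to positive affine rescaling", {
  vals <- cemct:::with_seed(5, list(x = rnorm(20), y = rnorm(20)))
  base <- pearson_with_ci(vals$x, vals$y)
  shifted <- pearson_with_ci(3 * vals$x + 7, 0.1 * vals$y - 2)
  expect_equal(shifted$r, base$r, tolerance = 1e-12)
  expect_equal(shifted$p_value, base$p_value, tolerance = 1e-12)
})

test_that("Fisher CI covers rho = 0.7 at the nominal rate (n = 8)", {
  rho <- 0.7; n <- 8; nsim <- 2000
  cover <- cemct:::with_seed(99, {
    hits <- 0L
    for (s in seq_len(nsim)) {
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      ci <- pearson_with_ci(x, y)
      if (ci$conf_low <= rho && rho <= ci$conf_high) hits <- hits + 1L
    }
    hits / nsim
  })
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("t_test contrast reproduces the pooled-variance formula", {
  df <- data.frame(region = rep(c("muscle", "tumor"), each = 3),
                   value = c(0.12, 0.14, 0.13, 0.22, 0.25, 0.24))
  res <- compare_groups(df, "value", "region", method = "t_test")
  m1 <- mean(df$value[1:3]); m2 <- mean(df$value[4:6])
  sp2 <- (2 * var(df$value[1:3]) + 2 * var(df$value[4:6])) / 4
  t_hand <- (m1 - m2) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$pairwise$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$pairwise$p_adj, 2 * pt(-abs(t_hand), df = 4),
               tolerance = 1e-12)
  expect_true(res$pairwise$significant)
})

test_that("one-way ANOVA + Tukey agrees with closed-form F on a balanced toy", {
  df <- data.frame(g = rep(c("a", "b", "c"), each = 4),
                   value = c(1, 2, 1.5, 1.5, 3, 4, 3.5, 3.5, 1, 1.5, 1.2, 1.3))
  res <- compare_groups(df, "value", "g", method = "one_way_tukey")
  # closed-form balanced one-way F
  gm <- mean(df$value)
  means <- tapply(df$value, df$g, mean)
  ssb <- 4 * sum((means - gm)^2)
  ssw <- sum((df$value - means[df$g])^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(res$anova["g", "F value"], f_hand, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(nrow(res$pairwise), 3L)
  expect_true(res$pairwise$significant[res$pairwise$contrast == "b-a"])
})

test_that("two-way ANOVA with Bonferroni: identical groups cap at p = 1", {
  df <- expand.grid(protocol = c("SE", "DE"), region = c("muscle", "tumor"),
                    rep = 1:4)
  # identical cell means (5 exactly), nonzero residual variance
  df$value <- 5 + ifelse(df$rep %% 2 == 0, 0.01, -0.01)
  res <- compare_groups(df, "value", c("protocol", "region"),
                        method = "two_way_bonferroni")
  expect_true(all(res$pairwise$p_adj == 1))
  expect_false(any(res$pairwise$significant))
  # empty/singleton cells are named
  df2 <- df[!(df$protocol == "SE" & df$region == "tumor") | df$rep == 1, ]
  expect_error(compare_groups(df2, "value", c("protocol", "region"),
                              method = "two_way_bonferroni"), "cell")
})

test_that("two-way pairwise contrast separates well-separated groups", {
  vals <- cemct:::with_seed(17, {
    df <- expand.grid(protocol = c("SE", "DE"), region = c("muscle", "tumor"),
                      rep = 1:6)
    mu <- ifelse(df$region == "tumor", 25, 11)
    df$value <- rnorm(nrow(df), mu, 1)
    df
  })
  res <- compare_groups(vals, "value", c("region", "protocol"),
                        method = "two_way_bonferroni")
  expect_true(all(res$pairwise$significant))
  expect_lt(max(res$pairwise$p_adj), 1e-4)
})

test_that("correlation_screen joins, ranks, skips degenerate pairs", {
  n <- 50
  data <- cemct:::with_seed(31, {
    rbv <- rnorm(n, 25, 5)
    sim <- histology_spec(n, rho = c(pn = 0.2, pi = 0, mvd = 0.9), seed = 32)
    list(rbv = rbv, hist = make_histology_table(sim, rbv))
  })
  imaging <- data.frame(tumor_id = 1:n, parameter = "rbv",
                        region = "periphery", value = data$rbv)
  res <- correlation_screen(imaging, data$hist)
  expect_identical(nrow(res), 3L)
  mvd_row <- res[res$histology_variable == "mvd", ]
  expect_true(mvd_row$significant)
  expect_gt(mvd_row$r, 0.8)
  expect_identical(res$histology_variable[1], "mvd")  # sorted by p

  # constant imaging column: every pair skipped with a zero-variance warning
  flat <- imaging; flat$value <- 1
  w <- capture_warnings(res_flat <- correlation_screen(flat, data$hist))
  expect_match(w, "zero variance", all = TRUE)
  expect_length(w, 3)
  expect_identical(nrow(res_flat), 0L)

  # n < 3 joined tumors: skipped with a warning
  tiny <- imaging[1:2, ]
  w2 <- capture_warnings(correlation_screen(tiny, data$hist))
  expect_match(w2, "joined", all = TRUE)

  # BH adjustment only raises p-values
  res_bh <- suppressWarnings(correlation_screen(imaging, data$hist,
                                                p_adjust = "BH"))
  expect_true(all(res_bh$p_value >= res$p_value - 1e-15))
})
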