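# Expected values below are frozen from independent closed-form oracles:
# hand-computed sums of squares / variance formulas pushed through the
# relevant distribution functions, not from the wrapped implementations.

test_that("five-number summaries use linear quantile interpolation", {
  s <- five_number_summary(c(1, 2, 3, 4, 5))
  expect_equal(unlist(unclass(s)),
               c(minimum = 1, q1 = 2, median = 3, q3 = 4, maximum = 5))
  expect_equal(unlist(unclass(five_number_summary(c(7, 7, 7)))),
               c(minimum = 7, q1 = 7, median = 7, q3 = 7, maximum = 7))
  # interpolated quartiles: q1 = 1 + 0.75, q3 = 3 + 0.25
  s4 <- five_number_summary(c(1, 2, 3, 4))
  expect_equal(c(s4$q1, s4$median, s4$q3), c(1.75, 2.5, 3.25))
  expect_true(s4$minimum <= s4$q1 && s4$q1 <= s4$median &&
                s4$median <= s4$q3 && s4$q3 <= s4$maximum)
  expect_error(five_number_summary(numeric(0)), class = "plgg_empty_error")
})

test_that("the unpaired t test matches the closed-form Welch oracle", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  # Welch formula by hand: se^2 = 1/3 + 1/3, t = -1/se,
  # df = se^4 / ((1/3)^2/2 + (1/3)^2/2) = 4
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_oracle <- (mean(a) - mean(b)) / se
  df_oracle <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df_oracle)

  res <- unpaired_t_test(a, b)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-6)
  expect_equal(res$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4, tolerance = 1e-6)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-6)
  expect_equal(res$p_value, 0.2878641, tolerance = 1e-6)

  same <- unpaired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # antisymmetry
  expect_equal(unpaired_t_test(b, a)$statistic, -res$statistic)

  expect_error(unpaired_t_test(c(1), b), class = "plgg_validation_error")
  expect_equal(unpaired_t_test(c(0, 0), c(0, 0))$p_value, 1)
  expect_error(unpaired_t_test(c(0, 0), c(1, 1)),
               class = "plgg_validation_error")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  # SSB = 2((1.5-3.5)^2 + 0 + (5.5-3.5)^2) = 16, SSW = 1.5,
  # F = (16/2)/(1.5/3) = 16
  res <- one_way_anova(groups)
  expect_equal(res$statistic, 16, tolerance = 1e-9)
  expect_equal(res$df, c(2, 3))
  expect_equal(res$p_value, stats::pf(16, 2, 3, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(res$p_value, 0.0250945733, tolerance = 1e-6)

  flat <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  expect_error(one_way_anova(list(c(1, 2))), class = "plgg_validation_error")
  expect_error(one_way_anova(list(c(1, 2), c(3))),
               class = "plgg_validation_error")
})

test_that("F = t^2 for two equal-variance groups", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  f_res <- one_way_anova(list(a, b))
  # pooled-variance t by hand (equal group sizes: equals the Welch statistic)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_pooled <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(f_res$statistic, t_pooled^2, tolerance = 1e-9)
})

test_that("Tukey HSD reproduces the studentized-range oracle", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  tab <- tukey_hsd(groups)
  expect_equal(nrow(tab), 3)

  # oracle: q = |diff| / sqrt(MSE/n), p = P(Q_{k, N-k} > q)
  mse <- 1.5 / 3
  q_or <- function(diff) abs(diff) / sqrt(mse / 2)
  p_or <- function(diff) stats::ptukey(q_or(diff), nmeans = 3, df = 3,
                                       lower.tail = FALSE)
  expect_equal(tab$diff[tab$comparison == "g2-g1"], 2)
  expect_equal(tab$p_adj[tab$comparison == "g2-g1"], p_or(2),
               tolerance = 1e-6)
  expect_equal(tab$p_adj[tab$comparison == "g3-g1"], p_or(4),
               tolerance = 1e-6)
  expect_equal(tab$p_adj[tab$comparison == "g3-g2"], p_or(2),
               tolerance = 1e-6)

  flat <- tukey_hsd(list(c(2, 2), c(2, 2)))
  expect_true(all(flat$p_adj == 1))

  # k = 2: the single adjusted p equals the plain studentized-range p
  two <- tukey_hsd(list(c(1, 2), c(3, 4)))
  expect_equal(nrow(two), 1)
  mse2 <- 1 / 2
  expect_equal(two$p_adj,
               stats::ptukey(2 / sqrt(mse2 / 2), nmeans = 2, df = 2,
                             lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("Pearson correlation matches the closed-form r and t transform", {
  perfect <- pearson_correlation(1:5, 1:5)
  expect_equal(perfect$statistic, 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(6, 4, 2))$statistic, -1)

  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  res <- pearson_correlation(x, y)
  # closed form: r = Sxy / sqrt(Sxx Syy) = 4 / 5
  expect_equal(res$statistic, 0.8, tolerance = 1e-9)
  t_or <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p_value, 2 * stats::pt(-t_or, 2), tolerance = 1e-6)
  expect_equal(res$df, 2)

  # affine invariance (up to the sign of the scale)
  shifted <- pearson_correlation(3 * x - 7, y)
  expect_equal(shifted$statistic, res$statistic, tolerance = 1e-12)
  flipped <- pearson_correlation(-2 * x + 1, y)
  expect_equal(flipped$statistic, -res$statistic, tolerance = 1e-12)

  expect_error(pearson_correlation(1:4, 1:5), class = "plgg_validation_error")
  expect_error(pearson_correlation(c(1, 1, 1), 1:3),
               class = "plgg_validation_error")
})
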