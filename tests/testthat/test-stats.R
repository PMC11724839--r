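test_that("mixed ANOVA degrees of freedom follow the split-plot identity", {
  set.seed(1)
  for (n in list(c(58, 59), c(48, 53), c(10, 14))) {
    sim <- simulate_metric_table(n)
    a <- mixed_anova(sim$Y, sim$group)
    N <- sum(n)
    expect_equal(a$effects$df1, c(1, 3, 3))
    expect_equal(a$effects$df2, c(N - 2, 3 * (N - 2), 3 * (N - 2)))
    expect_equal(a$n_per_group, n)
    expect_true(a$epsilon_gg >= 1 / 3 - 1e-9 && a$epsilon_gg <= 1 + 1e-9)
  }
  # structured failure modes
  sim <- simulate_metric_table(c(2, 1))
  expect_error(mixed_anova(sim$Y, sim$group), class = "inference_error")
  expect_error(mixed_anova(matrix(rnorm(40), 10, 4)),
               class = "inference_error")
})

test_that("mixed ANOVA agrees with the reference multivariate decomposition", {
  skip_if_not_installed("car")
  set.seed(99)
  for (i in 1:10) {
    n <- sample(5:20, 2)
    sim <- simulate_metric_table(n, sd_subject = runif(1, 0.3, 2),
                                 cor_structure = sample(c("cs", "ar1"), 1))
    a <- mixed_anova(sim$Y, sim$group)
    df <- data.frame(g = sim$group, sim$Y)
    mod <- lm(cbind(pert, rec1, rec2, rec3) ~ g, data = df,
              contrasts = list(g = contr.sum))
    idata <- data.frame(step = factor(colnames(sim$Y),
                                      levels = colnames(sim$Y)))
    s <- suppressWarnings(summary(
      car::Anova(mod, idata = idata, idesign = ~step, type = 3),
      multivariate = FALSE))
    ut <- s$univariate.tests
    ref <- c(ut["g", "F value"], ut["step", "F value"],
             ut["g:step", "F value"])
    expect_lt(max(abs(a$effects$F - ref) / ref), 1e-8)
    expect_lt(abs(a$mauchly$p - s$sphericity.tests["step", "p-value"]), 1e-8)
    expect_lt(abs(a$epsilon_gg - s$pval.adjustments["step", "GG eps"]), 1e-8)
  }
})

test_that("mixed ANOVA matches a split-plot aov on balanced data", {
  set.seed(5)
  sim <- simulate_metric_table(c(12, 12))
  a <- mixed_anova(sim$Y, sim$group)
  long <- sim$data
  long$step <- factor(long$step, levels = colnames(sim$Y))
  long$unit <- factor(long$unit)
  fit <- summary(aov(value ~ group * step + Error(unit / step), data = long))
  between <- fit[["Error: unit"]][[1]]
  within <- fit[["Error: unit:step"]][[1]]
  expect_equal(a$effects$F[1], between["group", "F value"], tolerance = 1e-8)
  expect_equal(a$effects$F[2], within["step", "F value"], tolerance = 1e-8)
  expect_equal(a$effects$F[3], within["group:step", "F value"],
               tolerance = 1e-8)
})

test_that("compound-symmetric data rarely trigger the sphericity correction", {
  set.seed(11)
  corrected <- replicate(200, {
    sim <- simulate_metric_table(c(20, 20), sd_subject = 1)
    mixed_anova(sim$Y, sim$group)$corrected
  })
  expect_lt(mean(corrected), 0.10)
})

test_that("the corrected interaction test is calibrated under the null", {
  set.seed(2024)
  # spherical null at the study-like group sizes
  rej_cs <- mean(replicate(400, {
    sim <- simulate_metric_table(c(60, 60))
    mixed_anova(sim$Y, sim$group)$effects$p[3] < 0.05
  }))
  expect_gt(rej_cs, 0.03)
  expect_lt(rej_cs, 0.07)
  # non-spherical null: Greenhouse-Geisser keeps size at or below ~nominal
  rej_ar <- mean(replicate(1000, {
    sim <- simulate_metric_table(c(30, 30), cor_structure = "ar1",
                                 ar1_rho = 0.8, sd_subject = 0.2)
    mixed_anova(sim$Y, sim$group)$effects$p[3] < 0.05
  }))
  expect_lte(rej_ar, 0.07)
})

test_that("Bonferroni post-hoc scales and caps raw p-values", {
  set.seed(8)
  sim <- simulate_metric_table(c(30, 30),
                               effect = c(0, -1.3, 0, 0), sd_error = 0.3,
                               sd_subject = 0.1)
  ph <- bonferroni_posthoc(sim$data)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 4))
  # the injected rec1 offset is recovered within 2 SE and flagged significant
  r1 <- ph[ph$step == "rec1", ]
  expect_lt(abs(r1$estimate - (-1.3)), 2 * r1$se)
  expect_lt(r1$p_adj, 0.001)
  # identical groups: adjusted p = 1
  Y <- matrix(rep(1:4, each = 20), 20, 4,
              dimnames = list(NULL, c("pert", "rec1", "rec2", "rec3")))
  long <- data.frame(unit = rep(1:20, 4),
                     group = rep(rep(c("inactive", "active"), each = 10), 4),
                     step = rep(colnames(Y), each = 20), value = as.vector(Y))
  ph0 <- bonferroni_posthoc(long)
  expect_true(all(ph0$p_adj == 1))
})

test_that("the Welch asymmetry contrast recovers injected asymmetries", {
  mk <- function(mI0, mP0, mI1, mP1, n = 60, sd = 1) {
    data.frame(side = rep(c("intact", "prosthetic"), each = 2 * n),
               group = rep(rep(c("inactive", "active"), each = n), 2),
               value = c(rnorm(n, mI0, sd), rnorm(n, mI1, sd),
                         rnorm(n, mP0, sd), rnorm(n, mP1, sd)))
  }
  set.seed(33)
  # symmetric shift on both sides: contrast centred on zero
  nulls <- replicate(200, welch_asymmetry_test(mk(5, 5, 4, 4))$estimate)
  expect_lt(abs(mean(nulls)), 0.05)
  # asymmetric unit effect recovered
  recs <- replicate(200, welch_asymmetry_test(mk(6, 5, 5, 5))$estimate)
  expect_lt(abs(mean(recs) - 1), 0.1)
  w <- welch_asymmetry_test(mk(6, 5, 5, 5))
  expect_lte(w$df, 4 * 60 - 4 + 1e-9)
  expect_true(w$p >= 0 && w$p <= 1)
  # degenerate constant groups are flagged
  cst <- mk(5, 5, 5, 5); cst$value <- 5
  expect_true(welch_asymmetry_test(cst)$degenerate)
  expect_error(welch_asymmetry_test(cst[1:3, ]), class = "inference_error")
})

test_that("handrail tallies partition by side and condition", {
  rep0 <- data.frame(side_label = character(), snp = character(),
                     handrail_grab = logical())
  expect_true(all(handrail_count_table(rep0) == 0))
  rep1 <- data.frame(
    side_label = c(rep("prosthetic", 10), "intact", "intact"),
    snp = c(rep("inactive", 10), "active", "inactive"),
    handrail_grab = c(rep(TRUE, 10), FALSE, TRUE))
  tab <- handrail_count_table(rep1)
  expect_equal(tab["prosthetic", "inactive"], 10)
  expect_equal(tab["intact", "inactive"], 1)
  expect_equal(tab["prosthetic", "active"], 0)
  expect_equal(sum(tab), 11)
})
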