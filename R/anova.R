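#' Mixed-design repeated-measures ANOVA (split-plot)
#'
#' Two-factor mixed ANOVA with one within-subject factor (recovery step:
#' `pert`, `rec1`, `rec2`, `rec3`) and one between-group factor (SNP
#' condition), with each perturbation trial as the analysis unit.  The
#' within-subject decomposition uses an orthonormal contrast basis of the
#' step factor; sphericity of the contrast covariance is evaluated with
#' Mauchly's test and, when violated, the degrees of freedom of the step
#' and interaction tests are deflated by the Greenhouse-Geisser epsilon
#' before p-values are computed.  The between-group effect is tested on the
#' subject means against the subject-within-group error (Type III,
#' unweighted cell means, matching `car::Anova`).
#'
#' Degrees of freedom: step and interaction carry `(k - 1,
#' (k - 1) * (N - 2))`; the SNP effect carries `(1, N - 2)`.
#'
#' @param data either a long data frame (columns `unit`, `group`, `step`,
#'   `value`, overridable via the `cols` argument) or an `N x k` wide matrix
#'   of per-unit step values (then `group` must be given).
#' @param group group factor of length `N` (wide-matrix interface only).
#' @param cols named character vector mapping `unit`, `group`, `step`,
#'   `value` to the data frame's column names.
#' @param step_levels within-factor levels in order.
#' @param sphericity_alpha Mauchly p-value below which the
#'   Greenhouse-Geisser correction is applied.
#' @return an object of class `mixed_anova`: a list with the `effects`
#'   table (SS, df pairs, F, p, corrected p), `mauchly` (W, chi-squared,
#'   df, p), `epsilon_gg`, `corrected`, `n_per_group`.
#' @export
mixed_anova <- function(data, group = NULL,
                        cols = c(unit = "unit", group = "group",
                                 step = "step", value = "value"),
                        step_levels = c("pert", "rec1", "rec2", "rec3"),
                        sphericity_alpha = 0.05) {
  if (is.matrix(data)) {
    Y <- data
    if (is.null(group))
      abort_stumblr("wide-matrix interface requires `group`", "inference_error")
    g <- factor(group)
  } else {
    df <- as.data.frame(data)
    unit <- df[[cols[["unit"]]]]
    g_all <- df[[cols[["group"]]]]
    step <- factor(df[[cols[["step"]]]], levels = step_levels)
    value <- df[[cols[["value"]]]]
    units <- unique(unit)
    k <- length(step_levels)
    Y <- matrix(NA_real_, length(units), k,
                dimnames = list(units, step_levels))
    Y[cbind(match(unit, units), as.integer(step))] <- value
    complete <- stats::complete.cases(Y)
    if (any(!complete))
      message(sprintf("dropping %d unit(s) with missing step values",
                      sum(!complete)))
    gu <- g_all[match(units, unit)]
    Y <- Y[complete, , drop = FALSE]
    g <- factor(gu[complete])
  }
  k <- ncol(Y)
  N <- nrow(Y)
  if (nlevels(g) != 2)
    abort_stumblr("the between factor must have exactly 2 levels",
                  "inference_error")
  n_per_group <- table(g)
  if (any(n_per_group < 2))
    abort_stumblr("each group needs at least 2 units", "inference_error")

  ## design with sum-to-zero coding -> intercept is the unweighted grand mean
  s <- ifelse(g == levels(g)[1], 1, -1)
  X <- cbind(1, s)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  E <- crossprod(Y - X %*% B)
  df_e <- N - 2

  ## orthonormal within-subject contrast basis
  M <- stats::contr.poly(k)
  EM <- t(M) %*% E %*% M
  q <- k - 1

  hyp <- function(L) {
    LBM <- L %*% B %*% M
    crossprod(LBM) / as.numeric(L %*% XtXi %*% t(L))
  }
  H_step <- hyp(matrix(c(1, 0), 1))
  H_int <- hyp(matrix(c(0, 1), 1))
  mse_w <- sum(diag(EM)) / (q * df_e)
  F_step <- (sum(diag(H_step)) / q) / mse_w
  F_int <- (sum(diag(H_int)) / q) / mse_w

  ## between-group test on subject means
  m_i <- rowMeans(Y)
  gm <- tapply(m_i, g, mean)
  ss_grp <- sum(n_per_group * (gm - sum(n_per_group * gm) / N)^2) * k
  ss_sub <- sum((m_i - gm[g])^2) * k
  F_grp <- (ss_grp / 1) / (ss_sub / df_e)

  ## Mauchly's sphericity test on the contrast covariance, with the
  ## second-order term of the asymptotic chi-squared expansion
  S <- EM / df_e
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  W <- prod(lam) / (mean(lam))^q
  rho <- 1 - (2 * q^2 + q + 2) / (6 * q * df_e)
  chisq <- -df_e * rho * log(W)
  df_m <- q * (q + 1) / 2 - 1
  w2 <- (q + 2) * (q - 1) * (q - 2) * (2 * q^3 + 6 * q^2 + 3 * k + 2) /
    (288 * (df_e * q * rho)^2)
  pr1 <- pchisq(chisq, df_m, lower.tail = FALSE)
  pr2 <- pchisq(chisq, df_m + 4, lower.tail = FALSE)
  mauchly_p <- pr1 + w2 * (pr2 - pr1)
  eps_gg <- sum(lam)^2 / (q * sum(lam^2))
  corrected <- mauchly_p < sphericity_alpha

  p_step <- pf(F_step, q, q * df_e, lower.tail = FALSE)
  p_int <- pf(F_int, q, q * df_e, lower.tail = FALSE)
  p_step_gg <- pf(F_step, q * eps_gg, q * df_e * eps_gg, lower.tail = FALSE)
  p_int_gg <- pf(F_int, q * eps_gg, q * df_e * eps_gg, lower.tail = FALSE)

  effects <- data.frame(
    effect = c("snp", "step", "step:snp"),
    ss = c(ss_grp, sum(diag(H_step)), sum(diag(H_int))),
    df1 = c(1, q, q),
    df2 = c(df_e, q * df_e, q * df_e),
    F = c(F_grp, F_step, F_int),
    p_uncorrected = c(pf(F_grp, 1, df_e, lower.tail = FALSE), p_step, p_int),
    p = c(pf(F_grp, 1, df_e, lower.tail = FALSE),
          if (corrected) p_step_gg else p_step,
          if (corrected) p_int_gg else p_int)
  )
  structure(list(effects = effects,
                 mauchly = list(W = W, chisq = chisq, df = df_m,
                                p = mauchly_p),
                 epsilon_gg = eps_gg,
                 corrected = corrected,
                 n_per_group = as.vector(n_per_group),
                 group_levels = levels(g),
                 error_ss_within = sum(diag(EM)),
                 error_ss_between = ss_sub),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed-design repeated-measures ANOVA\n")
  cat(sprintf("n per group: %s (%s)\n",
              paste(x$n_per_group, collapse = "/"),
              paste(x$group_levels, collapse = "/")))
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-9s F(%g, %g) = %.2f, p = %.4g\n", eff$effect[i],
                eff$df1[i], eff$df2[i], eff$F[i], eff$p[i]))
  cat(sprintf("Mauchly W = %.4f (p = %.4g); Greenhouse-Geisser eps = %.3f%s\n",
              x$mauchly$W, x$mauchly$p, x$epsilon_gg,
              if (x$corrected) " [correction applied]" else ""))
  invisible(x)
}

#' Bonferroni-corrected per-step post-hoc comparisons
#'
#' For each step label, a Welch two-sample comparison of the two SNP groups;
#' raw p-values are multiplied by the family size (one comparison per step
#' label, 4 by default) and capped at 1.
#'
#' @param data long metric table (columns as in [mixed_anova()]).
#' @param cols column mapping, as in [mixed_anova()].
#' @param step_levels within-factor levels.
#' @param family_size number of comparisons in the Bonferroni family.
#' @return data frame with per-step mean difference (group 2 minus group
#'   1), its standard error, t, df, raw and adjusted p.
#' @export
bonferroni_posthoc <- function(data,
                               cols = c(unit = "unit", group = "group",
                                        step = "step", value = "value"),
                               step_levels = c("pert", "rec1", "rec2", "rec3"),
                               family_size = length(step_levels)) {
  df <- as.data.frame(data)
  g <- factor(df[[cols[["group"]]]])
  lv <- levels(g)
  out <- lapply(step_levels, function(lab) {
    sel <- df[[cols[["step"]]]] == lab
    x <- df[[cols[["value"]]]][sel & g == lv[1]]
    y <- df[[cols[["value"]]]][sel & g == lv[2]]
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    se <- sqrt(vx + vy)
    est <- mean(y) - mean(x)
    if (se == 0) {
      data.frame(step = lab, estimate = est, se = 0, t = NA_real_,
                 df = NA_real_, p_raw = if (est == 0) 1 else 0,
                 p_adj = if (est == 0) 1 else 0)
    } else {
      dfw <- se^4 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
      tt <- est / se
      p <- 2 * pt(-abs(tt), dfw)
      data.frame(step = lab, estimate = est, se = se, t = tt, df = dfw,
                 p_raw = p, p_adj = min(1, p * family_size))
    }
  })
  res <- do.call(rbind, out)
  attr(res, "groups") <- lv
  res
}

#' Welch contrast on first-recovery-step asymmetry
#'
#' Tests whether the difference between intact-side and prosthetic-side
#' perturbation responses on a step changes with the SNP condition: the
#' contrast is `(mean[intact, off] - mean[prosthetic, off]) -
#' (mean[intact, on] - mean[prosthetic, on])`, with an unequal-variance
#' standard error over the four groups and Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param data data frame of (typically rec1) values with perturbed-side
#'   and SNP-condition columns.
#' @param cols named mapping with entries `side`, `group`, `value`.
#' @param side_levels intact/prosthetic level names, intact first.
#' @param group_levels SNP levels, inactive first.
#' @return list of class `welch_result`: `estimate`, `se`, `t`, `df`, `p`,
#'   `degenerate`.
#' @export
welch_asymmetry_test <- function(data,
                                 cols = c(side = "side", group = "group",
                                          value = "value"),
                                 side_levels = c("intact", "prosthetic"),
                                 group_levels = c("inactive", "active")) {
  df <- as.data.frame(data)
  side <- df[[cols[["side"]]]]
  grp <- df[[cols[["group"]]]]
  val <- df[[cols[["value"]]]]
  cells <- list(
    i_off = val[side == side_levels[1] & grp == group_levels[1]],
    p_off = val[side == side_levels[2] & grp == group_levels[1]],
    i_on = val[side == side_levels[1] & grp == group_levels[2]],
    p_on = val[side == side_levels[2] & grp == group_levels[2]])
  if (any(vapply(cells, length, integer(1)) < 2))
    abort_stumblr("every side x condition cell needs at least 2 values",
                  "inference_error")
  m <- vapply(cells, mean, numeric(1))
  vn <- vapply(cells, function(x) var(x) / length(x), numeric(1))
  est <- (m["i_off"] - m["p_off"]) - (m["i_on"] - m["p_on"])
  se <- sqrt(sum(vn))
  if (se == 0)
    return(structure(list(estimate = unname(est), se = 0, t = NA_real_,
                          df = NA_real_, p = NA_real_, degenerate = TRUE),
                     class = "welch_result"))
  dfw <- se^4 / sum(vn^2 / (vapply(cells, length, integer(1)) - 1))
  tt <- unname(est / se)
  structure(list(estimate = unname(est), se = se, t = tt, df = unname(dfw),
                 p = 2 * pt(-abs(tt), dfw), degenerate = FALSE),
            class = "welch_result")
}

#' Handrail-grab tally by perturbed side and SNP condition
#'
#' @param report screening report(s) with logical `handrail_grab`,
#'   `side_label` and an SNP condition column `snp`.
#' @return 2 x 2 integer table (side x condition).
#' @export
handrail_count_table <- function(report) {
  side <- factor(report$side_label, levels = c("intact", "prosthetic"))
  snp <- factor(report$snp, levels = c("inactive", "active"))
  table(side = side[report$handrail_grab], snp = snp[report$handrail_grab])
}

#' Simulate a per-step metric table for calibration studies
#'
#' Draws `n_per_group` analysis units per SNP condition with `k` repeated
#' step measurements each: a common step-mean profile, a per-unit random
#' intercept (compound symmetry) or an AR(1) within-unit covariance, and an
#' additive per-step effect in the second group.
#'
#' @param n_per_group length-2 vector of group sizes (inactive, active).
#' @param mean_profile per-step means shared by both groups.
#' @param effect per-step additive offsets applied to the second group.
#' @param sd_subject between-unit standard deviation (random intercept).
#' @param sd_error within-unit residual standard deviation.
#' @param cor_structure `"cs"` (compound symmetry) or `"ar1"`.
#' @param ar1_rho AR(1) lag-one correlation when `cor_structure = "ar1"`.
#' @return list with the wide matrix `Y`, the `group` factor and the long
#'   data frame `data`.
#' @export
simulate_metric_table <- function(n_per_group = c(60, 60),
                                  mean_profile = c(pert = 8, rec1 = 6,
                                                   rec2 = 4, rec3 = 3),
                                  effect = c(0, 0, 0, 0),
                                  sd_subject = 1,
                                  sd_error = 1,
                                  cor_structure = c("cs", "ar1"),
                                  ar1_rho = 0.6) {
  cor_structure <- match.arg(cor_structure)
  k <- length(mean_profile)
  N <- sum(n_per_group)
  g <- factor(rep(c("inactive", "active"), n_per_group),
              levels = c("inactive", "active"))
  if (cor_structure == "cs") {
    err <- matrix(rnorm(N * k, sd = sd_error), N, k) +
      rnorm(N, sd = sd_subject)
  } else {
    R <- ar1_rho^abs(outer(seq_len(k), seq_len(k), "-"))
    L <- chol(R)
    err <- (matrix(rnorm(N * k), N, k) %*% L) * sd_error +
      rnorm(N, sd = sd_subject)
  }
  Y <- matrix(rep(mean_profile, each = N), N, k) + err
  Y[g == "active", ] <- Y[g == "active", ] +
    matrix(rep(effect, each = sum(g == "active")), ncol = k)
  colnames(Y) <- names(mean_profile)
  long <- data.frame(unit = rep(seq_len(N), k),
                     group = rep(g, k),
                     step = rep(names(mean_profile), each = N),
                     value = as.vector(Y))
  list(Y = Y, group = g, data = long)
}
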