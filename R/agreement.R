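# Method-agreement and validation statistics: Pearson correlation,
# Bland-Altman limits of agreement, Wilcoxon signed-rank / Friedman tests,
# one-way repeated-measures ANOVA with Mauchly's sphericity test and the
# Greenhouse-Geisser correction, Bonferroni adjustment, and exact power /
# sample size for a Pearson correlation test.

#' Pearson correlation between two methods
#'
#' Product-moment correlation with the two-tailed t-based p value, used to
#' assess the strength of linear association between paired measurements from
#' two instruments.
#'
#' @param x,y Paired numeric vectors, n >= 4, finite.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_validate <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (!all(is.finite(c(x, y)))) stop("inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Bland-Altman method agreement
#'
#' Agreement between two measurement methods via the paired differences:
#' the bias is their mean, the limits of agreement are
#' `bias +/- 1.96 * SD(differences)` (sample SD), and proportional bias is
#' assessed by the least-squares slope of the differences on the pairwise
#' means with its t-test p value.
#'
#' @param a,b Paired numeric vectors (method A and method B), n >= 3.
#' @return An `rt_agreement` list: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `prop_slope`, `prop_slope_p`, `n`.
#' @examples
#' bland_altman(c(2, 4, 6), c(1, 2, 3))  # bias 2, loa (0.04, 3.96)
#' @export
bland_altman <- function(a, b) {
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3) stop("Bland-Altman needs at least 3 pairs", call. = FALSE)
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  slope <- NA_real_; slope_p <- NA_real_
  if (stats::sd(m) > 0) {
    fit <- summary(stats::lm(d ~ m))
    slope <- fit$coefficients["m", "Estimate"]
    slope_p <- fit$coefficients["m", "Pr(>|t|)"]
  }
  structure(list(bias = bias, sd_diff = sdd,
                 loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd,
                 prop_slope = slope, prop_slope_p = slope_p, n = n),
            class = "rt_agreement")
}

#' @export
print.rt_agreement <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, LoA [%.3f, %.3f], prop. slope %.4f (p = %.4g)\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$prop_slope, x$prop_slope_p))
  invisible(x)
}

# orthonormal polynomial contrasts across k conditions
ortho_contrasts <- function(k) t(stats::contr.poly(k))

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject F test of a condition effect on a complete subjects-by-
#' conditions matrix. Sphericity is assessed with Mauchly's test on the
#' orthonormal contrast covariance; when violated (Mauchly p < .05, or always
#' with `correction = "GG"`) both degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon before computing the p value. Effect size is
#' partial eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Numeric matrix or data frame, rows = subjects, columns =
#'   conditions; no missing cells (no imputation is attempted).
#' @param correction `"auto"` (apply GG when Mauchly p < .05), `"none"`, or
#'   `"GG"` (always apply).
#' @return An `rt_anova` list: `F`, `df1`, `df2` (corrected when applied),
#'   `p`, `partial_eta_sq`, `mauchly_w`, `mauchly_p`, `gg_epsilon`,
#'   `corrected`, and the uncorrected `df1_uncorrected`, `df2_uncorrected`.
#' @export
rm_anova_gg <- function(data, correction = c("auto", "none", "GG")) {
  correction <- match.arg(correction)
  x <- as.matrix(data)
  if (anyNA(x)) stop("missing cells; repeated-measures ANOVA needs a complete matrix",
                     call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  if (n < k) stop("need at least as many subjects as conditions", call. = FALSE)
  grand <- mean(x)
  ss_cond <- n * sum((colMeans(x) - grand)^2)
  ss_subj <- k * sum((rowMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  Fval <- (ss_cond / df1) / (ss_err / df2)
  # sphericity on the contrast covariance
  C <- ortho_contrasts(k)
  S <- C %*% stats::cov(x) %*% t(C)
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  eps <- sum(lam)^2 / (df1 * sum(lam^2))
  if (k == 2) {
    W <- 1; mauchly_p <- NA_real_; eps <- 1
  } else {
    W <- prod(lam) / (sum(lam) / df1)^df1
    f_corr <- 1 - (2 * df1^2 + df1 + 2) / (6 * df1 * (n - 1))
    chi2 <- -(n - 1) * f_corr * log(max(W, .Machine$double.xmin))
    df_chi <- df1 * (df1 + 1) / 2 - 1
    mauchly_p <- stats::pchisq(chi2, df_chi, lower.tail = FALSE)
  }
  apply_gg <- switch(correction,
                     none = FALSE,
                     GG = TRUE,
                     auto = !is.na(mauchly_p) && mauchly_p < 0.05)
  df1_use <- if (apply_gg) df1 * eps else df1
  df2_use <- if (apply_gg) df2 * eps else df2
  structure(list(F = Fval, df1 = df1_use, df2 = df2_use,
                 p = stats::pf(Fval, df1_use, df2_use, lower.tail = FALSE),
                 partial_eta_sq = ss_cond / (ss_cond + ss_err),
                 mauchly_w = W, mauchly_p = mauchly_p, gg_epsilon = eps,
                 corrected = apply_gg,
                 df1_uncorrected = df1, df2_uncorrected = df2),
            class = "rt_anova")
}

#' @export
print.rt_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g, partial eta^2 = %.3f%s\n",
              x$df1, x$df2, x$F, x$p, x$partial_eta_sq,
              if (x$corrected) sprintf(" [GG epsilon = %.3f]", x$gg_epsilon) else ""))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired-sample rank test for non-normal variables. Zero differences are
#' dropped (Wilcoxon's original rule) and ties receive mid-ranks. The exact
#' distribution is used for 25 or fewer nonzero differences without ties in
#' their absolute values; otherwise the normal approximation with continuity
#' correction.
#'
#' @param a,b Paired numeric vectors.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `statistic` (V), `p`, `n_effective`, `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ok <- stats::complete.cases(a, b)
  d <- a[ok] - b[ok]
  d <- d[d != 0]
  if (!length(d))
    stop("degenerate test: all paired differences are zero", call. = FALSE)
  use_exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, alternative = alternative,
                                            exact = use_exact,
                                            correct = !use_exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_effective = length(d), exact = use_exact)
}

#' Friedman test across repeated conditions
#'
#' Nonparametric k-condition comparison on a complete subjects-by-conditions
#' matrix (chi-square approximation on mean ranks).
#'
#' @param data Numeric matrix or data frame, rows = subjects, columns =
#'   conditions.
#' @return List with `statistic` (chi-square), `df`, `p`.
#' @export
friedman <- function(data) {
  x <- as.matrix(data)
  if (anyNA(x)) stop("missing cells in Friedman test input", call. = FALSE)
  if (all(apply(x, 1, function(r) length(unique(r)) == 1)))
    stop("degenerate test: every subject has identical values across conditions",
         call. = FALSE)
  ft <- stats::friedman.test(x)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value)
}

#' Bonferroni-adjusted alpha
#'
#' Familywise alpha divided by the number of tests, reported at 4 decimals
#' (e.g. 0.05 over 7 tests gives 0.0071; over 12 tests, 0.0042).
#'
#' @param alpha Familywise significance level.
#' @param m Number of tests (>= 1).
#' @return Adjusted per-test alpha, rounded to 4 decimals.
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("number of tests must be at least 1", call. = FALSE)
  round(alpha / m, 4)
}

# --- exact power for a Pearson correlation -------------------------------

# Gauss hypergeometric 2F1(1/2, 1/2; c; x) by its series (|x| <= 1, large c:
# fast convergence).
hyp2f1_half <- function(x, c) {
  term <- 1; s <- 1
  for (k in 0:999) {
    term <- term * (0.5 + k)^2 / ((c + k) * (k + 1)) * x
    s <- s + term
    if (abs(term) < 1e-16 * abs(s)) break
  }
  s
}

# Density of the sample correlation coefficient r from a bivariate normal
# sample of size n with population correlation rho (Hotelling's form).
sample_r_density <- function(r, n, rho) {
  lg <- lgamma(n - 1) - lgamma(n - 0.5)
  base <- (n - 2) / sqrt(2 * pi) * exp(lg) * (1 - rho^2)^((n - 1) / 2) *
    (1 - r^2)^((n - 4) / 2) * (1 - rho * r)^(-(n - 1.5))
  base * vapply(r, function(ri) hyp2f1_half((1 + rho * ri) / 2, n - 0.5), 0)
}

#' Exact power of a Pearson correlation test
#'
#' Power of the t-based test of `rho = 0` at sample size `n` when the true
#' correlation is `effect_r`, computed from the exact sampling distribution
#' of the correlation coefficient under bivariate normality (not the Fisher-z
#' approximation).
#'
#' @param effect_r True population correlation (0 < r < 1).
#' @param n Sample size (>= 4).
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @return Power in (0, 1).
#' @export
power_pearson <- function(effect_r, n, alpha = 0.05, tails = 2) {
  stopifnot(effect_r > 0, effect_r < 1, n >= 4, alpha > 0, alpha < 1,
            tails %in% c(1, 2))
  tc <- stats::qt(1 - alpha / tails, df = n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  hi <- stats::integrate(sample_r_density, rc, 1, n = n, rho = effect_r,
                         rel.tol = 1e-9)$value
  lo <- if (tails == 2)
    stats::integrate(sample_r_density, -1, -rc, n = n, rho = effect_r,
                     rel.tol = 1e-9)$value else 0
  hi + lo
}

#' Minimum sample size for a Pearson correlation test
#'
#' Smallest `n` at which the test of `rho = 0` attains the requested power
#' for a true correlation of `effect_r`. The default method uses the exact
#' sampling distribution of the correlation coefficient under bivariate
#' normality; `method = "fisher_z"` uses the classical approximation
#' `n = ((z_alpha + z_beta) / atanh(r))^2 + 3`, which can differ by one
#' participant (e.g. 47 rather than 46 at r = 0.4, alpha = .05, power = .80).
#'
#' @param effect_r True population correlation (0 < r < 1).
#' @param alpha Significance level.
#' @param power Required power (0 < power < 1).
#' @param tails 1 or 2.
#' @param method `"exact"` or `"fisher_z"`.
#' @return Required sample size (integer, >= 4).
#' @examples
#' power_pearson_n(0.4, 0.05, 0.80)  # 46
#' @export
power_pearson_n <- function(effect_r, alpha = 0.05, power = 0.80, tails = 2,
                            method = c("exact", "fisher_z")) {
  method <- match.arg(method)
  stopifnot(effect_r > 0, effect_r < 1, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (method == "fisher_z") {
    zc <- stats::qnorm(1 - alpha / tails) + stats::qnorm(power)
    return(max(4L, as.integer(ceiling((zc / atanh(effect_r))^2 + 3))))
  }
  for (n in 4:100000) {
    if (power_pearson(effect_r, n, alpha, tails) >= power) return(n)
  }
  stop("requested power unreachable below n = 100000", call. = FALSE)
}

#' Agreement report between two instruments
#'
#' Runs the validation battery over paired per-participant summaries:
#' Pearson correlation and Bland-Altman agreement for each continuous
#' variable, plus Wilcoxon signed-rank comparisons, with a single
#' Bonferroni-adjusted alpha for the family of comparisons.
#'
#' @param com,vr Data frames with one row per participant and identical
#'   numeric columns for the variables to compare (e.g. `rt_median`).
#' @param vars Character vector of column names to analyze; default is all
#'   shared numeric columns.
#' @param alpha Familywise alpha (default 0.05).
#' @return List with `table` (one row per variable: r, r_p, bias, loa_low,
#'   loa_high, prop_slope, prop_slope_p, wilcoxon_p) and `adjusted_alpha`.
#' @export
agreement_report <- function(com, vr, vars = NULL, alpha = 0.05) {
  if (is.null(vars)) {
    vars <- intersect(names(com), names(vr))
    vars <- vars[vapply(com[vars], is.numeric, TRUE)]
  }
  rows <- lapply(vars, function(v) {
    a <- vr[[v]]; b <- com[[v]]
    ok <- stats::complete.cases(a, b)
    r <- tryCatch(pearson_validate(b[ok], a[ok]),
                  error = function(e) list(r = NA_real_, p = NA_real_, n = sum(ok)))
    ba <- tryCatch(bland_altman(a[ok], b[ok]),
                   error = function(e) list(bias = NA_real_, sd_diff = NA_real_,
                                            loa_low = NA_real_, loa_high = NA_real_,
                                            prop_slope = NA_real_, prop_slope_p = NA_real_))
    w <- tryCatch(wilcoxon_signed_rank(a[ok], b[ok])$p,
                  error = function(e) NA_real_)
    data.frame(variable = v, n = sum(ok), r = r$r, r_p = r$p,
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               prop_slope = ba$prop_slope, prop_slope_p = ba$prop_slope_p,
               wilcoxon_p = w, stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows),
       adjusted_alpha = bonferroni(alpha, length(vars)))
}
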