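# Cohort statistics: paired sulci-vs-gyri comparison with effect size,
# one-way ANOVA with Tukey HSD across exposure profiles, two-way mixed
# repeated-measures ANOVA (between = profile, within = region), Pearson
# correlations with Fisher-z intervals, and multiple regression of sulcal
# metrics on peak kinematics. Engines are the classical base-R fits; the
# normality gate (Shapiro-Wilk at alpha) selects t vs Wilcoxon.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Paired sulci-versus-gyri comparison
#'
#' Two-tailed paired comparison of per-impact sulcal and gyral means.
#' Shapiro-Wilk on the paired differences (at `alpha`) selects the paired
#' t-test; when normality is rejected the Wilcoxon signed-rank test is used
#' instead. Cohen's d is the paired variant: mean difference / SD of
#' differences.
#'
#' @param sulcal,gyral Equal-length paired samples (n >= 3).
#' @param alpha Normality-gate level.
#' @return Object of class `paired_compare` with the test used, statistic,
#'   p-value, Cohen's d, group means and SDs. Has a [tidy()] method.
#' @export
paired_compare <- function(sulcal, gyral, alpha = 0.05) {
  n <- length(sulcal)
  if (length(gyral) != n) stop("samples must be paired (equal length)",
                               call. = FALSE)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  diffs <- sulcal - gyral
  sdd <- stats::sd(diffs)
  res <- list(n = n,
              mean_sulcal = mean(sulcal), sd_sulcal = stats::sd(sulcal),
              mean_gyral = mean(gyral), sd_gyral = stats::sd(gyral))
  if (sdd == 0) {
    # degenerate: all differences identical; no distributional test applies
    res <- c(res, list(test = "paired_t", statistic = 0,
                       p_value = if (mean(diffs) == 0) 1 else 0,
                       cohens_d = if (mean(diffs) == 0) 0 else Inf,
                       normality_p = NA_real_))
  } else {
    norm_p <- stats::shapiro.test(diffs)$p.value
    if (norm_p >= alpha) {
      tt <- stats::t.test(sulcal, gyral, paired = TRUE)
      res <- c(res, list(test = "paired_t", statistic = unname(tt$statistic),
                         p_value = tt$p.value))
    } else {
      wt <- suppressWarnings(stats::wilcox.test(sulcal, gyral, paired = TRUE))
      res <- c(res, list(test = "wilcoxon", statistic = unname(wt$statistic),
                         p_value = wt$p.value))
    }
    res$cohens_d <- mean(diffs) / sdd
    res$normality_p <- norm_p
  }
  structure(res, class = "paired_compare")
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Classical between/within sums-of-squares decomposition with degrees of
#' freedom reported as (k - 1, N - k), followed by Tukey HSD pairwise
#' comparisons via the studentized-range distribution. Unadjusted pairwise
#' p-values (pooled SD) are carried alongside for reference.
#'
#' @param values Numeric response.
#' @param group Group labels (coerced to factor; >= 2 groups, each n >= 2).
#' @return Object of class `anova_oneway` with `F`, `df_between`,
#'   `df_residual`, `p_value` and a `posthoc` tibble. Has [tidy()] and
#'   [glance()] methods.
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2)) stop("every group needs n >= 2", call. = FALSE)
  if (stats::sd(values) == 0) {
    # all values identical: no variance to partition
    lv <- levels(group)
    cmb <- utils::combn(lv, 2)
    post <- tibble::tibble(
      comparison = paste(cmb[2, ], cmb[1, ], sep = "-"),
      diff = 0, lwr = 0, upr = 0, p_adj = 1, p_unadj = 1)
    return(structure(list(F = 0, df_between = nlevels(group) - 1L,
                          df_residual = length(values) - nlevels(group),
                          p_value = 1, posthoc = post),
                     class = "anova_oneway"))
  }
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  unadj <- stats::pairwise.t.test(values, group, p.adjust.method = "none",
                                  pool.sd = TRUE)$p.value
  post <- tibble::tibble(comparison = rownames(tk),
                         diff = tk[, "diff"], lwr = tk[, "lwr"],
                         upr = tk[, "upr"], p_adj = tk[, "p adj"])
  post$p_unadj <- vapply(strsplit(post$comparison, "-", fixed = TRUE),
                         function(lv) {
                           p <- unadj[lv[1], lv[2]]
                           if (is.na(p)) p <- unadj[lv[2], lv[1]]
                           p
                         }, numeric(1))
  structure(list(F = tab["group", "F value"],
                 df_between = tab["group", "Df"],
                 df_residual = tab["Residuals", "Df"],
                 p_value = tab["group", "Pr(>F)"],
                 posthoc = post),
            class = "anova_oneway")
}

#' Two-way mixed repeated-measures ANOVA
#'
#' Between-subjects factor `profile`, within-subjects factor `region` (two
#' levels: gyral and sulcal means per impact) and their interaction, via the
#' standard sums-of-squares partition (`aov` with an `Error(subject/region)`
#' stratum). The response is transformed first to meet normality: square
#' root by default, falling back to log when Shapiro-Wilk on the cell
#' residuals still rejects at `alpha`.
#'
#' @param data Data frame in long format.
#' @param value,profile,region,subject Column names (strings).
#' @param transform `"auto"` (sqrt, then log fallback), `"sqrt"`, `"log"` or
#'   `"none"`.
#' @param alpha Level for the normality fallback check.
#' @return Object of class `rm_anova`: tibble of effects (`term`, `df1`,
#'   `df2`, `F`, `p_value`) plus the transform used. Has a [tidy()] method.
#' @export
rm_anova <- function(data, value = "value", profile = "profile",
                     region = "region", subject = "subject",
                     transform = c("auto", "sqrt", "log", "none"),
                     alpha = 0.05) {
  transform <- match.arg(transform)
  d <- data.frame(y = data[[value]],
                  profile = factor(data[[profile]]),
                  region = factor(data[[region]]),
                  subject = factor(data[[subject]]))
  counts <- table(d$subject, d$region)
  if (any(counts != 1))
    stop("incomplete within-subject data: every subject needs exactly one ",
         "value per region", call. = FALSE)
  apply_tf <- function(y, tf) {
    switch(tf,
           none = y,
           sqrt = sqrt(pmax(y, 0)),
           log = {
             off <- if (any(y <= 0)) min(y[y > 0], 1) / 2 else 0
             log(y + off)
           })
  }
  resid_norm_p <- function(y) {
    r <- stats::resid(stats::lm(y ~ profile * region, data = d))
    if (stats::sd(r) == 0) return(1)
    stats::shapiro.test(r)$p.value
  }
  used <- transform
  if (transform == "auto") {
    used <- "sqrt"
    if (resid_norm_p(apply_tf(d$y, "sqrt")) < alpha) used <- "log"
  }
  d$yt <- apply_tf(d$y, used)

  if (stats::sd(d$yt) == 0) {
    eff <- tibble::tibble(term = c("profile", "region", "profile:region"),
                          df1 = NA_integer_, df2 = NA_integer_,
                          F = 0, p_value = 1)
    strata <- tibble::tibble(stratum = character(), term = character(),
                             df = integer(), ss = numeric())
  } else {
    fit <- stats::aov(yt ~ profile * region + Error(subject / region), data = d)
    sm <- summary(fit)
    strata <- dplyr::bind_rows(lapply(names(sm), function(snm) {
      tab <- sm[[snm]][[1]]
      tibble::tibble(stratum = snm, term = trimws(rownames(tab)),
                     df = tab[, "Df"], ss = tab[, "Sum Sq"])
    }))
    pick <- function(stratum, term) {
      tab <- sm[[stratum]][[1]]
      i <- match(term, trimws(rownames(tab)))
      j <- match("Residuals", trimws(rownames(tab)))
      tibble::tibble(term = term, df1 = tab[i, "Df"], df2 = tab[j, "Df"],
                     F = tab[i, "F value"], p_value = tab[i, "Pr(>F)"])
    }
    eff <- dplyr::bind_rows(pick("Error: subject", "profile"),
                            pick("Error: subject:region", "region"),
                            pick("Error: subject:region", "profile:region"))
  }
  structure(list(effects = eff, strata = strata, transform = used,
                 normality_p = if (stats::sd(d$yt) == 0) NA_real_
                               else resid_norm_p(d$yt)),
            class = "rm_anova")
}

.fisher_r2_ci <- function(r, n, conf = 0.95) {
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  lo <- tanh(z - q * se); hi <- tanh(z + q * se)
  if (lo * hi < 0) c(0, max(lo^2, hi^2)) else sort(c(lo^2, hi^2))
}

#' Pearson correlations between kinematics and sulcal deformation
#'
#' Pearson r per response/predictor pair, reported as r^2 with a 95%
#' confidence interval obtained by Fisher z-transform on r, then squared and
#' ordered.
#'
#' @param table A `cohort_table` (or any data frame with the columns).
#' @param responses,predictors Column names to correlate.
#' @param conf Confidence level.
#' @return Tibble of class `kin_correlations`: `response`, `predictor`, `r`,
#'   `r2`, `r2_lo`, `r2_hi`, `p_value`, `n`.
#' @export
kinematics_correlations <- function(table,
                                    responses = c("sulcal_mean_strain",
                                                  "sulcal_mean_strain_rate"),
                                    predictors = c("peak_lin_vel",
                                                   "peak_lin_acc",
                                                   "peak_rot_vel",
                                                   "peak_rot_acc"),
                                    conf = 0.95) {
  cols <- c(responses, predictors)
  d <- table[stats::complete.cases(table[, cols]), cols]
  n <- nrow(d)
  if (n < 4) stop("need at least 4 complete rows", call. = FALSE)
  degen <- cols[vapply(d[cols], function(x) stats::sd(x) == 0, logical(1))]
  if (length(degen))
    stop("zero-variance column(s): ", paste(degen, collapse = ", "),
         call. = FALSE)
  out <- tidyr::expand_grid(response = responses, predictor = predictors)
  res <- purrr::pmap_dfr(out, function(response, predictor) {
    ct <- stats::cor.test(d[[response]], d[[predictor]])
    ci <- .fisher_r2_ci(unname(ct$estimate), n, conf)
    tibble::tibble(response = response, predictor = predictor,
                   r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
                   r2_lo = ci[1], r2_hi = ci[2],
                   p_value = ct$p.value, n = n)
  })
  class(res) <- c("kin_correlations", class(res))
  res
}

#' Multiple regression of a sulcal metric on peak kinematics
#'
#' Ordinary least squares with the four peak-kinematics predictors; reports
#' per-predictor beta, two-sided p and 95% confidence interval, plus the
#' overall R^2. A strongly collinear design (condition number of the scaled
#' design above `kappa_max`) is recorded as a warning in the result while
#' estimates are still returned.
#'
#' @param table A `cohort_table` (or data frame with the columns).
#' @param response Response column, typically `"sulcal_mean_strain"` or
#'   `"sulcal_mean_strain_rate"`.
#' @param predictors Predictor columns.
#' @param conf Confidence level for the intervals.
#' @param kappa_max Condition-number threshold for the collinearity flag.
#' @return Object of class `kin_regression` with a coefficient tibble
#'   (`term`, `beta`, `conf_lo`, `conf_hi`, `p_value`), `r_squared`,
#'   `condition_number`, `collinearity_warning`. Has [tidy()] and
#'   [glance()] methods.
#' @export
kinematics_regression <- function(table, response = "sulcal_mean_strain",
                                  predictors = c("peak_lin_vel",
                                                 "peak_lin_acc",
                                                 "peak_rot_vel",
                                                 "peak_rot_acc"),
                                  conf = 0.95, kappa_max = 100) {
  d <- table[stats::complete.cases(table[, c(response, predictors)]),
             c(response, predictors)]
  if (nrow(d) <= length(predictors) + 2)
    stop("need n > number of predictors + 2", call. = FALSE)
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = d)
  X <- as.matrix(d[, predictors])
  sds <- apply(X, 2, stats::sd)
  cn <- if (any(sds == 0)) Inf else kappa(scale(X), exact = TRUE)
  ci <- suppressWarnings(stats::confint(fit, level = conf))
  cf <- summary(fit)$coefficients
  terms <- rownames(cf)[-1]
  coefs <- tibble::tibble(term = terms,
                          beta = unname(cf[terms, "Estimate"]),
                          conf_lo = unname(ci[terms, 1]),
                          conf_hi = unname(ci[terms, 2]),
                          p_value = unname(cf[terms, "Pr(>|t|)"]))
  r2 <- summary(fit)$r.squared
  if (stats::sd(d[[response]]) == 0) r2 <- 0   # constant response: no fit
  structure(list(response = response, coefficients = coefs,
                 r_squared = r2,
                 condition_number = cn,
                 collinearity_warning = is.infinite(cn) || cn > kappa_max,
                 n = nrow(d)),
            class = "kin_regression")
}

# ---- tidiers ---------------------------------------------------------------

#' @export
tidy.paired_compare <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
                 cohens_d = x$cohens_d, n = x$n,
                 mean_sulcal = x$mean_sulcal, sd_sulcal = x$sd_sulcal,
                 mean_gyral = x$mean_gyral, sd_gyral = x$sd_gyral,
                 normality_p = x$normality_p)
}

#' @export
tidy.anova_oneway <- function(x, ...) x$posthoc

#' @export
glance.anova_oneway <- function(x, ...) {
  tibble::tibble(F = x$F, df_between = x$df_between,
                 df_residual = x$df_residual, p_value = x$p_value)
}

#' @export
tidy.rm_anova <- function(x, ...) x$effects

#' @export
tidy.kin_regression <- function(x, ...) x$coefficients

#' @export
glance.kin_regression <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared,
                 condition_number = x$condition_number,
                 collinearity_warning = x$collinearity_warning, n = x$n)
}

#' @export
print.paired_compare <- function(x, ...) {
  cat(sprintf("<paired_compare> %s: statistic = %.4g, p = %.3g, d = %.3g (n = %d)\n",
              x$test, x$statistic, x$p_value, x$cohens_d, x$n))
  cat(sprintf("  sulcal %.4g ± %.4g vs gyral %.4g ± %.4g\n",
              x$mean_sulcal, x$sd_sulcal, x$mean_gyral, x$sd_gyral))
  invisible(x)
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat(sprintf("<anova_oneway> F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_residual, x$F, x$p_value))
  invisible(x)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> transform = %s\n", x$transform))
  print(x$effects)
  invisible(x)
}

#' @export
print.kin_regression <- function(x, ...) {
  cat(sprintf("<kin_regression> %s ~ kinematics: R^2 = %.3f (n = %d)%s\n",
              x$response, x$r_squared, x$n,
              if (x$collinearity_warning) " [collinear design]" else ""))
  print(x$coefficients)
  invisible(x)
}
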