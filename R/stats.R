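#' Significance tier under the figure-legend star convention
#'
#' Maps a p value to the star tiers used throughout the figures:
#' `n.s.` (p >= 0.05), `*` (< 0.05), `**` (< 0.01), `***` (< 0.005) and
#' `****` (< 0.001). Note the unusual 0.005 cut for three stars; the tiers
#' are configurable.
#'
#' @param p p value(s).
#' @param cuts decreasing tier thresholds.
#' @param stars labels, one more than `cuts` (the first is the
#'   non-significant tier).
#' @return character vector of tier labels.
#' @export
significance_tier <- function(p, cuts = c(0.05, 0.01, 0.005, 0.001),
                              stars = c("n.s.", "*", "**", "***", "****")) {
  stopifnot(length(stars) == length(cuts) + 1)
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    stars[1 + sum(pi < cuts)]
  }, character(1))
}

#' One-way ANOVA with Tukey multiple-comparison post-hoc
#'
#' Fits a one-way fixed-effects ANOVA across the groups and, when requested,
#' all pairwise Tukey honestly-significant-difference comparisons, reporting
#' star tiers for both.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 2), or
#'   a data.frame with columns `value` and `group`.
#' @param tukey compute the Tukey table (default TRUE).
#' @param conf_level confidence level for Tukey intervals.
#' @return object of class `anova_tukey`: list with `F`, `df` (c(between,
#'   within)), `p`, `tier`, and `tukey` (data.frame: `comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj`, `tier`) or NULL.
#' @export
one_way_anova_tukey <- function(groups, tukey = TRUE, conf_level = 0.95) {
  df <- as_grouped_df(groups)
  ng <- nlevels(df$group)
  if (ng < 2) stop("need at least 2 groups")
  nper <- table(df$group)
  if (any(nper < 2)) stop("every group needs at least 2 values")
  if (stats::var(df$value) == 0)
    stop("zero residual variance: all values identical")
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  Fval <- s[["F value"]][1]
  pval <- s[["Pr(>F)"]][1]
  tk <- NULL
  if (tukey) {
    t <- stats::TukeyHSD(fit, conf.level = conf_level)$group
    tk <- data.frame(comparison = rownames(t), diff = t[, "diff"],
                     lwr = t[, "lwr"], upr = t[, "upr"],
                     p_adj = t[, "p adj"],
                     tier = significance_tier(t[, "p adj"]),
                     row.names = NULL)
  }
  structure(list(F = Fval, df = c(between = s$Df[1], within = s$Df[2]),
                 p = pval, tier = significance_tier(pval), tukey = tk),
            class = "anova_tukey")
}

as_grouped_df <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    df <- groups[, c("value", "group")]
  } else {
    stopifnot(is.list(groups), !is.null(names(groups)))
    df <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = rep(names(groups), lengths(groups)))
  }
  df$group <- factor(df$group)
  df
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g %s\n",
              x$df[1], x$df[2], x$F, x$p, x$tier))
  if (!is.null(x$tukey)) {
    cat("Tukey HSD:\n")
    print(x$tukey, digits = 4)
  }
  invisible(x)
}

#' Two-sample Student's t test
#'
#' Two-sided comparison of two groups; equal-variance (classical Student)
#' by default, Welch available via `var_equal = FALSE`.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param var_equal pool the variance (default TRUE).
#' @return list of class `t_result`: `t`, `df`, `p`, `tier`, `mean_diff`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (stats::var(c(a, b)) == 0) stop("zero variance: groups are constant")
  tt <- stats::t.test(a, b, var.equal = var_equal)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, tier = significance_tier(tt$p.value),
                 mean_diff = unname(diff(rev(tt$estimate)))),
            class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("t(%.3g) = %.4g, p = %.4g %s (mean diff %.4g)\n",
              x$df, x$t, x$p, x$tier, x$mean_diff))
  invisible(x)
}

#' Imaging-modality consistency check
#'
#' Tests whether per-cell intensities measured under two imaging modalities
#' (e.g. spinning-disc confocal versus widefield epifluorescence) differ only
#' by a constant factor — the control establishing that intensity differences
#' are not optical artefacts. Per-cell ratios are computed; the verdict is
#' "consistent" when the ratio coefficient of variation stays below
#' `cv_bound` and an intercept adds nothing over the slope-only (through-
#' origin) regression.
#'
#' @param modality1,modality2 paired per-cell values; `modality1` must be
#'   positive (non-positive pairs are dropped with a warning).
#' @param cv_bound CV bound for ratio constancy (default 0.15).
#' @return list of class `modality_report`: `slope` (through-origin),
#'   `intercept` (free fit), `ratio_mean`, `ratio_cv`, `p_intercept`,
#'   `n_used`, `n_dropped`, `verdict` ("consistent"/"inconsistent").
#' @export
modality_consistency <- function(modality1, modality2, cv_bound = 0.15) {
  stopifnot(length(modality1) == length(modality2))
  bad <- !(modality1 > 0) | !is.finite(modality1) | !is.finite(modality2)
  if (any(bad)) {
    warning(sprintf("dropping %d pairs with non-positive modality-1 values",
                    sum(bad)))
    modality1 <- modality1[!bad]; modality2 <- modality2[!bad]
  }
  if (length(modality1) == 0) stop("all pairs dropped")
  if (length(modality1) < 10) stop("need at least 10 valid pairs")
  ratio <- modality2 / modality1
  ratio_cv <- stats::sd(ratio) / mean(ratio)
  slope <- sum(modality1 * modality2) / sum(modality1^2)
  fit0 <- stats::lm(modality2 ~ 0 + modality1)
  fit1 <- stats::lm(modality2 ~ modality1)
  rss1 <- sum(stats::resid(fit1)^2)
  p_int <- if (rss1 < .Machine$double.eps * sum(modality2^2)) {
    1  # exact proportionality: intercept adds nothing
  } else {
    stats::anova(fit0, fit1)[["Pr(>F)"]][2]
  }
  consistent <- ratio_cv < cv_bound && (is.na(p_int) || p_int > 0.05)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit1)[1]),
                 ratio_mean = mean(ratio), ratio_cv = ratio_cv,
                 p_intercept = p_int,
                 n_used = length(modality1), n_dropped = sum(bad),
                 verdict = if (consistent) "consistent" else "inconsistent"),
            class = "modality_report")
}

#' @export
print.modality_report <- function(x, ...) {
  cat(sprintf(
    "modality consistency: slope %.4g, ratio CV %.3f (n = %d) -> %s\n",
    x$slope, x$ratio_cv, x$n_used, x$verdict))
  invisible(x)
}

#' Required culture area for a per-patient cluster dose
#'
#' Scale-up arithmetic for self-assembled cluster production in adherent
#' micropatterned culture: the culture area (cm²) needed to produce a given
#' number of islet-like clusters at a given areal yield. With the reported
#' yield of ~1000 uniform clusters per cm² a therapeutic dose of ~600,000
#' clusters per patient requires 600 cm².
#'
#' @param dose_clusters clusters needed per patient (default 6e5).
#' @param clusters_per_cm2 areal cluster yield (default 1000).
#' @return required area in cm².
#' @export
required_culture_area <- function(dose_clusters = 6e5, clusters_per_cm2 = 1000) {
  if (clusters_per_cm2 <= 0) stop("clusters_per_cm2 must be > 0")
  dose_clusters / clusters_per_cm2
}
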