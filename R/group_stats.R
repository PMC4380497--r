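#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration is used when the combined sample size is at most
#' `exact_max` and there are no ties; otherwise the normal approximation
#' with tie correction (and continuity correction) is used.
#'
#' @param x,y numeric samples (>= 2 values each).
#' @param exact_max combined-size limit for the exact path.
#' @return list with `statistic` (rank-sum W of `x`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
wilcoxon_ranksum <- function(x, y, exact_max = 12L) {
  check_that(length(x) >= 1 && length(y) >= 1, "empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact,
                alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal")
}

#' Linear mixed model for group x time outcomes
#'
#' Fits `outcome ~ group * time + covariates + (1 | subject)` by REML via
#' \pkg{lmerTest} (Satterthwaite degrees of freedom for the p-values),
#' handling missing repeated measures by simply omitting the missing rows.
#' A Shapiro-Wilk residual-normality diagnostic is attached.
#'
#' @param data long-format data frame with columns `subject`, `group`,
#'   `time`, the outcome, and any covariates.
#' @param outcome name of the outcome column.
#' @param covariates character vector of covariate column names.
#' @return data frame with one row per fixed effect (`effect`, `estimate`,
#'   `se`, `df`, `p`), plus attributes `singular` (logical flag; singular
#'   fits are flagged, not silently dropped), `residual_normality_p` and
#'   `fit` (the lmerMod object).
#' @export
mixed_model <- function(data, outcome, covariates = character()) {
  check_that(all(c("subject", "group", "time", outcome) %in% names(data)),
             "data must have subject, group, time and the outcome column")
  rhs <- paste(c("group * time", covariates, "(1 | subject)"), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- lmerTest::lmer(form, data = data,
                        control = lme4::lmerControl(calc.derivs = FALSE))
  singular <- lme4::isSingular(fit)
  sm <- summary(fit)$coefficients
  res <- data.frame(effect = rownames(sm),
                    estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"],
                    df = sm[, "df"],
                    p = sm[, "Pr(>|t|)"],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  r_all <- stats::residuals(fit)
  if (length(r_all) > 5000)  # shapiro.test caps at n = 5000
    r_all <- r_all[round(seq(1, length(r_all), length.out = 5000))]
  resid_p <- tryCatch(stats::shapiro.test(r_all)$p.value,
                      error = function(e) NA_real_)
  attr(res, "singular") <- singular
  attr(res, "residual_normality_p") <- resid_p
  attr(res, "fit") <- fit
  res
}

#' Cohen's d with qualitative effect-size band
#'
#' Pooled-SD standardized mean difference (n - 1 weights, no small-sample
#' correction). Bands: below 0.3 "negligible", 0.3 "small", 0.5 "medium",
#' 0.9 and above "large"; boundaries are inclusive upward (d = 0.5 is
#' "medium").
#'
#' @param x,y numeric samples.
#' @return list with `d` and `band`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  check_that(sp2 > 0, "pooled SD is zero")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  ad <- abs(d)
  band <- if (ad >= 0.9) "large" else if (ad >= 0.5) "medium"
          else if (ad >= 0.3) "small" else "negligible"
  list(d = d, band = band)
}

#' Pearson or Spearman correlation with two-sided p-value
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  check_that(length(x) >= 3, "need at least 3 complete pairs")
  check_that(sd(x) > 0 && sd(y) > 0, "constant input")
  ct <- suppressWarnings(cor.test(x, y, method = method,
                                  alternative = "two.sided"))
  list(r = unname(ct$estimate), p = ct$p.value, method = method)
}

#' Bonferroni adjustment with explicit comparison count
#'
#' `adjusted = min(1, p * m)`; `m` defaults to the number of p-values but
#' can be set to the full comparison count when only a subset is passed.
#'
#' @param p numeric vector of p-values.
#' @param m number of comparisons (>= `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  check_that(m >= length(p), "m must be at least length(p)")
  p.adjust(p, method = "bonferroni", n = m)
}

#' Pooled two-sample t-test from summary statistics
#'
#' The classic equal-variance two-sample t-test computed from printed group
#' means, SDs and sizes (as found in demographic tables), two-sided.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list with `t`, `df`, `p`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  check_that(n1 >= 2 && n2 >= 2, "need n >= 2 per group")
  check_that(sd1 >= 0 && sd2 >= 0, "SDs must be non-negative")
  check_that(sd1 > 0 || sd2 > 0, "both SDs are zero")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums the probabilities
#' of all tables at most as probable as the observed one.
#'
#' @param a,b,c,d cell counts: `a/(a+b)` vs `c/(c+d)` successes per group.
#' @return list with `p` and `odds_ratio` (conditional MLE).
#' @export
fisher_exact <- function(a, b, c, d) {
  check_that(all(c(a, b, c, d) >= 0) &&
             all(c(a, b, c, d) == floor(c(a, b, c, d))),
             "counts must be non-negative integers")
  ft <- fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Group-level effects table for regional water content
#'
#' Runs the full statistical layer on a cohort ROI table: per ROI x tissue
#' outcome, a linear mixed model (group, time, interaction, plus covariates
#' where supplied), Cohen's d for the baseline group difference, a baseline
#' Wilcoxon rank-sum test, and Bonferroni adjustment of the mixed-model
#' p-values over all outcomes tested.
#'
#' @param roi_table a [roi_water_table()] result.
#' @param manifest cohort manifest with `subject`, `group`, `timepoint`
#'   and covariate columns.
#' @param covariates covariate column names of `manifest` to include as
#'   fixed effects (columns with any missing value in the modeled rows are
#'   dropped with a message).
#' @param bonferroni_m comparison count for the adjustment; defaults to the
#'   number of outcomes x 3 effects.
#' @return `effects_table` data frame with columns `outcome`, `effect`,
#'   `estimate`, `se`, `p`, `p_adjusted`, `d`, `band`, `wilcoxon_p`,
#'   `singular`.
#' @export
effects_table <- function(roi_table, manifest, covariates = character(),
                          bonferroni_m = NULL) {
  df <- merge(roi_table,
              unique(manifest[, c("subject", "group", "timepoint",
                                  covariates), drop = FALSE]),
              by = c("subject", "group", "timepoint"))
  df$outcome_id <- paste(df$roi, df$tissue, sep = ":")
  df$time <- factor(df$timepoint)
  df$group <- factor(df$group)
  outcomes <- sort(unique(df$outcome_id))
  rows <- list()
  for (oc in outcomes) {
    d_oc <- df[df$outcome_id == oc, ]
    covs <- covariates[vapply(covariates, function(cv)
      !anyNA(d_oc[[cv]]), logical(1))]
    mm <- tryCatch(mixed_model(d_oc, "mean_water", covs),
                   error = function(e) NULL)
    if (is.null(mm)) next
    x1 <- d_oc$mean_water[d_oc$group == levels(d_oc$group)[2] &
                          d_oc$timepoint == 1]
    y1 <- d_oc$mean_water[d_oc$group == levels(d_oc$group)[1] &
                          d_oc$timepoint == 1]
    dd <- tryCatch(cohens_d(x1, y1), error = function(e)
      list(d = NA_real_, band = NA_character_))
    wp <- tryCatch(wilcoxon_ranksum(x1, y1)$p, error = function(e) NA_real_)
    keep <- grepl("^group|^time|:", mm$effect) & mm$effect != "(Intercept)"
    eff <- mm[keep, ]
    eff$outcome <- oc
    eff$d <- dd$d; eff$band <- dd$band; eff$wilcoxon_p <- wp
    eff$singular <- attr(mm, "singular")
    rows[[oc]] <- eff
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m <- if (is.null(bonferroni_m)) nrow(out) else bonferroni_m
  out$p_adjusted <- bonferroni(out$p, m)
  out <- out[, c("outcome", "effect", "estimate", "se", "df", "p",
                 "p_adjusted", "d", "band", "wilcoxon_p", "singular")]
  structure(out, class = c("effects_table", "data.frame"))
}

#' Correlations between clinical covariates and regional water content
#'
#' For each ROI x tissue outcome and each covariate, computes Pearson and
#' Spearman correlations of the covariate with the subjects' baseline
#' (timepoint 1) regional water, within the group carrying the covariate.
#'
#' @param roi_table a [roi_water_table()] result.
#' @param manifest cohort manifest.
#' @param covariates covariate column names.
#' @return data frame (`outcome`, `covariate`, `method`, `r`, `p`, `n`).
#' @export
covariate_correlations <- function(roi_table, manifest,
                                   covariates = c("vintage_months",
                                                  "weight_change_kg")) {
  base <- roi_table[roi_table$timepoint == 1, ]
  man1 <- unique(manifest[manifest$timepoint == 1,
                          c("subject", covariates), drop = FALSE])
  df <- merge(base, man1, by = "subject")
  df$outcome_id <- paste(df$roi, df$tissue, sep = ":")
  rows <- list()
  for (oc in unique(df$outcome_id)) {
    d_oc <- df[df$outcome_id == oc, ]
    for (cv in covariates) {
      ok <- is.finite(d_oc[[cv]]) & is.finite(d_oc$mean_water)
      if (sum(ok) < 3) next
      for (meth in c("pearson", "spearman")) {
        ct <- tryCatch(correlate(d_oc[[cv]][ok], d_oc$mean_water[ok], meth),
                       error = function(e) NULL)
        if (is.null(ct)) next
        rows[[length(rows) + 1]] <- data.frame(
          outcome = oc, covariate = cv, method = meth,
          r = ct$r, p = ct$p, n = sum(ok), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(outcome = character(),
                                      covariate = character(),
                                      method = character(), r = numeric(),
                                      p = numeric(), n = integer())
  rownames(out) <- NULL
  out
}
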