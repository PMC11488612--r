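#' Two-group comparison with normality QC
#'
#' Student's (pooled-variance) two-sample t test between the two group
#' levels, with per-group Shapiro-Wilk normality p-values reported as a QC
#' flag (no automatic switch to a nonparametric test). Welch's correction is
#' available via `var_equal = FALSE`.
#'
#' @param data A data frame.
#' @param value Column name of the per-subject scalar (e.g. an ALPS index or
#'   a cognitive score).
#' @param group Column name of the two-level group label; the t statistic is
#'   `mean(first level) - mean(second level)` in factor-level order.
#' @param var_equal Pooled variance (Student's t, default) or Welch.
#' @return A one-row tibble: group means/SDs/ns, `t`, `df`, `p_value`, and
#'   `shapiro_p_<level>` per group.
#' @export
group_compare <- function(data, value, group = "group", var_equal = TRUE) {
  v <- data[[value]]
  g <- factor(data[[group]])
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) != 2L) stop("`group` must have exactly two levels", call. = FALSE)
  lv <- levels(g)
  n1 <- sum(g == lv[1]); n2 <- sum(g == lv[2])
  if (n1 < 3L || n2 < 3L) stop("need >= 3 subjects per group", call. = FALSE)
  tt <- stats::t.test(v[g == lv[1]], v[g == lv[2]], var.equal = var_equal)
  sw <- lapply(lv, function(l) {
    x <- v[g == l]
    if (stats::var(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  })
  out <- tibble::tibble(
    variable = value,
    group1 = lv[1], group2 = lv[2], n1 = n1, n2 = n2,
    mean1 = mean(v[g == lv[1]]), sd1 = stats::sd(v[g == lv[1]]),
    mean2 = mean(v[g == lv[2]]), sd2 = stats::sd(v[g == lv[2]]),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
  out[[paste0("shapiro_p_", lv[1])]] <- sw[[1]]
  out[[paste0("shapiro_p_", lv[2])]] <- sw[[2]]
  out
}

#' Spearman partial correlation
#'
#' Rank-transforms `x`, `y` and the covariates (midranks for ties), partials
#' the covariates out of the ranked `x` and `y` by OLS, and correlates the
#' residuals. The p-value uses the t approximation with
#' `df = n - 2 - n_covariates`. With no covariates this equals the plain
#' Spearman rank correlation.
#'
#' @param data A data frame.
#' @param x,y Column names.
#' @param covariates Character vector of covariate columns (may be empty).
#' @return A one-row tibble: `rho`, `statistic`, `df`, `p_value`, `n`.
#' @export
spearman_partial <- function(data, x, y, covariates = character()) {
  cols <- c(x, y, covariates)
  d <- data[cols]
  d <- d[stats::complete.cases(d), ]
  n <- nrow(d)
  k <- length(covariates)
  if (n < k + 4L) stop("need n >= number of covariates + 4", call. = FALSE)
  R <- vapply(d, rank, numeric(n))
  rx <- R[, 1]; ry <- R[, 2]
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("constant variable after ranking", call. = FALSE)
  }
  if (k > 0) {
    Z <- cbind(1, R[, -(1:2), drop = FALSE])
    rx <- .lm.fit(Z, rx)$residuals
    ry <- .lm.fit(Z, ry)$residuals
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  stat <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  if (abs(rho) >= 1) p <- 0
  tibble::tibble(x = x, y = y, rho = rho, statistic = stat, df = df,
                 p_value = p, n = n)
}

#' Regression of a cognitive score on the ALPS index
#'
#' OLS of the score on the ALPS index, education years and age, reporting
#' the unstandardized ALPS coefficient with its 95% CI and two-sided
#' p-value. `direction = "alps_outcome"` offers the reversed orientation
#' (ALPS as the dependent variable, score as a regressor).
#'
#' @param data A data frame.
#' @param score Column name of the cognitive score.
#' @param alps,age,education Column names of the regressors.
#' @param direction `"score_outcome"` (default) or `"alps_outcome"`.
#' @param conf_level CI level (default 0.95).
#' @return A one-row tibble: `score`, `beta`, `ci_lower`, `ci_upper`,
#'   `p_value`, `n`.
#' @export
cognition_regression <- function(data, score, alps = "alps_bilateral",
                                 age = "age", education = "education",
                                 direction = c("score_outcome", "alps_outcome"),
                                 conf_level = 0.95) {
  direction <- match.arg(direction)
  cols <- c(score, alps, age, education)
  d <- data[cols]
  names(d) <- c("score", "alps", "age", "education")
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 10L) stop("need >= 10 complete cases", call. = FALSE)
  fml <- if (direction == "score_outcome") {
    score ~ alps + education + age
  } else {
    alps ~ score + education + age
  }
  term <- if (direction == "score_outcome") "alps" else "score"
  X <- stats::model.matrix(fml, d)
  if (qr(X)$rank < ncol(X)) stop("collinear regressors", call. = FALSE)
  fit <- stats::lm(fml, data = d)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, term, level = conf_level)
  tibble::tibble(
    score = score, beta = sm[term, "Estimate"],
    ci_lower = ci[1], ci_upper = ci[2],
    p_value = sm[term, "Pr(>|t|)"], n = nrow(d)
  )
}

#' Table-style cohort summaries
#'
#' Runs [group_compare()] over every cognitive score (plus any extra
#' columns) and [cognition_regression()] over every score, mirroring the
#' demographics-comparison and ALPS-regression tables of a typical
#' case-control report.
#'
#' @param data Cohort tibble containing an ALPS column.
#' @param alps Column name of the ALPS index.
#' @param scores Character vector of score columns; defaults to the
#'   intersection of [cognitive_score_info()] tests with `names(data)`.
#' @param adjust Optional p-adjustment method for the regression table
#'   (e.g. `"BH"`); default `"none"`, matching an analysis with no
#'   multiple-testing correction across subdomains.
#' @return A list of two tibbles: `group_comparison` and `alps_regression`.
#' @export
cohort_tables <- function(data, alps = "alps_bilateral", scores = NULL,
                          adjust = "none") {
  if (is.null(scores)) {
    scores <- intersect(cognitive_score_info()$test, names(data))
  }
  gc_tab <- dplyr::bind_rows(lapply(c(scores, alps), function(s) {
    group_compare(data, s)
  }))
  reg_tab <- dplyr::bind_rows(lapply(scores, function(s) {
    cognition_regression(data, s, alps = alps)
  }))
  reg_tab$p_adjusted <- stats::p.adjust(reg_tab$p_value, method = adjust)
  list(group_comparison = gc_tab, alps_regression = reg_tab)
}
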