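#' Finite-population sample size
#'
#' Sample size for estimating a proportion in a finite population:
#' `n = N Z^2 p q / (e^2 (N - 1) + Z^2 p q)`, where `N` is the population
#' size, `Z` the confidence statistic, `p`/`q` the success and failure
#' probabilities and `e` the maximum accepted estimation error.
#'
#' @param N population size (>= 1).
#' @param Z confidence statistic.
#' @param p,q success / failure probability (must sum to 1).
#' @param e maximum estimation error (> 0).
#' @return List with `n_real` and the rounded `n`.
#' @export
sample_size <- function(N, Z, p, q, e) {
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) stop("p, q must lie in (0, 1)")
  if (abs(p + q - 1) > 1e-9) stop("p and q must sum to 1")
  if (e <= 0) stop("e must be > 0")
  if (N < 1) stop("N must be >= 1")
  n <- N * Z^2 * p * q / (e^2 * (N - 1) + Z^2 * p * q)
  list(n_real = n, n = round(n))
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Compares the empirical CDF against a normal distribution with the given
#' (or sample-estimated) mean and sd, using the asymptotic p-value. With
#' estimated parameters the standard KS p-value is conservative (the
#' Lilliefors caveat); pass the known parameters when calibration matters.
#'
#' @param values numeric sample, n >= 5.
#' @param mean,sd reference normal parameters; `NULL` = estimate from the
#'   sample.
#' @return List with `statistic` (D), `p_value`, and the reference
#'   `mean` / `sd` used.
#' @export
ks_normality <- function(values, mean = NULL, sd = NULL) {
  if (length(values) < 5) stop("need at least 5 values")
  if (is.null(mean)) mean <- base::mean(values)
  if (is.null(sd)) sd <- stats::sd(values)
  if (!is.finite(sd) || sd == 0) stop("zero variance: KS test undefined")
  ht <- suppressWarnings(stats::ks.test(values, "pnorm", mean, sd,
                                        exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       mean = mean, sd = sd)
}

#' Two-sample t-test on raw data
#'
#' Thin wrapper around [stats::t.test()] reporting (t, df, two-sided p);
#' Welch (unequal variances) by default, pooled-variance Student on
#' request, paired for hemisphere comparisons where records align.
#'
#' @param values_a,values_b the two groups (each n >= 2).
#' @param variant `"welch"` (default) or `"student"`.
#' @param paired logical; paired test (groups must align).
#' @return List with `t`, `df`, `p_value`.
#' @export
t_test <- function(values_a, values_b, variant = c("welch", "student"),
                   paired = FALSE) {
  variant <- match.arg(variant)
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs >= 2 values")
  ht <- stats::t.test(values_a, values_b, var.equal = variant == "student",
                      paired = paired)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the t statistic from per-group mean, sd and n, for comparing a
#' cohort against published study summaries. Welch by default
#' (Welch-Satterthwaite df); pooled Student on request.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (sd > 0, n >= 2).
#' @param variant `"welch"` or `"student"`.
#' @return List with `t`, `df`, `p_value` (two-sided).
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           variant = c("welch", "student")) {
  variant <- match.arg(variant)
  if (sd1 <= 0 || sd2 <= 0 || n1 < 2 || n2 < 2) stop("invalid summaries")
  if (variant == "welch") {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Quadratic volume-age fit
#'
#' Degree-2 polynomial fit of volume on age, by ordinary least squares or
#' two weighted variants: `wls_residual` re-weights an initial OLS fit by
#' the reciprocal absolute residual `1 / (|r| + eps)` (down-weighting
#' outliers); `wls_binned` groups ages into 5-year bins and uses each bin's
#' mean volume as the weight of its members; `wls_raw_residual` uses the
#' raw absolute residuals as weights (up-weighting outliers) and exists
#' only for fidelity experiments. R^2 is computed on the weighted fit.
#'
#' @param cohort a `cohort_table` (or data.frame with `age`, `volume_cm3`).
#' @param scheme one of `"ols"`, `"wls_residual"`, `"wls_binned"`,
#'   `"wls_raw_residual"`.
#' @param eps floor inside the reciprocal-residual weights.
#' @return List of class `fit_result`: `coefficients` (intercept, age,
#'   age^2), `r_squared`, `peak_age`, `peak_volume`, `vertex_defined`,
#'   `scheme`.
#' @export
fit_volume_age <- function(cohort,
                           scheme = c("ols", "wls_residual", "wls_binned",
                                      "wls_raw_residual"),
                           eps = 1e-3) {
  scheme <- match.arg(scheme)
  if (nrow(cohort) < 6) stop("need >= 6 records")
  age <- cohort$age
  vol <- cohort$volume_cm3
  if (diff(range(age)) < 1e-9) stop("insufficient spread in age")
  w <- switch(scheme,
    ols = rep(1, length(age)),
    wls_residual = {
      r <- stats::residuals(stats::lm(vol ~ age + I(age^2)))
      1 / (abs(r) + eps)
    },
    wls_raw_residual = {
      r <- stats::residuals(stats::lm(vol ~ age + I(age^2)))
      abs(r) + eps
    },
    wls_binned = {
      bins <- floor((age - 18) / 5)
      stats::ave(vol, bins, FUN = mean)
    })
  fit <- stats::lm(vol ~ age + I(age^2), weights = w)
  cf <- stats::coef(fit)
  a2 <- unname(cf[3])
  vertex_defined <- is.finite(a2) && abs(a2) > 1e-9
  peak_age <- if (vertex_defined) -unname(cf[2]) / (2 * a2) else NA_real_
  peak_volume <- if (vertex_defined)
    unname(cf[1]) + unname(cf[2]) * peak_age + a2 * peak_age^2 else NA_real_
  # weighted R^2
  fitted <- stats::fitted(fit)
  ybar <- sum(w * vol) / sum(w)
  r2 <- 1 - sum(w * (vol - fitted)^2) / sum(w * (vol - ybar)^2)
  structure(list(coefficients = cf, r_squared = r2, peak_age = peak_age,
                 peak_volume = peak_volume, vertex_defined = vertex_defined,
                 scheme = scheme),
            class = "fit_result")
}

#' Group summary with pairwise comparison
#'
#' Per-group mean, sd and n of a descriptor plus the mean difference under
#' the study's sign conventions (male - female, right - left,
#' rater2 - rater1) and the corresponding two-sample t-test. No
#' multiple-testing adjustment is applied (flagged in the output).
#'
#' @param cohort a `cohort_table`.
#' @param by `"sex"`, `"hemisphere"` or `"rater"`.
#' @param descriptor column to summarize (default `volume_cm3`).
#' @param variant,paired passed to [t_test()].
#' @return List with `summary` (data.frame group/mean/sd/n), `difference`,
#'   `t_test`, `sign_convention`, `p_adjustment = "none"`.
#' @export
group_summary <- function(cohort, by = c("sex", "hemisphere", "rater"),
                          descriptor = "volume_cm3",
                          variant = c("welch", "student"), paired = FALSE) {
  by <- match.arg(by)
  col <- switch(by, sex = "sex", hemisphere = "hemisphere", rater = "rater")
  hi <- switch(by, sex = "M", hemisphere = "R", rater = 2L)
  lo <- switch(by, sex = "F", hemisphere = "L", rater = 1L)
  g <- cohort[[col]]
  x <- cohort[[descriptor]]
  if (length(unique(g)) < 2) stop("need two non-empty groups")
  smry <- do.call(rbind, lapply(unique(g), function(lev) {
    data.frame(group = as.character(lev), mean = mean(x[g == lev]),
               sd = stats::sd(x[g == lev]), n = sum(g == lev))
  }))
  # toy tables with one record per group still summarize; no test possible
  tt <- tryCatch(t_test(x[g == hi], x[g == lo], variant = variant,
                        paired = paired),
                 error = function(e) list(t = NA_real_, df = NA_real_,
                                          p_value = NA_real_))
  list(summary = smry,
       difference = mean(x[g == hi]) - mean(x[g == lo]),
       sign_convention = paste(hi, "-", lo),
       t_test = tt,
       p_adjustment = "none")
}

#' Average of the two raters' descriptor means
#'
#' The arithmetic mean of the per-rater means, rounded to the reporting
#' precision (2 decimals) used in the descriptor comparison tables.
#'
#' @param rater1_mean,rater2_mean the two rater means (same units).
#' @param digits rounding for reporting.
#' @return Rounded average.
#' @export
rater_average <- function(rater1_mean, rater2_mean, digits = 2) {
  round((rater1_mean + rater2_mean) / 2, digits)
}

#' Descriptor pattern of low-volume hippocampi
#'
#' Flags records whose volume is at or below a per-rater threshold and, for
#' each other descriptor, reports where the flagged subgroup's mean sits
#' within the full distribution (mean percentile, 50 = indistinguishable).
#' This operationalizes reading "where the low-volume dots fall relative to
#' the mean" off a distribution plot.
#'
#' @param cohort a `cohort_table`.
#' @param thresholds named numeric, cm^3 per rater (names `"1"`, `"2"`).
#' @param descriptors descriptor columns to probe.
#' @return data.frame with `descriptor`, `n_flagged`, `mean_percentile`;
#'   zero rows when nothing is flagged.
#' @export
low_volume_probe <- function(cohort, thresholds = c(`1` = 2.3, `2` = 2.4),
                             descriptors = c("aspect_ratio", "diameter_cm",
                                             "roundness", "sphericity",
                                             "vs_ratio")) {
  if (any(thresholds <= 0)) stop("thresholds must be > 0")
  thr <- thresholds[as.character(cohort$rater)]
  flagged <- which(cohort$volume_cm3 <= thr)
  if (length(flagged) == 0)
    return(data.frame(descriptor = character(), n_flagged = integer(),
                      mean_percentile = numeric()))
  do.call(rbind, lapply(descriptors, function(d) {
    all_v <- cohort[[d]]
    pct <- 100 * stats::ecdf(all_v)(all_v[flagged])
    data.frame(descriptor = d, n_flagged = length(flagged),
               mean_percentile = mean(pct))
  }))
}
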