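# Replicate variability (CV) summaries and two-sample t-test power planning:
# power for a given fold change and CV, the minimally detectable fold, and
# the maximum CV at which a target fold stays detectable.

#' Coefficient of variation of replicate measurements
#'
#' `cv = 100 * sample SD / mean`, requiring a positive mean.
#'
#' @param values Numeric vector of at least 2 measurements.
#' @return One-row tibble: `mean`, `sd`, `cv`.
#' @export
#' @examples
#' cv_per_feature(c(1, 2, 3))
cv_per_feature <- function(values) {
  if (length(values) < 2) abort("at least 2 measurements are required")
  m <- mean(values)
  if (m <= 0) abort("mean must be > 0 for a coefficient of variation")
  s <- sd(values)
  tibble::tibble(mean = m, sd = s, cv = 100 * s / m)
}

#' Per-feature CV report across replicate slides
#'
#' Computes the CV of the mean signal intensities across hybridizations for
#' each feature (the study uses 6 slides: 2 dyes x 3 biological replicates)
#' and expresses each CV's rank on a 100-based scale.
#'
#' @param intensities Tidy tibble: `feature_id`, `slide_id`, `intensity`.
#' @return Tibble of class `cv_report`: `feature_id`, `mean`, `sd`, `cv`,
#'   `rank_100`.
#' @export
cv_report <- function(intensities) {
  out <- intensities |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      mean = mean(.data$intensity),
      sd = sd(.data$intensity),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$mean > 0) |>
    dplyr::mutate(cv = 100 * .data$sd / .data$mean,
                  rank_100 = cv_rank_scale(.data$cv))
  class(out) <- c("cv_report", class(out))
  out
}

#' Express CV ranks on a 100-based scale
#'
#' `rank_100 = 100 * rank / count`, with ties sharing their mean rank.
#'
#' @param cvs Numeric vector of CVs (at least 1).
#' @return Numeric vector of ranks in `(0, 100]`.
#' @export
cv_rank_scale <- function(cvs) {
  if (length(cvs) < 1) abort("at least one CV is required")
  100 * rank(cvs, ties.method = "average") / length(cvs)
}

#' P90 of a CV distribution
#'
#' The CV at the smallest 100-based rank at or above `q`: the
#' `ceiling(q/100 * n)`-th order statistic.
#'
#' @param cvs Numeric vector of CVs.
#' @param q Rank on the 100-based scale (default 90).
#' @return Numeric scalar.
#' @export
cv_p90 <- function(cvs, q = 90) {
  sort(cvs)[ceiling(q / 100 * length(cvs))]
}

cv_to_sigma <- function(cv) sqrt(log(1 + (cv / 100)^2))

#' Analytic power of a two-sample t-test for an expression fold change
#'
#' Under the default lognormal (multiplicative) noise model, a raw-scale CV
#' maps to a log-scale SD `sigma = sqrt(ln(1 + cv^2))` and the test is the
#' equal-variance two-sample t on log values: noncentrality
#' `ln(fold) / (sigma * sqrt(2/n))` with `2n - 2` degrees of freedom. Under
#' the `additive_cv` model the group means are 1 and `fold` with SDs
#' `cv * mean`, using Welch-Satterthwaite degrees of freedom. Both report
#' the two-sided rejection probability.
#'
#' @param n_per_group Measurements per group (>= 2).
#' @param cv Coefficient of variation in percent.
#' @param fold Fold change >= 1 (use the reciprocal for down-regulation).
#' @param alpha Two-sided Type I error rate.
#' @param model `"lognormal"` (default) or `"additive_cv"`.
#' @return Power in `[0, 1]` (numeric scalar; vectorised over the first
#'   four arguments).
#' @export
#' @examples
#' power_two_sample_t(n_per_group = 6, cv = 35, fold = 2, alpha = 0.10)
power_two_sample_t <- function(n_per_group, cv, fold, alpha = 0.10,
                               model = c("lognormal", "additive_cv")) {
  model <- match.arg(model)
  if (any(fold < 1)) abort("`fold` must be >= 1 (use the reciprocal)")
  if (any(n_per_group < 2)) abort("`n_per_group` must be >= 2")
  assert_prob(alpha)
  args <- vctrs_recycle(n_per_group = n_per_group, cv = cv, fold = fold,
                        alpha = alpha)
  with(args, {
    if (model == "lognormal") {
      sigma <- cv_to_sigma(cv)
      ncp <- log(fold) / (sigma * sqrt(2 / n_per_group))
      df <- 2 * n_per_group - 2
    } else {
      s1 <- cv / 100; s2 <- cv / 100 * fold
      se <- sqrt((s1^2 + s2^2) / n_per_group)
      ncp <- (fold - 1) / se
      v1 <- s1^2 / n_per_group; v2 <- s2^2 / n_per_group
      df <- (v1 + v2)^2 / (v1^2 / (n_per_group - 1) +
                             v2^2 / (n_per_group - 1))
    }
    tc <- qt(1 - alpha / 2, df)
    pt(-tc, df, ncp) + 1 - pt(tc, df, ncp)
  })
}

# minimal recycling helper (keeps the power functions vectorised)
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Monte-Carlo check of the two-sample t-test power
#'
#' Simulates the two-group experiment under the lognormal model and reports
#' the empirical two-sided rejection rate, as an independent check on
#' [power_two_sample_t()].
#'
#' @inheritParams power_two_sample_t
#' @param n_sim Number of simulated experiments.
#' @param seed Integer seed.
#' @return Empirical power (numeric scalar).
#' @export
monte_carlo_power <- function(n_per_group, cv, fold, alpha = 0.10,
                              n_sim = 1e5, seed = 1) {
  sigma <- cv_to_sigma(cv)
  with_seed(seed, {
    x1 <- matrix(rnorm(n_per_group * n_sim, 0, sigma), n_per_group)
    x2 <- matrix(rnorm(n_per_group * n_sim, log(fold), sigma), n_per_group)
    m1 <- colMeans(x1); m2 <- colMeans(x2)
    v1 <- colSums((x1 - rep(m1, each = n_per_group))^2) / (n_per_group - 1)
    v2 <- colSums((x2 - rep(m2, each = n_per_group))^2) / (n_per_group - 1)
    sp <- sqrt((v1 + v2) / 2)
    tstat <- (m2 - m1) / (sp * sqrt(2 / n_per_group))
    tc <- qt(1 - alpha / 2, 2 * n_per_group - 2)
    mean(abs(tstat) > tc)
  })
}

#' Minimally detectable fold change
#'
#' The smallest fold change detected with at least `target_power` by the
#' two-sample t-test, found by bisection on [power_two_sample_t()] to a
#' relative tolerance of 1e-4.
#'
#' @inheritParams power_two_sample_t
#' @param target_power Target power in `(alpha, 1)`.
#' @return Fold change (numeric scalar).
#' @export
min_detectable_fold <- function(n_per_group, cv, alpha = 0.10,
                                target_power = 0.90,
                                model = c("lognormal", "additive_cv")) {
  model <- match.arg(model)
  if (target_power <= alpha || target_power >= 1) {
    abort("`target_power` must lie in (alpha, 1)")
  }
  f <- function(fold) {
    power_two_sample_t(n_per_group, cv, fold, alpha, model) - target_power
  }
  lo <- 1 + 1e-9
  hi <- 2
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e6) abort("no detectable fold below 1e6; check inputs")
  }
  bisect(f, lo, hi, rel_tol = 1e-4)
}

#' Maximum CV at which a fold change stays detectable
#'
#' The largest CV (percent) for which the two-sample t-test still reaches
#' `target_power` for the given fold change, by bisection (power is
#' decreasing in CV).
#'
#' @inheritParams min_detectable_fold
#' @return CV in percent (numeric scalar).
#' @export
max_cv_for_power <- function(n_per_group, fold, alpha = 0.10,
                             target_power = 0.90,
                             model = c("lognormal", "additive_cv")) {
  model <- match.arg(model)
  if (target_power <= alpha || target_power >= 1) {
    abort("`target_power` must lie in (alpha, 1)")
  }
  f <- function(cv) {
    target_power - power_two_sample_t(n_per_group, cv, fold, alpha, model)
  }
  lo <- 1e-6
  if (f(lo) > 0) abort("target power unreachable even at CV ~ 0")
  hi <- 10
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e6) abort("power never drops below target; check inputs")
  }
  bisect(f, lo, hi, rel_tol = 1e-4)
}

# bisection for a monotone increasing sign change on [lo, hi]
bisect <- function(f, lo, hi, rel_tol = 1e-4) {
  repeat {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
    if ((hi - lo) / max(abs(hi), 1) < rel_tol) break
  }
  (lo + hi) / 2
}

#' Power over a parameter grid
#'
#' Evaluates [power_two_sample_t()] over the cross product of the supplied
#' parameter values, for planning tables and curves.
#'
#' @inheritParams power_two_sample_t
#' @return Tibble of class `power_grid`: one row per combination with a
#'   `power` column.
#' @export
power_grid <- function(n_per_group = 6, cv = c(20, 35, 42),
                       fold = c(1.25, 1.5, 2, 2.5), alpha = 0.10,
                       model = c("lognormal", "additive_cv")) {
  model <- match.arg(model)
  grid <- tidyr::expand_grid(n_per_group = n_per_group, cv = cv,
                             fold = fold, alpha = alpha)
  grid$power <- power_two_sample_t(grid$n_per_group, grid$cv, grid$fold,
                                   grid$alpha, model)
  grid$model <- model
  class(grid) <- c("power_grid", class(grid))
  grid
}
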