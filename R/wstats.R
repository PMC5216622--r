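# Weighted and unweighted summary statistics and Welch two-sample tests.
#
# The SE convention follows the study design: sd / sqrt(n_obs), where n_obs is
# the number of measured cysts for observation-level statistics but the number
# of species for interspecific (species-level) statistics — at the
# interspecific level each species contributes one trait value, so the
# effective number of observations is the species count, not the cyst count.

#' Construct a weighted sample
#'
#' Bundles trait values with non-negative weights and an effective number of
#' observations. `n_obs` defaults to the number of values; for species-level
#' (interspecific) samples it equals the number of species, which is also the
#' number of values, so the default is almost always right — it is exposed
#' because the degrees of freedom of weighted tests flow from it.
#'
#' @param values Numeric vector of trait values (μm).
#' @param weights Non-negative numeric vector, same length as `values`; at
#'   least one weight must be positive. Only relative size matters.
#' @param n_obs Effective number of observations (default `length(values)`).
#' @return An object of class `weighted_sample`.
#' @export
weighted_sample <- function(values, weights = rep(1, length(values)),
                            n_obs = length(values)) {
  if (length(values) != length(weights)) {
    ps_stop("values and weights must have equal length", "paleosize_validation_error")
  }
  if (any(weights < 0) || all(weights == 0)) {
    ps_stop("weights must be non-negative with at least one positive",
            "paleosize_degenerate_error")
  }
  structure(list(values = as.numeric(values), weights = as.numeric(weights),
                 n_obs = as.integer(n_obs)),
            class = "weighted_sample")
}

.as_ws <- function(x) {
  if (inherits(x, "weighted_sample")) x else weighted_sample(x)
}

#' Weighted mean
#'
#' \eqn{\bar{x}_w = \sum(x_i w_i) / \sum(w_i)}. Invariant to uniform rescaling
#' of the weights; with equal weights it is the arithmetic mean.
#'
#' @param sample A [weighted_sample()] (a bare numeric vector is treated as
#'   equally weighted).
#' @return The weighted mean (μm).
#' @export
#' @examples
#' wtd_mean(weighted_sample(c(10, 12, 20), c(0.15, 0.15, 0.70)))  # 17.3
wtd_mean <- function(sample) {
  s <- .as_ws(sample)
  sum(s$values * s$weights) / sum(s$weights)
}

#' Weighted standard deviation
#'
#' \eqn{\sqrt{\frac{\sum w_i (x_i - \bar{x}_w)^2}{\sum w_i} \cdot
#' \frac{n}{n-1}}} with \eqn{n} the sample's `n_obs`. The small-sample factor
#' `n/(n-1)` (on by default) makes the equal-weight case coincide exactly with
#' the ordinary sample SD; set `correct = FALSE` for the plain weighted
#' population form.
#'
#' @inheritParams wtd_mean
#' @param correct Apply the `n/(n-1)` small-sample correction? Default `TRUE`.
#' @return The weighted SD (μm).
#' @export
wtd_sd <- function(sample, correct = TRUE) {
  s <- .as_ws(sample)
  if (s$n_obs < 2) {
    ps_stop("weighted SD needs n_obs >= 2", "paleosize_insufficient_data_error")
  }
  m <- wtd_mean(s)
  v <- sum(s$weights * (s$values - m)^2) / sum(s$weights)
  if (correct) v <- v * s$n_obs / (s$n_obs - 1)
  sqrt(v)
}

#' Standard error from an SD and an effective sample size
#'
#' `sd / sqrt(n_obs)`. At the observation level `n_obs` is the number of
#' measured cysts; at the interspecific level it is the number of species.
#'
#' @param sd Standard deviation (μm).
#' @param n_obs Effective number of observations (>= 1).
#' @return The standard error (μm).
#' @export
#' @examples
#' wtd_se(5.97, 219)  # about 0.40
#' wtd_se(6.60, 6)    # about 2.69
wtd_se <- function(sd, n_obs) {
  stopifnot(n_obs >= 1)
  sd / sqrt(n_obs)
}

.t_result <- function(t, df, mean_diff) {
  tibble::tibble(
    t_statistic = t, df = df,
    p_value = 2 * pt(-abs(t), df),
    mean_difference = mean_diff
  )
}

#' Welch two-sample t-test
#'
#' Unequal-variance test of a difference in means:
#' \eqn{t = (\bar{x}_b - \bar{x}_a) / \sqrt{s_a^2/n_a + s_b^2/n_b}} with
#' Welch–Satterthwaite degrees of freedom and a two-sided p-value. The
#' difference is reported as `b - a`, i.e. comparison minus reference.
#'
#' @param a,b Numeric vectors of at least 2 values each; at least one sample
#'   must have positive variance.
#' @return A one-row tibble with `t_statistic`, `df`, `p_value`,
#'   `mean_difference`.
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    ps_stop("each sample needs at least 2 values", "paleosize_insufficient_data_error")
  }
  welch_test_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
}

#' Welch test from summary statistics
#'
#' The same test as [welch_test()], computed from per-sample means, SDs and
#' sizes — the form needed when only published summary tables are available.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Summary statistics of the two
#'   samples.
#' @return A one-row tibble as in [welch_test()].
#' @export
welch_test_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  if (va + vb == 0) {
    ps_stop("both samples have zero variance; t statistic undefined",
            "paleosize_degenerate_error")
  }
  t <- (mean_b - mean_a) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  .t_result(t, df, mean_b - mean_a)
}

#' Weighted Welch two-sample t-test
#'
#' Tests a difference between two weighted means:
#' \eqn{t = (\bar{x}_{w,b} - \bar{x}_{w,a}) / \sqrt{SE_a^2 + SE_b^2}}, where
#' each SE is the weighted SD over the square root of the sample's effective
#' `n_obs`. With uniform weights this reduces exactly to [welch_test()].
#'
#' Degrees of freedom: `df_mode = "satterthwaite"` (default) applies the
#' Welch–Satterthwaite approximation to the weighted variance components
#' \eqn{s_{w,i}^2 / n_i} with component dfs \eqn{n_i - 1};
#' `df_mode = "pooled"` uses the classical \eqn{n_a + n_b - 2}.
#'
#' @param sample_a,sample_b [weighted_sample()] objects with `n_obs >= 2`.
#' @param df_mode Degrees-of-freedom rule, see Details.
#' @param correct Passed to [wtd_sd()].
#' @return A one-row tibble as in [welch_test()].
#' @export
weighted_welch_test <- function(sample_a, sample_b,
                                df_mode = c("satterthwaite", "pooled"),
                                correct = TRUE) {
  df_mode <- match.arg(df_mode)
  a <- .as_ws(sample_a)
  b <- .as_ws(sample_b)
  if (a$n_obs < 2 || b$n_obs < 2) {
    ps_stop("each sample needs n_obs >= 2", "paleosize_insufficient_data_error")
  }
  va <- wtd_sd(a, correct)^2 / a$n_obs
  vb <- wtd_sd(b, correct)^2 / b$n_obs
  if (va + vb == 0) {
    ps_stop("both samples have zero weighted variance; t statistic undefined",
            "paleosize_degenerate_error")
  }
  diff <- wtd_mean(b) - wtd_mean(a)
  t <- diff / sqrt(va + vb)
  df <- switch(df_mode,
    satterthwaite = (va + vb)^2 / (va^2 / (a$n_obs - 1) + vb^2 / (b$n_obs - 1)),
    pooled = a$n_obs + b$n_obs - 2
  )
  .t_result(t, df, diff)
}
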