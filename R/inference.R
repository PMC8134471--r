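# Performance metrics, permutation inference, and Steiger comparison of
# dependent model correlations.

#' Root mean square error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\frac{1}{n}\sum_i (\mathrm{actual}_i -
#' \mathrm{predicted}_i)^2}}
#'
#' @param predicted,actual Equal-length finite numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop(sprintf("rmse: length mismatch (%d vs %d)",
                 length(predicted), length(actual)))
  }
  if (!length(predicted)) stop("rmse: empty vectors")
  if (any(!is.finite(predicted)) || any(!is.finite(actual))) {
    stop("rmse: non-finite values")
  }
  sqrt(mean((actual - predicted)^2))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties (equivalently, Pearson
#' correlation of the rank-transformed vectors).  Used for all model
#' evaluation so no distributional assumption is placed on the behavior.
#' A constant vector has no defined rank correlation: returns `NA` with a
#' warning.
#'
#' @param predicted,actual Numeric vectors, length >= 3.
#' @return Scalar in \[-1, 1\], or `NA` for a constant input.
#' @export
spearman_rho <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("spearman_rho: length mismatch")
  }
  if (length(predicted) < 3L) stop("spearman_rho: need n >= 3")
  if (stats::sd(predicted) == 0 || stats::sd(actual) == 0) {
    warning("spearman_rho: constant vector, correlation undefined")
    return(NA_real_)
  }
  stats::cor(predicted, actual, method = "spearman")
}

#' Permutation p-value for a prediction correlation
#'
#' One-tailed \eqn{p = (\#\{\rho_{null} > \rho_{obs}\} + 1) / (n_{perm} + 1)}:
#' the count of null correlations numerically greater than the observed one
#' (strict inequality; ties do not count as exceedances), plus-one corrected.
#' The attainable floor is \eqn{1/(n_{perm}+1)}.
#'
#' @param rho_null Vector of null correlations (NAs from degenerate
#'   permutation runs count as non-exceedances).
#' @param rho_obs Observed statistic.
#' @return p-value in \[1/(n_perm+1), 1\].
#' @export
permutation_pvalue <- function(rho_null, rho_obs) {
  if (!length(rho_null)) stop("permutation_pvalue: empty null distribution")
  if (is.na(rho_obs)) stop("permutation_pvalue: observed statistic is NA")
  (sum(rho_null > rho_obs, na.rm = TRUE) + 1) / (length(rho_null) + 1)
}

#' Permutation test of CPM prediction performance
#'
#' Shuffles the correspondence between behavior and connectomes `n_perm`
#' times (covariates stay attached to their subjects) and re-runs the CPM
#' cross-validation on each shuffled dataset, giving the null distribution
#' of prediction correlations against which the observed statistic is
#' tested with [permutation_pvalue()].  Each permutation draws fresh folds
#' by default; set `refold = FALSE` to reuse one fixed fold assignment.
#'
#' By default each permutation runs a single cross-validation repeat
#' (`n_iterations_per_perm = 1`); under the null a single run is
#' exchangeable with the observed statistic and the full repeat count is
#' computationally disproportionate.
#'
#' @inheritParams run_cv
#' @param rho_observed Observed statistic, or a `cpm_result` (its
#'   `rho_median` is used).
#' @param n_perm Number of permutations (default 1000).
#' @param perm_seed Integer seed driving both the shuffles and the
#'   per-permutation fold draws.
#' @param n_iterations_per_perm Cross-validation repeats per permutation;
#'   with more than 1, each permutation contributes its median rho.
#' @param refold Draw fresh folds per permutation (default) or reuse the
#'   assignment seeded by `perm_seed`.
#' @return List of class `cpm_permutation`: `rho_null`, `rho_observed`,
#'   `p`, `n_perm`.
#' @export
permutation_test <- function(edges, behavior, config, rho_observed,
                             n_perm = 1000L, perm_seed = 1L,
                             covariates = NULL,
                             n_iterations_per_perm = 1L,
                             refold = TRUE) {
  if (n_perm < 1L) stop("permutation_test: n_perm must be >= 1")
  if (inherits(rho_observed, "cpm_result")) {
    rho_observed <- rho_observed$rho_median
  }
  n <- nrow(edges)
  rho_null <- vapply(seq_len(n_perm), function(b) {
    perm <- withr::with_seed(perm_seed + b, sample.int(n))
    y_b <- behavior[perm]
    fold_seed_base <- if (refold) perm_seed + n_perm + b * n_iterations_per_perm
                      else perm_seed
    rb <- vapply(seq_len(n_iterations_per_perm), function(t) {
      run_cv(edges, y_b, config,
             seed = if (refold) fold_seed_base + t - 1L else perm_seed,
             covariates = covariates)$rho
    }, numeric(1L))
    rb <- rb[!is.na(rb)]
    if (!length(rb)) NA_real_ else sort(rb)[ceiling(length(rb) / 2)]
  }, numeric(1L))
  structure(list(rho_null = rho_null,
                 rho_observed = rho_observed,
                 p = permutation_pvalue(rho_null, rho_observed),
                 n_perm = as.integer(n_perm)),
            class = "cpm_permutation")
}

#' @export
print.cpm_permutation <- function(x, ...) {
  cat(sprintf("<cpm_permutation> rho = %.3f, p = %.4g (%d permutations, one-tailed)\n",
              x$rho_observed, x$p, x$n_perm))
  invisible(x)
}

#' Steiger's z for two dependent correlations sharing a variable
#'
#' Compares correlations \eqn{\rho_{ya}} and \eqn{\rho_{yb}} that share the
#' variable y (here: the observed behavior correlated with two prediction
#' vectors).  Uses Fisher-transformed correlations with Steiger's (1980)
#' pooled-estimate covariance correction:
#' \deqn{\bar{r} = (r_{ya} + r_{yb})/2, \quad
#'   \bar{s} = \frac{r_{ab}(1 - 2\bar{r}^2) - \tfrac{1}{2}\bar{r}^2
#'     (1 - 2\bar{r}^2 - r_{ab}^2)}{(1 - \bar{r}^2)^2},}
#' \deqn{z = (z_{ya} - z_{yb})\sqrt{\frac{n - 3}{2 - 2\bar{s}}}.}
#' Two-tailed p from the standard normal; swapping the two correlations
#' negates z.
#'
#' @param rho_a,rho_b The two dependent correlations (each with y), in
#'   (-1, 1).
#' @param r_ab Correlation between the a and b vectors themselves.
#' @param n Sample size (>= 4).
#' @return List of class `cpm_model_comparison`: `rho_a`, `rho_b`, `r_ab`,
#'   `n`, `z`, `p` (two-tailed).
#' @export
steiger_compare <- function(rho_a, rho_b, r_ab, n) {
  if (n < 4L) stop("steiger_compare: need n >= 4")
  if (any(abs(c(rho_a, rho_b, r_ab)) >= 1)) {
    stop("steiger_compare: correlations must lie strictly in (-1, 1)")
  }
  z_a <- atanh(rho_a)
  z_b <- atanh(rho_b)
  rbar <- (rho_a + rho_b) / 2
  sbar <- (r_ab * (1 - 2 * rbar^2) -
             0.5 * rbar^2 * (1 - 2 * rbar^2 - r_ab^2)) / (1 - rbar^2)^2
  z <- (z_a - z_b) * sqrt((n - 3) / (2 - 2 * sbar))
  structure(list(rho_a = rho_a, rho_b = rho_b, r_ab = r_ab, n = n,
                 z = z, p = 2 * stats::pnorm(-abs(z))),
            class = "cpm_model_comparison")
}

#' @export
print.cpm_model_comparison <- function(x, ...) {
  cat(sprintf("<cpm_model_comparison> rho_a = %.3f vs rho_b = %.3f (r_ab = %.3f, n = %d): z = %.2f, p = %.4g\n",
              x$rho_a, x$rho_b, x$r_ab, x$n, x$z, x$p))
  invisible(x)
}

#' Compare two prediction vectors against the same observed behavior
#'
#' Convenience wrapper around [steiger_compare()]: computes the two
#' behavior-prediction rank correlations and the rank correlation between
#' the prediction vectors, then tests their difference.  All three
#' correlations are Spearman, matching the evaluation metric.
#'
#' @param pred_a,pred_b Prediction vectors from the two models.
#' @param actual Observed behavior vector common to both.
#' @return A `cpm_model_comparison`.
#' @export
compare_predictions <- function(pred_a, pred_b, actual) {
  steiger_compare(spearman_rho(pred_a, actual),
                  spearman_rho(pred_b, actual),
                  spearman_rho(pred_a, pred_b),
                  length(actual))
}

#' Partial correlation of two vectors given covariates
#'
#' Correlation of the least-squares residuals of `x` and `y` on the
#' covariates (with intercept); the t-based p-value uses
#' `df = n - n_covariates - 2`.  An empty covariate set reduces to the
#' plain Pearson correlation.  If either residual vector has zero variance
#' (e.g. `y` equals a covariate), the partial correlation is undefined:
#' `NA` with a warning.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional matrix/data.frame of covariate columns.
#' @return List with `r` and `p`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("partial_correlation: length mismatch")
  k <- 0L
  scale_x <- stats::sd(x)
  scale_y <- stats::sd(y)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (ncol(C)) {
      if (nrow(C) != n) stop("partial_correlation: covariate rows != n")
      if (n <= ncol(C) + 2L) {
        stop("partial_correlation: need n > n_covariates + 2")
      }
      qrC <- qr(cbind(1, C))
      if (qrC$rank < ncol(C) + 1L) {
        stop("partial_correlation: covariate matrix is rank deficient")
      }
      x <- qr.resid(qrC, x)
      y <- qr.resid(qrC, y)
      k <- ncol(C)
    }
  }
  # residuals of a vector lying in the covariate span are numerically ~0
  if (stats::sd(x) <= 1e-10 * max(scale_x, 1) ||
      stats::sd(y) <= 1e-10 * max(scale_y, 1)) {
    warning("partial_correlation: zero-variance residual, undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  df <- n - k - 2L
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE))
}
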