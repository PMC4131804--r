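## OLS on eigenvector scores, forward selection with the double stopping
## criterion, residual diagnostics and outlier flagging.

responseValues <- function(y) {
  if (inherits(y, "pcnm_response")) y$value else as.numeric(y)
}

scoreMatrix <- function(map, columns = NULL) {
  X <- if (inherits(map, "pcnm_eigenmap")) map$scores else as.matrix(map)
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  X
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - k - 1)`, the penalty that makes r-squared
#' comparable across models with different numbers of predictors — the
#' quantity the double stopping criterion is defined on.
#'
#' @param r2 coefficient of determination in `[0, 1]`.
#' @param n number of observations.
#' @param k number of predictors (excluding the intercept).
#' @return adjusted r-squared (can be negative).
#' @examples
#' adjustedR2(0.663, 320, 22)  # 0.638 to 3 decimals
#' @export
adjustedR2 <- function(r2, n, k) {
  if (any(r2 < 0 | r2 > 1)) stop("invalid parameter: r2 must be in [0, 1]")
  if (n <= k + 1) stop("invalid parameter: need n > k + 1")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Ordinary least squares on selected eigenvector columns
#'
#' Fits the response on the given score columns with an intercept and
#' assembles the bookkeeping the spatial-regression workflow reports:
#' standardized coefficients (`beta * sd(x) / sd(y)`), multiple correlation
#' `r`, `r2`, adjusted `r2`, raw residuals and internally studentized
#' residuals.
#'
#' @param y response: a `pcnm_response` or numeric vector.
#' @param scores n-by-k matrix of predictor columns (eigenvector scores), or
#'   a `pcnm_eigenmap` (all columns used).
#' @param selected optional column indices/names to subset `scores`.
#' @return object of class `pcnm_fit`: list with `selected`, `beta`
#'   (including intercept), `beta_std`, `r`, `r2`, `r2_adj`, `residuals`,
#'   `residuals_std`, `leverage`, `sigma`, `n`, `k`, and per-coefficient
#'   `p_values`.
#' @export
fitOLS <- function(y, scores, selected = NULL) {
  yv <- responseValues(y)
  X <- scoreMatrix(scores, selected)
  n <- length(yv)
  if (nrow(X) != n) stop("invalid input: response/score length mismatch")
  k <- ncol(X)
  if (n <= k + 1)
    stop("overfit: need n > k + 1 (n = ", n, ", k = ", k, ")")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(k))
  if (anyDuplicated(t(X)))
    stop("collinearity: duplicated predictor columns")
  fit <- stats::lm(yv ~ X)
  if (fit$rank < k + 1L)
    stop("collinearity: rank-deficient design (rank ", fit$rank,
         " < ", k + 1L, ")")
  # noiseless planted scenarios legitimately produce exact fits; the
  # "essentially perfect fit" caution from summary.lm is expected there
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  beta <- stats::coef(fit)
  names(beta) <- c("(Intercept)", colnames(X))
  sdy <- stats::sd(yv)
  beta_std <- beta[-1L] * apply(X, 2L, stats::sd) / sdy
  h <- stats::lm.influence(fit, do.coef = FALSE)$hat
  structure(list(
    selected = colnames(X),
    beta = beta,
    beta_std = beta_std,
    r = sqrt(sm$r.squared),
    r2 = sm$r.squared,
    r2_adj = sm$adj.r.squared,
    residuals = unname(stats::residuals(fit)),
    residuals_std = unname(stats::rstandard(fit)),
    leverage = unname(h),
    sigma = sm$sigma,
    n = n, k = k,
    p_values = sm$coefficients[-1L, 4L],
    fitted = unname(stats::fitted(fit))
  ), class = "pcnm_fit")
}

#' @export
print.pcnm_fit <- function(x, ...) {
  cat("OLS on", x$k, "eigenvector(s), n =", x$n, "\n")
  cat(sprintf("  r = %.3f  r2 = %.3f  adjusted r2 = %.3f\n",
              x$r, x$r2, x$r2_adj))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Internally studentized residuals
#'
#' `e_i / (s * sqrt(1 - h_ii))` with leverage `h_ii` from the design — the
#' standardized residuals used for outlier flagging.
#'
#' @param model a `pcnm_fit`.
#' @return numeric vector of studentized residuals.
#' @export
standardizedResiduals <- function(model) {
  if (!inherits(model, "pcnm_fit")) stop("expected a pcnm_fit")
  if (model$n <= model$k + 2L)
    stop("need n > k + 2 for studentized residuals")
  if (any(model$leverage >= 1 - 1e-10))
    stop("degenerate leverage: an observation is an exact interpolation point")
  model$residuals_std
}

#' Flag outliers by absolute standardized residual
#'
#' @param z standardized residuals.
#' @param cutoff flag `|z| > cutoff` (default 3).
#' @return logical mask.
#' @export
flagOutliersThreshold <- function(z, cutoff = 3) {
  if (!all(is.finite(z))) stop("invalid input: non-finite residuals")
  abs(z) > cutoff
}

#' Chauvenet critical value
#'
#' The absolute standardized residual beyond which the expected number of
#' equally extreme normal values in a sample of size `n` falls below 1/2:
#' the solution of `2 n (1 - Phi(z)) = 0.5`, i.e. `qnorm(1 - 0.25/n)`.
#'
#' @param n sample size.
#' @return critical `|z|`.
#' @export
chauvenetCritical <- function(n) {
  if (any(n < 1)) stop("invalid parameter: n must be >= 1")
  stats::qnorm(1 - 0.25 / n)
}

#' Chauvenet's criterion for outliers
#'
#' Flags observation `i` when `n * P(|Z| > |z_i|) < 0.5` under the standard
#' normal — fewer than half an observation this extreme is expected in the
#' sample.  Applied in a single pass (no iterative re-estimation).
#'
#' @param z standardized residuals (already on a standard-normal scale).
#' @return logical mask.
#' @export
chauvenetOutliers <- function(z) {
  if (length(z) < 4L) stop("too few observations for Chauvenet (need >= 4)")
  if (!all(is.finite(z))) stop("invalid input: non-finite residuals")
  n <- length(z)
  n * 2 * stats::pnorm(-abs(z)) < 0.5
}

#' Outlier report under both criteria
#'
#' @param model a `pcnm_fit`.
#' @param cutoff threshold for the absolute-residual rule.
#' @param site_id optional site identifiers.
#' @return data frame with `site_id`, `residual_std`, `over_threshold`,
#'   `chauvenet`; attribute `chauvenet_critical` carries the critical value.
#' @export
outlierReport <- function(model, cutoff = 3, site_id = NULL) {
  z <- standardizedResiduals(model)
  if (is.null(site_id)) site_id <- as.character(seq_along(z))
  out <- data.frame(site_id = site_id, residual_std = z,
                    over_threshold = flagOutliersThreshold(z, cutoff),
                    chauvenet = chauvenetOutliers(z),
                    stringsAsFactors = FALSE)
  attr(out, "chauvenet_critical") <- chauvenetCritical(length(z))
  attr(out, "cutoff") <- cutoff
  out
}
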