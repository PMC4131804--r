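## Forward selection of eigenvectors under the double stopping criterion.

interceptOnlyFit <- function(yv) {
  n <- length(yv)
  e <- yv - mean(yv)
  s <- sqrt(sum(e^2) / (n - 1))
  structure(list(
    selected = character(0), beta = c("(Intercept)" = mean(yv)),
    beta_std = numeric(0), r = 0, r2 = 0, r2_adj = 0,
    residuals = e,
    residuals_std = if (s > 0) e / (s * sqrt(1 - 1 / n)) else e * 0,
    leverage = rep(1 / n, n), sigma = s, n = n, k = 0L,
    p_values = numeric(0), fitted = rep(mean(yv), n)
  ), class = "pcnm_fit")
}

rssOf <- function(yv, X, cols) {
  if (length(cols) == 0L) return(sum((yv - mean(yv))^2))
  f <- stats::.lm.fit(cbind(1, X[, cols, drop = FALSE]), yv)
  sum(f$residuals^2)
}

#' Forward selection of PCNM eigenvectors with the double stopping criterion
#'
#' Iteratively enters the candidate eigenvector with the smallest
#' entry p-value (partial F-test of the entering coefficient; ties broken by
#' larger r-squared increment, then by lower eigenvector index, preferring
#' broader scales) while the p-value is below `alpha`.  Under the default
#' `criterion = "double_stop"`, selection additionally stops as soon as the
#' running adjusted r-squared reaches the adjusted r-squared of the model
#' using ALL candidate eigenvectors — without this ceiling, many eigenvectors
#' proxying the same spatial process inflate the fit.
#'
#' @param y response: `pcnm_response` or numeric vector.
#' @param map `pcnm_eigenmap` or plain score matrix of candidate columns.
#' @param alpha entry level (default 0.05).
#' @param criterion `"double_stop"` (alpha AND adjusted-r2 ceiling) or
#'   `"alpha_only"`.
#' @return object of class `pcnm_selection`: list with `model` (a
#'   [fitOLS()] fit on the selected columns, intercept-only when nothing
#'   enters), and `trace` — list with `steps` (data frame: step, index,
#'   column, p_entry, r2, r2_adj), `r2_adj_full`, `stop_reason`
#'   (`alpha_exhausted`, `r2_ceiling_reached` or `no_candidates`),
#'   `criterion`, `alpha`.
#' @export
forwardSelect <- function(y, map, alpha = 0.05,
                          criterion = c("double_stop", "alpha_only")) {
  criterion <- match.arg(criterion)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("invalid parameter: alpha must be in (0, 1)")
  yv <- responseValues(y)
  X <- scoreMatrix(map)
  n <- length(yv)
  if (nrow(X) != n) stop("invalid input: response/score length mismatch")
  m <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(m))
  tss <- sum((yv - mean(yv))^2)
  if (tss == 0) stop("undefined fit: response is constant")

  # Ceiling: adjusted r2 of the all-candidate model.  When that model is not
  # fittable (m >= n - 1) fall back to the broadest fittable prefix.
  full_cols <- seq_len(m)
  if (m > 0L && m >= n - 1L) {
    full_cols <- seq_len(floor(n / 2))
    warning("all-candidate model unfittable (m = ", m, " >= n - 1 = ",
            n - 1L, "); adjusted-r2 ceiling taken from the broadest ",
            length(full_cols), " eigenvectors")
  }
  r2_adj_full <- if (m == 0L) 0 else {
    rss_full <- rssOf(yv, X, full_cols)
    adjustedR2(1 - rss_full / tss, n, length(full_cols))
  }

  selected <- integer(0)
  rss_cur <- tss
  steps <- list()
  stop_reason <- NULL
  repeat {
    k <- length(selected)
    r2_adj_cur <- adjustedR2(1 - rss_cur / tss, n, k)
    if (criterion == "double_stop" && m > 0L && r2_adj_cur >= r2_adj_full) {
      stop_reason <- "r2_ceiling_reached"
      break
    }
    candidates <- setdiff(seq_len(m), selected)
    if (length(candidates) == 0L || n <= k + 2L) {
      stop_reason <- "no_candidates"
      break
    }
    rss_new <- vapply(candidates, function(j) rssOf(yv, X, c(selected, j)),
                      numeric(1))
    df2 <- n - k - 2L
    fstat <- (rss_cur - rss_new) / pmax(rss_new / df2, .Machine$double.xmin)
    p <- stats::pf(fstat, 1L, df2, lower.tail = FALSE)
    best <- order(p, rss_new, candidates)[1L]
    if (p[best] >= alpha) {
      stop_reason <- "alpha_exhausted"
      break
    }
    selected <- c(selected, candidates[best])
    rss_cur <- rss_new[best]
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(selected), index = candidates[best],
      column = colnames(X)[candidates[best]], p_entry = p[best],
      r2 = 1 - rss_cur / tss,
      r2_adj = adjustedR2(1 - rss_cur / tss, n, length(selected)),
      stringsAsFactors = FALSE)
  }

  model <- if (length(selected)) fitOLS(yv, X, selected)
           else interceptOnlyFit(yv)
  trace <- list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(step = integer(0), index = integer(0),
                 column = character(0), p_entry = numeric(0),
                 r2 = numeric(0), r2_adj = numeric(0)),
    r2_adj_full = r2_adj_full, stop_reason = stop_reason,
    criterion = criterion, alpha = alpha)
  structure(list(model = model, trace = trace, selected = selected),
            class = "pcnm_selection")
}

#' @export
print.pcnm_selection <- function(x, ...) {
  tr <- x$trace
  cat("Forward selection (", tr$criterion, ", alpha = ", tr$alpha, ")\n",
      sep = "")
  cat("  selected", length(x$selected), "eigenvector(s):",
      paste(x$model$selected, collapse = ", "), "\n")
  cat(sprintf("  r2 = %.3f  adjusted r2 = %.3f  (all-vector ceiling %.3f)\n",
              x$model$r2, x$model$r2_adj, tr$r2_adj_full))
  cat("  stop reason:", tr$stop_reason, "\n")
  invisible(x)
}
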