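## Truncated connectivity matrix and PCNM eigenvector extraction.

#' Truncate a distance matrix into a PCNM connectivity matrix
#'
#' Applies the truncation rule `w_ij = d_ij` if `d_ij <= t`, else
#' `w_ij = multiplier * t`.  Replacing all beyond-threshold distances by a
#' large constant makes the subsequent eigendecomposition describe spatial
#' relationships only up to the threshold scale.
#'
#' @param D distance matrix or `dist` object.
#' @param t truncation threshold, usually [mstThreshold()] of `D`.
#' @param multiplier factor applied to `t` for far pairs; must exceed 1.
#'   The canonical value is 4.
#' @return object of class `pcnm_connectivity`: the truncated matrix with
#'   attributes `threshold` and `multiplier`.
#' @export
truncateDistances <- function(D, t, multiplier = 4) {
  D <- asDistanceMatrix(D)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    stop("invalid parameter: threshold t must be a single positive number")
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 1)
    stop("invalid parameter: multiplier must exceed 1")
  W <- D
  W[D > t] <- multiplier * t
  diag(W) <- 0
  structure(W, class = c("pcnm_connectivity", class(W)),
            threshold = t, multiplier = multiplier)
}

#' Extract PCNM eigenvectors from a truncated connectivity matrix
#'
#' Performs a principal coordinate analysis of the connectivity matrix:
#' forms `A = -0.5 * W^2` (elementwise square, the Gower transformation),
#' double-centers it (row means and column means removed, grand mean added
#' back), eigendecomposes the centered matrix, and retains the eigenvectors
#' whose eigenvalues are positive.  Retained columns are mutually orthogonal
#' and zero-mean; they model positive spatial autocorrelation from broad
#' (first column) to fine (last column) scales.
#'
#' Eigenvector signs are arbitrary; for determinism each column is flipped so
#' that its largest-magnitude entry (ties broken by lowest site index) is
#' positive.
#'
#' @param W connectivity matrix from [truncateDistances()] (a plain distance
#'   matrix is accepted and treated as already truncated).
#' @param positivity_tol relative tolerance: eigenvalues above
#'   `positivity_tol * max(eigenvalue)` count as positive, separating true
#'   structure from floating-point zeros.
#' @param centering `"gower_sq"` (the canonical PCNM/PCoA construction on
#'   squared entries) or `"raw"` (double-center `W` itself; sensitivity
#'   analysis only).
#' @param scaling `"unit"` for unit-norm score columns (default; the
#'   regression stage is scale-invariant) or `"sqrt_lambda"` to scale each
#'   column by the square root of its eigenvalue so that scores reproduce
#'   intersite distances when the matrix is untruncated.
#' @return object of class `pcnm_eigenmap`: list with `values` (positive
#'   eigenvalues, descending), `scores` (n-by-m matrix, site ids as
#'   rownames, columns `PCNM1..PCNMm`), `n_sites`, `centering`, `scaling`,
#'   `threshold`, `multiplier`.
#' @export
computeEigenmap <- function(W, positivity_tol = 1e-9,
                            centering = c("gower_sq", "raw"),
                            scaling = c("unit", "sqrt_lambda")) {
  centering <- match.arg(centering)
  scaling <- match.arg(scaling)
  threshold <- attr(W, "threshold")
  multiplier <- attr(W, "multiplier")
  W <- asDistanceMatrix(unclass(W))
  n <- nrow(W)
  if (n < 3L) stop("invalid input: need at least 3 sites for an eigenmap")
  A <- if (centering == "gower_sq") -0.5 * W^2 else W
  B <- sweep(A, 1L, rowMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  B <- (B + t(B)) / 2                      # enforce exact symmetry
  eig <- eigen(B, symmetric = TRUE)
  lambda_max <- max(eig$values)
  if (lambda_max <= 0)
    stop("empty eigenmap: no positive eigenvalue (degenerate connectivity)")
  keep <- eig$values > positivity_tol * lambda_max
  if (!any(keep))
    stop("empty eigenmap: no eigenvalue above positivity tolerance ",
         positivity_tol)
  values <- eig$values[keep]
  scores <- eig$vectors[, keep, drop = FALSE]
  # Deterministic sign: largest |entry| positive, ties to the lowest index.
  for (k in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  if (scaling == "sqrt_lambda")
    scores <- sweep(scores, 2L, sqrt(values), `*`)
  site_ids <- rownames(W)
  if (is.null(site_ids)) site_ids <- as.character(seq_len(n))
  dimnames(scores) <- list(site_ids, paste0("PCNM", seq_len(ncol(scores))))
  structure(list(values = values, scores = scores, n_sites = n,
                 centering = centering, scaling = scaling,
                 threshold = threshold, multiplier = multiplier),
            class = "pcnm_eigenmap")
}

#' @export
print.pcnm_eigenmap <- function(x, ...) {
  cat("PCNM eigenmap:", ncol(x$scores), "positive eigenvectors over",
      x$n_sites, "sites\n")
  cat("  centering:", x$centering, "  scaling:", x$scaling, "\n")
  if (!is.null(x$threshold))
    cat("  truncation threshold:", format(x$threshold),
        " multiplier:", x$multiplier, "\n")
  cat("  eigenvalue range:", format(min(x$values)), "..",
      format(max(x$values)), "\n")
  invisible(x)
}

#' Moran's I spatial autocorrelation with binary within-threshold weights
#'
#' Computes Moran's I for a per-site variable with neighbor weights
#' `w*_ij = 1` if `0 < d_ij <= t` and 0 otherwise.  Binary within-threshold
#' connectivity is used deliberately: the beyond-threshold fill constant in
#' the PCNM connectivity matrix is a device for the eigendecomposition, not
#' a meaningful spatial weight.
#'
#' @param values numeric per-site vector, same order as `D`.
#' @param D distance matrix or `dist` object.
#' @param t neighborhood threshold (meters).
#' @return list with `I`, `expectation` (`-1/(n-1)`, the no-autocorrelation
#'   reference), `n`, and `s0` (sum of weights).
#' @export
moransI <- function(values, D, t) {
  D <- asDistanceMatrix(D)
  n <- nrow(D)
  if (length(values) != n)
    stop("invalid input: values length does not match distance matrix")
  if (!all(is.finite(values))) stop("invalid input: non-finite values")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0) stop("undefined statistic: values are constant")
  Wb <- (D > 0 & D <= t) * 1
  diag(Wb) <- 0
  s0 <- sum(Wb)
  if (s0 == 0) stop("no neighbors: no site pair within threshold ", t)
  I <- (n / s0) * drop(crossprod(z, Wb %*% z)) / ss
  list(I = I, expectation = -1 / (n - 1), n = n, s0 = s0)
}

#' Sign changes along an ordered score column
#'
#' For sites with a natural 1-D ordering (e.g. a transect), the number of
#' zero crossings of an eigenvector is a proxy for its spatial wavelength:
#' broad-scale vectors cross zero rarely, fine-scale ones often.
#'
#' @param v numeric vector in transect order; exact zeros are skipped.
#' @return integer count of sign changes.
#' @export
signChanges <- function(v) {
  v <- v[v != 0]
  if (length(v) < 2L) return(0L)
  sum(diff(sign(v)) != 0)
}
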