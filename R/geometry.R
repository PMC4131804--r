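## Site geometry: settlement centroids, intersite distances, MST threshold.

#' Population-weighted centroid of settlement points
#'
#' Collapses one area's settlement concentrations to a single representative
#' point: the arithmetic mean of the settlement coordinates weighted by the
#' number of inhabitants per concentration.
#'
#' @param x,y numeric planar coordinates in meters.
#' @param population nonnegative weights (inhabitants per settlement).
#' @return numeric vector `c(x, y)`.
#' @examples
#' weightedCentroid(c(0, 4), c(0, 0), c(1, 3))  # (3, 0)
#' @export
weightedCentroid <- function(x, y, population) {
  if (length(x) == 0L)
    stop("invalid input: no settlements supplied")
  if (length(x) != length(y) || length(x) != length(population))
    stop("invalid input: x, y and population must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(population)))
    stop("invalid input: non-finite coordinate or weight")
  if (any(population < 0))
    stop("invalid input: negative population weight")
  w <- sum(population)
  if (w <= 0)
    stop("invalid input: total settlement population is zero")
  c(x = sum(population * x) / w, y = sum(population * y) / w)
}

#' Derive one site per area from a settlement table
#'
#' Applies [weightedCentroid()] per `site_id` and returns a site table with
#' one row per area, in order of first appearance.
#'
#' @param settlements data frame with columns `site_id`, `x`, `y`,
#'   `population`.
#' @return data frame with columns `site_id`, `x`, `y`.
#' @export
weightedCentroids <- function(settlements) {
  need <- c("site_id", "x", "y", "population")
  missing_cols <- setdiff(need, names(settlements))
  if (length(missing_cols))
    stop("settlement table lacks column(s): ", paste(missing_cols, collapse = ", "))
  ids <- unique(as.character(settlements$site_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    s <- settlements[as.character(settlements$site_id) == id, , drop = FALSE]
    ct <- tryCatch(weightedCentroid(s$x, s$y, s$population),
                   error = function(e) stop("site ", id, ": ", conditionMessage(e),
                                            call. = FALSE))
    data.frame(site_id = id, x = ct[["x"]], y = ct[["y"]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Heuristic degree detection: planar coordinates in meters for any
# region-scale study are far outside +-180 / +-90.
looksLikeDegrees <- function(x, y) {
  all(abs(x) <= 180, na.rm = TRUE) && all(abs(y) <= 90, na.rm = TRUE)
}

validateSites <- function(sites, planar = FALSE, min_n = 2L) {
  need <- c("site_id", "x", "y")
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols))
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  ids <- as.character(sites$site_id)
  if (anyDuplicated(ids))
    stop("invalid input: duplicated site_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!all(is.finite(sites$x)) || !all(is.finite(sites$y)))
    stop("invalid input: non-finite site coordinate")
  if (nrow(sites) < min_n)
    stop("invalid input: need at least ", min_n, " sites")
  if (!planar && looksLikeDegrees(sites$x, sites$y))
    stop("coordinates look like longitude/latitude degrees; this tool works ",
         "on projected planar meters only. If the coordinates really are ",
         "planar, pass planar = TRUE.")
  invisible(sites)
}

#' Euclidean intersite distance matrix
#'
#' @param sites data frame with columns `site_id`, `x`, `y`; coordinates must
#'   be projected planar meters (no reprojection is performed).
#' @param planar set `TRUE` to acknowledge that small-magnitude coordinates
#'   are genuinely planar; otherwise coordinates within the longitude/latitude
#'   range are rejected to guard against degrees being treated as meters.
#' @return symmetric n-by-n matrix of Euclidean distances with `site_id`
#'   dimnames and zero diagonal.
#' @examples
#' siteDistances(data.frame(site_id = c("a", "b"), x = c(0, 3000),
#'                          y = c(0, 4000)))
#' @export
siteDistances <- function(sites, planar = FALSE) {
  validateSites(sites, planar = planar, min_n = 2L)
  xy <- as.matrix(sites[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  dimnames(d) <- list(as.character(sites$site_id), as.character(sites$site_id))
  dup <- d[upper.tri(d)] == 0
  if (any(dup))
    warning("duplicate coordinates across distinct sites (zero off-diagonal ",
            "distance); affected eigenvector scores are non-unique")
  d
}

asDistanceMatrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isSymmetric(unname(D), tol = 1e-8))
    stop("invalid input: distance matrix must be square and symmetric")
  if (any(D < 0) || any(abs(diag(D)) > 0))
    stop("invalid input: distances must be nonnegative with zero diagonal")
  D
}

#' Minimum-spanning-tree truncation threshold
#'
#' The longest edge of a minimum spanning tree of the complete intersite
#' graph weighted by Euclidean distance: the smallest distance threshold at
#' which every site remains connected to every other.  This is the truncation
#' distance used to build the PCNM connectivity matrix, and it bounds the
#' finest spatial wavelength the eigenvectors can represent.
#'
#' @param D distance matrix (from [siteDistances()]) or a `dist` object.
#' @return threshold `t` in the units of `D` (meters).
#' @export
mstThreshold <- function(D) {
  D <- asDistanceMatrix(D)
  n <- nrow(D)
  if (n < 2L) stop("invalid input: need at least 2 sites")
  # Prim's algorithm, tracking only the largest edge added.
  in_tree <- rep(FALSE, n)
  in_tree[1L] <- TRUE
  best <- D[1L, ]          # cheapest connection of each vertex to the tree
  best[1L] <- Inf
  t_max <- 0
  for (step in seq_len(n - 1L)) {
    j <- which.min(replace(best, in_tree, Inf))
    t_max <- max(t_max, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, D[j, ])
  }
  unname(t_max)
}
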