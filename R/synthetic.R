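## Synthetic site layouts, planted spatial responses, Poisson case counts.
## These generators make the whole pipeline testable without registry data:
## irregular or lattice layouts, responses that are known linear combinations
## of eigenvectors plus Gaussian noise, and case counts drawn from Poisson
## person-year processes around the planted rates.

#' Regular lattice of sites
#'
#' @param nx,ny lattice dimensions (each >= 2).
#' @param spacing lattice spacing in meters; the MST truncation threshold of
#'   the result equals `spacing`.
#' @return site table (`site_id`, `x`, `y`).
#' @export
makeGridSites <- function(nx, ny, spacing = 1000) {
  if (nx < 2 || ny < 2) stop("invalid parameter: nx and ny must be >= 2")
  if (spacing <= 0) stop("invalid parameter: spacing must be positive")
  g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  data.frame(site_id = sprintf("g%03d", seq_len(nrow(g))),
             x = g$ix * spacing, y = g$iy * spacing,
             stringsAsFactors = FALSE)
}

#' Uniform random sites in a rectangle
#'
#' @param n number of sites (>= 3).
#' @param extent width of the sampling rectangle in meters; a scalar gives a
#'   square, a length-2 vector `c(width, height)` a rectangle.
#' @param seed integer seed; the same seed reproduces the same table.
#' @return site table (`site_id`, `x`, `y`).
#' @export
makeRandomSites <- function(n, extent, seed) {
  if (n < 3) stop("invalid parameter: need n >= 3")
  if (any(extent <= 0)) stop("invalid parameter: extent must be positive")
  if (length(extent) == 1L) extent <- c(extent, extent)
  set.seed(as.integer(seed))
  data.frame(site_id = sprintf("s%04d", seq_len(n)),
             x = stats::runif(n, 0, extent[1L]),
             y = stats::runif(n, 0, extent[2L]),
             stringsAsFactors = FALSE)
}

#' Eigenmap of a site table (convenience composition)
#'
#' Chains [siteDistances()], [mstThreshold()], [truncateDistances()] and
#' [computeEigenmap()] with the standard settings.
#'
#' @param sites site table.
#' @param multiplier truncation fill factor (default 4).
#' @param ... passed to [computeEigenmap()].
#' @return `pcnm_eigenmap`.
#' @export
eigenmapOfSites <- function(sites, multiplier = 4, ...) {
  D <- siteDistances(sites, planar = TRUE)
  t <- mstThreshold(D)
  computeEigenmap(truncateDistances(D, t, multiplier), ...)
}

#' Simulate a spatially structured response with planted eigenvectors
#'
#' `y = sum_j beta_j * score_j + Normal(0, noise_sd^2)`: the model class the
#' regression stage assumes, with known truth for recovery experiments.
#'
#' @param map `pcnm_eigenmap`.
#' @param planted indices of the eigenvector columns carrying signal.
#' @param betas true coefficients, same length as `planted`.
#' @param noise_sd residual standard deviation (>= 0).
#' @param seed integer seed.
#' @return list with `y` (numeric, site order of the map) and `truth`
#'   (list: planted, betas, noise_sd, seed) sufficient to replay `y` exactly.
#' @export
simulateResponse <- function(map, planted, betas, noise_sd, seed) {
  X <- scoreMatrix(map)
  if (length(planted) != length(betas))
    stop("invalid input: planted and betas lengths differ")
  if (length(planted) && (any(planted < 1) || any(planted > ncol(X))))
    stop("invalid index: planted eigenvector outside the retained columns")
  if (noise_sd < 0) stop("invalid parameter: noise_sd must be >= 0")
  set.seed(as.integer(seed))
  signal <- if (length(planted))
    drop(X[, planted, drop = FALSE] %*% betas) else rep(0, nrow(X))
  y <- signal + stats::rnorm(nrow(X), 0, noise_sd)
  list(y = y,
       truth = list(planted = planted, betas = betas,
                    noise_sd = noise_sd, seed = as.integer(seed)))
}

#' Simulate Poisson case counts around true rates
#'
#' `cases_i ~ Poisson(rate_i * py_i / scale)`; [pooledRate()] applied to the
#' output is an unbiased estimate of the true rates.
#'
#' @param true_rates per-site rates on the `scale` denominator (>= 0).
#' @param py_per_site person-years per site (positive; recycled if scalar).
#' @param seed integer seed.
#' @param site_id optional identifiers (default s0001...).
#' @param scale rate denominator (default per 1,000 person-years).
#' @return list with `cases` and `person_years` tables in the standard
#'   delimited-text layout.
#' @export
simulateCaseCounts <- function(true_rates, py_per_site, seed,
                               site_id = NULL, scale = 1000) {
  if (any(true_rates < 0)) stop("invalid parameter: negative true rate")
  if (any(py_per_site <= 0)) stop("invalid parameter: person-years must be positive")
  n <- length(true_rates)
  py <- rep_len(py_per_site, n)
  if (is.null(site_id)) site_id <- sprintf("s%04d", seq_len(n))
  set.seed(as.integer(seed))
  cases <- stats::rpois(n, true_rates * py / scale)
  list(cases = data.frame(site_id = site_id, cases = cases,
                          stringsAsFactors = FALSE),
       person_years = data.frame(site_id = site_id, person_years = py,
                                 stringsAsFactors = FALSE))
}

#' Define a synthetic recovery scenario
#'
#' @param layout site table, e.g. [makeGridSites()] output.
#' @param planted,betas planted eigenvector indices and true coefficients.
#' @param noise_sd residual standard deviation; if `NULL`, derived from
#'   `snr` as `sqrt(var(signal) / snr)`.
#' @param snr signal-to-noise ratio used when `noise_sd` is `NULL`.
#' @param alpha entry level for selection.
#' @return list of class `pcnm_scenario` with the resolved eigenmap and
#'   noise level.
#' @export
syntheticScenario <- function(layout, planted, betas, noise_sd = NULL,
                              snr = 5, alpha = 0.05) {
  map <- eigenmapOfSites(layout)
  if (is.null(noise_sd)) {
    signal <- if (length(planted))
      drop(map$scores[, planted, drop = FALSE] %*% betas)
      else rep(0, map$n_sites)
    v <- stats::var(signal)
    noise_sd <- if (v > 0) sqrt(v / snr) else 1
  }
  structure(list(map = map, planted = planted, betas = betas,
                 noise_sd = noise_sd, alpha = alpha),
            class = "pcnm_scenario")
}

#' Selection-recovery experiment over seeded replicates
#'
#' Runs [simulateResponse()] plus [forwardSelect()] per replicate, under both
#' the double stopping criterion and plain alpha-only entry on the same
#' simulated response (paired comparison), and summarizes how often the
#' planted eigenvectors are recovered and how many spurious ones enter.
#'
#' @param scenario a `pcnm_scenario`.
#' @param reps number of replicates (>= 1).
#' @param seed base seed; replicate r uses `seed + r`.
#' @return list with per-rule summaries (`double_stop`, `alpha_only`), each
#'   holding `sensitivity` (mean fraction of planted vectors recovered),
#'   `all_recovered_rate` (fraction of replicates recovering every planted
#'   vector), `false_inclusion_rate` (mean fraction of non-planted candidates
#'   selected), `mean_selected`; plus `reps` and the scenario echo.
#' @export
recoveryExperiment <- function(scenario, reps, seed = 1) {
  if (reps < 1) stop("invalid parameter: reps must be >= 1")
  map <- scenario$map
  m <- ncol(map$scores)
  planted <- scenario$planted
  per_rule <- function() list(recovered = numeric(0), all_rec = logical(0),
                              spurious = numeric(0), nsel = integer(0))
  acc <- list(double_stop = per_rule(), alpha_only = per_rule())
  for (r in seq_len(reps)) {
    sim <- simulateResponse(map, planted, scenario$betas,
                            scenario$noise_sd, seed = seed + r)
    for (rule in names(acc)) {
      sel <- forwardSelect(sim$y, map, alpha = scenario$alpha,
                           criterion = rule)$selected
      hit <- if (length(planted)) mean(planted %in% sel) else NA_real_
      acc[[rule]]$recovered <- c(acc[[rule]]$recovered, hit)
      acc[[rule]]$all_rec <- c(acc[[rule]]$all_rec, all(planted %in% sel))
      denom <- m - length(planted)
      acc[[rule]]$spurious <- c(acc[[rule]]$spurious,
                                if (denom > 0)
                                  length(setdiff(sel, planted)) / denom
                                else 0)
      acc[[rule]]$nsel <- c(acc[[rule]]$nsel, length(sel))
    }
  }
  summarize <- function(a) list(
    sensitivity = mean(a$recovered), all_recovered_rate = mean(a$all_rec),
    false_inclusion_rate = mean(a$spurious), mean_selected = mean(a$nsel))
  list(double_stop = summarize(acc$double_stop),
       alpha_only = summarize(acc$alpha_only),
       reps = reps, planted = planted, noise_sd = scenario$noise_sd)
}
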