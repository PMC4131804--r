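## End-to-end pipeline: geometry -> eigenmap -> incidence -> model fit,
## with a staged output directory so failed runs leave no partial files.

#' Assemble and validate a pipeline configuration
#'
#' @param sites path to a site table, or `NULL` when `settlements` is given.
#' @param settlements path to a settlement table (optional; sites are then
#'   derived as population-weighted centroids).
#' @param cases,person_years paths to the case and person-years tables.
#' @param out_dir output directory (created if absent).
#' @param sex_filter `"all"`, `"female"` or `"male"`.
#' @param alpha entry level for forward selection.
#' @param multiplier truncation fill factor (default 4).
#' @param positivity_tol relative eigenvalue tolerance.
#' @param transform `"auto"`, `"never"` or `"always"` (log10 policy).
#' @param criterion `"double_stop"` or `"alpha_only"`.
#' @param cutoff standardized-residual outlier cutoff (default 3).
#' @param scale rate denominator (default 1,000 person-years).
#' @param sep field separator for all tables.
#' @param planar acknowledgment flag for small-magnitude planar coordinates.
#' @param seed integer recorded in the log (the deterministic pipeline itself
#'   draws no random numbers; the seed matters for simulation commands).
#' @return list of class `pcnm_config`.
#' @export
pipelineConfig <- function(sites = NULL, settlements = NULL,
                           cases, person_years, out_dir,
                           sex_filter = "all", alpha = 0.05, multiplier = 4,
                           positivity_tol = 1e-9,
                           transform = "auto",
                           criterion = "double_stop", cutoff = 3,
                           scale = 1000, sep = ",", planar = FALSE,
                           seed = 1L) {
  if (is.null(sites) && is.null(settlements))
    stop("config error: one of sites/settlements is required")
  if (alpha <= 0 || alpha >= 1) stop("config error: alpha must be in (0, 1)")
  if (multiplier <= 1) stop("config error: multiplier must exceed 1")
  cfg <- list(sites = sites, settlements = settlements, cases = cases,
              person_years = person_years, out_dir = out_dir,
              sex_filter = sex_filter, alpha = alpha,
              multiplier = multiplier, positivity_tol = positivity_tol,
              transform = transform, criterion = criterion, cutoff = cutoff,
              scale = scale, sep = sep, planar = planar,
              seed = as.integer(seed))
  class(cfg) <- "pcnm_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match the [pipelineConfig()] arguments.
#' @return `pcnm_config`.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full spatial-incidence pipeline
#'
#' Reads the input tables, derives one representative point per area
#' (weighted centroids if a settlement table is given), builds the truncated
#' distance eigenmap, computes pooled incidence rates with the normality/
#' log10 gate, forward-selects eigenvectors, and writes the report bundle:
#' `eigenmap.csv` (+ eigenvalue sidecar), `scores.geojson`, `rates.csv`,
#' `model.csv`, `selection_trace.csv`, `outliers.csv`, `summary.txt` and
#' `run_log.yaml`.  Every number in the human-readable summary also appears
#' in a machine-readable file.  Outputs are staged in a temporary directory
#' and moved into `out_dir` only on success, so a failed stage leaves no
#' partial bundle.
#'
#' @param config a `pcnm_config` (from [pipelineConfig()] or
#'   [readPipelineConfig()]).
#' @return list (invisibly) with the fitted objects: `sites`, `threshold`,
#'   `map`, `rates`, `response`, `selection`, `outliers`, `files`.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "pcnm_config")) stop("expected a pcnm_config")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sites <- stage("read", {
    if (!is.null(config$settlements)) {
      st <- readSettlementTable(config$settlements, config$sep,
                                config$planar)
      weightedCentroids(st)
    } else readSiteTable(config$sites, config$sep, config$planar)
  })
  cases <- stage("read", readCaseTable(config$cases, config$sep))
  py <- stage("read", readPersonYearsTable(config$person_years, config$sep))
  unknown <- setdiff(unique(cases$site_id), sites$site_id)
  if (length(unknown))
    stop("pipeline stage 'read' failed: case table names site(s) absent ",
         "from the site table: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  D <- stage("geometry", siteDistances(sites, planar = TRUE))
  t_thr <- stage("geometry", mstThreshold(D))
  map <- stage("eigenmaps", computeEigenmap(
    truncateDistances(D, t_thr, config$multiplier),
    positivity_tol = config$positivity_tol))
  rates <- stage("incidence", pooledRate(cases, py, config$sex_filter,
                                         config$scale))
  rates <- rates[match(sites$site_id, rates$site_id), , drop = FALSE]
  if (anyNA(rates$rate))
    stop("pipeline stage 'incidence' failed: no cases/person-years for ",
         "site(s): ",
         paste(sites$site_id[is.na(rates$rate)], collapse = ", "),
         call. = FALSE)
  response <- stage("incidence",
                    prepareResponse(rates, alpha = config$alpha,
                                    transform = config$transform))
  sel <- stage("modelfit", forwardSelect(response, map,
                                         alpha = config$alpha,
                                         criterion = config$criterion))
  outl <- stage("modelfit", outlierReport(sel$model, config$cutoff,
                                          site_id = sites$site_id))

  staging <- file.path(tempfile("pcnmepi_out"))
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  files <- writeReportBundle(staging, config, sites, t_thr, map, rates,
                             response, sel, outl)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  for (f in files) file.copy(file.path(staging, f),
                             file.path(config$out_dir, f), overwrite = TRUE)
  invisible(list(sites = sites, threshold = t_thr, map = map, rates = rates,
                 response = response, selection = sel, outliers = outl,
                 files = file.path(config$out_dir, files)))
}

writeReportBundle <- function(dir, config, sites, t_thr, map, rates,
                              response, sel, outl) {
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = config$sep, row.names = FALSE, quote = FALSE)
  writeEigenmap(map, file.path(dir, "eigenmap.csv"), config$sep)
  writeScoresGeoJSON(sites, map, file.path(dir, "scores.geojson"))
  wt(rates, "rates.csv")
  model <- sel$model
  model_df <- data.frame(
    term = names(model$beta),
    beta = unname(model$beta),
    beta_std = c(NA, unname(model$beta_std)),
    stringsAsFactors = FALSE)
  wt(model_df, "model.csv")
  wt(sel$trace$steps, "selection_trace.csv")
  wt(outl, "outliers.csv")

  summary_lines <- c(
    "Spatial eigenvector incidence model",
    sprintf("sites: %d   truncation threshold t: %.6g m   multiplier: %g",
            nrow(sites), t_thr, config$multiplier),
    sprintf("positive eigenvectors: %d", ncol(map$scores)),
    sprintf("response: pooled rate per %g person-years, transform = %s (KS p = %.4g)",
            config$scale, response$transform, response$ks_p),
    sprintf("selection (%s, alpha = %g): %d vector(s): %s",
            config$criterion, config$alpha, length(sel$selected),
            paste(model$selected, collapse = ", ")),
    sprintf("r = %.4f  r2 = %.4f  adjusted r2 = %.4f  (all-vector ceiling %.4f)",
            model$r, model$r2, model$r2_adj, sel$trace$r2_adj_full),
    sprintf("stop reason: %s", sel$trace$stop_reason),
    sprintf("outliers |z| > %g: %s", config$cutoff,
            paste(outl$site_id[outl$over_threshold], collapse = ", ")),
    sprintf("outliers (Chauvenet, critical |z| = %.4f): %s",
            attr(outl, "chauvenet_critical"),
            paste(outl$site_id[outl$chauvenet], collapse = ", ")))
  writeLines(summary_lines, file.path(dir, "summary.txt"))

  log <- list(config = unclass(config), config_hash = configHash(config),
              n_sites = nrow(sites), threshold = t_thr,
              n_eigenvectors = ncol(map$scores),
              transform = response$transform, ks_p = response$ks_p,
              selected = model$selected, r2 = model$r2,
              r2_adj = model$r2_adj, r2_adj_full = sel$trace$r2_adj_full,
              stop_reason = sel$trace$stop_reason)
  yaml::write_yaml(log, file.path(dir, "run_log.yaml"))
  c("eigenmap.csv", "eigenmap.csv.eigenvalues", "scores.geojson",
    "rates.csv", "model.csv", "selection_trace.csv", "outliers.csv",
    "summary.txt", "run_log.yaml")
}
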