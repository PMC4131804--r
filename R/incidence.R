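## Pooled incidence rates, normality gate, log10 transform.

poolBySite <- function(tab, value_col, sex_filter) {
  if (sex_filter != "all") {
    if (!"sex" %in% names(tab))
      stop("sex-specific analysis requested (", sex_filter, ") but table ",
           "has no sex column; sex-specific denominators are mandatory")
    tab <- tab[tab$sex == sex_filter, , drop = FALSE]
  } else if ("sex" %in% names(tab) && !all(tab$sex == "all")) {
    # pooling both sexes is fine; 'all' rows must then not coexist with
    # sex-specific rows for the same site (double counting)
    for (id in unique(tab$site_id)) {
      s <- tab$sex[tab$site_id == id]
      if ("all" %in% s && length(unique(s)) > 1L)
        stop("site ", id, " mixes sex='all' rows with sex-specific rows")
    }
  }
  stats::aggregate(tab[[value_col]], by = list(site_id = as.character(tab$site_id)),
                   FUN = sum)
}

#' Pooled unadjusted incidence rate per site
#'
#' Sums cases and person-years over all years (and, for `sex_filter = "all"`,
#' over sexes) before dividing, then scales.  Pooling before division is what
#' absorbs zero-case years in small areas: the rate is total cases over total
#' person-years, not an average of annual rates.
#'
#' @param cases data frame with columns `site_id`, `cases` and optionally
#'   `year`, `sex` (`female`/`male`/`all`).
#' @param py data frame with columns `site_id`, `person_years` and optionally
#'   `year`, `sex`.
#' @param sex_filter `"all"`, `"female"` or `"male"`.  Sex-specific responses
#'   require sex-specific denominators; a missing sex column is then an
#'   error, not a fallback.
#' @param scale rate denominator scale; 1000 gives cases per 1,000
#'   person-years.
#' @return data frame with columns `site_id`, `cases`, `person_years`,
#'   `rate` (ordered as in `py` site first appearance, restricted to sites
#'   present in `cases`).
#' @export
pooledRate <- function(cases, py, sex_filter = c("all", "female", "male"),
                       scale = 1000) {
  sex_filter <- match.arg(sex_filter)
  for (nm in c("site_id", "cases")) if (!nm %in% names(cases))
    stop("case table lacks column ", nm)
  for (nm in c("site_id", "person_years")) if (!nm %in% names(py))
    stop("person-years table lacks column ", nm)
  if (any(cases$cases < 0) || any(cases$cases != round(cases$cases)))
    stop("invalid input: cases must be nonnegative integers")
  cs <- poolBySite(cases, "cases", sex_filter)
  ps <- poolBySite(py, "person_years", sex_filter)
  miss <- setdiff(cs$site_id, ps$site_id)
  if (length(miss))
    stop("missing person-years denominator for site(s): ",
         paste(miss, collapse = ", "))
  m <- merge(cs, ps, by = "site_id", sort = FALSE)
  names(m) <- c("site_id", "cases", "person_years")
  if (any(m$person_years <= 0))
    stop("invalid denominator: zero or negative pooled person-years for ",
         "site(s): ",
         paste(m$site_id[m$person_years <= 0], collapse = ", "))
  m$rate <- scale * m$cases / m$person_years
  m[order(match(m$site_id, unique(as.character(py$site_id)))), , drop = FALSE]
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' One-sample test of composite normality with mean and standard deviation
#' estimated from the data.  The default is the Lilliefors-corrected version
#' (the plain KS test with estimated parameters is anti-conservative); the
#' uncorrected test is available as `method = "plain"` for replicating
#' toolchains that use it.
#'
#' @param values numeric vector, `n >= 5`, not constant.
#' @param alpha rejection level.
#' @param method `"lilliefors"` or `"plain"`.
#' @return list with `p`, `statistic`, `reject` (`p < alpha`), `method`.
#' @export
ksNormality <- function(values, alpha = 0.05,
                        method = c("lilliefors", "plain")) {
  method <- match.arg(method)
  if (length(values) < 5L) stop("need at least 5 observations")
  if (stats::sd(values) == 0) stop("undefined test: values are constant")
  if (method == "lilliefors") {
    ht <- nortest::lillie.test(values)
  } else {
    ht <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  }
  list(p = unname(ht$p.value), statistic = unname(ht$statistic),
       reject = unname(ht$p.value) < alpha, method = method)
}

#' Prepare the regression response from pooled rates
#'
#' Tests the pooled rates for normality and, if normality is rejected (or
#' `transform = "always"`), log10-transforms them.  Zero rates make the log
#' transform undefined; by default that is a hard error because pooling over
#' many years is supposed to remove zeros, and silently offsetting would hide
#' data problems.  `zero_policy = "offset"` adds half the smallest nonzero
#' rate before the log and records the offset.
#'
#' @param rates output of [pooledRate()], or a numeric vector of rates (site
#'   ids then taken from names or positions).
#' @param alpha normality rejection level.
#' @param transform `"auto"` (log10 when normality is rejected), `"never"`,
#'   or `"always"`.
#' @param method normality test variant, see [ksNormality()].
#' @param zero_policy `"error"` or `"offset"` for zero rates under log10.
#' @return object of class `pcnm_response`: list with `site_id`, `value`,
#'   `rate` (untransformed), `transform` (`"none"` or `"log10"`), `ks_p`,
#'   `scale_note`, `offset` (0 unless applied).
#' @export
prepareResponse <- function(rates, alpha = 0.05,
                            transform = c("auto", "never", "always"),
                            method = c("lilliefors", "plain"),
                            zero_policy = c("error", "offset")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  zero_policy <- match.arg(zero_policy)
  if (is.data.frame(rates)) {
    site_id <- as.character(rates$site_id)
    r <- rates$rate
  } else {
    r <- as.numeric(rates)
    site_id <- if (!is.null(names(rates))) names(rates)
               else as.character(seq_along(r))
  }
  if (!all(is.finite(r)) || any(r < 0))
    stop("invalid input: rates must be finite and nonnegative")
  ks <- ksNormality(r, alpha = alpha, method = method)
  do_log <- switch(transform,
                   auto = ks$reject, never = FALSE, always = TRUE)
  offset <- 0
  value <- r
  if (do_log) {
    if (any(r == 0)) {
      if (zero_policy == "error")
        stop("zero pooled rate: log10 transform undefined for site(s) ",
             paste(site_id[r == 0], collapse = ", "),
             "; pool over more years or set zero_policy = 'offset'")
      offset <- min(r[r > 0]) / 2
      message("log10 offset applied: +", format(offset),
              " to absorb zero rates")
    }
    value <- log10(r + offset)
  }
  structure(list(site_id = site_id, value = value, rate = r,
                 transform = if (do_log) "log10" else "none",
                 ks_p = ks$p, ks_method = method, offset = offset),
            class = "pcnm_response")
}

#' @export
print.pcnm_response <- function(x, ...) {
  cat("Incidence response over", length(x$value), "sites\n")
  cat("  transform:", x$transform,
      sprintf(" (KS normality p = %.4g, %s)", x$ks_p, x$ks_method), "\n")
  if (x$offset > 0) cat("  log10 offset:", format(x$offset), "\n")
  invisible(x)
}
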