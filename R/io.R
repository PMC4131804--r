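## Delimited-text readers/writers and score exports.
## Dialect: UTF-8, header row required, "." decimal, comma separator by
## default with tab accepted via sep = "\t".

readDelimited <- function(path, required, numeric_cols, sep = ",",
                          what = "table") {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fill = FALSE,
                           colClasses = NA, check.names = TRUE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (nm in intersect(numeric_cols, names(tab))) {
    v <- tab[[nm]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("parse error in ", path, ": non-numeric value '",
             v[bad[1L]], "' in column ", nm, ", line ", bad[1L] + 1L)
      tab[[nm]] <- vn
    }
    if (anyNA(tab[[nm]]))
      stop("parse error in ", path, ": missing value in column ", nm)
  }
  tab$site_id <- as.character(tab$site_id)
  tab
}

#' Read a site table (site_id, x, y)
#' @param path delimited-text file with header.
#' @param sep field separator (`","` default, `"\t"` accepted).
#' @param planar acknowledgment that small-magnitude coordinates are planar
#'   meters; see [siteDistances()].
#' @return validated site data frame.
#' @export
readSiteTable <- function(path, sep = ",", planar = FALSE) {
  tab <- readDelimited(path, c("site_id", "x", "y"), c("x", "y"), sep,
                       "site table")
  validateSites(tab, planar = planar, min_n = 2L)
  tab[, c("site_id", "x", "y")]
}

#' Read a settlement table (site_id, x, y, population)
#' @inheritParams readSiteTable
#' @return settlement data frame.
#' @export
readSettlementTable <- function(path, sep = ",", planar = FALSE) {
  tab <- readDelimited(path, c("site_id", "x", "y", "population"),
                       c("x", "y", "population"), sep, "settlement table")
  if (!planar && looksLikeDegrees(tab$x, tab$y))
    stop("coordinates look like longitude/latitude degrees; pass ",
         "planar = TRUE if they really are planar meters")
  tab[, c("site_id", "x", "y", "population")]
}

#' Read a case table (site_id [, year] [, sex], cases)
#' @inheritParams readSiteTable
#' @return case data frame.
#' @export
readCaseTable <- function(path, sep = ",") {
  tab <- readDelimited(path, c("site_id", "cases"), c("cases"), sep,
                       "case table")
  checkSexColumn(tab, path)
  key <- tab[, intersect(c("site_id", "year", "sex"), names(tab)), drop = FALSE]
  if (anyDuplicated(key))
    stop("parse error in ", path, ": duplicated (site_id, year, sex) row")
  tab
}

#' Read a person-years table (site_id [, year] [, sex], person_years)
#' @inheritParams readSiteTable
#' @return person-years data frame.
#' @export
readPersonYearsTable <- function(path, sep = ",") {
  tab <- readDelimited(path, c("site_id", "person_years"), c("person_years"),
                       sep, "person-years table")
  checkSexColumn(tab, path)
  if (any(tab$person_years <= 0))
    stop("parse error in ", path, ": person_years must be positive")
  tab
}

checkSexColumn <- function(tab, path) {
  if ("sex" %in% names(tab) &&
      !all(tab$sex %in% c("female", "male", "all")))
    stop("parse error in ", path,
         ": sex must be one of female, male, all")
  invisible(tab)
}

#' Write eigenvector scores with an eigenvalue sidecar
#'
#' Writes one row per site (`site_id`, `PCNM1..PCNMm`) to `path` and the
#' eigenvalues to `paste0(path, ".eigenvalues")` (columns `vector`,
#' `eigenvalue`).
#'
#' @param map `pcnm_eigenmap`.
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeEigenmap <- function(map, path, sep = ",") {
  df <- data.frame(site_id = rownames(map$scores), map$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  side <- data.frame(vector = colnames(map$scores), eigenvalue = map$values)
  utils::write.table(side, paste0(path, ".eigenvalues"), sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export site scores as GeoJSON point features
#'
#' Each site becomes a Point feature whose properties carry the site id and
#' its eigenvector scores, ready for choropleth-style mapping of individual
#' spatial scales.  Coordinates are emitted as given (projected meters); the
#' `crs_note` property on the collection records that.
#'
#' @param sites site table aligned with the map's score rows.
#' @param map `pcnm_eigenmap`.
#' @param path output `.geojson` file.
#' @param columns which score columns to attach (default all).
#' @return `path`, invisibly.
#' @export
writeScoresGeoJSON <- function(sites, map, path, columns = NULL) {
  S <- scoreMatrix(map, columns)
  if (nrow(S) != nrow(sites))
    stop("invalid input: sites and scores row counts differ")
  feats <- lapply(seq_len(nrow(sites)), function(i) {
    props <- c(list(site_id = sites$site_id[i]),
               as.list(S[i, , drop = TRUE]))
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(sites$x[i], sites$y[i])),
         properties = props)
  })
  fc <- list(type = "FeatureCollection",
             crs_note = "projected planar meters (not WGS84 degrees)",
             features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
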