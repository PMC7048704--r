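#' File formats
#'
#' All tabular interchange uses tidy long-format CSV (one estimate per
#' row); survey datasets are a directory of four CSV tables plus a JSON
#' sidecar recording the generating configuration; lives-saved
#' scenarios are nested JSON.
#'
#' @name cli_io
NULL

coverage_required_cols <- c("indicator", "year", "stratum_type",
                            "stratum", "coverage")

#' Read and validate a tidy coverage table
#'
#' @param path CSV file with columns `indicator`, `year`,
#'   `stratum_type`, `stratum`, `coverage` (percent; may be empty for
#'   explicitly missing estimates) and optionally `n_weighted`,
#'   `n_unweighted`.
#' @return validated data.frame.
#' @details Rows with coverage outside \[0, 100\] or duplicated
#'   (indicator, year, stratum_type, stratum) keys are rejected with a
#'   row-numbered error; an empty file is an explicit error.
#' @export
read_coverage_table <- function(path) {
  check_that(file.exists(path), "no such file: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_that(nrow(tab) > 0, "coverage table %s is empty", path)
  missing <- setdiff(coverage_required_cols, names(tab))
  check_that(length(missing) == 0, "%s: missing column(s) %s",
             path, paste(missing, collapse = ", "))
  bad <- which(!is.na(tab$coverage) &
                 (tab$coverage < 0 | tab$coverage > 100))
  check_that(length(bad) == 0,
             "%s: coverage out of [0,100] at row(s) %s", path,
             paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(tab$indicator, tab$year, tab$stratum_type, tab$stratum)
  dup <- which(duplicated(key))
  check_that(length(dup) == 0, "%s: duplicate estimate at row(s) %s",
             path, paste(utils::head(dup, 5), collapse = ", "))
  tab
}

#' Write a tidy coverage table
#' @param tab coverage data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a survey dataset to a directory of CSV tables
#'
#' Writes `households.csv`, `women.csv`, `births.csv`, `children.csv`
#' and a `survey.json` sidecar holding the generating configuration and
#' seed, sufficient to regenerate the dataset byte-identically.
#'
#' @param survey an `rmnch_survey`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tb in c("households", "women", "births", "children"))
    utils::write.csv(survey[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE, na = "")
  cfg <- survey$config
  cfg$coverage_spec <- lapply(cfg$coverage_spec, as.numeric)
  cfg$asset_catalog <- as.list(cfg$asset_catalog)   # keep names in JSON
  jsonlite::write_json(
    list(config = unclass(cfg), truth = survey$truth),
    file.path(dir, "survey.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a survey dataset written by [write_survey()]
#' @param dir directory containing the survey tables.
#' @return an `rmnch_survey`.
#' @export
read_survey <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  check_that(file.exists(file.path(dir, "survey.json")),
             "%s does not look like a survey directory", dir)
  meta <- jsonlite::read_json(file.path(dir, "survey.json"),
                              simplifyVector = TRUE)
  hh <- rd("households.csv")
  hh$wealth_quintile <- factor(hh$wealth_quintile,
                               levels = wealth_quintile_levels())
  cfg <- meta$config
  cfg$asset_catalog <- unlist(cfg$asset_catalog)
  cfg <- do.call(survey_config, cfg[setdiff(names(cfg), character())])
  structure(list(households = hh, women = rd("women.csv"),
                 births = rd("births.csv"), children = rd("children.csv"),
                 config = cfg, truth = meta$truth),
            class = "rmnch_survey")
}

#' Read a lives-saved scenario from JSON
#'
#' The JSON mirrors the [list_scenario()] arguments: top-level
#' `base_year`, `target_year`, `births_per_year`, optional
#' `birth_growth`, and `groups` keyed by outcome group, each with
#' `rate`, `per`, optional `causes`, and `interventions` (arrays with
#' `name`, `effectiveness`, `affected_fraction`, `baseline`,
#' `scaleup`).
#'
#' @param path JSON scenario file.
#' @return an `rmnch_scenario`.
#' @export
read_scenario <- function(path) {
  check_that(file.exists(path), "no such file: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  groups <- lapply(raw$groups, function(g) {
    g$causes <- if (!is.null(g$causes)) unlist(g$causes)
    g$interventions <- lapply(g$interventions, function(iv) {
      iv$effectiveness <- unlist(iv$effectiveness)
      iv$affected_fraction <- unlist(iv$affected_fraction %||% 1)
      iv$baseline <- unlist(iv$baseline)
      iv$scaleup <- unlist(iv$scaleup)
      iv
    })
    g
  })
  list_scenario(base_year = raw$base_year, target_year = raw$target_year,
                births_per_year = raw$births_per_year,
                birth_growth = raw$birth_growth %||% 0, groups = groups)
}

#' Bundled published coverage tables
#'
#' Tidy transcriptions of the national coverage trend table
#' (2001-2016), the 2016 urban/rural table and the 2016
#' maternal-education table shipped with the package. Composite-index
#' rows are not included: the CCI is always recomputed from the
#' component coverages.
#'
#' @param which `"trend"`, `"residence"` or `"education"`.
#' @return validated coverage data.frame.
#' @export
nepal_coverage_table <- function(which = c("trend", "residence",
                                           "education")) {
  which <- match.arg(which)
  f <- c(trend = "nepal_coverage_2001_2016.csv",
         residence = "nepal_coverage_2016_residence.csv",
         education = "nepal_coverage_2016_education.csv")[[which]]
  read_coverage_table(system.file("extdata", f, package = "rmnch",
                                  mustWork = TRUE))
}
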