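#' Pipeline orchestration
#'
#' One reproducible run: generate or load data, estimate coverage,
#' compute CCIs, equity tables, trends/projections and the lives-saved
#' scenario, writing tidy outputs plus a run manifest. The whole
#' pipeline is a pure function of (config, seed): rerunning with the
#' same config yields byte-identical CSV outputs.
#'
#' @name pipeline
NULL

#' CCI per year and stratum of a tidy coverage table
#'
#' Computes the CCI for every (year, stratum_type, stratum) cell that
#' carries all eight components; cells with missing components are
#' skipped silently (they are not CCI-able, e.g. education strata of
#' household-level indicators).
#'
#' @param tab tidy coverage data.frame.
#' @return data.frame with `year`, `stratum_type`, `stratum`, `cci`.
#' @export
cci_table <- function(tab) {
  keys <- unique(tab[, c("year", "stratum_type", "stratum")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    val <- tryCatch(
      cci_from_table(tab, k$year, k$stratum_type, k$stratum),
      error = function(e) NA_real_)
    if (!is.na(val))
      rows[[length(rows) + 1L]] <-
        data.frame(year = k$year, stratum_type = k$stratum_type,
                   stratum = k$stratum, cci = val)
  }
  check_that(length(rows) > 0, "no stratum with all eight CCI components")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Stages, in order, each optional depending on the configuration:
#' `simulate` (synthetic survey), `coverage` (weighted estimation),
#' `cci`, `equity`, `trends` (ARC + projection from a multi-year
#' coverage table), `avert` (lives-saved scenario). A stage failure
#' aborts the run with the stage name in the error.
#'
#' @param config a named list (or path to a JSON file) with elements:
#'   `out_dir` (required); `survey` — either arguments for
#'   [survey_config()] or a directory written by [write_survey()];
#'   `coverage_table` — path to a tidy coverage CSV (used for CCI,
#'   equity and trends when no microdata are given, and for trends in
#'   any case); `equity` — list with `year`, `coverage_threshold`,
#'   `gap_threshold`; `trend` — list with `year1`, `year2`,
#'   `target_year`; `scenario` — path to a scenario JSON; `seed` —
#'   overrides the survey seed.
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  check_that(!is.null(config$out_dir), "config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(obj, name, writer = write_coverage_table) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    message(sprintf("[rmnch] stage %-8s ...", name))
    t0 <- Sys.time()
    val <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[rmnch] stage %-8s done (%.2fs)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    val
  }

  survey <- NULL
  if (!is.null(config$survey)) {
    survey <- stage("simulate", {
      if (is.character(config$survey)) {
        read_survey(config$survey)
      } else {
        args <- config$survey
        if (!is.null(config$seed)) args$seed <- config$seed
        if (!is.null(args$coverage_spec))
          args$coverage_spec <- lapply(args$coverage_spec, unlist)
        if (!is.null(args$asset_catalog))
          args$asset_catalog <- unlist(args$asset_catalog)
        args <- args[intersect(names(args), names(formals(survey_config)))]
        sv <- generate_survey(do.call(survey_config, args))
        write_survey(sv, file.path(config$out_dir, "survey"))
        outputs <- c(outputs, file.path(config$out_dir, "survey"))
        sv
      }
    })
  }

  cov <- NULL
  if (!is.null(survey)) {
    cov <- stage("coverage", {
      tab <- estimate_all_coverage(survey)
      emit(tab, "coverage.csv")
      tab
    })
  } else if (!is.null(config$coverage_table)) {
    cov <- stage("coverage", read_coverage_table(config$coverage_table))
  }

  if (!is.null(cov)) {
    stage("cci", emit(cci_table(cov), "cci.csv"))
    eq_cfg <- config$equity %||% list()
    eq_year <- eq_cfg$year %||% max(cov$year, na.rm = TRUE)
    if (any(cov$stratum_type != "overall" & cov$year == eq_year)) {
      stage("equity", {
        eq <- equity_table(cov, eq_year,
                           eq_cfg$coverage_threshold %||% 80,
                           eq_cfg$gap_threshold %||% 10)
        emit(eq, "equity.csv")
        if (any(cov$stratum_type == "wealth_quintile")) {
          ep <- equiplot_data(cov, eq_year)
          emit(ep, "equiplot.json", writer = function(o, p)
            jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
        }
      })
    }
  }

  trend_tab <- if (!is.null(config$coverage_table))
    read_coverage_table(config$coverage_table) else cov
  tr_cfg <- config$trend %||% list()
  if (!is.null(trend_tab) && !is.null(tr_cfg$year1) &&
      !is.null(tr_cfg$year2)) {
    stage("trends", {
      at <- arc_table(trend_tab, tr_cfg$year1, tr_cfg$year2)
      emit(at, "arc.csv")
      tgt <- tr_cfg$target_year %||% 2030
      proj <- do.call(rbind, lapply(seq_len(nrow(at)), function(i) {
        if (is.na(at$arc[i]) || is.na(at$coverage2[i])) return(NULL)
        p <- project_coverage(at$coverage2[i], tr_cfg$year2, at$arc[i], tgt)
        cbind(indicator = at$indicator[i], p)
      }))
      emit(proj, "projection.csv")
    })
  }

  if (!is.null(config$scenario)) {
    stage("avert", {
      sc <- if (is.character(config$scenario)) read_scenario(config$scenario)
            else config$scenario
      av <- deaths_averted(sc)
      emit(av$by_year, "averted.csv")
      emit(av$rates, "mortality_rates.csv")
      emit(list(cumulative = as.list(av$cumulative), mode = av$mode),
           "averted_summary.json",
           writer = function(o, p)
             jsonlite::write_json(o, p, auto_unbox = TRUE, digits = NA))
    })
  }

  manifest <- list(
    tool = "rmnch",
    version = as.character(utils::packageVersion("rmnch")),
    seed = config$seed %||% (config$survey$seed %||% NA),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = unlist(outputs)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
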