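#' Simplified lives-saved engine
#'
#' Translates intervention coverage scale-up into deaths averted, by
#' outcome group (maternal, stillbirth, neonatal, post-neonatal
#' under-five) and cause, in the manner of cohort lives-saved models:
#' baseline deaths are cause-specific mortality rates applied to the
#' birth cohort; each intervention averts a share
#' `effectiveness x affected fraction x coverage change` of the deaths
#' from the causes it acts on; and linked interventions acting on the
#' same cause are combined on the residual hazard,
#'
#' \deqn{reduction = 1 - \prod_i (1 - Eff_i \cdot AF_i \cdot \Delta Cov_i)}
#'
#' so that no death can be averted twice. Demography is deliberately
#' minimal (a constant or geometrically growing annual birth cohort);
#' country databases, indirect effects and nutrition pathways of full
#' lives-saved software are out of scope.
#'
#' @name lives_saved
NULL

# expand a coverage trajectory to one value per simulated year (percent)
expand_trajectory <- function(x, years, what) {
  if (is.data.frame(x)) {
    check_that(all(c("year", "coverage") %in% names(x)),
               "%s: trajectory data.frame needs columns year, coverage", what)
    miss <- setdiff(years, x$year)
    check_that(length(miss) == 0, "%s: trajectory missing year(s) %s",
               what, paste(miss, collapse = ", "))
    x <- x$coverage[match(years, x$year)]
  } else if (length(x) == 1) {
    x <- rep(as.numeric(x), length(years))
  } else {
    check_that(length(x) == length(years),
               "%s: trajectory has %d values for %d years (%d-%d)",
               what, length(x), length(years), min(years), max(years))
    x <- as.numeric(x)
  }
  check_pct(x, what)
  x
}

# per-cause value from a scalar or a named vector
per_cause <- function(x, causes, what) {
  if (is.null(names(x))) {
    check_that(length(x) == 1, "%s must be a scalar or named by cause", what)
    return(stats::setNames(rep(as.numeric(x), length(causes)), causes))
  }
  out <- stats::setNames(rep(0, length(causes)), causes)
  known <- intersect(names(x), causes)
  out[known] <- as.numeric(x[known])
  out
}

#' Build and validate a lives-saved scenario
#'
#' @param base_year,target_year simulated period (annual steps,
#'   inclusive).
#' @param births_per_year live births in the base year.
#' @param birth_growth annual proportional growth of the birth cohort
#'   (default 0: constant cohort).
#' @param groups named list of outcome groups. Each group is a list
#'   with: `rate` (baseline deaths per `per` births, e.g. 21 with
#'   `per = 1000` for a neonatal mortality rate of 21/1000);
#'   `per` (rate denominator, 1000 for child outcomes, 100000 for
#'   maternal); optional `causes`, named proportions of the group
#'   envelope summing to 1 (default: a single cause `"all"`); and
#'   `interventions`, a list of interventions, each a list with
#'   `name`, `effectiveness` (in \[0,1\], scalar or named per cause),
#'   `affected_fraction` (in \[0,1\], scalar or named per cause),
#'   `baseline` and `scaleup` coverage trajectories (percent; scalar,
#'   per-year vector, or a `data.frame(year, coverage)` such as a
#'   [project_coverage()] series).
#' @return an object of class `rmnch_scenario`.
#' @export
list_scenario <- function(base_year, target_year, births_per_year,
                          birth_growth = 0, groups) {
  check_that(target_year >= base_year, "target_year must be >= base_year")
  check_that(births_per_year >= 0, "births_per_year must be nonnegative")
  check_that(is.list(groups) && length(groups) > 0 &&
               !is.null(names(groups)), "groups must be a named list")
  years <- seq(base_year, target_year)
  groups <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    check_that(is.numeric(g$rate) && g$rate >= 0,
               "group %s: rate must be nonnegative", gname)
    g$per <- g$per %||% 1000
    if (is.null(g$causes)) g$causes <- c(all = 1)
    check_that(abs(sum(g$causes) - 1) < 1e-8,
               "group %s: cause fractions must sum to 1", gname)
    check_that(all(g$causes >= 0), "group %s: negative cause fraction", gname)
    g$interventions <- lapply(g$interventions %||% list(), function(iv) {
      check_that(!is.null(iv$name), "interventions must be named")
      what <- sprintf("group %s / intervention %s", gname, iv$name)
      eff <- per_cause(iv$effectiveness, names(g$causes),
                       paste(what, "effectiveness"))
      af <- per_cause(iv$affected_fraction %||% 1, names(g$causes),
                      paste(what, "affected_fraction"))
      check_prob(unname(eff), paste(what, "effectiveness"))
      check_prob(unname(af), paste(what, "affected_fraction"))
      iv$effectiveness <- eff
      iv$affected_fraction <- af
      iv$baseline <- expand_trajectory(iv$baseline, years,
                                       paste(what, "baseline"))
      iv$scaleup <- expand_trajectory(iv$scaleup, years,
                                      paste(what, "scaleup"))
      iv
    })
    g$name <- gname
    g
  })
  names(groups) <- vapply(groups, `[[`, "", "name")
  structure(list(base_year = base_year, target_year = target_year,
                 years = years, births_per_year = births_per_year,
                 birth_growth = birth_growth, groups = groups),
            class = "rmnch_scenario")
}

#' Annual birth cohort of a scenario
#' @param scenario an `rmnch_scenario`.
#' @return numeric vector of births, one per simulated year.
#' @export
scenario_births <- function(scenario) {
  scenario$births_per_year *
    (1 + scenario$birth_growth)^(scenario$years - scenario$base_year)
}

#' Baseline deaths per year, group and cause
#'
#' `deaths(y, cause) = births(y) * rate / per * cause_fraction`; cause
#' totals conserve the group envelope by construction.
#'
#' @param scenario an `rmnch_scenario`.
#' @return data.frame with columns `year`, `group`, `cause`, `deaths`.
#' @export
baseline_deaths <- function(scenario) {
  check_that(inherits(scenario, "rmnch_scenario"),
             "scenario must come from list_scenario()")
  births <- scenario_births(scenario)
  rows <- list()
  for (g in scenario$groups) {
    env <- births * g$rate / g$per
    for (cz in names(g$causes)) {
      rows[[length(rows) + 1L]] <- data.frame(
        year = scenario$years, group = g$name, cause = cz,
        deaths = env * g$causes[[cz]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combined proportional impact of linked interventions on one cause
#'
#' Each intervention contributes `Eff x AF x max(dCov, 0)` where `dCov`
#' is the scale-up minus baseline coverage in year `year_index`,
#' expressed as a proportion and clamped to \[-1, 1\]. Contributions
#' are combined on the residual hazard (`1 - prod(1 - impact_i)`), the
#' mechanism that prevents a death being averted twice; an
#' additive-capped alternative (`min(1, sum)`) is available for
#' sensitivity analysis. With `floor_negative = FALSE`, coverage
#' declines feed through as negative impacts (symmetric mode).
#'
#' @param interventions list of validated interventions (from a
#'   scenario group).
#' @param cause cause name.
#' @param year_index index into the scenario years.
#' @param mode `"residual"` (default) or `"additive"`.
#' @param floor_negative if `TRUE` (default), coverage decreases
#'   contribute no aversion.
#' @return proportional reduction, in \[0, 1\] in the default mode.
#' @export
combined_impact <- function(interventions, cause, year_index,
                            mode = c("residual", "additive"),
                            floor_negative = TRUE) {
  mode <- match.arg(mode)
  impacts <- vapply(interventions, function(iv) {
    dcov <- (iv$scaleup[year_index] - iv$baseline[year_index]) / 100
    dcov <- max(-1, min(1, dcov))
    if (floor_negative) dcov <- max(dcov, 0)
    unname(iv$effectiveness[cause] * iv$affected_fraction[cause] * dcov)
  }, numeric(1))
  if (mode == "residual") 1 - prod(1 - impacts)
  else max(-1, min(1, sum(impacts)))
}

#' Deaths averted by coverage scale-up
#'
#' Runs the scenario year by year: for each outcome group and cause,
#' deaths averted are the baseline deaths times the combined impact of
#' the interventions acting on that cause; scenario deaths are baseline
#' minus averted, and mortality-rate trajectories are recomputed from
#' scenario deaths and the birth cohort.
#'
#' @param scenario an `rmnch_scenario`.
#' @inheritParams combined_impact
#' @return an object of class `rmnch_averted`: list with `by_year`
#'   (year x group: baseline, scenario and averted deaths), `by_cause`
#'   (the same at cause level), `cumulative` (named totals per group
#'   and `"total"`), and `rates` (year x group mortality rates per the
#'   group's denominator, baseline and scenario).
#' @export
deaths_averted <- function(scenario, mode = c("residual", "additive"),
                           floor_negative = TRUE) {
  mode <- match.arg(mode)
  base <- baseline_deaths(scenario)
  births <- scenario_births(scenario)
  ny <- length(scenario$years)
  base$averted <- 0
  for (g in scenario$groups) {
    for (cz in names(g$causes)) {
      sel <- base$group == g$name & base$cause == cz
      red <- vapply(seq_len(ny), function(yi)
        combined_impact(g$interventions, cz, yi, mode, floor_negative),
        numeric(1))
      base$averted[sel] <- base$deaths[sel] * red
    }
  }
  base$scenario_deaths <- base$deaths - base$averted
  by_year <- do.call(rbind, lapply(names(scenario$groups), function(gn) {
    sel <- base$group == gn
    data.frame(year = scenario$years, group = gn,
               baseline_deaths = tapply(base$deaths[sel], base$year[sel], sum),
               scenario_deaths = tapply(base$scenario_deaths[sel],
                                        base$year[sel], sum),
               averted = tapply(base$averted[sel], base$year[sel], sum))
  }))
  rownames(by_year) <- NULL
  cum <- tapply(by_year$averted, by_year$group, sum)
  cum <- c(cum, total = sum(by_year$averted))
  rates <- do.call(rbind, lapply(names(scenario$groups), function(gn) {
    g <- scenario$groups[[gn]]
    sel <- by_year$group == gn
    data.frame(year = by_year$year[sel], group = gn, per = g$per,
               rate_baseline = by_year$baseline_deaths[sel] / births * g$per,
               rate_scenario = by_year$scenario_deaths[sel] / births * g$per)
  }))
  rownames(rates) <- NULL
  structure(list(by_year = by_year, by_cause = base, cumulative = cum,
                 rates = rates, mode = mode),
            class = "rmnch_averted")
}

#' @export
print.rmnch_averted <- function(x, ...) {
  yrs <- range(x$by_year$year)
  cat("Deaths averted (", x$mode, " combination), ",
      yrs[1], "-", yrs[2], ":\n", sep = "")
  for (g in setdiff(names(x$cumulative), "total"))
    cat(sprintf("  %-28s %12.0f\n", g, x$cumulative[[g]]))
  cat(sprintf("  %-28s %12.0f\n", "total", x$cumulative[["total"]]))
  invisible(x)
}
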