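#' RMNCH intervention indicators and the Composite Coverage Index
#'
#' Thirteen standard indicators along the continuum of care, from family
#' planning through under-five case management, estimated as
#' survey-weighted proportions. Eight of them enter the Composite
#' Coverage Index (CCI), a weighted mean across four service domains:
#'
#' \deqn{CCI = \frac{1}{4}\Big(FP + \frac{SBA + ANC}{2} +
#'   \frac{2\,DPT3 + MSL + BCG}{4} + \frac{ORT + CPNM}{2}\Big)}
#'
#' where FP is family-planning demand satisfied, SBA skilled birth
#' attendance, ANC skilled antenatal care, DPT3/MSL/BCG vaccination
#' coverages, ORT diarrhoea treatment and CPNM care-seeking for
#' pneumonia (all percent).
#'
#' @name indicators
NULL

#' Indicator registry
#'
#' Defines, for each indicator, the record table it is measured on, the
#' eligible-population (denominator) rule and the numerator rule.
#' Denominator conventions follow DHS practice: births within the 2-year
#' recall window for delivery/ANC/tetanus care, children 12-23 months
#' for vaccination, children 6-59 months for vitamin A, and children
#' with a recent illness episode for treatment indicators.
#'
#' @return named list of indicator definitions.
#' @export
indicator_definitions <- function() {
  defs <- list(
    cpr_modern = list(
      label = "CPR of modern method", table = "women",
      denominator = function(d) rep(TRUE, nrow(d)),
      numerator = function(d) d$modern_fp == 1L),
    unmet_need = list(
      label = "Unmet need", table = "women",
      denominator = function(d) rep(TRUE, nrow(d)),
      numerator = function(d) d$unmet_need == 1L),
    fp_need_satisfied = list(
      label = "Family planning need satisfied", table = "women",
      denominator = function(d) d$fp_need == 1L,
      numerator = function(d) d$modern_fp == 1L),
    anc_skilled = list(
      label = "ANC by skilled provider", table = "births",
      denominator = function(d) rep(TRUE, nrow(d)),
      numerator = function(d) d$anc_skilled == 1L),
    td2plus = list(
      label = "Tetanus toxoid 2+ doses", table = "births",
      denominator = function(d) rep(TRUE, nrow(d)),
      numerator = function(d) d$td2plus == 1L),
    sba = list(
      label = "SBA assisted delivery", table = "births",
      denominator = function(d) rep(TRUE, nrow(d)),
      numerator = function(d) d$sba == 1L),
    bcg = list(
      label = "BCG vaccination", table = "children",
      denominator = function(d) d$age_months >= 12 & d$age_months <= 23,
      numerator = function(d) d$bcg == 1L),
    dpt3 = list(
      label = "DPT-HiB-Hb vaccination", table = "children",
      denominator = function(d) d$age_months >= 12 & d$age_months <= 23,
      numerator = function(d) d$dpt3 == 1L),
    msl = list(
      label = "Measles rubella vaccination", table = "children",
      denominator = function(d) d$age_months >= 12 & d$age_months <= 23,
      numerator = function(d) d$msl == 1L),
    all_basic_vacc = list(
      label = "All basic vaccination", table = "children",
      denominator = function(d) d$age_months >= 12 & d$age_months <= 23,
      numerator = function(d)
        d$bcg == 1L & d$dpt3 == 1L & d$polio3 == 1L & d$msl == 1L),
    ort = list(
      label = "Treatment of diarrhea by ORT and continued feeding",
      table = "children",
      denominator = function(d) d$diarrhoea == 1L,
      numerator = function(d) d$ort == 1L),
    cpnm = list(
      label = "Care seeking for pneumonia", table = "children",
      denominator = function(d) d$ari == 1L,
      numerator = function(d) d$cpnm == 1L),
    vitamin_a = list(
      label = "Vitamin A supplementation", table = "children",
      denominator = function(d) d$age_months >= 6 & d$age_months <= 59,
      numerator = function(d) d$vitamin_a == 1L),
    water_improved = list(
      label = "Access to improved water source", table = "households",
      denominator = function(d) rep(TRUE, nrow(d)),
      numerator = function(d) d$water_improved == 1L)
  )
  for (nm in names(defs)) defs[[nm]]$name <- nm
  defs
}

# unit table for a definition, joined with household (+ woman) context
analysis_table <- function(survey, def) {
  hh <- survey$households[, c("hh_id", "weight", "residence",
                              "wealth_quintile")]
  switch(def$table,
    households = survey$households,
    women = merge(survey$women, hh, by = "hh_id"),
    births = {
      b <- merge(survey$births,
                 survey$women[, c("woman_id", "hh_id", "education")],
                 by = "woman_id")
      merge(b, hh, by = "hh_id")
    },
    children = {
      ch <- merge(survey$children,
                  survey$women[, c("woman_id", "hh_id", "education")],
                  by = "woman_id")
      merge(ch, hh, by = "hh_id")
    },
    stop("unknown analysis table: ", def$table))
}

#' Survey-weighted coverage estimation
#'
#' Estimates coverage for one indicator as
#' `100 * sum(weights in numerator) / sum(weights in denominator)`,
#' overall or within the levels of a stratifier. Units with a missing
#' numerator response are excluded from both numerator and denominator
#' (complete-case, as in standard survey reporting). A stratum with an
#' empty denominator is returned with `coverage = NA` and a flag, never
#' as a silent zero.
#'
#' @param survey an `rmnch_survey` (or a compatible list of tables).
#' @param indicator indicator name, one of `names(indicator_definitions())`.
#' @param by optional stratifier: `"wealth_quintile"`, `"residence"` or
#'   `"education"` (education applies to woman-linked records only).
#' @return data.frame with columns `indicator`, `year`, `stratum_type`,
#'   `stratum`, `coverage`, `n_weighted`, `n_unweighted`, `flag`.
#' @export
compute_coverage <- function(survey, indicator, by = NULL) {
  defs <- indicator_definitions()
  check_that(indicator %in% names(defs),
             "unknown indicator `%s`", indicator)
  def <- defs[[indicator]]
  d <- analysis_table(survey, def)
  if (!is.null(by)) {
    check_that(by %in% c("wealth_quintile", "residence", "education"),
               "unknown stratifier `%s`", by)
    check_that(by %in% names(d),
               "stratifier `%s` is not defined for the %s table",
               by, def$table)
  }
  in_denom <- def$denominator(d)
  num_val <- def$numerator(d)
  usable <- in_denom & !is.na(num_val)
  strata <- if (is.null(by)) factor(rep("overall", nrow(d)))
            else factor(d[[by]])
  out <- lapply(levels(strata), function(s) {
    sel <- usable & strata == s
    wsum <- sum(d$weight[sel])
    data.frame(
      indicator = indicator,
      year = survey$config$year %||% NA_integer_,
      stratum_type = if (is.null(by)) "overall" else by,
      stratum = s,
      coverage = if (wsum > 0)
        100 * sum(d$weight[sel & num_val]) / wsum else NA_real_,
      n_weighted = wsum,
      n_unweighted = sum(sel),
      flag = if (wsum > 0) "" else "empty_denominator"
    )
  })
  do.call(rbind, out)
}

#' Coverage of all indicators across stratifiers
#'
#' Convenience wrapper producing one tidy coverage table for a survey:
#' every registered indicator, overall and per requested stratifier.
#'
#' @param survey an `rmnch_survey`.
#' @param indicators indicator names (default: all registered).
#' @param stratifiers character vector drawn from `"overall"`,
#'   `"wealth_quintile"`, `"residence"`, `"education"`.
#' @return tidy coverage data.frame (see [compute_coverage()]).
#' @export
estimate_all_coverage <- function(survey,
                                  indicators = names(indicator_definitions()),
                                  stratifiers = c("overall",
                                                  "wealth_quintile",
                                                  "residence",
                                                  "education")) {
  defs <- indicator_definitions()
  rows <- list()
  for (ind in indicators) {
    for (s in stratifiers) {
      if (s != "overall" && s == "education" &&
          defs[[ind]]$table == "households") next
      rows[[length(rows) + 1L]] <-
        compute_coverage(survey, ind, by = if (s == "overall") NULL else s)
    }
  }
  do.call(rbind, rows)
}

#' CCI component symbols and the indicators they map to
#' @return named character vector: component symbol -> indicator name.
#' @export
cci_components <- function() {
  c(FP = "fp_need_satisfied", SBA = "sba", ANC = "anc_skilled",
    DPT3 = "dpt3", MSL = "msl", BCG = "bcg", ORT = "ort", CPNM = "cpnm")
}

#' Compute the Composite Coverage Index
#'
#' Weighted mean of eight intervention coverages across the four
#' domains family planning, maternity care, immunization and case
#' management. The FP term is family-planning *demand satisfied* (not
#' modern contraceptive prevalence). Returned unrounded; use
#' [round_half_up()] for table-style presentation.
#'
#' @param components named numeric vector of the eight coverages in
#'   percent; names may be the component symbols (`FP`, `SBA`, `ANC`,
#'   `DPT3`, `MSL`, `BCG`, `ORT`, `CPNM`) or the corresponding
#'   indicator names.
#' @return CCI in percent (numeric scalar, unrounded).
#' @examples
#' compute_cci(c(FP = 64, SBA = 63, ANC = 86, DPT3 = 86,
#'               MSL = 90, BCG = 98, ORT = 61.4, CPNM = 84.9))
#' @export
compute_cci <- function(components) {
  map <- cci_components()
  x <- components
  # translate indicator names to symbols where needed
  idx <- match(names(x), map)
  names(x)[!is.na(idx)] <- names(map)[idx[!is.na(idx)]]
  missing <- setdiff(names(map), names(x))
  check_that(length(missing) == 0,
             "missing CCI component(s): %s", paste(missing, collapse = ", "))
  x <- x[names(map)]
  check_that(!anyNA(x), "CCI components must not be NA")
  check_pct(unname(x), "CCI components")
  as.numeric(
    (x["FP"] + (x["SBA"] + x["ANC"]) / 2 +
       (2 * x["DPT3"] + x["MSL"] + x["BCG"]) / 4 +
       (x["ORT"] + x["CPNM"]) / 2) / 4)
}

#' CCI from a tidy coverage table
#'
#' Extracts the eight component coverages for one year and stratum from
#' a tidy coverage table (as produced by [estimate_all_coverage()] or
#' [read_coverage_table()]) and computes the CCI on them. When the table
#' holds printed (rounded) values, the CCI inherits that rounding in its
#' inputs, matching how published stratified CCIs are reproduced.
#'
#' @param tab tidy coverage data.frame.
#' @param year survey year to select.
#' @param stratum_type,stratum stratum selector (defaults: overall).
#' @return CCI in percent (unrounded combination of the table's values).
#' @export
cci_from_table <- function(tab, year, stratum_type = "overall",
                           stratum = "overall") {
  map <- cci_components()
  sel <- tab$year == year & tab$stratum_type == stratum_type &
    tab$stratum == stratum & tab$indicator %in% map
  sub <- tab[sel, , drop = FALSE]
  comp <- stats::setNames(sub$coverage, sub$indicator)
  missing <- setdiff(map, names(comp))
  check_that(length(missing) == 0,
             "coverage table lacks CCI component(s): %s for %s/%s/%s",
             paste(missing, collapse = ", "), year, stratum_type, stratum)
  compute_cci(comp)
}
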