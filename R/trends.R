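#' Coverage trends: annualized rate of change and projection
#'
#' Between two survey years, coverage change is summarised by the
#' annualized rate of change (ARC), the geometric per-year growth rate
#'
#' \deqn{ARC = \left(\left(\frac{c_{t_2}}{c_{t_1}}\right)^{1/(t_2-t_1)}
#'   - 1\right)\times 100}
#'
#' positive when coverage increases. Projection compounds the ARC
#' forward from a base year, clamped to the meaningful range
#' \[0, 100\]%.
#'
#' @name trends
NULL

#' Annualized rate of change between two coverage observations
#'
#' @param c1,c2 coverage percent at the earlier and later year; `c1`
#'   must be positive.
#' @param t1,t2 calendar years with `t2 > t1`.
#' @return ARC in percent per year (unrounded).
#' @examples
#' arc(12, 63, 2001, 2016)   # ~11.7 %/yr
#' @export
arc <- function(c1, c2, t1, t2) {
  check_pct(c1, "c1"); check_pct(c2, "c2")
  check_that(all(c1 > 0), "ARC is undefined for zero baseline coverage")
  check_that(all(t2 > t1), "t2 must be after t1")
  ((c2 / c1)^(1 / (t2 - t1)) - 1) * 100
}

#' Project coverage forward at a constant annualized rate
#'
#' Compound growth from the base observation, with values clamped to
#' \[0, 100\] percent; the series records in which years the cap or
#' floor binds.
#'
#' @param base_coverage coverage percent in the base year.
#' @param base_year base calendar year.
#' @param arc annualized rate of change, percent per year.
#' @param target_year final projection year (>= base year).
#' @return data.frame with columns `year`, `coverage` (clamped),
#'   `uncapped` (raw compound-growth value) and `capped` (logical).
#' @examples
#' project_coverage(63, 2016, 11.7, 2030)
#' @export
project_coverage <- function(base_coverage, base_year, arc, target_year) {
  check_pct(base_coverage, "base_coverage")
  check_that(is.finite(arc), "arc must be finite")
  check_that(target_year >= base_year, "target_year must be >= base_year")
  years <- seq(base_year, target_year)
  raw <- base_coverage * (1 + arc / 100)^(years - base_year)
  clamped <- pmin(100, pmax(0, raw))
  data.frame(year = years, coverage = clamped, uncapped = raw,
             capped = raw != clamped)
}

#' ARC per indicator from a tidy coverage table
#'
#' Computes the two-point ARC between a pair of survey years for every
#' indicator in the table (overall stratum). Indicators missing either
#' year, or with zero or missing baseline coverage, get `NA` rather
#' than an error.
#'
#' @param tab tidy coverage data.frame.
#' @param year1,year2 the two survey years (`year2 > year1`).
#' @return data.frame with `indicator`, the two coverages, `change`
#'   (percentage points) and `arc` (%/yr, unrounded).
#' @export
arc_table <- function(tab, year1, year2) {
  check_that(year2 > year1, "year2 must be after year1")
  ov <- tab[tab$stratum_type == "overall", , drop = FALSE]
  inds <- unique(ov$indicator)
  pick <- function(ind, yr) {
    v <- ov$coverage[ov$indicator == ind & ov$year == yr]
    if (length(v) == 1) v else NA_real_
  }
  res <- do.call(rbind, lapply(inds, function(ind) {
    c1 <- pick(ind, year1); c2 <- pick(ind, year2)
    a <- if (!is.na(c1) && !is.na(c2) && c1 > 0)
      arc(c1, c2, year1, year2) else NA_real_
    data.frame(indicator = ind, year1 = year1, year2 = year2,
               coverage1 = c1, coverage2 = c2,
               change = c2 - c1, arc = a)
  }))
  rownames(res) <- NULL
  res
}
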