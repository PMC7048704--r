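#' Equity analysis: two-stratum gaps and coverage-by-inequity patterns
#'
#' Inequity in intervention coverage is summarised by comparing an
#' advantaged stratum (wealthiest quintile, urban, educated) with a
#' disadvantaged one (poorest, rural, no education): the difference in
#' percentage points and the ratio. Combining overall coverage with the
#' gap classifies each intervention into one of four patterns
#' (high/low coverage x high/low inequity), the standard display for
#' prioritising equity-oriented programming.
#'
#' @name equity
NULL

#' Two-stratum equity gap
#'
#' @param cov_advantaged,cov_disadvantaged coverage (percent) in the
#'   advantaged and disadvantaged strata.
#' @param indicator optional indicator name carried into the result.
#' @param pair optional length-2 character naming the strata, e.g.
#'   `c("urban", "rural")`.
#' @return data.frame with coverage of both strata, `difference`
#'   (advantaged - disadvantaged, percentage points), `ratio`
#'   (advantaged / disadvantaged; `NA` flagged when the disadvantaged
#'   coverage is zero), and a `flag` column.
#' @examples
#' equity_gap(71.4, 52.8, "sba", c("urban", "rural"))
#' @export
equity_gap <- function(cov_advantaged, cov_disadvantaged,
                       indicator = NA_character_,
                       pair = c("advantaged", "disadvantaged")) {
  check_pct(cov_advantaged, "cov_advantaged")
  check_pct(cov_disadvantaged, "cov_disadvantaged")
  check_that(length(pair) == 2, "pair must name two strata")
  ratio <- ifelse(cov_disadvantaged > 0,
                  cov_advantaged / cov_disadvantaged, NA_real_)
  data.frame(
    indicator = indicator,
    stratum_advantaged = pair[1],
    stratum_disadvantaged = pair[2],
    coverage_advantaged = cov_advantaged,
    coverage_disadvantaged = cov_disadvantaged,
    difference = cov_advantaged - cov_disadvantaged,
    ratio = ratio,
    flag = ifelse(cov_disadvantaged > 0, "", "undefined_ratio")
  )
}

#' Classify an intervention into a coverage-by-inequity pattern
#'
#' Coverage at or above `coverage_threshold` counts as high coverage;
#' an absolute gap at or above `gap_threshold` counts as high inequity
#' (the absolute value is used so that a pro-disadvantaged gap, e.g.
#' measles at -4.2 points, still reads as low inequity only when
#' small). The default thresholds of 80% coverage and 10 percentage
#' points are configurable, not baked into the logic.
#'
#' @param overall_coverage coverage percent.
#' @param gap equity gap in percentage points (signed).
#' @param coverage_threshold,gap_threshold classification cut-points.
#' @return data.frame with the inputs, the thresholds used, and
#'   `pattern`, one of `"high coverage & low inequity"`,
#'   `"high coverage & high inequity"`, `"low coverage & low inequity"`,
#'   `"low coverage & high inequity"`.
#' @examples
#' classify_pattern(86, 17.6)   # high coverage & high inequity
#' @export
classify_pattern <- function(overall_coverage, gap,
                             coverage_threshold = 80, gap_threshold = 10) {
  check_pct(overall_coverage, "overall_coverage")
  check_that(all(is.finite(gap)), "gap must be finite")
  hi_cov <- overall_coverage >= coverage_threshold
  hi_gap <- abs(gap) >= gap_threshold
  pattern <- paste0(ifelse(hi_cov, "high", "low"), " coverage & ",
                    ifelse(hi_gap, "high", "low"), " inequity")
  data.frame(
    coverage = overall_coverage, gap = gap,
    coverage_threshold = coverage_threshold,
    gap_threshold = gap_threshold,
    pattern = pattern
  )
}

#' Equiplot-ready records
#'
#' Reshapes per-quintile coverage into one record per indicator with
#' the five ordered quintile values and the poorest-wealthiest span —
#' the coordinates an equiplot (dot plot of strata per indicator)
#' needs. Records missing any quintile are flagged incomplete rather
#' than dropped.
#'
#' @param tab tidy coverage data.frame with `stratum_type ==
#'   "wealth_quintile"` rows (others are ignored).
#' @param year survey year to select (default: all years present).
#' @return data.frame with columns `indicator`, `year`, one column per
#'   quintile, `span` (wealthiest - poorest) and `flag`.
#' @export
equiplot_data <- function(tab, year = NULL) {
  q <- tab[tab$stratum_type == "wealth_quintile", , drop = FALSE]
  if (!is.null(year)) q <- q[q$year %in% year, , drop = FALSE]
  check_that(nrow(q) > 0, "no wealth-quintile rows in coverage table")
  levs <- wealth_quintile_levels()
  out <- list()
  for (ind in unique(q$indicator)) for (yr in unique(q$year[q$indicator == ind])) {
    sub <- q[q$indicator == ind & q$year == yr, ]
    vals <- stats::setNames(rep(NA_real_, 5), levs)
    vals[sub$stratum] <- sub$coverage
    rec <- data.frame(indicator = ind, year = yr, t(vals))
    rec$span <- vals["wealthiest"] - vals["poorest"]
    rec$flag <- if (anyNA(vals)) "incomplete" else ""
    out[[length(out) + 1L]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Equity table across standard stratum pairs
#'
#' For every indicator present, computes the gap for the standard
#' advantaged/disadvantaged pairs available in the table:
#' wealthiest vs poorest quintile, urban vs rural, educated
#' (primary+) vs none.
#'
#' @param tab tidy coverage data.frame.
#' @param year survey year.
#' @param coverage_threshold,gap_threshold pattern thresholds passed to
#'   [classify_pattern()]; classification uses the overall coverage row
#'   of each indicator when present.
#' @return data.frame of equity results with pattern labels.
#' @export
equity_table <- function(tab, year, coverage_threshold = 80,
                         gap_threshold = 10) {
  pairs <- list(
    wealth_quintile = c("wealthiest", "poorest"),
    residence = c("urban", "rural"),
    education = c("primary+", "none")
  )
  rows <- list()
  for (st in names(pairs)) {
    adv <- pairs[[st]][1]; dis <- pairs[[st]][2]
    sub <- tab[tab$year == year & tab$stratum_type == st, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (ind in unique(sub$indicator)) {
      a <- sub$coverage[sub$indicator == ind & sub$stratum == adv]
      d <- sub$coverage[sub$indicator == ind & sub$stratum == dis]
      if (length(a) != 1 || length(d) != 1 || is.na(a) || is.na(d)) next
      g <- equity_gap(a, d, ind, c(adv, dis))
      ov <- tab$coverage[tab$year == year & tab$indicator == ind &
                           tab$stratum_type == "overall"]
      g$year <- year
      g$stratum_type <- st
      g$pattern <- if (length(ov) == 1 && !is.na(ov))
        classify_pattern(ov, g$difference, coverage_threshold,
                         gap_threshold)$pattern
      else NA_character_
      rows[[length(rows) + 1L]] <- g
    }
  }
  check_that(length(rows) > 0, "no stratified coverage for year %s", year)
  do.call(rbind, rows)
}
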