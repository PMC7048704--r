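#' Synthetic DHS-style survey microdata
#'
#' Real demographic and health survey microdata are access-controlled, so
#' this module generates household/woman/birth/child tables with a known
#' ground-truth coverage gradient across wealth quintiles. Every
#' downstream stage (coverage estimation, CCI, equity, trends, lives
#' saved) can then be tested against the generator's own parameters.
#'
#' The generator draws a latent household wealth factor, derives binary
#' asset indicators from it, builds the asset index with
#' [compute_asset_index()] and weighted quintiles with
#' [assign_wealth_quintiles()], and finally draws each intervention
#' outcome with the per-quintile probability requested in
#' `coverage_spec`. Because outcomes are drawn conditional on the
#' *constructed* quintile, re-deriving quintiles downstream reproduces
#' the generating strata exactly and coverage recovery is unbiased.
#'
#' @name synthetic_survey
NULL

#' Default asset catalogue
#'
#' Twelve binary asset/housing indicators with baseline ownership
#' probabilities typical of a South Asian DHS round. Ownership
#' probability rises with the latent wealth factor.
#'
#' @return named numeric vector of baseline ownership proportions.
#' @export
default_asset_catalog <- function() {
  c(electricity = 0.75, radio = 0.50, television = 0.45, phone = 0.80,
    refrigerator = 0.30, bicycle = 0.35, motorcycle = 0.25,
    improved_floor = 0.40, improved_roof = 0.55, improved_toilet = 0.60,
    bank_account = 0.45, agricultural_land = 0.65)
}

#' Default ground-truth coverage specification
#'
#' Per-quintile true coverage (percent, poorest to wealthiest) for the
#' directly generated intervention indicators. Values are anchored so
#' the population-level coverage is close to Nepal's 2016 national
#' estimates, with monotone pro-rich gradients of 6-45 percentage
#' points; they are illustrative, not survey transcriptions.
#'
#' @return named list of length-5 numeric vectors (percent).
#' @export
default_coverage_spec <- function() {
  list(
    fp_need_satisfied = c(58, 61, 64, 67, 70),
    anc_skilled       = c(74, 82, 87, 91, 96),
    sba               = c(42, 52, 63, 74, 86),
    td2plus           = c(58, 62, 65, 68, 72),
    bcg               = c(96, 97, 98, 99, 100),
    dpt3              = c(80, 84, 86, 88, 92),
    polio3            = c(78, 82, 85, 88, 92),
    msl               = c(84, 88, 90, 92, 96),
    ort               = c(52, 57, 61, 66, 71),
    cpnm              = c(74, 81, 85, 89, 95),
    vitamin_a         = c(80, 82, 83, 84, 86),
    water_improved    = c(90, 93, 95, 97, 99)
  )
}

#' Build a synthetic-survey configuration
#'
#' @param n_households number of households to simulate (>= 1).
#' @param seed integer RNG seed; required, every draw is reproducible.
#' @param year calendar survey year.
#' @param asset_catalog named vector of baseline asset ownership
#'   proportions (see [default_asset_catalog()]).
#' @param residence_split proportion of households that are urban, in
#'   \[0, 1\]; urban residence is positively associated with wealth.
#' @param education_split proportion of women with at least primary
#'   education, in \[0, 1\]; also wealth-graded.
#' @param coverage_spec named list: per-indicator true coverage per
#'   wealth quintile, percent, length 5 (poorest..wealthiest) or a
#'   scalar recycled to all quintiles. See [default_coverage_spec()].
#' @param fertility_spec mean live births per woman inside the 2-year
#'   recall window (Poisson).
#' @param child_rate mean children under five per woman (Poisson).
#' @param fp_need_prob proportion of women with demand for family
#'   planning (modern use + unmet need); `fp_need_satisfied` coverage
#'   applies within this group.
#' @param diarrhoea_prob two-week diarrhoea episode prevalence in
#'   children under five.
#' @param ari_prob two-week acute-respiratory-infection symptom
#'   prevalence in children under five.
#' @param urban_weight_factor multiplicative design-weight factor for
#'   urban households (< 1 emulates urban oversampling).
#' @param wealth_loading logit-scale loading of asset ownership on the
#'   latent wealth factor; larger values make the asset index a sharper
#'   proxy for wealth.
#' @return an object of class `rmnch_survey_config`.
#' @export
survey_config <- function(n_households,
                          seed,
                          year = 2016,
                          asset_catalog = default_asset_catalog(),
                          residence_split = 0.6,
                          education_split = 0.65,
                          coverage_spec = default_coverage_spec(),
                          fertility_spec = 0.25,
                          child_rate = 0.6,
                          fp_need_prob = 0.66,
                          diarrhoea_prob = 0.08,
                          ari_prob = 0.05,
                          urban_weight_factor = 0.8,
                          wealth_loading = 2.2) {
  check_that(length(n_households) == 1 && n_households >= 1,
             "n_households must be a single count >= 1")
  check_that(length(seed) == 1 && is.finite(seed), "seed is required")
  check_prob(residence_split, "residence_split")
  check_prob(education_split, "education_split")
  check_prob(fp_need_prob, "fp_need_prob")
  check_prob(diarrhoea_prob, "diarrhoea_prob")
  check_prob(ari_prob, "ari_prob")
  check_that(length(asset_catalog) >= 2 && !is.null(names(asset_catalog)),
             "asset_catalog must be a named vector of >= 2 assets")
  check_that(is.list(coverage_spec) && length(coverage_spec) > 0 &&
               !is.null(names(coverage_spec)),
             "coverage_spec must be a named list")
  coverage_spec <- lapply(coverage_spec, function(v) {
    if (length(v) == 1) v <- rep(v, 5)
    check_that(length(v) == 5, "coverage_spec entries must have length 5 or 1")
    check_pct(v, "coverage_spec")
    as.numeric(v)
  })
  check_that(fertility_spec >= 0 && child_rate >= 0,
             "fertility_spec and child_rate must be nonnegative")
  structure(
    list(n_households = as.integer(n_households), seed = as.integer(seed),
         year = as.integer(year), asset_catalog = asset_catalog,
         residence_split = residence_split,
         education_split = education_split,
         coverage_spec = coverage_spec,
         fertility_spec = fertility_spec, child_rate = child_rate,
         fp_need_prob = fp_need_prob, diarrhoea_prob = diarrhoea_prob,
         ari_prob = ari_prob, urban_weight_factor = urban_weight_factor,
         wealth_loading = wealth_loading),
    class = "rmnch_survey_config")
}

# draw Bernoulli outcomes with per-quintile probability spec (percent)
draw_by_quintile <- function(spec_pct, quintile_idx) {
  p <- spec_pct[quintile_idx] / 100
  stats::rbinom(length(quintile_idx), 1L, p)
}

#' Generate a synthetic survey dataset
#'
#' @param config an `rmnch_survey_config` from [survey_config()].
#' @return an object of class `rmnch_survey`: a list with data.frames
#'   `households`, `women`, `births`, `children`, the generating
#'   `config`, and `truth` (the per-indicator, per-quintile
#'   probabilities actually used, percent).
#' @details Identical configs (including seed) yield identical datasets.
#'   Household sampling weights are log-normal with urban households
#'   down-weighted by `urban_weight_factor`. Vaccination indicators are
#'   drawn for every child; indicator definitions restrict denominators
#'   (e.g. 12-23 months) at estimation time. Treatment indicators
#'   (`ort`, `cpnm`) are missing for children without the corresponding
#'   illness episode.
#' @export
generate_survey <- function(config) {
  check_that(inherits(config, "rmnch_survey_config"),
             "config must come from survey_config()")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_households
  wl <- stats::rnorm(n)                       # latent wealth factor

  # assets: logistic in latent wealth
  assets <- sapply(config$asset_catalog, function(p0) {
    stats::rbinom(n, 1L, stats::plogis(stats::qlogis(p0) +
                                         config$wealth_loading * wl))
  })
  assets <- matrix(assets, nrow = n,
                   dimnames = list(NULL, names(config$asset_catalog)))

  residence <- ifelse(
    stats::rbinom(n, 1L, stats::plogis(stats::qlogis(config$residence_split) +
                                         0.8 * wl)) == 1L,
    "urban", "rural")
  weight <- stats::rlnorm(n, meanlog = 0, sdlog = 0.25)
  weight <- weight * ifelse(residence == "urban",
                            config$urban_weight_factor, 1)

  score <- compute_asset_index(assets)
  wq <- assign_wealth_quintiles(score, weight)
  qidx <- as.integer(wq$quintile)
  spec <- config$coverage_spec
  has <- function(ind) !is.null(spec[[ind]])

  households <- data.frame(
    hh_id = seq_len(n), weight = weight, residence = residence,
    wealth_score = score, wealth_quintile = wq$quintile,
    water_improved = if (has("water_improved"))
      draw_by_quintile(spec$water_improved, qidx) else NA_integer_
  )
  households <- cbind(households, as.data.frame(assets))

  # one ever-married woman of reproductive age per household
  education <- ifelse(
    stats::rbinom(n, 1L, stats::plogis(stats::qlogis(config$education_split) +
                                         0.7 * wl)) == 1L,
    "primary+", "none")
  fp_need <- stats::rbinom(n, 1L, config$fp_need_prob)
  satisfied <- if (has("fp_need_satisfied"))
    draw_by_quintile(spec$fp_need_satisfied, qidx) else 0L
  women <- data.frame(
    woman_id = seq_len(n), hh_id = seq_len(n), education = education,
    fp_need = fp_need,
    modern_fp = as.integer(fp_need == 1L & satisfied == 1L),
    unmet_need = as.integer(fp_need == 1L & satisfied == 0L)
  )

  # births in the 2-year recall window
  nb <- stats::rpois(n, config$fertility_spec)
  bwoman <- rep(seq_len(n), nb)
  bq <- qidx[bwoman]
  m <- length(bwoman)
  births <- data.frame(
    birth_id = seq_len(m), woman_id = bwoman,
    year = config$year - sample(0:1, m, replace = TRUE),
    sba = if (has("sba")) draw_by_quintile(spec$sba, bq) else NA_integer_,
    anc_skilled = if (has("anc_skilled"))
      draw_by_quintile(spec$anc_skilled, bq) else NA_integer_,
    td2plus = if (has("td2plus"))
      draw_by_quintile(spec$td2plus, bq) else NA_integer_
  )

  # children under five
  nc <- stats::rpois(n, config$child_rate)
  cwoman <- rep(seq_len(n), nc)
  cq <- qidx[cwoman]
  k <- length(cwoman)
  diarrhoea <- stats::rbinom(k, 1L, config$diarrhoea_prob)
  ari <- stats::rbinom(k, 1L, config$ari_prob)
  ort <- rep(NA_integer_, k)
  if (has("ort") && any(diarrhoea == 1L))
    ort[diarrhoea == 1L] <-
      draw_by_quintile(spec$ort, cq[diarrhoea == 1L])
  cpnm <- rep(NA_integer_, k)
  if (has("cpnm") && any(ari == 1L))
    cpnm[ari == 1L] <- draw_by_quintile(spec$cpnm, cq[ari == 1L])
  children <- data.frame(
    child_id = seq_len(k), woman_id = cwoman,
    age_months = sample(0:59, k, replace = TRUE),
    bcg = if (has("bcg")) draw_by_quintile(spec$bcg, cq) else NA_integer_,
    dpt3 = if (has("dpt3")) draw_by_quintile(spec$dpt3, cq) else NA_integer_,
    polio3 = if (has("polio3"))
      draw_by_quintile(spec$polio3, cq) else NA_integer_,
    msl = if (has("msl")) draw_by_quintile(spec$msl, cq) else NA_integer_,
    diarrhoea = diarrhoea, ort = ort, ari = ari, cpnm = cpnm,
    vitamin_a = if (has("vitamin_a"))
      draw_by_quintile(spec$vitamin_a, cq) else NA_integer_
  )

  truth <- do.call(rbind, lapply(names(spec), function(ind) {
    data.frame(indicator = ind,
               quintile = wealth_quintile_levels(),
               coverage = spec[[ind]])
  }))

  structure(list(households = households, women = women, births = births,
                 children = children, config = config, truth = truth),
            class = "rmnch_survey")
}

#' @export
print.rmnch_survey <- function(x, ...) {
  cat("Synthetic RMNCH survey (year ", x$config$year, ", seed ",
      x$config$seed, ")\n", sep = "")
  cat("  households:", nrow(x$households),
      "| women:", nrow(x$women),
      "| births:", nrow(x$births),
      "| children:", nrow(x$children), "\n")
  invisible(x)
}
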