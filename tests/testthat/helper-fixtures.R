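# Shared fixtures, built in code.

# hand-countable toy survey: 4 households/women, 4 births, 4 children
toy_survey <- function() {
  households <- data.frame(
    hh_id = 1:4, weight = 1,
    residence = c("urban", "urban", "rural", "rural"),
    wealth_score = c(1.2, 0.4, -0.4, -1.2),
    wealth_quintile = factor(
      c("wealthiest", "wealthier", "poorer", "poorest"),
      levels = wealth_quintile_levels()),
    water_improved = c(1L, 1L, 0L, 1L)
  )
  women <- data.frame(
    woman_id = 1:4, hh_id = 1:4,
    education = c("primary+", "primary+", "none", "none"),
    fp_need = c(1L, 1L, 1L, 0L),
    modern_fp = c(1L, 0L, 0L, 0L),
    unmet_need = c(0L, 1L, 1L, 0L)
  )
  births <- data.frame(
    birth_id = 1:4, woman_id = c(1L, 2L, 3L, 4L), year = 2016L,
    sba = c(1L, 0L, 0L, 0L),
    anc_skilled = c(1L, 1L, 0L, 0L),
    td2plus = c(1L, 1L, 1L, 0L)
  )
  children <- data.frame(
    child_id = 1:4, woman_id = c(1L, 2L, 3L, 4L),
    age_months = c(14L, 20L, 13L, 40L),
    bcg = 1L, dpt3 = c(1L, 1L, 0L, 1L), polio3 = 1L,
    msl = c(1L, 0L, 1L, 1L),
    diarrhoea = 0L, ort = NA_integer_, ari = 0L, cpnm = NA_integer_,
    vitamin_a = c(1L, 1L, 0L, 1L)
  )
  structure(list(households = households, women = women, births = births,
                 children = children,
                 config = list(year = 2016L), truth = NULL),
            class = "rmnch_survey")
}

# moderately sized generated survey, memoised across tests
shared_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- survey_config(n_households = 8000, seed = 123)
      cache <<- generate_survey(cfg)
    }
    cache
  }
})

# independent first-principal-component oracle (eigen decomposition of
# the correlation matrix), used to cross-check compute_asset_index()
pca_oracle <- function(assets) {
  x <- as.matrix(assets)
  v <- apply(x, 2, stats::var)
  x <- x[, v > 0, drop = FALSE]
  z <- scale(x)
  ev <- eigen(stats::cor(x), symmetric = TRUE)
  s <- drop(z %*% ev$vectors[, 1])
  if (sum(s * (rowSums(x) - mean(rowSums(x)))) < 0) s <- -s
  as.numeric(scale(s))
}

# minimal single-group scenario builder for lives-saved tests
tiny_scenario <- function(interventions,
                          causes = c(all = 1),
                          rate = 10, per = 1000,
                          births = 100000, years = c(2016, 2020)) {
  list_scenario(
    base_year = years[1], target_year = years[2],
    births_per_year = births,
    groups = list(g = list(rate = rate, per = per, causes = causes,
                           interventions = interventions)))
}

iv <- function(name, eff, af = 1, baseline = 20, scaleup = 60) {
  list(name = name, effectiveness = eff, affected_fraction = af,
       baseline = baseline, scaleup = scaleup)
}
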