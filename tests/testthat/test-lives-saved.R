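test_that("baseline deaths apply rates to the birth cohort", {
  sc <- tiny_scenario(list(), rate = 21, per = 1000, births = 100000)
  bd <- baseline_deaths(sc)
  expect_true(all(bd$deaths == 2100))
  # zero births, zero deaths
  sc0 <- tiny_scenario(list(), births = 0)
  expect_true(all(baseline_deaths(sc0)$deaths == 0))
  # cause split conserves the group envelope
  sc2 <- tiny_scenario(list(), causes = c(a = 0.6, b = 0.4),
                       rate = 10, births = 100000)
  bd2 <- baseline_deaths(sc2)
  expect_equal(bd2$deaths[bd2$cause == "a"][1], 600)
  expect_equal(bd2$deaths[bd2$cause == "b"][1], 400)
  expect_equal(sum(bd2$deaths[bd2$year == 2016]), 1000)
})

test_that("combined impact: hand oracles and residual-hazard combination", {
  sc <- tiny_scenario(list(iv("a", 0.5, 1, baseline = 20, scaleup = 60)))
  g <- sc$groups$g
  expect_equal(combined_impact(g$interventions, "all", 1), 0.2)
  # no coverage change: zero impact
  sc0 <- tiny_scenario(list(iv("a", 0.5, 1, baseline = 60, scaleup = 60)))
  expect_equal(combined_impact(sc0$groups$g$interventions, "all", 1), 0)
  # two interventions each 0.20 alone: 1 - 0.8^2, strictly sub-additive
  sc2 <- tiny_scenario(list(iv("a", 0.5, 1, 20, 60),
                            iv("b", 0.5, 1, 20, 60)))
  expect_equal(combined_impact(sc2$groups$g$interventions, "all", 1), 0.36)
  # additive-capped alternative
  expect_equal(combined_impact(sc2$groups$g$interventions, "all", 1,
                               mode = "additive"), 0.4)
})

test_that("residual combination matches the product oracle exhaustively", {
  set.seed(21)
  for (n_iv in 2:4) for (rep in 1:10) {
    eff <- runif(n_iv); af <- runif(n_iv)
    b <- runif(n_iv, 0, 80); s <- pmin(100, b + runif(n_iv, 0, 40))
    ivs <- lapply(seq_len(n_iv), function(i)
      iv(paste0("i", i), eff[i], af[i], b[i], s[i]))
    sc <- tiny_scenario(ivs)
    impacts <- eff * af * (s - b) / 100
    oracle <- 1 - prod(1 - impacts)
    got <- combined_impact(sc$groups$g$interventions, "all", 1)
    expect_equal(got, oracle, tolerance = 1e-10)
    # never saves a life twice: below the additive sum, above any single
    expect_lte(got, min(1, sum(impacts)) + 1e-12)
    expect_gte(got, max(impacts) - 1e-12)
  }
})

test_that("deaths averted: closed-form toy and conservation", {
  # 1000 deaths/yr, Eff 0.5, AF 1, dCov 0.4, 5 years -> 200/yr, 1000 total
  sc <- tiny_scenario(list(iv("a", 0.5, 1, 20, 60)),
                      rate = 10, births = 100000, years = c(2016, 2020))
  av <- deaths_averted(sc)
  expect_equal(av$by_year$averted, rep(200, 5), tolerance = 1e-10)
  expect_equal(unname(av$cumulative[["g"]]), 1000, tolerance = 1e-10)
  # conservation is exact
  expect_equal(av$by_year$scenario_deaths + av$by_year$averted,
               av$by_year$baseline_deaths)
  # identical trajectories avert nothing
  sc0 <- tiny_scenario(list(iv("a", 0.9, 1, 50, 50)))
  expect_true(all(deaths_averted(sc0)$by_year$averted == 0))
})

test_that("coverage declines avert nothing by default, bite in symmetric mode", {
  sc <- tiny_scenario(list(iv("a", 0.5, 1, baseline = 60, scaleup = 30)))
  expect_true(all(deaths_averted(sc)$by_year$averted == 0))
  sym <- deaths_averted(sc, floor_negative = FALSE)
  expect_true(all(sym$by_year$averted < 0))      # deaths increase
})

test_that("averted never exceeds baseline across random scenarios", {
  set.seed(22)
  for (rep in 1:200) {
    n_iv <- sample(1:4, 1)
    ivs <- lapply(seq_len(n_iv), function(i) {
      b <- runif(1, 0, 100)
      iv(paste0("i", i), runif(1), runif(1), b,
         min(100, b + runif(1, 0, 100 - b)))
    })
    sc <- tiny_scenario(ivs, causes = c(a = 0.7, b = 0.3),
                        rate = runif(1, 1, 50),
                        births = runif(1, 1e4, 1e6),
                        years = c(2016, 2016 + sample(1:6, 1)))
    av <- deaths_averted(sc)
    expect_true(all(av$by_year$averted >= -1e-9))
    expect_true(all(av$by_year$averted <=
                      av$by_year$baseline_deaths + 1e-9))
  }
})

test_that("deaths averted are monotone in effectiveness, AF and coverage", {
  set.seed(23)
  for (rep in 1:50) {
    eff <- runif(1, 0, 0.9); af <- runif(1, 0, 0.9)
    b <- runif(1, 0, 60); s <- runif(1, b, 90)
    base_av <- function(e, a, bb, ss)
      sum(deaths_averted(tiny_scenario(list(iv("x", e, a, bb, ss))))$by_year$averted)
    v0 <- base_av(eff, af, b, s)
    expect_gte(base_av(eff + 0.1, af, b, s), v0)
    expect_gte(base_av(eff, af + 0.1, b, s), v0)
    expect_gte(base_av(eff, af, b, min(100, s + 5)), v0)
  }
})

test_that("scenario validation names the offending input", {
  expect_error(tiny_scenario(list(iv("a", 1.2, 1))), "effectiveness")
  expect_error(tiny_scenario(list(iv("a", 0.5, -0.1))), "affected_fraction")
  expect_error(
    tiny_scenario(list(list(name = "a", effectiveness = 0.5,
                            baseline = 20,
                            scaleup = data.frame(year = 2016:2018,
                                                 coverage = 50)))),
    "2019")
  expect_error(
    list_scenario(2016, 2020, 1000,
                  groups = list(g = list(rate = 10,
                                         causes = c(a = 0.5, b = 0.3)))),
    "sum to 1")
})

test_that("the bundled synthetic scenario runs end to end", {
  path <- system.file("extdata", "scenario_nepal_2016_2030_synthetic.json",
                      package = "rmnch")
  sc <- read_scenario(path)
  expect_s3_class(sc, "rmnch_scenario")
  expect_equal(sc$years, 2016:2030)
  av <- deaths_averted(sc)
  expect_equal(unname(av$cumulative[["total"]]),
               sum(av$by_year$averted))
  expect_true(all(av$rates$rate_scenario <= av$rates$rate_baseline + 1e-9))
  # baseline rates echo the configured national rates in the base year
  r16 <- av$rates[av$rates$year == 2016, ]
  expect_equal(r16$rate_baseline[r16$group == "neonatal"], 21)
  expect_equal(r16$rate_baseline[r16$group == "stillbirth"], 18)
})
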