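test_that("generation is deterministic given the seed", {
  cfg <- survey_config(n_households = 300, seed = 2024)
  a <- generate_survey(cfg)
  b <- generate_survey(cfg)
  for (tb in c("households", "women", "births", "children"))
    expect_identical(a[[tb]], b[[tb]])
  # a different seed changes the draw
  c2 <- generate_survey(survey_config(n_households = 300, seed = 2025))
  expect_false(identical(a$households$weight, c2$households$weight))
})

test_that("boundary coverage specs are honoured exactly", {
  cfg <- survey_config(n_households = 400, seed = 5,
                       coverage_spec = list(sba = 100, bcg = 0))
  sv <- generate_survey(cfg)
  expect_true(all(sv$births$sba == 1L))
  expect_true(all(sv$children$bcg == 0L))
})

test_that("per-quintile coverage is recovered within Monte Carlo tolerance", {
  cfg <- survey_config(n_households = 6000, seed = 31,
                       coverage_spec = list(sba = c(20, 35, 50, 65, 80)))
  sv <- generate_survey(cfg)
  est <- compute_coverage(sv, "sba", by = "wealth_quintile")
  spec <- c(20, 35, 50, 65, 80)
  se <- sqrt(spec / 100 * (1 - spec / 100) / est$n_unweighted) * 100
  expect_true(all(abs(est$coverage - spec) <= 3 * se))
})

test_that("record linkage and weight invariants hold", {
  sv <- shared_survey()
  expect_true(all(sv$births$woman_id %in% sv$women$woman_id))
  expect_true(all(sv$children$woman_id %in% sv$women$woman_id))
  expect_true(all(sv$women$hh_id %in% sv$households$hh_id))
  expect_true(all(sv$households$weight > 0))
  # treatment indicators are missing exactly when no episode occurred
  expect_true(all(is.na(sv$children$ort[sv$children$diarrhoea == 0L])))
  expect_true(all(!is.na(sv$children$ort[sv$children$diarrhoea == 1L])))
  # quintiles partition households with ~20% weighted shares
  shares <- tapply(sv$households$weight, sv$households$wealth_quintile,
                   sum) / sum(sv$households$weight)
  expect_true(all(abs(shares - 0.2) <=
                    max(sv$households$weight) / sum(sv$households$weight)))
})

test_that("invalid configurations are rejected", {
  expect_error(survey_config(100, seed = 1, residence_split = 1.4),
               "proportion")
  expect_error(survey_config(100, seed = 1,
                             coverage_spec = list(sba = c(10, 20, 30, 40, 120))),
               "\\[0, 100\\]")
  expect_error(survey_config(100, seed = 1,
                             coverage_spec = list(sba = c(10, 20))),
               "length 5")
  expect_error(survey_config(0, seed = 1), "n_households")
  expect_error(generate_survey(list()), "survey_config")
})

test_that("survey CSV serialization round-trips", {
  sv <- generate_survey(survey_config(n_households = 250, seed = 77))
  dir <- withr::local_tempdir()
  write_survey(sv, dir)
  expect_true(all(file.exists(file.path(
    dir, c("households.csv", "women.csv", "births.csv", "children.csv",
           "survey.json")))))
  back <- read_survey(dir)
  expect_equal(back$households$weight, sv$households$weight)
  expect_equal(as.character(back$households$wealth_quintile),
               as.character(sv$households$wealth_quintile))
  # downstream estimates agree between original and round-tripped data
  expect_equal(compute_coverage(back, "sba")$coverage,
               compute_coverage(sv, "sba")$coverage)
  expect_equal(back$config$seed, sv$config$seed)
})
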