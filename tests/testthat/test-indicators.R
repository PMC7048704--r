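test_that("coverage is a weighted numerator/denominator share", {
  sv <- toy_survey()
  # 1 of 4 equal-weight births attended
  expect_equal(compute_coverage(sv, "sba")$coverage, 25)
  # all eligible children (12-23 months) got BCG
  expect_equal(compute_coverage(sv, "bcg")$coverage, 100)
  # 2 of 3 children aged 12-23 months have measles vaccination
  est <- compute_coverage(sv, "msl")
  expect_equal(est$coverage, 100 * 2 / 3)
  expect_equal(est$n_unweighted, 3)
  # family-planning demand satisfied: 1 modern user of 3 with need
  expect_equal(compute_coverage(sv, "fp_need_satisfied")$coverage,
               100 * 1 / 3)
})

test_that("stratified estimation splits by household context", {
  sv <- toy_survey()
  est <- compute_coverage(sv, "sba", by = "residence")
  expect_equal(est$coverage[est$stratum == "urban"], 50)
  expect_equal(est$coverage[est$stratum == "rural"], 0)
  edu <- compute_coverage(sv, "anc_skilled", by = "education")
  expect_equal(edu$coverage[edu$stratum == "primary+"], 100)
  expect_equal(edu$coverage[edu$stratum == "none"], 0)
})

test_that("empty denominators are flagged, never silent zeros", {
  sv <- toy_survey()              # no diarrhoea episodes
  est <- compute_coverage(sv, "ort")
  expect_true(is.na(est$coverage))
  expect_equal(est$flag, "empty_denominator")
})

test_that("estimates are invariant to uniform weight rescaling", {
  sv <- shared_survey()
  sv2 <- sv
  sv2$households$weight <- sv2$households$weight * 3.7
  for (ind in c("sba", "msl", "fp_need_satisfied", "water_improved"))
    expect_equal(compute_coverage(sv2, ind)$coverage,
                 compute_coverage(sv, ind)$coverage)
})

test_that("generator round-trip: overall coverage near spec", {
  sv <- shared_survey()
  spec <- sv$config$coverage_spec
  # population shares per quintile are ~equal, so overall ~ mean(spec)
  for (ind in c("sba", "anc_skilled", "msl", "water_improved")) {
    est <- compute_coverage(sv, ind)
    p <- mean(spec[[ind]]) / 100
    se <- sqrt(p * (1 - p) / est$n_unweighted) * 100
    expect_lt(abs(est$coverage - mean(spec[[ind]])), 4 * se + 1)
  }
})

test_that("CCI is the domain-weighted mean with weights summing to one", {
  # CCI(all = k) = k for any k
  for (k in c(0, 13.7, 50, 100)) {
    comp <- setNames(rep(k, 8), names(cci_components()))
    expect_equal(compute_cci(comp), k)
  }
  # convex combination and strict monotonicity on random component sets
  set.seed(42)
  for (rep in 1:25) {
    comp <- setNames(runif(8, 0, 100), names(cci_components()))
    cci <- compute_cci(comp)
    expect_gte(cci, min(comp)); expect_lte(cci, max(comp))
    bump <- comp
    j <- sample(8, 1)
    bump[j] <- min(100, bump[j] + 1)
    if (bump[j] > comp[j]) expect_gt(compute_cci(bump), cci)
  }
})

test_that("CCI accepts indicator names and reports missing components", {
  by_symbol <- compute_cci(c(FP = 64, SBA = 63, ANC = 86, DPT3 = 86,
                             MSL = 90, BCG = 98, ORT = 61.4, CPNM = 84.9))
  by_name <- compute_cci(c(fp_need_satisfied = 64, sba = 63,
                           anc_skilled = 86, dpt3 = 86, msl = 90,
                           bcg = 98, ort = 61.4, cpnm = 84.9))
  expect_equal(by_symbol, by_name)
  expect_error(compute_cci(c(FP = 64, SBA = 63)), "ANC")
  expect_error(compute_cci(c(FP = 164, SBA = 63, ANC = 86, DPT3 = 86,
                             MSL = 90, BCG = 98, ORT = 61.4, CPNM = 84.9)),
               "\\[0, 100\\]")
})

test_that("cci_from_table pulls one stratum's components", {
  tab <- nepal_coverage_table("residence")
  expect_equal(round_half_up(cci_from_table(tab, 2016, "residence", "rural"), 1),
               72.5)
  expect_error(cci_from_table(tab, 2001, "residence", "rural"), "lacks")
})
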