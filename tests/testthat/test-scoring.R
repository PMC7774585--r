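test_that("score-to-RR transformation reproduces all published (PPS, RR) pairs", {
  pairs <- list( # (score, published RR, printed decimals)
    list(9, 7.94, 2), list(18, 63.10, 2), list(-3, 0.5, 1),
    list(14.5, 28.18, 2), list(-14, 0.04, 2), list(-1.75, 0.67, 2),
    list(-15, 0.03, 2), list(39.5, 8912.51, 2), list(0, 1, 2)
  )
  for (p in pairs) {
    expect_equal(round(rr_from_score(p[[1]]), p[[3]]), p[[2]],
                 info = paste("score", p[[1]]))
  }
})

test_that("rr_from_score is log-linear and strictly increasing", {
  set.seed(13)
  a <- stats::runif(100, -20, 50)
  b <- stats::runif(100, -20, 50)
  expect_equal(rr_from_score(a + b), rr_from_score(a) * rr_from_score(b),
               tolerance = 1e-12)
  s <- sort(stats::runif(100, -20, 55))
  expect_true(all(diff(rr_from_score(s)) > 0))
  expect_identical(rr_from_score(0), 1)
})

test_that("resolve_profile applies the conditional item logic", {
  reg <- default_registry()
  # male & 25-35 window, inclusive bounds
  expect_identical(resolve_profile(make_raw(sex = "male", age = 30))$selections[["Male & 25-35 years old"]], "Yes")
  expect_identical(resolve_profile(make_raw(sex = "male", age = 25))$selections[["Male & 25-35 years old"]], "Yes")
  expect_identical(resolve_profile(make_raw(sex = "male", age = 35))$selections[["Male & 25-35 years old"]], "Yes")
  expect_identical(resolve_profile(make_raw(sex = "male", age = 36))$selections[["Male & 25-35 years old"]], "No")
  expect_identical(resolve_profile(make_raw(sex = "female", age = 30))$selections[["Male & 25-35 years old"]], "No")
  # paternal age bins; boundaries 35 and 45 in the middle bin
  bins <- vapply(c(20, 34.9, 35, 45, 45.1, 50), function(a) {
    resolve_profile(make_raw(paternal_age = a))$selections[["Paternal age"]]
  }, "")
  expect_identical(bins, c("<35", "<35", "35-45", "35-45", ">45", ">45"))
  # ethnicity x density combination; density ignored for White
  p <- resolve_profile(make_raw(ethnicity = "black_caribbean", ethnic_density = "medium"))
  expect_identical(p$selections[["Ethnicity"]], "Black Caribbean, medium ethnic density")
  p <- resolve_profile(make_raw(ethnicity = "other", ethnic_density = "high"))
  expect_identical(p$selections[["Ethnicity"]], "Other, high ethnic density")
  p <- resolve_profile(make_raw(ethnicity = "white", ethnic_density = "low"))
  expect_identical(p$selections[["Ethnicity"]], "White")
  # immigration x origin combination
  p <- resolve_profile(make_raw(immigration = "first_generation", origin = "north_africa"))
  expect_identical(p$selections[["Immigration"]], "1st generation, North Africa")
  p <- resolve_profile(make_raw(immigration = "second_generation", origin = "other"))
  expect_identical(p$selections[["Immigration"]], "2nd generation, other region")
})

test_that("resolve_profile emits warnings for implausible combinations, not errors", {
  p <- resolve_profile(make_raw(immigration = "none", origin = "north_africa"))
  expect_match(p$warnings, "non-immigrant", all = FALSE)
  p <- resolve_profile(make_raw(ethnicity = "black_caribbean", ethnic_density = "low",
                                immigration = "first_generation", origin = "north_africa"))
  expect_match(p$warnings, "implausible", all = FALSE)
  p <- resolve_profile(make_raw(age = 12))
  expect_match(p$warnings, "inclusion floor", all = FALSE)
})

test_that("missing-data policy: strict errors name the item, reference imputes", {
  raw <- make_raw(heavy_cannabis = NA)
  expect_error(resolve_profile(raw, policy = "strict"), "heavy_cannabis")
  p <- resolve_profile(raw, policy = "reference")
  expect_identical(p$selections[["Heavy cannabis use"]], "No")
  expect_match(p$warnings, "imputed reference", all = FALSE)
  # conditional sub-item missing
  raw <- make_raw(immigration = "first_generation", origin = NA)
  expect_error(resolve_profile(raw, policy = "strict"), "origin")
  p <- resolve_profile(raw, policy = "reference")
  expect_identical(p$selections[["Immigration"]], "Not immigrant")
})

test_that("unknown categorical labels are rejected", {
  expect_error(resolve_profile(make_raw(ethnicity = "martian")), "ethnicity")
  expect_error(resolve_profile(make_raw(sex = "unknown")), "sex")
  expect_error(resolve_profile(make_raw(immigration = "third_generation")), "immigration")
  expect_error(resolve_profile(make_raw(ethnicity = "other", ethnic_density = "sparse")),
               "ethnic_density")
})

test_that("score_profile: extreme profiles hit the enumeration-oracle bounds", {
  reg <- default_registry()
  totals <- enumerate_totals(reg) # independent oracle over all level choices
  expect_identical(min(totals), -16)
  expect_identical(max(totals), 54)
  all_ref <- vapply(reg$groups, function(g) g$reference_level, "")
  expect_identical(score_profile(all_ref, reg)$total, -16)
  all_max <- vapply(reg$groups, function(g) {
    g$levels$label[which.max(g$levels$weight)]
  }, "")
  expect_identical(score_profile(all_max, reg)$total, 54)
})

test_that("score_profile totals and contributions are consistent", {
  reg <- default_registry()
  sc <- score_profile(resolve_profile(make_raw()), reg)
  expect_identical(sc$total, sum(sc$contributions))
  expect_setequal(names(sc$contributions), names(reg$groups))
  expect_equal(sc$relative_risk, 10^(sc$total / 10))
  # heavy cannabis toggles the total by exactly its weight
  sc_yes <- score_profile(resolve_profile(make_raw(heavy_cannabis = TRUE)), reg)
  expect_identical(sc_yes$total - sc$total, 7)
  # random profiles stay on the half-point grid inside the oracle bounds
  set.seed(23)
  for (i in 1:50) {
    sel <- vapply(reg$groups, function(g) sample(g$levels$label, 1), "")
    tot <- score_profile(sel, reg)$total
    expect_true(tot >= -16 && tot <= 54 && abs(tot * 2 - round(tot * 2)) < 1e-9)
  }
})

test_that("score_profile rejects incomplete or mislabelled profiles", {
  reg <- default_registry()
  sel <- vapply(reg$groups, function(g) g$reference_level, "")
  expect_error(score_profile(sel[-1], reg), "missing group")
  sel_bad <- sel
  sel_bad[["Pollution"]] <- "Maybe"
  expect_error(score_profile(sel_bad, reg), "unknown level 'Maybe'")
})

test_that("score_cohort summarises totals with quartile ranges and strict thresholds", {
  # four respondents engineered (from the all-reference total of -16) to
  # score exactly -2, 0, 6 and 16
  records <- list(
    make_raw(respondent_id = "A", childhood_trauma = TRUE, pollution = TRUE,
             non_right_handedness = TRUE),                          # -16 + 14 = -2
    make_raw(respondent_id = "B", parental_smi = TRUE, adult_life_events = TRUE,
             low_paternal_ses = TRUE),                              # -16 + 16 = 0
    make_raw(respondent_id = "C", heavy_cannabis = TRUE, trait_anhedonia = TRUE,
             pollution = TRUE, low_paternal_ses = TRUE),            # -16 + 22 = 6
    make_raw(respondent_id = "D", heavy_cannabis = TRUE, trait_anhedonia = TRUE,
             parental_smi = TRUE, adult_life_events = TRUE,
             urbanicity = TRUE)                                     # -16 + 32 = 16
  )
  out <- score_cohort(records, thresholds = c(5, 15))
  totals <- vapply(out$results, `[[`, numeric(1), "total")
  expect_identical(totals, c(-2, 0, 6, 16))
  expect_equal(out$summary$threshold_proportions, c("5" = 50, "15" = 25))
  expect_equal(sum(out$summary$quartile_ranges$pct), 100)
  expect_equal(out$summary$mean, 5)
  expect_equal(out$summary$median, 3)
  # single respondent: mean = median = total, sd = 0
  one <- score_cohort(records[1])
  expect_equal(one$summary$mean, -2)
  expect_equal(one$summary$median, -2)
  expect_equal(one$summary$sd, 0)
})

test_that("score_cohort is invariant to respondent ordering and deterministic", {
  fix <- generate_fixture_cohort(n = 60, seed = 402)
  a <- score_cohort(fix)$summary
  set.seed(1)
  b <- score_cohort(fix[sample(nrow(fix)), ])$summary
  for (f in c("n", "mean", "sd", "median", "quartile_ranges", "threshold_proportions")) {
    expect_equal(a[[f]], b[[f]], info = f)
  }
  c2 <- score_cohort(generate_fixture_cohort(n = 60, seed = 402))$summary
  expect_equal(a, c2)
})

test_that("score_cohort policies and guard rails", {
  expect_error(score_cohort(list()), "empty cohort")
  expect_error(score_cohort(list(make_raw()), thresholds = c(15, 5)),
               "strictly increasing")
  records <- list(make_raw(respondent_id = "ok"),
                  make_raw(respondent_id = "gap", daily_smoker = NA))
  expect_error(score_cohort(records, policy = "strict"), "daily_smoker")
  out <- score_cohort(records, policy = "exclude")
  expect_identical(out$summary$n, 1L)
  expect_identical(out$summary$excluded, "gap")
  out <- score_cohort(records, policy = "reference")
  expect_identical(out$summary$n, 2L)
  # proportion above 5 is never below proportion above 15
  expect_true(out$summary$threshold_proportions[["5"]] >=
                out$summary$threshold_proportions[["15"]])
})
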