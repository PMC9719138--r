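test_that("the death definition matches a brute-force truth table", {
  grid <- expand.grid(ed = c("expired", "admitted_inpatient", "observation",
                             "transferred", "discharged", "other"),
                      hosp = c("expired", "discharged", "transferred",
                               "other", "not_applicable"),
                      stringsAsFactors = FALSE)
  cases <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    make_case(case_id = paste0("C", i), ed_disposition = grid$ed[i],
              hospital_disposition = grid$hosp[i])
  }))
  kept <- filter_trauma_deaths(cases)
  expected <- vapply(seq_len(nrow(grid)),
                     function(i) naive_is_death(grid$ed[i], grid$hosp[i]),
                     TRUE)
  expect_setequal(kept$case_id, cases$case_id[expected])
  # transfer breaks the admission chain even if the patient later expired
  expect_false("expired" %in% grid$hosp[grid$ed == "transferred"] &&
                 any(kept$ed_disposition == "transferred"))
  # order preserved
  expect_identical(kept$case_id, cases$case_id[expected])
})

test_that("decedent filters drop by year, age, type and arrival with a cascade", {
  cases <- rbind(
    make_case("keep1"),
    make_case("keep2", ed_disposition = "admitted_inpatient",
              hospital_disposition = "expired"),
    make_case("y", year = 2013L),
    make_case("a15", age = 15L),
    make_case("a16", age = 16L),
    make_case("burn", trauma_type = "burn"),
    make_case("car", arrival_mode = "private_vehicle"),
    make_case("alive", ed_disposition = "discharged",
              hospital_disposition = "discharged")
  )
  kept <- filter_trauma_deaths(cases)
  expect_identical(kept$case_id, c("keep1", "keep2", "a16"))
  cascade <- attr(kept, "cascade")
  expect_equal(cascade$n_dropped[cascade$criterion == "age_under_16"], 1)
  expect_equal(sum(cascade$n_dropped), nrow(cases) - nrow(kept))
})

test_that("classify_vitals honors strict thresholds and any-reading semantics", {
  cases <- rbind(
    make_case("hypo", ems_sbp = "89", ems_hr = "80"),
    make_case("boundary", ems_sbp = "90", ems_hr = "110"),
    make_case("none", ems_sbp = "", ems_hr = ""),
    make_case("any", ems_sbp = "120;85", ems_hr = "90"),
    make_case("tachy", ems_sbp = "140", ems_hr = "111"),
    make_case("hr_only", ems_sbp = "", ems_hr = "130")
  )
  expect_equal(classify_vitals(cases),
               c("hypotensive", "neither", "missing", "hypotensive",
                 "tachycardic_only", "tachycardic_only"))
  expect_error(classify_vitals(cases, sbp_threshold = -5), "positive")
})

test_that("classify_vitals agrees with the per-reading brute-force oracle", {
  set.seed(404)
  for (i in 1:100) {
    sbp <- sample(60:150, sample(0:3, 1))
    hr <- sample(50:160, sample(0:3, 1))
    case <- data.frame(ems_sbp = paste(sbp, collapse = ";"),
                       ems_hr = paste(hr, collapse = ";"))
    expect_equal(classify_vitals(case), naive_classify(sbp, hr),
                 info = paste("sbp:", case$ems_sbp, "hr:", case$ems_hr))
  }
})

test_that("vitals classification is threshold-monotone and partitions", {
  g <- gen_ntdb_cases(ntdb_gen_params(seed = 5, n_deaths = 2000))
  deaths <- filter_trauma_deaths(g$cases)
  for (t in c(70, 80, 90, 100)) {
    lower <- sum(classify_vitals(deaths, sbp_threshold = t) == "hypotensive")
    higher <- sum(classify_vitals(deaths, sbp_threshold = t + 10) == "hypotensive")
    expect_lte(lower, higher)
  }
  for (t in c(90, 110, 130)) {
    cls_lo <- classify_vitals(deaths, hr_threshold = t)
    cls_hi <- classify_vitals(deaths, hr_threshold = t + 20)
    expect_gte(sum(cls_lo != "neither" & cls_lo != "missing"),
               sum(cls_hi != "neither" & cls_hi != "missing"))
  }
  s <- summarize_vitals(deaths)
  cls <- classify_vitals(deaths)
  expect_equal(sum(cls == "hypotensive") + sum(cls == "tachycardic_only") +
                 sum(cls == "neither"), s$n_complete)
  expect_lte(s$n_hypotensive, s$n_with_sbp)
  expect_gte(s$n_tachy_or_hypo, s$n_hypotensive)
})

test_that("summarize_vitals computes complete-case proportions", {
  cases <- rbind(
    do.call(rbind, lapply(1:90, function(i)
      make_case(paste0("h", i), ems_sbp = "85", ems_hr = "100"))),
    do.call(rbind, lapply(1:410, function(i)
      make_case(paste0("n", i), ems_sbp = "120", ems_hr = "90"))),
    do.call(rbind, lapply(1:500, function(i)
      make_case(paste0("m", i), ems_sbp = "", ems_hr = "")))
  )
  s <- summarize_vitals(cases)
  expect_equal(s$n_deaths_included, 1000L)
  expect_equal(s$n_complete, 500L)
  expect_equal(s$p_hypotensive, 0.18)
  expect_error(summarize_vitals(cases[nzchar(cases$ems_sbp) == FALSE, ]),
               "undefined")
})

test_that("denominator conventions differ only when vitals are partial", {
  cases <- rbind(
    make_case("both", ems_sbp = "85", ems_hr = "90"),
    make_case("sbp_only", ems_sbp = "85", ems_hr = ""),
    make_case("hr_only", ems_sbp = "", ems_hr = "120"),
    make_case("none", ems_sbp = "", ems_hr = "")
  )
  any_v <- summarize_vitals(cases, denominator = "any_vital")
  both_v <- summarize_vitals(cases, denominator = "both_vitals")
  expect_equal(any_v$n_complete, 3L)
  expect_equal(both_v$n_complete, 1L)
  expect_equal(any_v$n_hypotensive, 2L)
  expect_equal(any_v$n_tachy_or_hypo, 3L)
  expect_equal(both_v$n_hypotensive, 1L)
})

test_that("complete-case estimate recovers the generative truth (MAR)", {
  p_true <- 0.181
  g <- gen_ntdb_cases(ntdb_gen_params(seed = 11, n_deaths = 20000))
  deaths <- filter_trauma_deaths(g$cases)
  s <- summarize_vitals(deaths)
  se <- sqrt(p_true * (1 - p_true) / s$n_complete)  # binomial oracle
  expect_lt(abs(s$p_hypotensive - p_true), 3 * se)
  expect_lt(abs(s$p_tachy_or_hypo - 0.402),
            3 * sqrt(0.402 * 0.598 / s$n_complete))
})

test_that("registry extracts round-trip through both reading formats", {
  cases <- rbind(make_case("A", ems_sbp = "120;85", ems_hr = "90"),
                 make_case("B", ems_sbp = "", ems_hr = ""),
                 make_case("C", trauma_type = "penetrating",
                           arrival_mode = "ems_air", ems_sbp = "95",
                           ems_hr = "111;70",
                           ed_disposition = "admitted_inpatient",
                           hospital_disposition = "expired"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trauma_cases(cases, f)
  got <- read_trauma_cases(f)
  expect_equal(as.data.frame(got), as.data.frame(cases))

  # wide numbered columns collapse to the same reading lists
  wide <- data.frame(INC_KEY = c("A", "B"), YOADMIT = 2008, AGE = 30,
                     TRAUMATYPE = "Blunt", TRANSPORT = "Ground Ambulance",
                     EMSSBP1 = c("120", ""), EMSSBP2 = c("85", ""),
                     EMSPULSERATE1 = c("90", ""),
                     EDDISP = "Deceased/Expired", HOSPDISP = "Not Applicable",
                     check.names = FALSE)
  wf <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, wf, row.names = FALSE)
  got_wide <- read_trauma_cases(wf, ntdb_dialect(reading_format = "wide"))
  expect_equal(got_wide$ems_sbp, c("120;85", ""))
  expect_equal(got_wide$ems_hr, c("90", ""))
})
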