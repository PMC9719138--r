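test_that("read_death_strata parses well-formed exports and rejects bad rows", {
  strata <- rbind(make_stratum(count = 5L),
                  make_stratum(state = "NY", mechanism = "fall",
                               intent = "unintentional", count = 3L),
                  make_stratum(state = "TX", mechanism = "drowning",
                               count = 2L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_death_strata(strata, f)
  got <- read_death_strata(f)
  expect_s3_class(got, "death_strata")
  expect_equal(nrow(got), 3L)
  expect_equal(got$count, c(5L, 3L, 2L))
  expect_equal(got$mechanism, c("firearm", "fall", "drowning"))
  expect_true(all(got$age_over_15))

  # header only -> empty strata
  writeLines(readLines(f)[1], f)
  expect_equal(nrow(read_death_strata(f)), 0L)

  # negative count -> error naming the file line
  write_death_strata(transform(make_stratum(), count = -4L), f)
  expect_error(read_death_strata(f), "line 2.*-4")

  # missing column -> format error naming it
  writeLines(c("State\tYear", "MA\t2008"), f)
  expect_error(read_death_strata(f), "Injury Mechanism")

  # unknown category label with no mapping -> vocabulary error
  write_death_strata(make_stratum(intent = "vendetta"), f)
  expect_error(read_death_strata(f), "intent label.*vendetta")

  # duplicate stratum tuple -> error
  write_death_strata(rbind(make_stratum(), make_stratum(count = 9L)), f)
  expect_error(read_death_strata(f), "duplicate stratum")
})

test_that("suppressed small-count cells are zeroed with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_death_strata(make_stratum(), f)
  txt <- readLines(f)
  txt[2] <- sub("\t1$", "\tSuppressed", txt[2])
  writeLines(txt, f)
  expect_warning(got <- read_death_strata(f), "suppressed")
  expect_equal(got$count, 0L)
})

test_that("classify_trauma follows the taxonomy and never drops silently", {
  expect_equal(classify_trauma(c("drowning", "fire_flame", "poisoning",
                                 "suffocation")),
               rep("excluded", 4))
  expect_equal(classify_trauma("firearm"), "penetrating")
  expect_equal(classify_trauma("motor_vehicle_traffic"), "blunt")
  expect_error(classify_trauma("meteorite"), "unmapped.*meteorite")
  bad_map <- data.frame(mechanism = c("firearm", "firearm"),
                        class = c("blunt", "excluded"))
  expect_error(classify_trauma("firearm", bad_map), "more than one class")
})

test_that("filter_cohort reproduces flowchart totals and obeys conservation", {
  strata <- rbind(
    make_stratum(mechanism = "firearm", count = 155657L),
    make_stratum(mechanism = "fall", intent = "unintentional",
                 state = "NY", count = 100000L),
    make_stratum(mechanism = "drowning", count = 50000L),
    make_stratum(mechanism = "poisoning", state = "NY",
                 intent = "unintentional", count = 32668L),
    # rows failing each upstream filter never reach the mechanism stage
    make_stratum(intent = "suicide", count = 11L),
    make_stratum(place = "home", count = 13L),
    make_stratum(age_group = "0-15", count = 17L),
    make_stratum(year = 2013L, count = 19L)
  )
  ct <- filter_cohort(strata)
  expect_equal(ct$n_identified, 338325)
  expect_equal(ct$n_excluded_mechanism, 82668)
  expect_equal(ct$n_included, 255657)
  expect_equal(ct$n_included, ct$n_identified - ct$n_excluded_mechanism)
  expect_equal(sum(ct$by_state), ct$n_included)
  expect_equal(sum(ct$by_year), ct$n_included)
  expect_equal(unname(ct$by_state[c("MA", "NY")]), c(155657, 100000))
  expect_equal(ct$cascade$n_dropped,
               c(19, 17, 11, 13, 82668))
})

test_that("degenerate cohorts: empty input and disallowed intents", {
  ct <- filter_cohort(make_stratum()[0, ])
  expect_equal(ct$n_identified, 0)
  expect_equal(ct$n_included, 0)
  expect_equal(sum(ct$by_state), 0)
  ct2 <- filter_cohort(make_stratum(intent = "suicide"))
  expect_equal(ct2$n_identified, 0)
})

test_that("age bands straddling the 15/16 boundary raise a boundary error", {
  expect_error(filter_cohort(make_stratum(age_group = "15-19")),
               "straddle")
})

test_that("filtering is idempotent and matches the naive recount oracle", {
  g <- gen_wonder_export(wonder_gen_params(seed = 42, total_deaths = 500))
  strata <- g$strata
  expect_lte(nrow(strata), 1000L)

  ct <- filter_cohort(strata)
  oracle <- naive_cohort_totals(strata)
  expect_equal(ct$n_identified, oracle$n_identified)
  expect_equal(ct$n_excluded_mechanism, oracle$n_excluded_mechanism)
  expect_equal(ct$n_included, oracle$n_included)
  nz <- ct$by_state[ct$by_state > 0]
  expect_equal(as.list(nz), oracle$by_state[names(nz)])
  nzy <- ct$by_year[ct$by_year > 0]
  expect_equal(as.list(nzy), oracle$by_year[names(nzy)])

  once <- filter_strata(strata)
  twice <- filter_strata(once)
  expect_identical(once, twice)
  expect_identical(filter_cohort(once)$n_included, ct$n_included)
})

test_that("cohort totals serialize to JSON and per-state CSV", {
  ct <- filter_cohort(rbind(make_stratum(count = 4L),
                            make_stratum(state = "NY", count = 6L)))
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_cohort_totals(ct, json_path = jf, state_csv_path = cf)
  j <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(j$n_included, 10)
  csv <- read.csv(cf)
  expect_equal(sum(csv$n_included), 10)
  expect_setequal(names(csv), c("state", "n_included"))
})
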