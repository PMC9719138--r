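# Seeded synthetic emulations of both national data sources.
#
# Neither real source can ship with the package (one is a live public query
# system, the other is license-restricted), so every pipeline stage is
# exercised against generated data with known ground truth. One seed governs
# each generator through per-field sub-seeded streams, so adding a field
# never perturbs earlier fields' draws.

#' Relative population weights for jurisdiction allocation
#'
#' Approximate 2010 census populations (thousands) for the 50 states plus DC,
#' used only as relative weights when spreading synthetic deaths across
#' jurisdictions.
#'
#' @return Named numeric vector over [state_codes()].
#' @export
default_state_weights <- function() {
  c(AL = 4780, AK = 710, AZ = 6392, AR = 2916, CA = 37254, CO = 5029,
    CT = 3574, DE = 898, DC = 602, FL = 18801, GA = 9688, HI = 1360,
    ID = 1568, IL = 12831, IN = 6484, IA = 3046, KS = 2853, KY = 4339,
    LA = 4533, ME = 1328, MD = 5774, MA = 6548, MI = 9884, MN = 5304,
    MS = 2967, MO = 5989, MT = 989, NE = 1826, NV = 2701, NH = 1316,
    NJ = 8792, NM = 2059, NY = 19378, NC = 9535, ND = 673, OH = 11537,
    OK = 3751, OR = 3831, PA = 12702, RI = 1053, SC = 4625, SD = 814,
    TN = 6346, TX = 25146, UT = 2764, VT = 626, VA = 8001, WA = 6725,
    WV = 1853, WI = 5687, WY = 564)
}

check_mix <- function(mix, what) {
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop(what, " weights must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  }
  invisible(mix)
}

#' Parameters for the death-certificate export generator
#'
#' The declared mixtures define the synthetic world: which fraction of raw
#' certificate records carry disallowed intents, non-facility places of
#' death, under-16 age bands, or one of the four excluded mechanisms.
#' `total_deaths` targets the *eligible blunt/penetrating* count — the
#' generator draws enough raw records that the included cohort lands near it
#' in expectation. Defaults put 24% of mechanism mass on the excluded
#' mechanisms (the source cohort excluded 82,668 of 338,325, i.e. 24.4%) and
#' target the published six-year national total.
#'
#' @param seed Integer seed.
#' @param years Study years.
#' @param states Named relative weights over jurisdictions.
#' @param total_deaths Target included (eligible blunt/penetrating) count.
#' @param mechanism_mix,intent_mix,place_mix,age_band_mix Named probability
#'   vectors, each summing to 1 within 1e-9.
#' @param mechanism_map Taxonomy used to score mechanism eligibility.
#' @return An object of class `wonder_gen_params`.
#' @export
wonder_gen_params <- function(seed = 1L,
                              years = 2007:2012,
                              states = default_state_weights(),
                              total_deaths = 255657,
                              mechanism_mix = c(firearm = 0.30,
                                                cut_pierce = 0.04,
                                                motor_vehicle_traffic = 0.25,
                                                fall = 0.10,
                                                struck_by_against = 0.03,
                                                machinery = 0.01,
                                                other_transport = 0.02,
                                                other_land_transport = 0.01,
                                                drowning = 0.045,
                                                fire_flame = 0.045,
                                                poisoning = 0.10,
                                                suffocation = 0.05),
                              intent_mix = c(unintentional = 0.55,
                                             homicide = 0.28,
                                             undetermined = 0.05,
                                             legal_intervention_or_war = 0.01,
                                             suicide = 0.09,
                                             other = 0.02),
                              place_mix = c(medical_facility_inpatient_or_ed = 0.80,
                                            medical_facility_dead_on_arrival = 0.07,
                                            medical_facility_unknown_status = 0.03,
                                            home = 0.05,
                                            other = 0.03,
                                            unknown = 0.02),
                              age_band_mix = c("0-15" = 0.03, "16-20" = 0.10,
                                               "21-25" = 0.11, "26-35" = 0.18,
                                               "36-45" = 0.16, "46-55" = 0.15,
                                               "56-65" = 0.12, "66-75" = 0.08,
                                               "76+" = 0.07),
                              mechanism_map = default_mechanism_map()) {
  check_mix(mechanism_mix, "mechanism_mix")
  check_mix(intent_mix, "intent_mix")
  check_mix(place_mix, "place_mix")
  check_mix(age_band_mix, "age_band_mix")
  if (any(states < 0) || is.null(names(states))) {
    stop("states must be a named vector of non-negative weights", call. = FALSE)
  }
  stopifnot(total_deaths >= 0)
  structure(list(seed = as.integer(seed), years = as.integer(years),
                 states = states / sum(states), total_deaths = total_deaths,
                 mechanism_mix = mechanism_mix, intent_mix = intent_mix,
                 place_mix = place_mix, age_band_mix = age_band_mix,
                 mechanism_map = mechanism_map),
            class = "wonder_gen_params")
}

#' Generate a synthetic death-certificate export
#'
#' Draws raw certificate records independently per field under sub-seeded
#' streams, aggregates them into strata (multinomial allocation over the
#' product of the declared mixtures), and optionally writes a delimited
#' export in the given dialect plus a ground-truth JSON beside it. Identical
#' seeds give byte-identical output.
#'
#' @param params A [wonder_gen_params()].
#' @param path Optional output path for the delimited export; the exact
#'   eligible/excluded tallies are written to `<path>.truth.json`.
#' @param dialect A [wonder_dialect()] controlling the written layout.
#' @return List with `strata` (a `death_strata` data.frame), `ground_truth`
#'   (exact identified/excluded/included counts and the included per-state
#'   marginal, so filter results are checkable without re-derivation), and
#'   `path`.
#' @export
gen_wonder_export <- function(params, path = NULL, dialect = wonder_dialect()) {
  stopifnot(inherits(params, "wonder_gen_params"))
  crit <- cohort_criteria(years = range(params$years),
                          mechanism_map = params$mechanism_map)
  band_lo <- parse_age_band(names(params$age_band_mix))[, "lo"]
  p_age <- sum(params$age_band_mix[band_lo >= 16])
  p_intent <- sum(params$intent_mix[names(params$intent_mix) %in%
                                      crit$allowed_intents])
  p_place <- sum(params$place_mix[names(params$place_mix) %in%
                                    crit$allowed_places])
  mech_class <- classify_trauma(names(params$mechanism_mix),
                                params$mechanism_map)
  p_mech <- sum(params$mechanism_mix[mech_class != "excluded"])
  p_pass <- p_age * p_intent * p_place * p_mech
  if (p_pass <= 0 && params$total_deaths > 0) {
    stop("declared mixtures give zero probability of an eligible death",
         call. = FALSE)
  }
  n_raw <- if (params$total_deaths == 0) 0L else
    as.integer(round(params$total_deaths / p_pass))

  if (n_raw == 0L) {
    strata <- empty_death_strata()
  } else {
    seed <- params$seed
    state <- with_field_seed(seed, 1L, sample(names(params$states), n_raw,
                                              TRUE, prob = params$states))
    year <- with_field_seed(
      seed, 2L, params$years[sample.int(length(params$years), n_raw, TRUE)])
    mechanism <- with_field_seed(seed, 3L, sample(names(params$mechanism_mix),
                                                  n_raw, TRUE,
                                                  prob = params$mechanism_mix))
    intent <- with_field_seed(seed, 4L, sample(names(params$intent_mix),
                                               n_raw, TRUE,
                                               prob = params$intent_mix))
    place <- with_field_seed(seed, 5L, sample(names(params$place_mix),
                                              n_raw, TRUE,
                                              prob = params$place_mix))
    age_group <- with_field_seed(seed, 6L, sample(names(params$age_band_mix),
                                                  n_raw, TRUE,
                                                  prob = params$age_band_mix))
    key <- paste(state, year, mechanism, intent, place, age_group, sep = "|")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "|", fixed = TRUE))
    strata <- data.frame(state = parts[, 1], year = as.integer(parts[, 2]),
                         mechanism = parts[, 3], intent = parts[, 4],
                         place_of_death = parts[, 5], age_group = parts[, 6],
                         count = as.integer(tab), stringsAsFactors = FALSE)
    strata$age_over_15 <- parse_age_band(strata$age_group)[, "lo"] >= 16
    strata <- strata[c("state", "year", "mechanism", "intent",
                       "place_of_death", "age_group", "age_over_15", "count")]
    rownames(strata) <- NULL
    class(strata) <- c("death_strata", "data.frame")
  }

  totals <- filter_cohort(strata, crit)  # exact tallies for the realized draw
  ground_truth <- list(n_raw = n_raw,
                       target_included = params$total_deaths,
                       n_identified = totals$n_identified,
                       n_excluded_mechanism = totals$n_excluded_mechanism,
                       n_included = totals$n_included,
                       by_state = as.list(totals$by_state))

  if (!is.null(path)) {
    write_death_strata(strata, path, dialect)
    jsonlite::write_json(ground_truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(strata = strata, ground_truth = ground_truth, path = path)
}

#' Write strata in an export dialect
#'
#' @param strata A `death_strata` data.frame.
#' @param path Output path.
#' @param dialect A [wonder_dialect()].
#' @return `path`, invisibly.
#' @export
write_death_strata <- function(strata, path, dialect = wonder_dialect()) {
  cols <- dialect$columns
  out <- data.frame(
    a = strata$state, b = strata$year,
    c = unmap_labels(strata$mechanism, dialect$mechanism_labels),
    d = unmap_labels(strata$intent, dialect$intent_labels),
    e = unmap_labels(strata$place_of_death, dialect$place_labels),
    f = strata$age_group, g = strata$count, stringsAsFactors = FALSE)
  names(out) <- unname(cols[c("state", "year", "mechanism", "intent",
                              "place_of_death", "age_group", "count")])
  utils::write.table(out, path, sep = dialect$delimiter, row.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

#' Parameters for the trauma-registry case generator
#'
#' The generated records are all deaths; the declared probabilities control
#' how many fall to each exclusion criterion and the true (latent) shock
#' class. Vitals are drawn from class-conditional ranges that respect the
#' 90 mmHg / 110 bpm thresholds with probability 1, and EMS documentation is
#' dropped as a whole block, missing at random, with probability
#' `p_vitals_missing`; a positive `mnar_delta` adds that much extra dropout
#' probability for truly hypotensive cases (missing-not-at-random stressor,
#' used to demonstrate — not correct — complete-case bias).
#'
#' Defaults emulate the published cohort's composition: 10.75% under-16 and
#' 5.41% non-blunt/penetrating (16,126 then 7,244 of 149,978), roughly half
#' of records missing EMS vitals, and true shock-class proportions 0.181
#' hypotensive / 0.402 hypotensive-or-tachycardic.
#'
#' @param seed Integer seed.
#' @param n_deaths Number of registry death records to draw.
#' @param p_under16,p_nonblunt_pen,p_non_ems_arrival Exclusion-branch
#'   probabilities.
#' @param p_vitals_missing Whole-block EMS-vitals dropout probability (MAR).
#' @param p_hypotensive_true,p_tachy_or_hypo_true Latent shock-class targets;
#'   the hypotensive target may not exceed the combined target.
#' @param mnar_delta Extra dropout probability for hypotensive cases (0 = MAR).
#' @param years Study years.
#' @param disposition_mix Death-pathway mix over `ed_expired`,
#'   `admit_then_expired`, `observation_then_expired`.
#' @return An object of class `ntdb_gen_params`.
#' @export
ntdb_gen_params <- function(seed = 1L, n_deaths = 100000L,
                            p_under16 = 0.1075, p_nonblunt_pen = 0.0541,
                            p_non_ems_arrival = 0.03,
                            p_vitals_missing = 0.5,
                            p_hypotensive_true = 0.181,
                            p_tachy_or_hypo_true = 0.402,
                            mnar_delta = 0,
                            years = 2007:2012,
                            disposition_mix = c(ed_expired = 0.55,
                                                admit_then_expired = 0.40,
                                                observation_then_expired = 0.05)) {
  probs <- c(p_under16, p_nonblunt_pen, p_non_ems_arrival, p_vitals_missing,
             p_hypotensive_true, p_tachy_or_hypo_true)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_hypotensive_true > p_tachy_or_hypo_true) {
    stop("inconsistent class targets: p_hypotensive_true exceeds ",
         "p_tachy_or_hypo_true", call. = FALSE)
  }
  check_mix(disposition_mix, "disposition_mix")
  stopifnot(n_deaths >= 0, mnar_delta >= 0)
  structure(list(seed = as.integer(seed), n_deaths = as.integer(n_deaths),
                 p_under16 = p_under16, p_nonblunt_pen = p_nonblunt_pen,
                 p_non_ems_arrival = p_non_ems_arrival,
                 p_vitals_missing = p_vitals_missing,
                 p_hypotensive_true = p_hypotensive_true,
                 p_tachy_or_hypo_true = p_tachy_or_hypo_true,
                 mnar_delta = mnar_delta, years = as.integer(years),
                 disposition_mix = disposition_mix),
            class = "ntdb_gen_params")
}

# Assemble ";"-delimited reading strings from a draw matrix and counts.
paste_readings <- function(m, k) {
  out <- character(nrow(m))
  out[k == 1L] <- as.character(m[k == 1L, 1L])
  out[k == 2L] <- paste(m[k == 2L, 1L], m[k == 2L, 2L], sep = ";")
  out[k == 3L] <- paste(m[k == 3L, 1L], m[k == 3L, 2L], m[k == 3L, 3L],
                        sep = ";")
  out
}

runif_int <- function(n, lo, hi) {
  # vectorized over lo/hi; uniform integers on [lo, hi]
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

#' Generate synthetic trauma-registry death records
#'
#' Draws each case's fields under per-field sub-seeded streams (see
#' [ntdb_gen_params()]), and optionally writes a delimited registry extract
#' plus ground-truth JSON. Identical seeds give byte-identical output.
#'
#' @param params An [ntdb_gen_params()].
#' @param path Optional output path; exact tallies go to `<path>.truth.json`.
#' @param dialect An [ntdb_dialect()] (delimited reading format).
#' @return List with `cases` (a `trauma_cases` data.frame), `ground_truth`
#'   (realized exclusion tallies, the latent class of every retained
#'   complete-case record, and the realized complete-case hypotension
#'   proportion), and `path`.
#' @export
gen_ntdb_cases <- function(params, path = NULL, dialect = ntdb_dialect()) {
  stopifnot(inherits(params, "ntdb_gen_params"))
  n <- params$n_deaths
  seed <- params$seed
  if (n == 0L) {
    cases <- data.frame(case_id = character(), year = integer(),
                        age = integer(), trauma_type = character(),
                        arrival_mode = character(), ems_sbp = character(),
                        ems_hr = character(), ed_disposition = character(),
                        hospital_disposition = character(),
                        stringsAsFactors = FALSE)
    class(cases) <- c("trauma_cases", "data.frame")
    gt <- list(n_cases = 0L)
    if (!is.null(path)) {
      write_trauma_cases(cases, path, dialect)
      jsonlite::write_json(gt, paste0(path, ".truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    return(list(cases = cases, ground_truth = gt, path = path))
  }

  year <- with_field_seed(
    seed, 1L, params$years[sample.int(length(params$years), n, TRUE)])
  age <- with_field_seed(seed, 2L, {
    u <- stats::runif(n)
    ifelse(u < params$p_under16, runif_int(n, 1, 15), runif_int(n, 16, 89))
  })
  trauma_type <- with_field_seed(seed, 3L, {
    u <- stats::runif(n); v <- stats::runif(n)
    ifelse(u < params$p_nonblunt_pen,
           ifelse(v < 0.5, "burn", "other"),
           ifelse(v < 0.65, "blunt", "penetrating"))
  })
  arrival_mode <- with_field_seed(seed, 4L, {
    u <- stats::runif(n); v <- stats::runif(n)
    non_ems <- c("private_vehicle", "walk_in", "other", "unknown")
    ifelse(u < params$p_non_ems_arrival,
           non_ems[1L + floor(v * 4)],
           ifelse(v < 0.85, "ems_ground", "ems_air"))
  })
  pathway <- with_field_seed(seed, 5L, sample(names(params$disposition_mix),
                                              n, TRUE,
                                              prob = params$disposition_mix))
  ed_disposition <- c(ed_expired = "expired",
                      admit_then_expired = "admitted_inpatient",
                      observation_then_expired = "observation")[pathway]
  hospital_disposition <- ifelse(pathway == "ed_expired", "not_applicable",
                                 "expired")

  shock_class <- with_field_seed(seed, 6L, {
    u <- stats::runif(n)
    ifelse(u < params$p_hypotensive_true, "hypotensive",
           ifelse(u < params$p_tachy_or_hypo_true, "tachycardic_only",
                  "neither"))
  })
  missing <- with_field_seed(seed, 7L, {
    p_miss <- pmin(1, params$p_vitals_missing +
                     params$mnar_delta * (shock_class == "hypotensive"))
    stats::runif(n) < p_miss
  })
  # class-conditional vitals; first reading pins the class, extras stay in
  # class-safe ranges so labels hold with probability 1
  sbp <- with_field_seed(seed, 8L, {
    k <- runif_int(n, 1, 3)
    hypo <- shock_class == "hypotensive"
    m <- cbind(ifelse(hypo, runif_int(n, 50, 89), runif_int(n, 90, 150)),
               ifelse(hypo, runif_int(n, 60, 160), runif_int(n, 90, 150)),
               ifelse(hypo, runif_int(n, 60, 160), runif_int(n, 90, 150)))
    paste_readings(m, k)
  })
  hr <- with_field_seed(seed, 9L, {
    k <- runif_int(n, 1, 3)
    first <- ifelse(shock_class == "tachycardic_only", runif_int(n, 111, 160),
                    ifelse(shock_class == "hypotensive", runif_int(n, 60, 160),
                           runif_int(n, 55, 110)))
    extra1 <- ifelse(shock_class == "neither", runif_int(n, 55, 110),
                     runif_int(n, 60, 160))
    extra2 <- ifelse(shock_class == "neither", runif_int(n, 55, 110),
                     runif_int(n, 60, 160))
    paste_readings(cbind(first, extra1, extra2), k)
  })
  sbp[missing] <- ""
  hr[missing] <- ""

  cases <- data.frame(case_id = sprintf("S%07d", seq_len(n)),
                      year = year, age = as.integer(age),
                      trauma_type = trauma_type, arrival_mode = arrival_mode,
                      ems_sbp = sbp, ems_hr = hr,
                      ed_disposition = unname(ed_disposition),
                      hospital_disposition = hospital_disposition,
                      stringsAsFactors = FALSE)
  class(cases) <- c("trauma_cases", "data.frame")

  retained <- age >= 16 & trauma_type %in% c("blunt", "penetrating") &
    arrival_mode %in% c("ems_ground", "ems_air")
  cc <- retained & !missing
  ground_truth <- list(
    n_cases = n,
    p_hypotensive_true = params$p_hypotensive_true,
    p_tachy_or_hypo_true = params$p_tachy_or_hypo_true,
    n_retained = sum(retained),
    n_complete_retained = sum(cc),
    n_hypotensive_complete = sum(cc & shock_class == "hypotensive"),
    n_tachy_or_hypo_complete = sum(cc & shock_class != "neither"),
    realized_p_hypotensive = if (any(cc)) {
      sum(cc & shock_class == "hypotensive") / sum(cc)
    } else NA
  )
  if (!is.null(path)) {
    write_trauma_cases(cases, path, dialect)
    jsonlite::write_json(ground_truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cases = cases, ground_truth = ground_truth, path = path)
}
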