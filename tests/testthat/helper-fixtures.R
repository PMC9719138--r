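# Builders and independent naive oracles. The oracles deliberately re-derive
# results with plain loops and never call the implementation under test.

make_stratum <- function(state = "MA", year = 2008L,
                         mechanism = "firearm", intent = "homicide",
                         place = "medical_facility_inpatient_or_ed",
                         age_group = "21-25", count = 1L) {
  data.frame(state = state, year = year, mechanism = mechanism,
             intent = intent, place_of_death = place, age_group = age_group,
             age_over_15 = !grepl("^(0|1[0-5])-", age_group),
             count = count, stringsAsFactors = FALSE)
}

make_case <- function(case_id = "C1", year = 2008L, age = 30L,
                      trauma_type = "blunt", arrival_mode = "ems_ground",
                      ems_sbp = "120", ems_hr = "80",
                      ed_disposition = "expired",
                      hospital_disposition = "not_applicable") {
  data.frame(case_id = case_id, year = year, age = age,
             trauma_type = trauma_type, arrival_mode = arrival_mode,
             ems_sbp = ems_sbp, ems_hr = ems_hr,
             ed_disposition = ed_disposition,
             hospital_disposition = hospital_disposition,
             stringsAsFactors = FALSE)
}

# Row-by-row naive recount of cohort totals: an independent implementation of
# the filter semantics using a loop and explicit lists.
naive_cohort_totals <- function(strata,
                                years = c(2007, 2012),
                                intents = c("unintentional", "homicide",
                                            "undetermined",
                                            "legal_intervention_or_war"),
                                places = "medical_facility_inpatient_or_ed",
                                map = utils::read.csv(system.file(
                                  "extdata", "mechanism_map.csv",
                                  package = "txavert"))) {
  n_identified <- 0; n_excluded <- 0
  by_state <- list(); by_year <- list()
  for (i in seq_len(nrow(strata))) {
    r <- strata[i, ]
    lo <- as.numeric(sub("[-+].*$", "", r$age_group))
    if (r$year < years[1] || r$year > years[2]) next
    if (lo < 16) next
    if (!(r$intent %in% intents)) next
    if (!(r$place_of_death %in% places)) next
    n_identified <- n_identified + r$count
    cls <- map$class[map$mechanism == r$mechanism]
    if (cls == "excluded") {
      n_excluded <- n_excluded + r$count
    } else {
      by_state[[r$state]] <- (by_state[[r$state]] %||% 0) + r$count
      yk <- as.character(r$year)
      by_year[[yk]] <- (by_year[[yk]] %||% 0) + r$count
    }
  }
  list(n_identified = n_identified, n_excluded_mechanism = n_excluded,
       n_included = n_identified - n_excluded,
       by_state = by_state, by_year = by_year)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force death definition: enumeration over disposition pairs.
naive_is_death <- function(ed, hosp) {
  if (ed == "expired") return(TRUE)
  if (hosp == "expired" && (ed == "admitted_inpatient" || ed == "observation")) {
    return(TRUE)
  }
  FALSE
}

# Brute-force vitals classification over individual readings.
naive_classify <- function(sbp, hr, sbp_t = 90, hr_t = 110) {
  if (!length(sbp) && !length(hr)) return("missing")
  for (r in sbp) if (r < sbp_t) return("hypotensive")
  for (r in hr) if (r > hr_t) return("tachycardic_only")
  "neither"
}
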