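# Input dialects: how source files name columns and category labels.
#
# Both national sources arrive as delimited text with source-specific column
# headers and vocabularies. A dialect maps them onto the package's controlled
# vocabulary so the cohort filters never see raw source labels.

#' Dialect for WONDER-style underlying-cause-of-death exports
#'
#' Describes the delimited-text layout of an aggregated death-certificate
#' export: the delimiter, the source names of the seven required columns, and
#' the label mappings from source vocabulary to the controlled vocabulary for
#' injury mechanism, injury intent and place of death. The default mirrors a
#' tab-separated Underlying Cause of Death query export already categorized by
#' injury mechanism (no ICD-10 parsing).
#'
#' @param delimiter Field separator, default tab.
#' @param columns Named character vector mapping internal field names
#'   (`state`, `year`, `mechanism`, `intent`, `place_of_death`, `age_group`,
#'   `count`) to source column headers.
#' @param mechanism_labels,intent_labels,place_labels Named character vectors
#'   mapping source labels to controlled-vocabulary labels. Identity mappings
#'   may be omitted: a source label equal to a controlled label passes through.
#' @return An object of class `wonder_dialect`.
#' @seealso [read_death_strata()]
#' @export
wonder_dialect <- function(delimiter = "\t",
                           columns = c(state = "State",
                                       year = "Year",
                                       mechanism = "Injury Mechanism",
                                       intent = "Injury Intent",
                                       place_of_death = "Place of Death",
                                       age_group = "Age Group",
                                       count = "Deaths"),
                           mechanism_labels = character(),
                           intent_labels = c("Unintentional" = "unintentional",
                                             "Homicide" = "homicide",
                                             "Undetermined" = "undetermined",
                                             "Legal Intervention / Operations of War" = "legal_intervention_or_war",
                                             "Suicide" = "suicide",
                                             "Other" = "other"),
                           place_labels = c("Medical Facility - Inpatient/ER" = "medical_facility_inpatient_or_ed",
                                            "Medical Facility - Dead on Arrival" = "medical_facility_dead_on_arrival",
                                            "Medical Facility - Status unknown" = "medical_facility_unknown_status",
                                            "Home" = "home",
                                            "Other" = "other",
                                            "Unknown" = "unknown")) {
  req <- c("state", "year", "mechanism", "intent", "place_of_death",
           "age_group", "count")
  missing_cols <- setdiff(req, names(columns))
  if (length(missing_cols)) {
    stop("dialect columns must name all of: ", paste(req, collapse = ", "),
         "; missing: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  structure(list(delimiter = delimiter, columns = columns,
                 mechanism_labels = mechanism_labels,
                 intent_labels = intent_labels,
                 place_labels = place_labels),
            class = "wonder_dialect")
}

#' Dialect for NTDB-style trauma-registry extracts
#'
#' Maps registry column names onto the patient-level case schema. Repeated EMS
#' vitals are carried in a single column of semicolon-delimited readings
#' (`reading_format = "delimited"`, the format the synthetic generator writes)
#' or spread over numbered wide columns such as `EMSSBP1..EMSSBP3`
#' (`reading_format = "wide"`, with `sbp_prefix`/`hr_prefix`).
#'
#' @param delimiter Field separator, default comma.
#' @param columns Named character vector mapping internal field names to source
#'   column headers.
#' @param reading_format `"delimited"` or `"wide"`.
#' @param sbp_prefix,hr_prefix Column-name prefixes used when
#'   `reading_format = "wide"`.
#' @param trauma_type_labels,arrival_labels,ed_disposition_labels,hospital_disposition_labels
#'   Source-to-controlled label maps; identity labels pass through.
#' @return An object of class `ntdb_dialect`.
#' @seealso [read_trauma_cases()]
#' @export
ntdb_dialect <- function(delimiter = ",",
                         columns = c(case_id = "INC_KEY",
                                     year = "YOADMIT",
                                     age = "AGE",
                                     trauma_type = "TRAUMATYPE",
                                     arrival_mode = "TRANSPORT",
                                     ems_sbp = "EMSSBP",
                                     ems_hr = "EMSPULSERATE",
                                     ed_disposition = "EDDISP",
                                     hospital_disposition = "HOSPDISP"),
                         reading_format = c("delimited", "wide"),
                         sbp_prefix = "EMSSBP", hr_prefix = "EMSPULSERATE",
                         trauma_type_labels = c(Blunt = "blunt",
                                                Penetrating = "penetrating",
                                                Burn = "burn",
                                                Other = "other"),
                         arrival_labels = c("Ground Ambulance" = "ems_ground",
                                            "Helicopter Ambulance" = "ems_air",
                                            "Private/Public Vehicle" = "private_vehicle",
                                            "Walk-in" = "walk_in",
                                            "Other" = "other",
                                            "Unknown" = "unknown"),
                         ed_disposition_labels = c("Deceased/Expired" = "expired",
                                                   "Admitted" = "admitted_inpatient",
                                                   "Observation" = "observation",
                                                   "Transferred" = "transferred",
                                                   "Home" = "discharged",
                                                   "Other" = "other"),
                         hospital_disposition_labels = c("Deceased/Expired" = "expired",
                                                         "Home" = "discharged",
                                                         "Transferred" = "transferred",
                                                         "Other" = "other",
                                                         "Not Applicable" = "not_applicable")) {
  reading_format <- match.arg(reading_format)
  structure(list(delimiter = delimiter, columns = columns,
                 reading_format = reading_format,
                 sbp_prefix = sbp_prefix, hr_prefix = hr_prefix,
                 trauma_type_labels = trauma_type_labels,
                 arrival_labels = arrival_labels,
                 ed_disposition_labels = ed_disposition_labels,
                 hospital_disposition_labels = hospital_disposition_labels),
            class = "ntdb_dialect")
}

#' Read a dialect description from a JSON file
#'
#' @param path Path to a JSON file whose top-level fields are the arguments of
#'   [wonder_dialect()] or [ntdb_dialect()].
#' @param type `"wonder"` or `"ntdb"`.
#' @return A dialect object.
#' @export
read_dialect <- function(path, type = c("wonder", "ntdb")) {
  type <- match.arg(type)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  ctor <- if (type == "wonder") wonder_dialect else ntdb_dialect
  ok <- intersect(names(spec), names(formals(ctor)))
  do.call(ctor, spec[ok])
}

# Map source labels to the controlled vocabulary. Labels already in the
# controlled vocabulary pass through; anything else must be in `map`.
map_labels <- function(x, map, vocabulary, field) {
  out <- as.character(x)
  mapped <- !is.na(match(out, names(map)))
  out[mapped] <- unname(map[out[mapped]])
  unknown <- !(out %in% vocabulary)
  if (any(unknown)) {
    stop("unknown ", field, " label(s) with no dialect mapping: ",
         paste(unique(out[unknown]), collapse = ", "), call. = FALSE)
  }
  out
}
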