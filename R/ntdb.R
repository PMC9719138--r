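# Patient-level trauma-registry cohort: decedent filters and complete-case
# prehospital vital-sign proportions.

#' Read patient-level trauma-registry cases
#'
#' Parses a delimited registry extract into the case schema. EMS vitals may
#' arrive as one semicolon-delimited column per channel or as numbered wide
#' columns (see [ntdb_dialect()]); either way they are normalized to
#' semicolon-delimited reading lists, with the empty string meaning "EMS
#' vitals not documented".
#'
#' @param source Path to a delimited text file with a header row.
#' @param dialect An [ntdb_dialect()].
#' @return A data.frame of class `trauma_cases` with columns `case_id`,
#'   `year`, `age`, `trauma_type`, `arrival_mode`, `ems_sbp`, `ems_hr`,
#'   `ed_disposition`, `hospital_disposition`.
#' @export
read_trauma_cases <- function(source, dialect = ntdb_dialect()) {
  raw <- utils::read.delim(source, sep = dialect$delimiter,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  cols <- dialect$columns
  fixed <- setdiff(names(cols), c("ems_sbp", "ems_hr"))
  missing_cols <- setdiff(unname(cols[fixed]), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (dialect$reading_format == "wide") {
    sbp <- collapse_wide_readings(raw, dialect$sbp_prefix)
    hr <- collapse_wide_readings(raw, dialect$hr_prefix)
  } else {
    for (ch in c("ems_sbp", "ems_hr")) {
      if (!cols[[ch]] %in% names(raw)) {
        stop("missing required column(s): ", cols[[ch]], call. = FALSE)
      }
    }
    sbp <- raw[[cols[["ems_sbp"]]]]
    hr <- raw[[cols[["ems_hr"]]]]
  }
  df <- data.frame(
    case_id = raw[[cols[["case_id"]]]],
    year = as.integer(raw[[cols[["year"]]]]),
    age = as.integer(raw[[cols[["age"]]]]),
    trauma_type = map_labels(raw[[cols[["trauma_type"]]]],
                             dialect$trauma_type_labels, trauma_type_levels(),
                             "trauma type"),
    arrival_mode = map_labels(raw[[cols[["arrival_mode"]]]],
                              dialect$arrival_labels, arrival_mode_levels(),
                              "arrival mode"),
    ems_sbp = as.character(sbp),
    ems_hr = as.character(hr),
    ed_disposition = map_labels(raw[[cols[["ed_disposition"]]]],
                                dialect$ed_disposition_labels,
                                ed_disposition_levels(), "ED disposition"),
    hospital_disposition = map_labels(raw[[cols[["hospital_disposition"]]]],
                                      dialect$hospital_disposition_labels,
                                      hospital_disposition_levels(),
                                      "hospital disposition"),
    stringsAsFactors = FALSE
  )
  validate_trauma_cases(df)
  class(df) <- c("trauma_cases", "data.frame")
  df
}

collapse_wide_readings <- function(raw, prefix) {
  cand <- grep(paste0("^", prefix, "[0-9]+$"), names(raw), value = TRUE)
  if (!length(cand)) {
    stop("no wide reading columns matching prefix '", prefix, "'",
         call. = FALSE)
  }
  cand <- cand[order(as.integer(sub(prefix, "", cand, fixed = TRUE)))]
  apply(raw[cand], 1L, function(r) paste(r[nzchar(r) & !is.na(r)], collapse = ";"))
}

validate_trauma_cases <- function(cases) {
  if (anyNA(cases$age) || any(cases$age < 0)) {
    stop("case ages must be non-negative integers", call. = FALSE)
  }
  for (ch in c("ems_sbp", "ems_hr")) {
    vals <- unlist(decode_readings(cases[[ch]]))
    if (length(vals) && any(vals <= 0)) {
      stop("vitals readings must be positive (", ch, ")", call. = FALSE)
    }
  }
  invisible(cases)
}

#' Write trauma cases in a registry dialect
#'
#' Inverse of [read_trauma_cases()] for the delimited reading format; used by
#' the synthetic generator and round-trip tests.
#'
#' @param cases A `trauma_cases` data.frame.
#' @param path Output path.
#' @param dialect An [ntdb_dialect()] with `reading_format = "delimited"`.
#' @return `path`, invisibly.
#' @export
write_trauma_cases <- function(cases, path, dialect = ntdb_dialect()) {
  stopifnot(dialect$reading_format == "delimited")
  cols <- dialect$columns
  out <- data.frame(
    a = cases$case_id, b = cases$year, c = cases$age,
    d = unmap_labels(cases$trauma_type, dialect$trauma_type_labels),
    e = unmap_labels(cases$arrival_mode, dialect$arrival_labels),
    f = cases$ems_sbp, g = cases$ems_hr,
    h = unmap_labels(cases$ed_disposition, dialect$ed_disposition_labels),
    i = unmap_labels(cases$hospital_disposition,
                     dialect$hospital_disposition_labels),
    stringsAsFactors = FALSE
  )
  names(out) <- unname(cols[c("case_id", "year", "age", "trauma_type",
                              "arrival_mode", "ems_sbp", "ems_hr",
                              "ed_disposition", "hospital_disposition")])
  utils::write.table(out, path, sep = dialect$delimiter, row.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

unmap_labels <- function(x, map) {
  if (!length(map)) return(x)
  inv <- stats::setNames(names(map), unname(map))
  out <- unname(inv[x])
  out[is.na(out)] <- x[is.na(out)]
  out
}

#' Filter registry cases to the decedent cohort
#'
#' Sequentially keeps cases with a trauma year in the study window, age 16 or
#' older, blunt or penetrating primary trauma type, arrival by EMS (ground or
#' air), and an in-hospital death: ED disposition "expired", or hospital
#' disposition "expired" after an ED disposition of inpatient admission or
#' observation (a transfer breaks the admission chain, so a transferred
#' patient who later expired elsewhere is not counted). Order-preserving;
#' nothing errors — records failing a criterion are dropped and tallied in the
#' `"cascade"` attribute (criterion, n_dropped), enabling flowchart-style
#' reporting.
#'
#' @param cases A `trauma_cases` data.frame.
#' @param years Inclusive study-year range.
#' @param min_age Minimum included age (16; "less than 16" is excluded).
#' @return The retained rows, with attribute `cascade`.
#' @export
filter_trauma_deaths <- function(cases, years = c(2007L, 2012L),
                                 min_age = 16L) {
  keep <- rep(TRUE, nrow(cases))
  steps <- list(
    year_window = cases$year >= years[1] & cases$year <= years[2],
    age_under_16 = cases$age >= min_age,
    non_blunt_penetrating = cases$trauma_type %in% c("blunt", "penetrating"),
    non_ems_arrival = cases$arrival_mode %in% c("ems_ground", "ems_air"),
    not_a_death = trauma_death_mask(cases$ed_disposition,
                                    cases$hospital_disposition)
  )
  cascade <- data.frame(criterion = names(steps),
                        n_dropped = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(steps)) {
    before <- sum(keep)
    keep <- keep & steps[[i]]
    cascade$n_dropped[i] <- before - sum(keep)
  }
  out <- cases[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(cases)
  attr(out, "cascade") <- cascade
  out
}

# Death definition: expired in the ED, or admitted (inpatient/observation)
# and expired in hospital.
trauma_death_mask <- function(ed, hosp) {
  ed == "expired" |
    (hosp == "expired" & ed %in% c("admitted_inpatient", "observation"))
}

#' Classify prehospital vitals against shock thresholds
#'
#' "Any reading" semantics: a single EMS systolic blood pressure below
#' `sbp_threshold` makes a case hypotensive (min over readings); otherwise a
#' single EMS heart rate above `hr_threshold` makes it tachycardic-only (max
#' over readings). Both inequalities are strict, so boundary readings of
#' exactly 90 mmHg / 110 bpm qualify for neither. Cases with no documented
#' readings of either kind are `missing`.
#'
#' @param cases A `trauma_cases` data.frame (or any data.frame with `ems_sbp`
#'   and `ems_hr` semicolon-delimited reading columns).
#' @param sbp_threshold Hypotension threshold, mmHg (default 90).
#' @param hr_threshold Tachycardia threshold, bpm (default 110).
#' @return Character vector over
#'   `{"hypotensive", "tachycardic_only", "neither", "missing"}`.
#' @examples
#' cases <- data.frame(ems_sbp = c("89", "90", "", "120;85"),
#'                     ems_hr = c("80", "110", "", "90"))
#' classify_vitals(cases)
#' @export
classify_vitals <- function(cases, sbp_threshold = 90, hr_threshold = 110) {
  if (sbp_threshold <= 0 || hr_threshold <= 0) {
    stop("vital-sign thresholds must be positive", call. = FALSE)
  }
  min_sbp <- readings_extreme(cases$ems_sbp, min)
  max_hr <- readings_extreme(cases$ems_hr, max)
  out <- rep("neither", length(min_sbp))
  out[is.na(min_sbp) & is.na(max_hr)] <- "missing"
  tachy <- !is.na(max_hr) & max_hr > hr_threshold
  out[tachy] <- "tachycardic_only"
  hypo <- !is.na(min_sbp) & min_sbp < sbp_threshold
  out[hypo] <- "hypotensive"
  out
}

#' Complete-case summary of prehospital shock vitals
#'
#' Computes counts and complete-case proportions of hypotensive and
#' tachycardic-or-hypotensive decedents. Records with no documented EMS
#' vitals are treated as missing at random and excluded from the denominator.
#' Two denominator conventions are offered because the source text does not
#' pin one down: `"any_vital"` (default) counts every record with at least one
#' documented reading of either channel — a heart-rate-only record can still
#' classify as tachycardic, a pressure-only record as hypotensive;
#' `"both_vitals"` restricts to records documenting both channels.
#'
#' @param deaths A `trauma_cases` data.frame that already passed
#'   [filter_trauma_deaths()].
#' @param denominator `"any_vital"` or `"both_vitals"`.
#' @param sbp_threshold,hr_threshold Thresholds passed to [classify_vitals()].
#' @return An object of class `vitals_summary`: list with
#'   `n_deaths_included`, `n_with_sbp`, `n_with_hr`, `n_with_any_vital`,
#'   `n_complete` (the denominator used), `n_hypotensive`, `n_tachy_or_hypo`,
#'   `p_hypotensive`, `p_tachy_or_hypo`, `denominator`.
#' @export
summarize_vitals <- function(deaths, denominator = c("any_vital", "both_vitals"),
                             sbp_threshold = 90, hr_threshold = 110) {
  denominator <- match.arg(denominator)
  has_sbp <- nzchar(deaths$ems_sbp)
  has_hr <- nzchar(deaths$ems_hr)
  complete <- if (denominator == "any_vital") has_sbp | has_hr else has_sbp & has_hr
  if (!any(complete)) {
    stop("no records with documented EMS vitals: complete-case proportions ",
         "are undefined", call. = FALSE)
  }
  cls <- classify_vitals(deaths[complete, , drop = FALSE],
                         sbp_threshold = sbp_threshold,
                         hr_threshold = hr_threshold)
  n_complete <- sum(complete)
  n_hypo <- sum(cls == "hypotensive")
  n_tachy_or_hypo <- n_hypo + sum(cls == "tachycardic_only")
  structure(list(n_deaths_included = nrow(deaths),
                 n_with_sbp = sum(has_sbp),
                 n_with_hr = sum(has_hr),
                 n_with_any_vital = sum(has_sbp | has_hr),
                 n_complete = n_complete,
                 n_hypotensive = n_hypo,
                 n_tachy_or_hypo = n_tachy_or_hypo,
                 p_hypotensive = n_hypo / n_complete,
                 p_tachy_or_hypo = n_tachy_or_hypo / n_complete,
                 denominator = denominator),
            class = "vitals_summary")
}

#' @export
print.vitals_summary <- function(x, ...) {
  cat("Prehospital vitals summary (complete-case, denominator =",
      x$denominator, ")\n")
  cat(sprintf("  deaths: %d; with any vital: %d (%.1f%%)\n",
              x$n_deaths_included, x$n_with_any_vital,
              100 * x$n_with_any_vital / max(x$n_deaths_included, 1)))
  cat(sprintf("  hypotensive: %d (%.1f%%)\n", x$n_hypotensive,
              100 * x$p_hypotensive))
  cat(sprintf("  tachycardic or hypotensive: %d (%.1f%%)\n",
              x$n_tachy_or_hypo, 100 * x$p_tachy_or_hypo))
  invisible(x)
}
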