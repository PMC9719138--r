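# Aggregated death-certificate cohort: ingest WONDER-style strata and apply
# the study's inclusion/exclusion criteria for the TXA-naive window.

#' Default injury-mechanism taxonomy
#'
#' The source criteria name only four excluded mechanisms (drowning,
#' fire/flame, poisoning, suffocation); everything else must be classified as
#' blunt or penetrating trauma. The default taxonomy is modeled on the CDC
#' external-cause-of-injury mechanism categories — cut/pierce and firearm are
#' penetrating; falls, motor-vehicle and other transport, struck by/against,
#' and machinery are blunt — and ships as a data file so users can align it to
#' their source's vocabulary rather than editing code.
#'
#' @param path CSV file with columns `mechanism` and `class`
#'   (blunt/penetrating/excluded). Defaults to the taxonomy shipped with the
#'   package.
#' @return A data.frame with columns `mechanism`, `class`.
#' @export
default_mechanism_map <- function(path = system.file("extdata", "mechanism_map.csv",
                                                     package = "txavert")) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_mechanism_map(map)
  map
}

validate_mechanism_map <- function(map) {
  if (!all(c("mechanism", "class") %in% names(map))) {
    stop("mechanism map must have columns 'mechanism' and 'class'",
         call. = FALSE)
  }
  bad <- setdiff(unique(map$class), c("blunt", "penetrating", "excluded"))
  if (length(bad)) {
    stop("mechanism map classes must be blunt/penetrating/excluded; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- map$mechanism[duplicated(map$mechanism)]
  if (length(dup)) {
    stop("mechanism mapped to more than one class: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  invisible(map)
}

#' Classify an injury mechanism as blunt, penetrating or excluded
#'
#' Deterministic lookup into the configured taxonomy. Mechanisms absent from
#' the taxonomy raise an error — an unmapped mechanism is never silently
#' dropped, because it would silently shrink the cohort.
#'
#' @param mechanism Character vector of mechanism labels.
#' @param map Taxonomy data.frame as from [default_mechanism_map()].
#' @return Character vector over `{"blunt", "penetrating", "excluded"}`.
#' @examples
#' classify_trauma(c("drowning", "firearm", "motor_vehicle_traffic"))
#' @export
classify_trauma <- function(mechanism, map = default_mechanism_map()) {
  validate_mechanism_map(map)
  idx <- match(mechanism, map$mechanism)
  if (anyNA(idx)) {
    stop("unmapped injury mechanism(s): ",
         paste(unique(mechanism[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  map$class[idx]
}

#' Read aggregated death-certificate strata
#'
#' Parses a delimited export into one row per stratum (state, year, mechanism,
#' intent, place of death, age group, count). Suppressed small-count cells
#' (the export dialect's `"Suppressed"` marker) are treated as zero with a
#' warning, since the source criteria give no disclosure-recovery rule.
#' Unparseable rows are reported with their file line numbers.
#'
#' @param source Path to a delimited text file with a header row.
#' @param dialect A [wonder_dialect()] describing separators and label maps.
#' @param mechanism_vocabulary Permitted mechanism labels after mapping;
#'   defaults to the shipped taxonomy's mechanisms.
#' @return A data.frame of class `death_strata` with columns `state`, `year`,
#'   `mechanism`, `intent`, `place_of_death`, `age_group`, `age_over_15`,
#'   `count`.
#' @export
read_death_strata <- function(source, dialect = wonder_dialect(),
                              mechanism_vocabulary = default_mechanism_map()$mechanism) {
  raw <- utils::read.delim(source, sep = dialect$delimiter,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", stringsAsFactors = FALSE)
  cols <- dialect$columns
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(empty_death_strata())
  }
  df <- data.frame(
    state = as.character(raw[[cols[["state"]]]]),
    year = raw[[cols[["year"]]]],
    mechanism = map_labels(raw[[cols[["mechanism"]]]],
                           dialect$mechanism_labels, mechanism_vocabulary,
                           "mechanism"),
    intent = map_labels(raw[[cols[["intent"]]]], dialect$intent_labels,
                        intent_levels(), "intent"),
    place_of_death = map_labels(raw[[cols[["place_of_death"]]]],
                                dialect$place_labels, place_levels(),
                                "place of death"),
    age_group = as.character(raw[[cols[["age_group"]]]]),
    count = raw[[cols[["count"]]]],
    stringsAsFactors = FALSE
  )

  # header occupies file line 1; data row i is file line i + 1
  problems <- character()
  year <- suppressWarnings(as.integer(df$year))
  bad_year <- which(is.na(year))
  if (length(bad_year)) {
    problems <- c(problems, paste0("line ", bad_year + 1L,
                                   ": unparseable year '", df$year[bad_year], "'"))
  }
  suppressed <- df$count %in% c("Suppressed", "suppressed")
  if (any(suppressed)) {
    warning(sum(suppressed), " suppressed cell(s) treated as count 0",
            call. = FALSE)
    df$count[suppressed] <- "0"
  }
  count <- suppressWarnings(as.numeric(df$count))
  bad_count <- which(is.na(count) | count < 0 | count != floor(count))
  if (length(bad_count)) {
    problems <- c(problems, paste0("line ", bad_count + 1L,
                                   ": invalid count '", df$count[bad_count], "'"))
  }
  bad_state <- which(!(df$state %in% state_codes()))
  if (length(bad_state)) {
    problems <- c(problems, paste0("line ", bad_state + 1L,
                                   ": unknown jurisdiction '", df$state[bad_state], "'"))
  }
  if (length(problems)) {
    stop("unparseable row(s):\n", paste(problems, collapse = "\n"),
         call. = FALSE)
  }
  df$year <- year
  df$count <- as.integer(count)

  key <- do.call(paste, c(df[c("state", "year", "mechanism", "intent",
                               "place_of_death", "age_group")], sep = "\r"))
  if (anyDuplicated(key)) {
    dup_lines <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate stratum tuple(s) at line(s): ",
         paste(dup_lines + 1L, collapse = ", "), call. = FALSE)
  }

  bounds <- parse_age_band(df$age_group)
  df$age_over_15 <- bounds[, "lo"] >= 16
  df <- df[c("state", "year", "mechanism", "intent", "place_of_death",
             "age_group", "age_over_15", "count")]
  class(df) <- c("death_strata", "data.frame")
  df
}

empty_death_strata <- function() {
  df <- data.frame(state = character(), year = integer(),
                   mechanism = character(), intent = character(),
                   place_of_death = character(), age_group = character(),
                   age_over_15 = logical(), count = integer(),
                   stringsAsFactors = FALSE)
  class(df) <- c("death_strata", "data.frame")
  df
}

#' Cohort inclusion/exclusion criteria for the death-certificate source
#'
#' Encodes the study query: deaths in 2007-2012, age over 15, injury intent of
#' unintentional, homicide, undetermined, or legal intervention/operations of
#' war, and place of death in a medical facility but not dead on arrival.
#' Mechanism exclusions (drowning, fire/flame, poisoning, suffocation) come
#' from the taxonomy. "Age > 15" is enforced as "age band entirely at or above
#' 16"; a band straddling the boundary raises an error rather than being
#' silently prorated. Facility deaths with unknown inpatient/DOA status are
#' excluded by default (conservative); set `include_unknown_facility = TRUE`
#' to keep them.
#'
#' @param years Inclusive two-element year range.
#' @param min_age_exclusive Deaths must be strictly older than this (15).
#' @param allowed_intents,allowed_places Controlled-vocabulary label sets.
#' @param include_unknown_facility Keep `medical_facility_unknown_status`?
#' @param mechanism_map Taxonomy as from [default_mechanism_map()].
#' @return An object of class `cohort_criteria`.
#' @export
cohort_criteria <- function(years = c(2007L, 2012L),
                            min_age_exclusive = 15L,
                            allowed_intents = c("unintentional", "homicide",
                                                "undetermined",
                                                "legal_intervention_or_war"),
                            allowed_places = "medical_facility_inpatient_or_ed",
                            include_unknown_facility = FALSE,
                            mechanism_map = default_mechanism_map()) {
  stopifnot(length(years) == 2L, years[1] <= years[2])
  validate_mechanism_map(mechanism_map)
  if (include_unknown_facility) {
    allowed_places <- union(allowed_places, "medical_facility_unknown_status")
  }
  stopifnot(all(allowed_intents %in% intent_levels()),
            all(allowed_places %in% place_levels()))
  structure(list(years = as.integer(years),
                 min_age_exclusive = as.integer(min_age_exclusive),
                 allowed_intents = allowed_intents,
                 allowed_places = allowed_places,
                 mechanism_map = mechanism_map,
                 excluded_mechanisms =
                   mechanism_map$mechanism[mechanism_map$class == "excluded"],
                 retained_trauma_classes = c("blunt", "penetrating")),
            class = "cohort_criteria")
}

check_age_bands <- function(strata, criteria) {
  bounds <- parse_age_band(strata$age_group)
  cut <- criteria$min_age_exclusive  # keep bands with lo >= cut + 1
  straddle <- bounds[, "lo"] <= cut & bounds[, "hi"] > cut
  if (any(straddle)) {
    stop("age band(s) straddle the age-", cut, " boundary (no proration rule): ",
         paste(unique(strata$age_group[straddle]), collapse = ", "),
         call. = FALSE)
  }
  bounds[, "lo"] >= cut + 1
}

#' Subset strata to the included cohort
#'
#' Applies the year, age, intent, place and mechanism filters and returns the
#' retained strata. [filter_cohort()] builds its totals on top of this;
#' exposed separately so that idempotence (filtering a filtered cohort is a
#' no-op) is directly checkable.
#'
#' @inheritParams filter_cohort
#' @return A `death_strata` data.frame.
#' @export
filter_strata <- function(strata, criteria = cohort_criteria()) {
  keep <- cohort_masks(strata, criteria)
  out <- strata[keep$included, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sequential filter masks shared by filter_strata / filter_cohort.
cohort_masks <- function(strata, criteria) {
  stopifnot(inherits(criteria, "cohort_criteria"))
  age_ok <- check_age_bands(strata, criteria)
  year_ok <- strata$year >= criteria$years[1] & strata$year <= criteria$years[2]
  intent_ok <- strata$intent %in% criteria$allowed_intents
  place_ok <- strata$place_of_death %in% criteria$allowed_places
  identified <- year_ok & age_ok & intent_ok & place_ok
  cls <- rep(NA_character_, nrow(strata))
  if (any(identified)) {
    cls[identified] <- classify_trauma(strata$mechanism[identified],
                                       criteria$mechanism_map)
  }
  list(year_ok = year_ok, age_ok = age_ok, intent_ok = intent_ok,
       place_ok = place_ok, identified = identified,
       mech_excluded = identified & !is.na(cls) & cls == "excluded",
       included = identified & !is.na(cls) & cls != "excluded")
}

#' Filter death-certificate strata and tally the cohort
#'
#' Applies the cohort criteria and returns totals: `n_identified` (deaths
#' passing the year, age, intent and place filters), `n_excluded_mechanism`
#' (identified deaths whose mechanism classifies as excluded — drowning,
#' fire/flame, poisoning, suffocation), `n_included` (blunt/penetrating), the
#' per-state and per-year marginals of the included count, and a sequential
#' exclusion cascade for flowchart-style reporting.
#'
#' @param strata A `death_strata` data.frame from [read_death_strata()] (or
#'   built in code with the same columns).
#' @param criteria A [cohort_criteria()].
#' @return An object of class `cohort_totals`: list with `n_identified`,
#'   `n_excluded_mechanism`, `n_included`, `by_state`, `by_year`, `cascade`.
#' @examples
#' strata <- data.frame(
#'   state = "MA", year = 2008L, mechanism = c("firearm", "drowning"),
#'   intent = "homicide", place_of_death = "medical_facility_inpatient_or_ed",
#'   age_group = "21-25", age_over_15 = TRUE, count = c(10L, 2L))
#' filter_cohort(strata)
#' @export
filter_cohort <- function(strata, criteria = cohort_criteria()) {
  m <- cohort_masks(strata, criteria)
  cnt <- as.numeric(strata$count)
  total <- sum(cnt)
  # sequential cascade: year -> age -> intent -> place -> mechanism
  s1 <- m$year_ok
  s2 <- s1 & m$age_ok
  s3 <- s2 & m$intent_ok
  s4 <- s3 & m$place_ok
  cascade <- data.frame(
    criterion = c("year_window", "age_over_15", "injury_intent",
                  "place_of_death", "non_blunt_penetrating_mechanism"),
    n_dropped = c(total - sum(cnt[s1]),
                  sum(cnt[s1]) - sum(cnt[s2]),
                  sum(cnt[s2]) - sum(cnt[s3]),
                  sum(cnt[s3]) - sum(cnt[s4]),
                  sum(cnt[m$mech_excluded])),
    stringsAsFactors = FALSE
  )
  n_identified <- sum(cnt[m$identified])
  n_excluded <- sum(cnt[m$mech_excluded])
  inc <- strata[m$included, , drop = FALSE]
  by_state <- tapply_sum(inc$count, inc$state, sort(unique(strata$state)))
  years_seq <- seq(criteria$years[1], criteria$years[2])
  by_year <- tapply_sum(inc$count, as.character(inc$year),
                        as.character(years_seq))
  structure(list(n_identified = n_identified,
                 n_excluded_mechanism = n_excluded,
                 n_included = n_identified - n_excluded,
                 by_state = by_state, by_year = by_year, cascade = cascade),
            class = "cohort_totals")
}

tapply_sum <- function(x, by, levels) {
  out <- stats::setNames(numeric(length(levels)), levels)
  if (length(x)) {
    s <- tapply(as.numeric(x), factor(by, levels = levels), sum)
    s[is.na(s)] <- 0
    out[names(s)] <- s
  }
  out
}

#' @export
print.cohort_totals <- function(x, ...) {
  cat("Death-certificate cohort totals\n")
  cat("  identified (year/age/intent/place):", format(x$n_identified, big.mark = ","), "\n")
  cat("  excluded (non-blunt/penetrating):  ", format(x$n_excluded_mechanism, big.mark = ","), "\n")
  cat("  included (blunt/penetrating):      ", format(x$n_included, big.mark = ","), "\n")
  cat("  jurisdictions:", length(x$by_state), " years:",
      paste(range(as.integer(names(x$by_year))), collapse = "-"), "\n")
  invisible(x)
}

#' Serialize cohort totals
#'
#' @param totals A `cohort_totals` object.
#' @param json_path Optional path for a JSON rendering of the totals.
#' @param state_csv_path Optional path for a per-state CSV
#'   (columns `state`, `n_included`).
#' @return `totals`, invisibly.
#' @export
write_cohort_totals <- function(totals, json_path = NULL, state_csv_path = NULL) {
  stopifnot(inherits(totals, "cohort_totals"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_identified = totals$n_identified,
           n_excluded_mechanism = totals$n_excluded_mechanism,
           n_included = totals$n_included,
           by_state = as.list(totals$by_state),
           by_year = as.list(totals$by_year),
           cascade = totals$cascade),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(state_csv_path)) {
    utils::write.csv(data.frame(state = names(totals$by_state),
                                n_included = unname(totals$by_state)),
                     state_csv_path, row.names = FALSE)
  }
  invisible(totals)
}
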