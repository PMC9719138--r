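# Shared vocabularies, rounding, and seed-stream helpers.

#' Jurisdiction codes covered by the pipeline
#'
#' The 50 U.S. states plus the District of Columbia, which the underlying
#' death-certificate source treats as a state-level jurisdiction.
#'
#' @return Character vector of 51 two-letter codes.
#' @export
state_codes <- function() {
  c("AL", "AK", "AZ", "AR", "CA", "CO", "CT", "DE", "DC", "FL", "GA", "HI",
    "ID", "IL", "IN", "IA", "KS", "KY", "LA", "ME", "MD", "MA", "MI", "MN",
    "MS", "MO", "MT", "NE", "NV", "NH", "NJ", "NM", "NY", "NC", "ND", "OH",
    "OK", "OR", "PA", "RI", "SC", "SD", "TN", "TX", "UT", "VT", "VA", "WA",
    "WV", "WI", "WY")
}

intent_levels <- function() {
  c("unintentional", "homicide", "undetermined", "legal_intervention_or_war",
    "suicide", "other")
}

place_levels <- function() {
  c("medical_facility_inpatient_or_ed", "medical_facility_dead_on_arrival",
    "medical_facility_unknown_status", "home", "other", "unknown")
}

trauma_type_levels <- function() c("blunt", "penetrating", "burn", "other")

arrival_mode_levels <- function() {
  c("ems_ground", "ems_air", "private_vehicle", "walk_in", "other", "unknown")
}

ed_disposition_levels <- function() {
  c("expired", "admitted_inpatient", "observation", "transferred",
    "discharged", "other")
}

hospital_disposition_levels <- function() {
  c("expired", "discharged", "transferred", "other", "not_applicable")
}

#' Round half away from zero
#'
#' Report-time rounding rule. All internal arithmetic is kept at full
#' precision; printed integers round halves away from zero, so an annual mean
#' of 42,609.5 reports as 42,610 (base [round()] would banker-round).
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @export
round_half_away <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive an independent 31-bit sub-seed for one named field of one generator,
# so adding a field to a generator never perturbs earlier fields' draws.
field_seed <- function(seed, field_id) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(field_id) == 1L)
  as.integer((as.double(seed) %% 2147483647) * 48271 + field_id * 9973) %%
    2147483647L
}

with_field_seed <- function(seed, field_id, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(field_seed(seed, field_id))
  force(expr)
}

# Parse an age-band label ("16-20", "76+", "0-15") into c(lo, hi); hi is Inf
# for open-ended bands.
parse_age_band <- function(band) {
  out <- matrix(NA_real_, nrow = length(band), ncol = 2L,
                dimnames = list(NULL, c("lo", "hi")))
  open <- grepl("^[0-9]+\\+$", band)
  rng <- grepl("^[0-9]+-[0-9]+$", band)
  bad <- !(open | rng)
  if (any(bad)) {
    stop("unparseable age band label(s): ",
         paste(unique(band[bad]), collapse = ", "), call. = FALSE)
  }
  out[open, "lo"] <- as.numeric(sub("\\+$", "", band[open]))
  out[open, "hi"] <- Inf
  sp <- strsplit(band[rng], "-", fixed = TRUE)
  out[rng, "lo"] <- as.numeric(vapply(sp, `[`, "", 1L))
  out[rng, "hi"] <- as.numeric(vapply(sp, `[`, "", 2L))
  if (any(out[, "lo"] > out[, "hi"])) {
    stop("age band with lower bound above upper bound", call. = FALSE)
  }
  out
}

# Encode / decode semicolon-delimited vitals reading lists ("" = undocumented).
encode_readings <- function(readings) {
  vapply(readings, function(r) paste(r, collapse = ";"), "")
}

decode_readings <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(r) {
    r <- r[nzchar(r)]
    if (!length(r)) return(numeric(0))
    v <- suppressWarnings(as.numeric(r))
    if (anyNA(v)) stop("non-numeric vitals reading: ", paste(r, collapse = ";"),
                       call. = FALSE)
    v
  })
}

# Row-wise min/max over encoded reading strings; NA where no readings.
readings_extreme <- function(x, fun) {
  vals <- decode_readings(x)
  vapply(vals, function(v) if (length(v)) fun(v) else NA_real_, 0)
}
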