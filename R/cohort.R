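# Cohort data model: neonate records, observation timelines, validation,
# and CSV serialization. A cohort is stored as two data frames (one row per
# record; one row per timestamped observation, keyed by record id), the
# layout in which cohorts are read, written, and processed.

RESPIRATORY_SUPPORT_LEVELS <- c("none", "supplemental_O2", "HFNC", "nCPAP",
                                "mechanical_ventilation")
DELIVERY_MODES <- c("vaginal", "cesarean")
GBS_STATUSES <- c("positive", "negative", "unknown")
TRIAGE_LEVELS <- c("rooming_in", "intermediate_care", "NICU")

RECORD_COLUMNS <- c(
  id = "character",
  gestational_age_weeks = "numeric",
  delivery_mode = "character",
  gbs_status = "character",
  gbs_bacteriuria = "logical",
  prior_gbs_infant = "logical",
  rom_hours = "numeric",
  max_intrapartum_temp_c = "numeric",
  iap_given = "logical",
  iap_adequate = "logical",
  apgar_5min = "integer",
  delivery_room_support_only = "logical",
  prior_override_per_1000 = "numeric",
  true_eos = "logical"
)

OBSERVATION_COLUMNS <- c(
  id = "character",
  age_hours = "numeric",
  heart_rate_bpm = "numeric",
  resp_rate_bpm = "numeric",
  temp_c = "numeric",
  spo2_pct = "numeric",
  base_excess_mmol_l = "numeric",
  capillary_refill_s = "numeric",
  respiratory_support = "character",
  increased_effort = "logical",
  vasoactive_drugs = "logical",
  seizure = "logical",
  apnoea = "logical",
  lethargy = "logical",
  irritability = "logical",
  poor_perfusion_or_shock = "logical",
  abnormal_skin_color = "logical",
  worsening_wellbeing = "logical"
)

empty_frame <- function(spec) {
  out <- lapply(spec, function(cl) vector(cl, 0L))
  structure(as.data.frame(out, stringsAsFactors = FALSE),
            names = names(spec))
}

#' Maternal risk-factor profile
#'
#' Bundles the intrapartum variables used by both management strategies:
#' gestational age, delivery mode, group B Streptococcus (GBS) status,
#' membrane-rupture duration, highest intrapartum temperature, and
#' intrapartum antibiotic prophylaxis (IAP).
#'
#' @param gestational_age_weeks decimal weeks; the cohort inclusion rule is
#'   a gestational age of at least 34 weeks.
#' @param delivery_mode `"vaginal"` or `"cesarean"`.
#' @param gbs_status `"positive"`, `"negative"`, or `"unknown"` (unscreened).
#' @param gbs_bacteriuria logical, GBS bacteriuria during this pregnancy.
#' @param prior_gbs_infant logical, previous infant with invasive GBS disease.
#' @param rom_hours duration of membrane rupture before delivery, hours.
#' @param max_intrapartum_temp_c highest maternal intrapartum temperature, Celsius.
#' @param iap_given logical, intrapartum antibiotic prophylaxis administered.
#' @param iap_adequate logical, prophylaxis adequate (timing/agent); only
#'   meaningful when `iap_given` is `TRUE`.
#' @return a named list of class `maternal_profile`.
#' @export
maternal_profile <- function(gestational_age_weeks,
                             delivery_mode = "vaginal",
                             gbs_status = "unknown",
                             gbs_bacteriuria = FALSE,
                             prior_gbs_infant = FALSE,
                             rom_hours = 0,
                             max_intrapartum_temp_c = 36.8,
                             iap_given = FALSE,
                             iap_adequate = FALSE) {
  structure(list(
    gestational_age_weeks = as.numeric(gestational_age_weeks),
    delivery_mode = delivery_mode,
    gbs_status = gbs_status,
    gbs_bacteriuria = isTRUE(gbs_bacteriuria),
    prior_gbs_infant = isTRUE(prior_gbs_infant),
    rom_hours = as.numeric(rom_hours),
    max_intrapartum_temp_c = as.numeric(max_intrapartum_temp_c),
    iap_given = isTRUE(iap_given),
    iap_adequate = isTRUE(iap_adequate)
  ), class = "maternal_profile")
}

#' One timestamped clinical observation
#'
#' Vitals are optional ("not measured"), encoded as `NA`; decision engines
#' treat an absent vital as non-abnormal, never imputed. Categorical flags
#' default to `FALSE`.
#'
#' @param age_hours decimal hours since birth (0 = at birth).
#' @param heart_rate_bpm,resp_rate_bpm,temp_c,spo2_pct,base_excess_mmol_l,capillary_refill_s
#'   optional vitals (`NA` if not measured).
#' @param respiratory_support one of `"none"`, `"supplemental_O2"`,
#'   `"HFNC"`, `"nCPAP"`, `"mechanical_ventilation"`.
#' @param increased_effort grunting, nasal flaring, or retracting.
#' @param vasoactive_drugs,seizure,apnoea,lethargy,irritability,poor_perfusion_or_shock,abnormal_skin_color,worsening_wellbeing
#'   categorical clinical flags.
#' @return one-row data frame with the observation columns (without `id`).
#' @export
observation <- function(age_hours,
                        heart_rate_bpm = NA_real_,
                        resp_rate_bpm = NA_real_,
                        temp_c = NA_real_,
                        spo2_pct = NA_real_,
                        base_excess_mmol_l = NA_real_,
                        capillary_refill_s = NA_real_,
                        respiratory_support = "none",
                        increased_effort = FALSE,
                        vasoactive_drugs = FALSE,
                        seizure = FALSE,
                        apnoea = FALSE,
                        lethargy = FALSE,
                        irritability = FALSE,
                        poor_perfusion_or_shock = FALSE,
                        abnormal_skin_color = FALSE,
                        worsening_wellbeing = FALSE) {
  data.frame(
    age_hours = as.numeric(age_hours),
    heart_rate_bpm = as.numeric(heart_rate_bpm),
    resp_rate_bpm = as.numeric(resp_rate_bpm),
    temp_c = as.numeric(temp_c),
    spo2_pct = as.numeric(spo2_pct),
    base_excess_mmol_l = as.numeric(base_excess_mmol_l),
    capillary_refill_s = as.numeric(capillary_refill_s),
    respiratory_support = respiratory_support,
    increased_effort = isTRUE(increased_effort),
    vasoactive_drugs = isTRUE(vasoactive_drugs),
    seizure = isTRUE(seizure),
    apnoea = isTRUE(apnoea),
    lethargy = isTRUE(lethargy),
    irritability = isTRUE(irritability),
    poor_perfusion_or_shock = isTRUE(poor_perfusion_or_shock),
    abnormal_skin_color = isTRUE(abnormal_skin_color),
    worsening_wellbeing = isTRUE(worsening_wellbeing),
    stringsAsFactors = FALSE
  )
}

#' Empty observation timeline
#'
#' @return zero-row data frame with the observation columns (without `id`).
#' @export
empty_timeline <- function() {
  empty_frame(OBSERVATION_COLUMNS[setdiff(names(OBSERVATION_COLUMNS), "id")])
}

#' One neonate record
#'
#' @param id unique record identifier (character).
#' @param maternal a [maternal_profile()].
#' @param apgar_5min integer Apgar score at 5 minutes, 0-10.
#' @param delivery_room_support_only logical: any respiratory support ceased
#'   before leaving the delivery room (such support does not count towards
#'   "persistent support" in the risk-calculator exam).
#' @param timeline data frame of observations (rows built by
#'   [observation()]), strictly increasing in `age_hours`.
#' @param prior_override_per_1000 optional externally supplied prior EOS
#'   risk per 1,000 live births (e.g. from the original multivariate model).
#' @param true_eos optional latent infection status; only synthetic cohorts
#'   carry it.
#' @return a list of class `neonate_record` with maternal fields flattened
#'   to the top level (the CSV column layout).
#' @export
neonate_record <- function(id,
                           maternal,
                           apgar_5min = 9L,
                           delivery_room_support_only = FALSE,
                           timeline = empty_timeline(),
                           prior_override_per_1000 = NA_real_,
                           true_eos = NA) {
  stopifnot(inherits(maternal, "maternal_profile"))
  rec <- c(
    list(id = as.character(id)),
    unclass(maternal),
    list(
      apgar_5min = as.integer(apgar_5min),
      delivery_room_support_only = isTRUE(delivery_room_support_only),
      prior_override_per_1000 = as.numeric(prior_override_per_1000),
      true_eos = as.logical(true_eos),
      timeline = timeline
    )
  )
  structure(rec, class = "neonate_record")
}

#' Assemble a cohort from neonate records
#'
#' @param records list of [neonate_record()] objects.
#' @param validate validate invariants (default `TRUE`).
#' @return an `eos_cohort`: a list with elements `records` (one row per
#'   neonate) and `observations` (long format, keyed by `id`).
#' @export
eos_cohort <- function(records = list(), validate = TRUE) {
  scalar_cols <- setdiff(names(RECORD_COLUMNS), character(0))
  if (length(records) == 0L) {
    out <- structure(list(records = empty_frame(RECORD_COLUMNS),
                          observations = empty_frame(OBSERVATION_COLUMNS)),
                     class = "eos_cohort")
    return(out)
  }
  rows <- lapply(records, function(r) {
    as.data.frame(r[scalar_cols], stringsAsFactors = FALSE)
  })
  rec_df <- do.call(rbind, rows)
  obs_list <- lapply(records, function(r) {
    tl <- r$timeline
    if (is.null(tl) || nrow(tl) == 0L) return(NULL)
    cbind(id = r$id, tl, stringsAsFactors = FALSE)
  })
  obs_list <- Filter(Negate(is.null), obs_list)
  obs_df <- if (length(obs_list)) do.call(rbind, obs_list) else
    empty_frame(OBSERVATION_COLUMNS)
  rownames(rec_df) <- NULL
  rownames(obs_df) <- NULL
  coh <- structure(list(records = rec_df, observations = obs_df),
                   class = "eos_cohort")
  if (validate) validate_cohort(coh)
  coh
}

new_cohort_from_frames <- function(records, observations, validate = TRUE) {
  records <- records[, names(RECORD_COLUMNS), drop = FALSE]
  observations <- observations[, names(OBSERVATION_COLUMNS), drop = FALSE]
  records$apgar_5min <- as.integer(records$apgar_5min)
  rownames(records) <- NULL
  rownames(observations) <- NULL
  coh <- structure(list(records = records, observations = observations),
                   class = "eos_cohort")
  if (validate) validate_cohort(coh)
  coh
}

#' @export
print.eos_cohort <- function(x, ...) {
  cat(sprintf("<eos_cohort> %d neonates, %d observations\n",
              nrow(x$records), nrow(x$observations)))
  invisible(x)
}

#' Number of records in a cohort
#' @param cohort an `eos_cohort`.
#' @return integer count.
#' @export
n_records <- function(cohort) nrow(cohort$records)

#' Extract one neonate record from a cohort
#'
#' @param cohort an `eos_cohort`.
#' @param id record identifier.
#' @return a `neonate_record` (maternal fields flattened, `timeline`
#'   attached).
#' @export
cohort_record <- function(cohort, id) {
  i <- match(id, cohort$records$id)
  if (is.na(i)) stop("no record with id '", id, "'")
  record_from_row(cohort$records[i, , drop = FALSE],
                  cohort$observations[cohort$observations$id == id, ,
                                      drop = FALSE])
}

record_from_row <- function(row, obs) {
  tl <- obs[, setdiff(names(OBSERVATION_COLUMNS), "id"), drop = FALSE]
  rownames(tl) <- NULL
  rec <- as.list(row)
  rec$apgar_5min <- as.integer(rec$apgar_5min)
  rec$timeline <- tl
  structure(rec, class = "neonate_record")
}

# ---- validation -------------------------------------------------------------

fail_validation <- function(id, field, msg) {
  stop(sprintf("validation error [record %s, field %s]: %s", id, field, msg),
       call. = FALSE)
}

#' Validate a single neonate record
#'
#' Checks the study inclusion rule (gestational age >= 34 weeks), range
#' invariants on vitals and scores, the IAP consistency rule, and strict
#' ordering of the observation timeline. Either returns invisibly or stops
#' with an error naming the record id and the offending field.
#'
#' @param record a `neonate_record`.
#' @return `invisible(TRUE)` on success.
#' @export
validate_record <- function(record) {
  id <- record$id
  ga <- record$gestational_age_weeks
  if (!is_num1(ga) || ga < 34)
    fail_validation(id, "gestational_age_weeks",
                    "study inclusion requires ≥34 weeks of gestation")
  if (!record$delivery_mode %in% DELIVERY_MODES)
    fail_validation(id, "delivery_mode", "unknown delivery mode")
  if (!record$gbs_status %in% GBS_STATUSES)
    fail_validation(id, "gbs_status", "unknown GBS status")
  if (!is_num1(record$rom_hours) || record$rom_hours < 0)
    fail_validation(id, "rom_hours", "membrane-rupture duration must be >= 0")
  tc <- record$max_intrapartum_temp_c
  if (!is_num1(tc) || tc < 30 || tc > 43)
    fail_validation(id, "max_intrapartum_temp_c",
                    "temperature must be within 30-43 °C")
  if (isTRUE(record$iap_adequate) && !isTRUE(record$iap_given))
    fail_validation(id, "iap_adequate", "adequate IAP implies IAP was given")
  ap <- record$apgar_5min
  if (is.na(ap) || ap < 0 || ap > 10)
    fail_validation(id, "apgar_5min", "Apgar score must be within 0-10")
  po <- record$prior_override_per_1000
  if (!is.na(po) && (po <= 0 || po >= 1000))
    fail_validation(id, "prior_override_per_1000",
                    "risk per 1,000 must lie in (0, 1000)")
  tl <- record$timeline
  if (nrow(tl)) {
    if (any(is.na(tl$age_hours)) || any(tl$age_hours < 0))
      fail_validation(id, "age_hours", "observation ages must be >= 0")
    if (is.unsorted(tl$age_hours, strictly = TRUE))
      fail_validation(id, "age_hours",
                      "timeline must be strictly increasing in age_hours")
    sp <- tl$spo2_pct
    if (any(!is.na(sp) & (sp < 0 | sp > 100)))
      fail_validation(id, "spo2_pct", "SpO2 must be within 0-100%")
    cr <- tl$capillary_refill_s
    if (any(!is.na(cr) & cr < 0))
      fail_validation(id, "capillary_refill_s", "refill time must be >= 0")
    if (any(!tl$respiratory_support %in% RESPIRATORY_SUPPORT_LEVELS))
      fail_validation(id, "respiratory_support", "unknown support level")
  }
  invisible(TRUE)
}

#' Validate every record in a cohort
#'
#' Vectorized over the cohort frames; the first violated invariant raises an
#' error naming the record id and field. Validation is total: a record
#' either passes all invariants or fails with a named error; nothing is
#' silently coerced.
#'
#' @param cohort an `eos_cohort`.
#' @return `invisible(TRUE)` on success.
#' @export
validate_cohort <- function(cohort) {
  rec <- cohort$records
  obs <- cohort$observations
  if (nrow(rec) == 0L) {
    if (nrow(obs)) stop("observations present without any records")
    return(invisible(TRUE))
  }
  if (anyDuplicated(rec$id))
    stop("validation error: duplicated record id '",
         rec$id[duplicated(rec$id)][1L], "'")
  check <- function(bad, field, msg) {
    if (any(bad, na.rm = TRUE)) {
      i <- which(bad)[1L]
      fail_validation(rec$id[i], field, msg)
    }
  }
  check(is.na(rec$gestational_age_weeks) | rec$gestational_age_weeks < 34,
        "gestational_age_weeks",
        "study inclusion requires ≥34 weeks of gestation")
  check(!rec$delivery_mode %in% DELIVERY_MODES, "delivery_mode",
        "unknown delivery mode")
  check(!rec$gbs_status %in% GBS_STATUSES, "gbs_status", "unknown GBS status")
  check(is.na(rec$rom_hours) | rec$rom_hours < 0, "rom_hours",
        "membrane-rupture duration must be >= 0")
  check(is.na(rec$max_intrapartum_temp_c) |
          rec$max_intrapartum_temp_c < 30 | rec$max_intrapartum_temp_c > 43,
        "max_intrapartum_temp_c", "temperature must be within 30-43 °C")
  check(rec$iap_adequate & !rec$iap_given, "iap_adequate",
        "adequate IAP implies IAP was given")
  check(is.na(rec$apgar_5min) | rec$apgar_5min < 0 | rec$apgar_5min > 10,
        "apgar_5min", "Apgar score must be within 0-10")
  check(!is.na(rec$prior_override_per_1000) &
          (rec$prior_override_per_1000 <= 0 |
             rec$prior_override_per_1000 >= 1000),
        "prior_override_per_1000", "risk per 1,000 must lie in (0, 1000)")
  if (nrow(obs)) {
    orphan <- !obs$id %in% rec$id
    if (any(orphan))
      stop("observations reference unknown record id '",
           obs$id[orphan][1L], "'")
    ocheck <- function(bad, field, msg) {
      if (any(bad, na.rm = TRUE)) {
        i <- which(bad)[1L]
        fail_validation(obs$id[i], field, msg)
      }
    }
    ocheck(is.na(obs$age_hours) | obs$age_hours < 0, "age_hours",
           "observation ages must be >= 0")
    ocheck(!is.na(obs$spo2_pct) & (obs$spo2_pct < 0 | obs$spo2_pct > 100),
           "spo2_pct", "SpO2 must be within 0-100%")
    ocheck(!is.na(obs$capillary_refill_s) & obs$capillary_refill_s < 0,
           "capillary_refill_s", "refill time must be >= 0")
    ocheck(!obs$respiratory_support %in% RESPIRATORY_SUPPORT_LEVELS,
           "respiratory_support", "unknown support level")
    strictly_up <- vapply(split(obs$age_hours, obs$id),
                          function(a) !is.unsorted(a, strictly = TRUE),
                          logical(1L))
    if (!all(strictly_up))
      fail_validation(names(strictly_up)[!strictly_up][1L], "age_hours",
                      "timeline must be strictly increasing in age_hours")
  }
  invisible(TRUE)
}

# ---- CSV I/O ----------------------------------------------------------------

observations_path_for <- function(path) {
  sub("(\\.[Cc][Ss][Vv])?$", "_observations.csv", path)
}

#' Write a cohort to CSV
#'
#' Writes two UTF-8 comma-separated files with fixed, documented column
#' order: one row per neonate, and a companion long-format observations
#' file keyed by record id. Absent optional values are written as empty
#' cells, never as sentinel numbers.
#'
#' @param cohort an `eos_cohort`.
#' @param path path of the cohort CSV; the observations file defaults to
#'   the same path with an `_observations.csv` suffix.
#' @param observations_path optional explicit path for the timeline file.
#' @return invisibly, the two paths written.
#' @export
write_cohort <- function(cohort, path,
                         observations_path = observations_path_for(path)) {
  stopifnot(inherits(cohort, "eos_cohort"))
  utils::write.csv(cohort$records, path, row.names = FALSE, na = "",
                   quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(cohort$observations, observations_path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(cohort = path, observations = observations_path))
}

apply_schema <- function(df, schema, required, what) {
  if (!is.null(schema)) {
    hit <- match(names(df), schema)
    names(df)[!is.na(hit)] <- names(schema)[hit[!is.na(hit)]]
  }
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("schema error: %s file is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  df
}

read_typed_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  colClasses = NA, fileEncoding = "UTF-8")
}

coerce_columns <- function(df, spec) {
  for (nm in names(spec)) {
    df[[nm]] <- switch(spec[[nm]],
      character = as.character(df[[nm]]),
      numeric = as.numeric(df[[nm]]),
      integer = as.integer(df[[nm]]),
      logical = as.logical(df[[nm]])
    )
  }
  df[, names(spec), drop = FALSE]
}

#' Read a cohort from CSV
#'
#' Reads the record file and its companion observations file, optionally
#' translating column names through a schema mapping, validates every
#' record, and preserves row order.
#'
#' @param path path of the cohort CSV.
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(gestational_age_weeks = "ga_wk")`.
#' @param observations_path path of the timeline file (defaulted from
#'   `path`); may be `NULL` for a cohort with no observations file.
#' @param validate validate invariants after reading (default `TRUE`).
#' @return an `eos_cohort`.
#' @export
read_cohort <- function(path, schema = NULL,
                        observations_path = observations_path_for(path),
                        validate = TRUE) {
  rec <- read_typed_csv(path)
  rec <- apply_schema(rec, schema, names(RECORD_COLUMNS), "cohort")
  rec <- coerce_columns(rec, RECORD_COLUMNS)
  if (!is.null(observations_path) && file.exists(observations_path)) {
    obs <- read_typed_csv(observations_path)
    obs <- apply_schema(obs, schema, names(OBSERVATION_COLUMNS),
                        "observations")
    obs <- coerce_columns(obs, OBSERVATION_COLUMNS)
    # empty support cells mean "none"
    obs$respiratory_support[is.na(obs$respiratory_support)] <- "none"
    flag_cols <- names(OBSERVATION_COLUMNS)[OBSERVATION_COLUMNS == "logical"]
    for (fc in flag_cols) obs[[fc]][is.na(obs[[fc]])] <- FALSE
  } else {
    obs <- empty_frame(OBSERVATION_COLUMNS)
  }
  new_cohort_from_frames(rec, obs, validate = validate)
}
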