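# Updated serial clinical observation (SCO) strategy: scheduled structured
# examinations of at-risk neonates, minor/major symptom grading, 2-hour
# re-evaluation of minor symptoms, and escalation to laboratory evaluation
# ("rule out sepsis") on major findings, worsening, or persistence.

#' Configuration of the serial clinical observation strategy
#'
#' Defaults encode the protocol: structured examinations at ages 1, 3, 6,
#' 12, 18, 24, 36, and 48 h; re-evaluation of minor symptoms every 2 h; and
#' escalation to laboratory evaluation when minor symptoms persist for
#' 12-24 h (default: the lower edge, 12 h).
#'
#' @param schedule_hours ordered examination ages in hours.
#' @param reeval_interval_hours re-evaluation interval for minor symptoms.
#' @param minor_persistence_hours persistence of minor symptoms (union of
#'   symptomatic intervals) that triggers evaluation; admissible 12-24 h.
#' @param rr_minor_cutoff breaths/min above which tachypnea is a minor sign.
#' @param hr_minor_cutoff beats/min above which tachycardia is a minor sign.
#' @param base_excess_cutoff mmol/L at or below which metabolic acidosis is
#'   a minor sign.
#' @param temp_minor_low_c,temp_minor_high_c,temp_major_c temperature bands:
#'   minor below `temp_minor_low_c` or strictly between `temp_minor_high_c`
#'   and `temp_major_c`; major at or above `temp_major_c`.
#' @param spo2_major_cutoff_pct saturation below which an unsupported
#'   infant is graded hypoxic (major).
#' @param refill_major_s capillary refill time at or above which perfusion
#'   is graded major.
#' @param treat_policy antibiotic decision after evaluation:
#'   `"major_only"` (treat if a major finding is present at or after
#'   evaluation; the deterministic default), `"always_on_eval"`, or
#'   `"probabilistic"` (treat with probability `treat_prob`, seeded by the
#'   caller).
#' @param treat_prob treatment probability under the probabilistic policy.
#' @return a list of class `sco_config`.
#' @export
sco_config <- function(schedule_hours = c(1, 3, 6, 12, 18, 24, 36, 48),
                       reeval_interval_hours = 2,
                       minor_persistence_hours = 12,
                       rr_minor_cutoff = 60,
                       hr_minor_cutoff = 160,
                       base_excess_cutoff = -10,
                       temp_minor_low_c = 36.0,
                       temp_minor_high_c = 37.5,
                       temp_major_c = 38.0,
                       spo2_major_cutoff_pct = 90,
                       refill_major_s = 3,
                       treat_policy = c("major_only", "always_on_eval",
                                        "probabilistic"),
                       treat_prob = 0.5) {
  treat_policy <- match.arg(treat_policy)
  if (length(schedule_hours) && is.unsorted(schedule_hours, strictly = TRUE))
    stop("schedule_hours must be strictly increasing")
  if (reeval_interval_hours <= 0)
    stop("reeval_interval_hours must be > 0")
  if (minor_persistence_hours < 12 || minor_persistence_hours > 24)
    stop("minor_persistence_hours must lie within [12, 24]")
  structure(list(
    schedule_hours = as.numeric(schedule_hours),
    reeval_interval_hours = reeval_interval_hours,
    minor_persistence_hours = minor_persistence_hours,
    rr_minor_cutoff = rr_minor_cutoff,
    hr_minor_cutoff = hr_minor_cutoff,
    base_excess_cutoff = base_excess_cutoff,
    temp_minor_low_c = temp_minor_low_c,
    temp_minor_high_c = temp_minor_high_c,
    temp_major_c = temp_major_c,
    spo2_major_cutoff_pct = spo2_major_cutoff_pct,
    refill_major_s = refill_major_s,
    treat_policy = treat_policy,
    treat_prob = treat_prob
  ), class = "sco_config")
}

not_na_true <- function(x) !is.na(x) & x

# Vectorized grading core over the rows of an observation frame. Returns
# the grade value, the number of findings at the dominating grade, and the
# two logical finding matrices. grade_observation() and the cohort runners
# share this single implementation.
grade_frame <- function(tl, config) {
  sup <- tl$respiratory_support
  tachypnea <- not_na_true(tl$resp_rate_bpm > config$rr_minor_cutoff)
  major <- cbind(
    respiratory_distress_support =
      sup %in% c("nCPAP", "mechanical_ventilation") |
      (tachypnea & tl$increased_effort & sup != "none"),
    hypoxia = not_na_true(tl$spo2_pct < config$spo2_major_cutoff_pct) &
      sup == "none",
    poor_perfusion = tl$poor_perfusion_or_shock |
      not_na_true(tl$capillary_refill_s >= config$refill_major_s),
    fever_major = not_na_true(tl$temp_c >= config$temp_major_c),
    abnormal_skin_color = tl$abnormal_skin_color,
    worsening_wellbeing = tl$worsening_wellbeing,
    apnoea = tl$apnoea,
    lethargy = tl$lethargy,
    irritability = tl$irritability,
    seizure = tl$seizure
  )
  minor <- cbind(
    tachypnea_minor = tachypnea & sup == "none",
    tachycardia = not_na_true(tl$heart_rate_bpm > config$hr_minor_cutoff),
    metabolic_acidosis =
      not_na_true(tl$base_excess_mmol_l <= config$base_excess_cutoff),
    hypothermia_minor = not_na_true(tl$temp_c < config$temp_minor_low_c),
    fever_minor = not_na_true(tl$temp_c > config$temp_minor_high_c &
                                tl$temp_c < config$temp_major_c)
  )
  n_major <- rowSums(major)
  n_minor <- rowSums(minor)
  value <- ifelse(n_major > 0L, "major",
                  ifelse(n_minor > 0L, "minor", "none"))
  list(value = value,
       n_findings = ifelse(n_major > 0L, n_major, n_minor),
       major = major, minor = minor)
}

#' Grade one observation as none / minor / major
#'
#' Pure function of a single observation and the configuration. Major
#' findings: moderate-to-severe respiratory distress requiring support
#' (nCPAP or mechanical ventilation, or tachypnea plus increased effort on
#' any support), hypoxia while unsupported, reduced skin perfusion or
#' shock, fever at or above 38 °C, grayish/pale/marbled skin, worsening of
#' general wellbeing, apnoea, lethargy, irritability, or seizures. Minor
#' findings: mild tachypnea without support, tachycardia above 160 bpm,
#' metabolic acidosis (base excess at or below -10 mmol/L), and mild
#' temperature deviations. Absent vitals are not abnormal.
#'
#' @param obs one observation (a one-row data frame from [observation()]).
#' @param config an [sco_config()].
#' @return a list of class `symptom_grade` with elements `value`
#'   (`"none"`, `"minor"`, `"major"`) and `findings` (character vector of
#'   triggered criteria; empty iff `value == "none"`).
#' @export
grade_observation <- function(obs, config = sco_config()) {
  g <- grade_frame(obs, config)
  findings <- switch(g$value,
                     major = colnames(g$major)[g$major[1L, ]],
                     minor = colnames(g$minor)[g$minor[1L, ]],
                     character(0))
  structure(list(value = g$value, findings = findings),
            class = "symptom_grade")
}

grade_timeline <- function(timeline, config) {
  if (nrow(timeline) == 0L)
    return(list(value = character(0), n_findings = integer(0)))
  grade_frame(timeline, config)
}

# Escalation analysis of a graded timeline. Evaluation is triggered at the
# first of: a major-grade observation; worsening, operationalized as a
# strict increase in the number of distinct minor findings between
# consecutive minor-graded assessments; or minor symptoms persisting (union
# of symptomatic intervals, values carried to the next assessment) for at
# least `minor_persistence_hours`.
sco_escalation <- function(timeline, config) {
  g <- grade_timeline(timeline, config)
  ages <- timeline$age_hours
  t_major <- if (any(g$value == "major")) ages[g$value == "major"][1L] else
    NA_real_
  t_worse <- NA_real_
  if (length(g$value) >= 2L) {
    for (i in 2:length(g$value)) {
      if (g$value[i] == "minor" && g$value[i - 1L] == "minor" &&
          g$n_findings[i] > g$n_findings[i - 1L]) {
        t_worse <- ages[i]
        break
      }
    }
  }
  iv <- held_abnormal_intervals(ages, g$value != "none")
  t_persist <- time_cumulative_reaches(iv, config$minor_persistence_hours)
  persist_observed <- if (nrow(iv)) sum(iv[, 2L] - iv[, 1L]) else 0
  cands <- c(major = t_major, worsening = t_worse, persistence = t_persist)
  t_eval <- suppressWarnings(min(cands, na.rm = TRUE))
  list(grades = g,
       evaluation_time = if (is.finite(t_eval)) t_eval else NA_real_,
       trigger = if (is.finite(t_eval))
         names(cands)[which.min(cands)] else NA_character_,
       first_major_time = t_major,
       minor_persistence_observed = persist_observed,
       symptomatic = any(g$value != "none"))
}

#' Planned examination times under serial clinical observation
#'
#' Returns the standard examination schedule, augmented with 2-hour
#' re-evaluations after any assessment graded minor, until the grade
#' returns to none or escalation occurs (after which the infant leaves the
#' observation pathway and the remaining schedule is dropped).
#'
#' Between charted observations the most recent grade is carried forward;
#' before the first observation the infant is ungraded (treated as none).
#'
#' @param record a `neonate_record`.
#' @param config an [sco_config()].
#' @return sorted numeric vector of examination ages in hours.
#' @export
schedule_observations <- function(record, config = sco_config()) {
  if (length(config$schedule_hours) == 0L)
    stop("sco schedule must be non-empty")
  horizon <- max(config$schedule_hours)
  esc <- sco_escalation(record$timeline, config)
  t_eval <- esc$evaluation_time
  grade_at <- function(t) {
    tl <- record$timeline
    if (nrow(tl) == 0L) return("none")
    i <- findInterval(t, tl$age_hours)
    if (i == 0L) return("none")
    esc$grades$value[i]
  }
  pending <- sort(config$schedule_hours)
  visited <- numeric(0)
  while (length(pending)) {
    t <- pending[1L]
    pending <- pending[-1L]
    if (!is.na(t_eval) && t > t_eval) break
    visited <- c(visited, t)
    if (!is.na(t_eval) && t >= t_eval) break
    if (grade_at(t) == "minor") {
      t_next <- t + config$reeval_interval_hours
      if (t_next <= horizon && !t_next %in% pending && !t_next %in% visited)
        pending <- sort(c(pending, t_next))
    }
  }
  sort(unique(visited))
}

#' Triage location under the observation protocol
#'
#' Severely ill neonates and those on nCPAP or mechanical ventilation (or
#' with vasoactive drugs or seizures) go to the NICU; infants requiring
#' supplemental oxygen or a high-flow nasal cannula go to intermediate
#' care; asymptomatic infants of 34 weeks' gestation are admitted to
#' intermediate care; everyone else rooms in with the mother.
#'
#' @param record a `neonate_record`.
#' @param grades optional grade values (from grading the timeline); graded
#'   internally when omitted.
#' @param config an [sco_config()].
#' @return `"rooming_in"`, `"intermediate_care"`, or `"NICU"`.
#' @export
sco_triage <- function(record, grades = NULL, config = sco_config()) {
  if (is.null(grades))
    grades <- grade_timeline(record$timeline, config)$value
  triage_core(record$timeline, grades, record$gestational_age_weeks)
}

triage_core <- function(tl, grades, ga_weeks) {
  if (nrow(tl)) {
    if (any(tl$respiratory_support %in% c("nCPAP", "mechanical_ventilation")) ||
        any(tl$vasoactive_drugs) || any(tl$seizure))
      return("NICU")
    if (any(tl$respiratory_support %in% c("supplemental_O2", "HFNC")))
      return("intermediate_care")
  }
  asymptomatic <- length(grades) == 0L || all(grades == "none")
  if (asymptomatic && ga_weeks < 35)
    return("intermediate_care")
  "rooming_in"
}

#' Run the serial clinical observation strategy on one record
#'
#' Walks the graded observation timeline and applies the escalation rules:
#' asymptomatic infants (and infants whose symptoms remain mild and
#' non-progressive) are never evaluated and never treated; a major finding,
#' worsening of minor findings, or persistence of minor findings triggers
#' "rule out sepsis" at that time. The antibiotic decision after evaluation
#' follows `config$treat_policy`.
#'
#' @param record a `neonate_record`.
#' @param config an [sco_config()].
#' @return a list of class `sco_decision`: `strategy`, `evaluated`,
#'   `evaluation_time_hours`, `antibiotics`, `antibiotics_time_hours`,
#'   `triage`, `trigger`, `first_major_time`,
#'   `minor_persistence_hours_observed`, `symptomatic`.
#' @export
sco_decide <- function(tl, ga_weeks, config) {
  esc <- sco_escalation(tl, config)
  evaluated <- !is.na(esc$evaluation_time)
  abx <- FALSE
  abx_time <- NA_real_
  if (evaluated) {
    if (config$treat_policy == "major_only") {
      ages <- tl$age_hours
      later <- esc$grades$value == "major" & ages >= esc$evaluation_time
      if (any(later)) {
        abx <- TRUE
        abx_time <- ages[later][1L]
      }
    } else if (config$treat_policy == "always_on_eval") {
      abx <- TRUE
      abx_time <- esc$evaluation_time
    } else {
      abx <- stats::runif(1L) < config$treat_prob
      if (abx) abx_time <- esc$evaluation_time
    }
  }
  list(
    evaluated = evaluated,
    evaluation_time_hours = esc$evaluation_time,
    antibiotics = abx,
    antibiotics_time_hours = abx_time,
    triage = triage_core(tl, esc$grades$value, ga_weeks),
    trigger = esc$trigger,
    first_major_time = esc$first_major_time,
    minor_persistence_hours_observed = esc$minor_persistence_observed,
    symptomatic = esc$symptomatic
  )
}

run_sco <- function(record, config = sco_config()) {
  structure(c(list(strategy = "SCO"),
              sco_decide(record$timeline, record$gestational_age_weeks,
                         config)),
            class = "sco_decision")
}

#' Run the serial clinical observation strategy on a cohort
#'
#' @param cohort an `eos_cohort`.
#' @param config an [sco_config()].
#' @return data frame with one row per record: `id`, `symptomatic`,
#'   `evaluated`, `evaluation_time_hours`, `antibiotics`,
#'   `antibiotics_time_hours`, `triage`, `first_major_time`,
#'   `minor_persistence_hours_observed`.
#' @export
run_sco_cohort <- function(cohort, config = sco_config()) {
  rec <- cohort$records
  n <- nrow(rec)
  symptomatic <- logical(n)
  evaluated <- logical(n)
  eval_time <- rep(NA_real_, n)
  antibiotics <- logical(n)
  abx_time <- rep(NA_real_, n)
  triage <- ifelse(rec$gestational_age_weeks < 35,
                   "intermediate_care", "rooming_in")
  first_major <- rep(NA_real_, n)
  persist <- numeric(n)
  if (nrow(cohort$observations) && n) {
    obs_by_id <- split(cohort$observations, cohort$observations$id)
    idx <- match(names(obs_by_id), rec$id)
    ga <- rec$gestational_age_weeks
    for (k in seq_along(obs_by_id)) {
      i <- idx[k]
      d <- sco_decide(obs_by_id[[k]], ga[i], config)
      symptomatic[i] <- d$symptomatic
      evaluated[i] <- d$evaluated
      eval_time[i] <- d$evaluation_time_hours
      antibiotics[i] <- d$antibiotics
      abx_time[i] <- d$antibiotics_time_hours
      triage[i] <- d$triage
      first_major[i] <- d$first_major_time
      persist[i] <- d$minor_persistence_hours_observed
    }
  }
  data.frame(
    id = rec$id,
    symptomatic = symptomatic,
    evaluated = evaluated,
    evaluation_time_hours = eval_time,
    antibiotics = antibiotics,
    antibiotics_time_hours = abx_time,
    triage = triage,
    first_major_time = first_major,
    minor_persistence_hours_observed = persist,
    stringsAsFactors = FALSE
  )
}
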