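# Neonatal sepsis risk calculator (NSC): a Bayesian tool that converts a
# maternal-risk-factor prior EOS risk into a posterior risk through
# likelihood ratios attached to the infant's clinical presentation within
# the first hours of life, then maps the posterior to a management
# recommendation.

PRESENTATION_LEVELS <- c("well_appearing", "equivocal", "clinical_illness")
NSC_RECOMMENDATIONS <- c("routine_vitals", "enhanced_vitals",
                         "culture_and_vitals",
                         "strongly_consider_antibiotics",
                         "empiric_antibiotics")

#' Configuration of the sepsis risk calculator
#'
#' Defaults are the published operating points: baseline EOS incidence
#' 0.6/1,000 live births; likelihood ratios 0.41 (well appearing), 5.0
#' (equivocal), 21.2 (clinical illness); risk strata cut at 0.65 and 1.54
#' per 1,000; management thresholds at 1 and 3 per 1,000; presentation
#' scored within the first 4 h after birth; persistence thresholds of 4 h
#' (single abnormality) and 2 h (two or more abnormalities); supplemental
#' oxygen beyond 2 h qualifying as clinical illness. Temperature
#' instability uses the calculator's strict Fahrenheit-derived bounds
#' (> 38.0 °C i.e. > 100.4 °F, < 36.4 °C i.e. < 97.5 °F).
#'
#' @param incidence_per_1000 baseline EOS incidence per 1,000 live births.
#' @param lr_well,lr_equivocal,lr_clinical likelihood ratios per category.
#' @param strata_cutoffs_per_1000 increasing pair splitting the posterior
#'   into low / middle / high risk strata.
#' @param decision_thresholds_per_1000 increasing pair used by the
#'   management decision table.
#' @param assessment_window_hours presentation is scored from observations
#'   beginning within this many hours after birth.
#' @param persistence_hours_single,persistence_hours_multi persistence (h)
#'   making one, or each of two or more, physiologic abnormalities count.
#' @param o2_duration_hours supplemental-oxygen duration beyond which the
#'   infant is classified as clinically ill.
#' @param hr_cutoff_bpm,rr_cutoff_bpm,temp_high_c,temp_low_c,spo2_cutoff_pct
#'   physiologic abnormality cutoffs.
#' @param apgar5_cutoff clinical illness if the 5-min Apgar is below this.
#' @param update_scale `"odds"` (posterior odds = prior odds x LR; the
#'   definition of a likelihood ratio) or `"multiplicative"` (naive
#'   posterior = prior x LR; negligible difference at these risks).
#' @param prior_coefficients optional named numeric vector of odds
#'   multipliers applied to the incidence for each maternal covariate that
#'   is present; names are logical maternal fields (`"iap_given"`,
#'   `"gbs_bacteriuria"`, ...) or `"gbs_positive"` for
#'   `gbs_status == "positive"`. No coefficients ship by default: the
#'   original regression is not published here, so the prior model is a
#'   pluggable interface.
#' @param recommend_fn optional override of the management decision table:
#'   a `function(prior_per_1000, posterior_per_1000, category, config)`
#'   returning one of the recommendation labels.
#' @return a list of class `nsc_config`.
#' @export
nsc_config <- function(incidence_per_1000 = 0.6,
                       lr_well = 0.41,
                       lr_equivocal = 5.0,
                       lr_clinical = 21.2,
                       strata_cutoffs_per_1000 = c(0.65, 1.54),
                       decision_thresholds_per_1000 = c(1, 3),
                       assessment_window_hours = 4,
                       persistence_hours_single = 4,
                       persistence_hours_multi = 2,
                       o2_duration_hours = 2,
                       hr_cutoff_bpm = 160,
                       rr_cutoff_bpm = 60,
                       temp_high_c = 38.0,
                       temp_low_c = 36.4,
                       apgar5_cutoff = 5,
                       spo2_cutoff_pct = 90,
                       update_scale = c("odds", "multiplicative"),
                       prior_coefficients = NULL,
                       recommend_fn = NULL) {
  update_scale <- match.arg(update_scale)
  if (incidence_per_1000 <= 0 || incidence_per_1000 >= 1000)
    stop("incidence_per_1000 must lie in (0, 1000)")
  if (any(c(lr_well, lr_equivocal, lr_clinical) <= 0))
    stop("likelihood ratios must be > 0")
  if (is.unsorted(strata_cutoffs_per_1000, strictly = TRUE))
    stop("strata cutoffs must be strictly increasing")
  if (is.unsorted(decision_thresholds_per_1000, strictly = TRUE))
    stop("decision thresholds must be strictly increasing")
  if (any(c(assessment_window_hours, persistence_hours_single,
            persistence_hours_multi, o2_duration_hours) <= 0))
    stop("window and persistence durations must be > 0")
  structure(list(
    incidence_per_1000 = incidence_per_1000,
    lr_well = lr_well, lr_equivocal = lr_equivocal,
    lr_clinical = lr_clinical,
    strata_cutoffs_per_1000 = strata_cutoffs_per_1000,
    decision_thresholds_per_1000 = decision_thresholds_per_1000,
    assessment_window_hours = assessment_window_hours,
    persistence_hours_single = persistence_hours_single,
    persistence_hours_multi = persistence_hours_multi,
    o2_duration_hours = o2_duration_hours,
    hr_cutoff_bpm = hr_cutoff_bpm, rr_cutoff_bpm = rr_cutoff_bpm,
    temp_high_c = temp_high_c, temp_low_c = temp_low_c,
    apgar5_cutoff = apgar5_cutoff, spo2_cutoff_pct = spo2_cutoff_pct,
    update_scale = update_scale,
    prior_coefficients = prior_coefficients,
    recommend_fn = recommend_fn
  ), class = "nsc_config")
}

likelihood_ratio_for <- function(category, config) {
  switch(category,
         well_appearing = config$lr_well,
         equivocal = config$lr_equivocal,
         clinical_illness = config$lr_clinical,
         stop("unknown presentation category '", category, "'"))
}

#' Prior EOS risk from maternal risk factors
#'
#' The prior is the local baseline incidence, optionally rescaled on the
#' odds scale by configured covariate multipliers, or replaced outright by
#' an externally supplied override (e.g. a risk computed by the original
#' multivariate model). No covariate coefficients ship by default.
#'
#' @param maternal a [maternal_profile()] (or a `neonate_record`, whose
#'   flattened maternal fields are used).
#' @param config an [nsc_config()].
#' @param override optional risk per 1,000 that short-circuits the model.
#' @return prior risk per 1,000 live births.
#' @export
compute_prior <- function(maternal, config = nsc_config(),
                          override = NA_real_) {
  if (!is.na(override)) {
    if (override <= 0 || override >= 1000)
      stop("configuration error: prior override must lie in (0, 1000)")
    return(override)
  }
  p <- config$incidence_per_1000 / 1000
  coefs <- config$prior_coefficients
  if (!is.null(coefs) && length(coefs)) {
    odds <- p / (1 - p)
    for (nm in names(coefs)) {
      present <- if (nm == "gbs_positive") {
        identical(maternal$gbs_status, "positive")
      } else {
        isTRUE(maternal[[nm]])
      }
      if (present) odds <- odds * coefs[[nm]]
    }
    p <- odds / (1 + odds)
  }
  out <- p * 1000
  if (out <= 0 || out >= 1000)
    stop("configuration error: prior risk fell outside (0, 1000) per 1,000")
  out
}

#' Classify an infant's clinical presentation
#'
#' Scores the infant as clinically ill, equivocal, or well appearing from
#' observations beginning within the assessment window (default 4 h after
#' birth). Clinical illness: persistent need for nCPAP, HFNC, or
#' mechanical ventilation outside the delivery room; vasoactive drugs;
#' seizures or a 5-min Apgar below 5; or supplemental oxygen for a
#' cumulative duration above 2 h. Equivocal: a single physiologic
#' abnormality (tachycardia, tachypnea, temperature instability, or
#' respiratory distress without supplemental oxygen) persisting more than
#' 4 h, or two or more abnormalities each lasting more than 2 h.
#' Abnormalities may be intermittent: durations accumulate over the union
#' of abnormal intervals, a charted value being carried forward until the
#' next charting of the same item. Otherwise well appearing.
#'
#' @param record a `neonate_record`.
#' @param config an [nsc_config()].
#' @return a list of class `presentation_category` with elements `value`
#'   and `findings`.
#' @export
classify_presentation <- function(record, config = nsc_config()) {
  classify_core(record$timeline, record$apgar_5min,
                record$delivery_room_support_only, config)
}

classify_core <- function(tl, apgar_5min, delivery_room_support_only,
                          config) {
  res <- function(value, findings = character(0))
    structure(list(value = value, findings = findings),
              class = "presentation_category")
  if (apgar_5min < config$apgar5_cutoff)
    return(res("clinical_illness", "perinatal_depression"))
  if (nrow(tl) == 0L) return(res("well_appearing"))
  tl <- tl[order(tl$age_hours), , drop = FALSE]
  w <- config$assessment_window_hours
  in_window <- tl$age_hours <= w
  clinical <- character(0)
  if (!isTRUE(delivery_room_support_only)) {
    if (any(in_window & tl$respiratory_support %in%
              c("nCPAP", "HFNC", "mechanical_ventilation")))
      clinical <- c(clinical, "persistent_respiratory_support")
    o2_dur <- held_abnormal_duration(
      tl$age_hours, tl$respiratory_support == "supplemental_O2", w)
    if (o2_dur > config$o2_duration_hours)
      clinical <- c(clinical, "supplemental_o2_duration")
  }
  if (any(in_window & tl$vasoactive_drugs))
    clinical <- c(clinical, "vasoactive_drugs")
  if (any(in_window & tl$seizure))
    clinical <- c(clinical, "seizure")
  if (length(clinical)) return(res("clinical_illness", clinical))
  vital_duration <- function(values, abnormal_fn) {
    measured <- !is.na(values)
    if (!any(measured)) return(0)
    held_abnormal_duration(tl$age_hours[measured],
                           abnormal_fn(values[measured]), w)
  }
  durations <- c(
    tachycardia = vital_duration(tl$heart_rate_bpm,
                                 function(x) x > config$hr_cutoff_bpm),
    tachypnea = vital_duration(tl$resp_rate_bpm,
                               function(x) x > config$rr_cutoff_bpm),
    temperature_instability = vital_duration(
      tl$temp_c, function(x) x > config$temp_high_c | x < config$temp_low_c),
    respiratory_distress = held_abnormal_duration(
      tl$age_hours,
      tl$increased_effort & tl$respiratory_support == "none", w)
  )
  single <- durations > config$persistence_hours_single
  multi <- durations > config$persistence_hours_multi
  if (any(single))
    return(res("equivocal", names(durations)[single]))
  if (sum(multi) >= 2L)
    return(res("equivocal", names(durations)[multi]))
  res("well_appearing")
}

posterior_from_prior <- function(prior_per_1000, lr, update_scale = "odds") {
  p <- prior_per_1000 / 1000
  if (update_scale == "odds") {
    odds <- p / (1 - p) * lr
    1000 * odds / (1 + odds)
  } else {
    pmin(1000 * p * lr, 999.999)
  }
}

stratum_for <- function(posterior_per_1000, cutoffs) {
  ifelse(posterior_per_1000 < cutoffs[1L], "low",
         ifelse(posterior_per_1000 <= cutoffs[2L], "middle", "high"))
}

#' Posterior EOS risk via the likelihood-ratio update
#'
#' Converts the prior risk to posterior risk using the likelihood ratio of
#' the presentation category (by default on the odds scale, the definition
#' of a likelihood ratio), and assigns the risk stratum: low below 0.65,
#' middle from 0.65 to 1.54, high above 1.54 per 1,000 live births.
#'
#' @param prior_per_1000 prior risk per 1,000 live births, in (0, 1000).
#' @param category a presentation category (string or the object returned
#'   by [classify_presentation()]).
#' @param config an [nsc_config()].
#' @return a list of class `risk_estimate`: `prior_per_1000`, `category`,
#'   `likelihood_ratio`, `posterior_per_1000`, `stratum`.
#' @export
bayes_posterior <- function(prior_per_1000, category,
                            config = nsc_config()) {
  if (is.list(category)) category <- category$value
  if (!category %in% PRESENTATION_LEVELS)
    stop("unknown presentation category '", category, "'")
  if (prior_per_1000 <= 0 || prior_per_1000 >= 1000)
    stop("prior risk must lie in (0, 1000) per 1,000")
  lr <- likelihood_ratio_for(category, config)
  post <- posterior_from_prior(prior_per_1000, lr, config$update_scale)
  structure(list(
    prior_per_1000 = prior_per_1000,
    category = category,
    likelihood_ratio = lr,
    posterior_per_1000 = post,
    stratum = stratum_for(post, config$strata_cutoffs_per_1000)
  ), class = "risk_estimate")
}

recommend_vec <- function(prior, posterior, category, config) {
  lo <- config$decision_thresholds_per_1000[1L]
  hi <- config$decision_thresholds_per_1000[2L]
  ifelse(category == "clinical_illness" | posterior > hi,
         "empiric_antibiotics",
  ifelse(category == "equivocal",
         "strongly_consider_antibiotics",
  ifelse(posterior >= lo,
         "culture_and_vitals",
  ifelse(prior > lo,
         "enhanced_vitals",
         "routine_vitals"))))
}

#' Management recommendation from a risk estimate
#'
#' The default decision table mirrors the calculator's five published
#' management categories: (1) routine vitals; (2) enhanced vitals when the
#' posterior is below 1/1,000 but the prior exceeds 1/1,000; (3) blood
#' culture plus enhanced vitals for posteriors from 1 to 3/1,000 in
#' well-appearing infants; (4) strong consideration of empiric antibiotics
#' for an equivocal presentation with posterior at or below 3/1,000; and
#' (5) empiric antibiotics when the posterior exceeds 3/1,000 or the infant
#' is clinically ill. Fully overridable through `config$recommend_fn`.
#'
#' @param estimate a `risk_estimate` from [bayes_posterior()].
#' @param config the same [nsc_config()] used to produce the estimate.
#' @return a list of class `nsc_recommendation`: `value`,
#'   `implies_evaluation`, `implies_antibiotics`.
#' @export
nsc_recommend <- function(estimate, config = nsc_config()) {
  value <- if (is.function(config$recommend_fn)) {
    config$recommend_fn(estimate$prior_per_1000,
                        estimate$posterior_per_1000,
                        estimate$category, config)
  } else {
    recommend_vec(estimate$prior_per_1000, estimate$posterior_per_1000,
                  estimate$category, config)
  }
  structure(list(
    value = value,
    implies_evaluation = value %in% c("culture_and_vitals",
                                      "strongly_consider_antibiotics",
                                      "empiric_antibiotics"),
    implies_antibiotics = value %in% c("strongly_consider_antibiotics",
                                       "empiric_antibiotics")
  ), class = "nsc_recommendation")
}

#' Run the sepsis risk calculator on a cohort
#'
#' Applies [compute_prior()], [classify_presentation()],
#' [bayes_posterior()], and [nsc_recommend()] to every record. As in the
#' published projection, "strongly consider antibiotics" counts as an
#' antibiotic recommendation, and the culture-bearing categories count as
#' "rule out sepsis" evaluations.
#'
#' @param cohort an `eos_cohort`.
#' @param config an [nsc_config()].
#' @return data frame with one row per record: `id`, `category`,
#'   `prior_per_1000`, `posterior_per_1000`, `stratum`, `recommendation`,
#'   `implies_evaluation`, `implies_antibiotics`, and the comparison
#'   aliases `evaluated` and `antibiotics`.
#' @export
run_nsc <- function(cohort, config = nsc_config()) {
  rec <- cohort$records
  n <- nrow(rec)
  prior <- ifelse(!is.na(rec$prior_override_per_1000),
                  rec$prior_override_per_1000,
                  config$incidence_per_1000)
  if (!is.null(config$prior_coefficients)) {
    for (i in seq_len(n)) {
      prior[i] <- compute_prior(rec[i, , drop = FALSE], config,
                                override = rec$prior_override_per_1000[i])
    }
  }
  category <- rep("well_appearing", n)
  category[rec$apgar_5min < config$apgar5_cutoff] <- "clinical_illness"
  if (nrow(cohort$observations)) {
    obs_by_id <- split(cohort$observations, cohort$observations$id)
    idx <- match(names(obs_by_id), rec$id)
    for (k in seq_along(obs_by_id)) {
      i <- idx[k]
      category[i] <- classify_core(obs_by_id[[k]], rec$apgar_5min[i],
                                   rec$delivery_room_support_only[i],
                                   config)$value
    }
  }
  lr <- vapply(category, likelihood_ratio_for, numeric(1L),
               config = config, USE.NAMES = FALSE)
  posterior <- posterior_from_prior(prior, lr, config$update_scale)
  recommendation <- recommend_vec(prior, posterior, category, config)
  if (is.function(config$recommend_fn)) {
    recommendation <- vapply(seq_len(n), function(i)
      config$recommend_fn(prior[i], posterior[i], category[i], config),
      character(1L))
  }
  implies_eval <- recommendation %in% c("culture_and_vitals",
                                        "strongly_consider_antibiotics",
                                        "empiric_antibiotics")
  implies_abx <- recommendation %in% c("strongly_consider_antibiotics",
                                       "empiric_antibiotics")
  data.frame(
    id = rec$id,
    category = category,
    prior_per_1000 = prior,
    posterior_per_1000 = posterior,
    stratum = stratum_for(posterior, config$strata_cutoffs_per_1000),
    recommendation = recommendation,
    implies_evaluation = implies_eval,
    implies_antibiotics = implies_abx,
    evaluated = implies_eval,
    antibiotics = implies_abx,
    stringsAsFactors = FALSE
  )
}
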