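# Seeded synthetic cohort generator. Emulates the structure of a single-
# centre birth cohort of neonates born at >= 34 weeks: risk-factor
# prevalences, a continuous maternal-temperature model calibrated to two
# tail probabilities, symptom incidence and onset timing, and per-infant
# symptom trajectories whose charted vitals realize an intended
# none/minor/major grade path.

#' Parameters of the synthetic cohort generator
#'
#' Defaults encode the cohort the generator emulates: 178/3,445 late
#' preterm; gestational age from two truncated normal distributions
#' matched to the published medians and interquartile ranges; risk-factor
#' prevalences (vaginal delivery 77.2%, screening 95.2%, GBS positivity
#' 21.8% of screened, prolonged rupture and IAP conditioned on the
#' late-preterm stratum); a continuous right-skewed maternal-temperature
#' model calibrated so that both P(T >= 37.5 °C) = 110/3,445 and
#' P(T >= 38 °C) = 36/3,445 emerge from one distribution; symptom
#' incidence 264/3,445 with onset split 68.2% at birth, 18.6% at 1-6 h,
#' 13.3% after 6 h; and log-normal symptom durations with median 72 h.
#'
#' @param n cohort size.
#' @param seed integer RNG seed; all randomness flows from it (per-record
#'   timeline streams are derived from it, so any one timeline can be
#'   regenerated independently).
#' @param p_late_preterm probability of gestational age 34-36.9 weeks.
#' @param ga_late,ga_term lists with `median`, `iqr` (length-2), and
#'   `range` (truncation bounds) describing the two gestational-age
#'   distributions.
#' @param p_vaginal,p_screened,p_gbs_pos_given_screened,p_gbs_bacteriuria,p_prior_gbs_infant
#'   Bernoulli prevalences.
#' @param p_prom,p_iap named pairs (`late_preterm`, `term`) of
#'   stratum-conditional probabilities of prolonged membrane rupture
#'   (>= 18 h) and of intrapartum antibiotic prophylaxis.
#' @param p_iap_adequate_given_iap adequacy probability among IAP-exposed.
#' @param temp_tail named pair `p_ge_37_5`, `p_ge_38`: target upper-tail
#'   probabilities of the maternal-temperature distribution.
#' @param temp_shift_c location shift of the log-normal temperature excess.
#' @param p_symptomatic probability an infant shows symptoms of suspected
#'   EOS within 48 h.
#' @param onset_split probabilities (`at_birth`, `h1_6`, `after_6`)
#'   summing to 1.
#' @param trajectory list of trajectory parameters: `p_major_onset`,
#'   `p_progression` (minor to major mid-course), `duration_meanlog`,
#'   `duration_sdlog`, `support_probs` (respiratory-support mix of
#'   major-grade infants), `minor_type_probs` (minor-finding mix).
#' @param eos_incidence_per_1000 latent true-EOS incidence; such infants
#'   are forced to symptomatic major-grade trajectories. Set to 0 to
#'   mirror a cohort with no culture-proven EOS.
#' @return a list of class `cohort_params`.
#' @export
cohort_params <- function(n = 1000,
                          seed = NULL,
                          p_late_preterm = 178 / 3445,
                          ga_late = list(median = 36.14,
                                         iqr = c(35.29, 36.57),
                                         range = c(34, 36.99)),
                          ga_term = list(median = 39.71,
                                         iqr = c(39.0, 40.29),
                                         range = c(37, 42.5)),
                          p_vaginal = 2661 / 3445,
                          p_screened = 3279 / 3445,
                          p_gbs_pos_given_screened = 716 / 3279,
                          p_gbs_bacteriuria = 46 / 3445,
                          p_prior_gbs_infant = 2 / 3445,
                          p_prom = c(late_preterm = 41 / 178,
                                     term = 473 / 3267),
                          p_iap = c(late_preterm = 98 / 178,
                                    term = 923 / 3267),
                          p_iap_adequate_given_iap = 575 / 1021,
                          temp_tail = c(p_ge_37_5 = 110 / 3445,
                                        p_ge_38 = 36 / 3445),
                          temp_shift_c = 36.5,
                          p_symptomatic = 264 / 3445,
                          onset_split = c(at_birth = 180 / 264,
                                          h1_6 = 49 / 264,
                                          after_6 = 35 / 264),
                          trajectory = list(
                            p_major_onset = 0.30,
                            p_progression = 0.15,
                            duration_meanlog = log(72),
                            duration_sdlog =
                              (log(120) - log(24)) / (2 * stats::qnorm(0.75)),
                            support_probs = c(nCPAP = 0.40, HFNC = 0.30,
                                              supplemental_O2 = 0.15,
                                              none = 0.15),
                            minor_type_probs = c(tachypnea = 0.60,
                                                 tachycardia = 0.15,
                                                 fever = 0.10,
                                                 acidosis = 0.15)),
                          eos_incidence_per_1000 = 0.6) {
  probs <- c(p_late_preterm, p_vaginal, p_screened, p_gbs_pos_given_screened,
             p_gbs_bacteriuria, p_prior_gbs_infant, p_prom, p_iap,
             p_iap_adequate_given_iap, temp_tail, p_symptomatic, onset_split,
             trajectory$p_major_onset, trajectory$p_progression)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("parameter error: all probabilities must lie in [0, 1]")
  if (abs(sum(onset_split) - 1) > 1e-8)
    stop("parameter error: onset_split must sum to 1")
  if (n < 0) stop("parameter error: n must be >= 0")
  if (eos_incidence_per_1000 < 0 || eos_incidence_per_1000 >= 1000)
    stop("parameter error: eos_incidence_per_1000 must lie in [0, 1000)")
  structure(list(
    n = n, seed = seed, p_late_preterm = p_late_preterm,
    ga_late = ga_late, ga_term = ga_term,
    p_vaginal = p_vaginal, p_screened = p_screened,
    p_gbs_pos_given_screened = p_gbs_pos_given_screened,
    p_gbs_bacteriuria = p_gbs_bacteriuria,
    p_prior_gbs_infant = p_prior_gbs_infant,
    p_prom = p_prom, p_iap = p_iap,
    p_iap_adequate_given_iap = p_iap_adequate_given_iap,
    temp_tail = temp_tail, temp_shift_c = temp_shift_c,
    p_symptomatic = p_symptomatic, onset_split = onset_split,
    trajectory = trajectory,
    eos_incidence_per_1000 = eos_incidence_per_1000
  ), class = "cohort_params")
}

# Two-point quantile matching of the shifted log-normal temperature model:
# solves for (meanlog, sdlog) so that the two configured tail targets hold
# exactly.
temp_model_coefs <- function(params) {
  p1 <- params$temp_tail[["p_ge_37_5"]]
  p2 <- params$temp_tail[["p_ge_38"]]
  x1 <- 37.5 - params$temp_shift_c
  x2 <- 38.0 - params$temp_shift_c
  z1 <- stats::qnorm(1 - p1)
  z2 <- stats::qnorm(1 - p2)
  sdlog <- (log(x2) - log(x1)) / (z2 - z1)
  meanlog <- log(x1) - z1 * sdlog
  c(meanlog = meanlog, sdlog = sdlog)
}

ga_sd <- function(spec) diff(spec$iqr) / (2 * stats::qnorm(0.75))

# Derived per-record stream seed: lets one infant's timeline be regenerated
# without redrawing the whole cohort.
derive_stream_seed <- function(seed, index) {
  (seed + index * 1000003) %% 2147483647L
}

#' Median symptom-duration draws of the trajectory model
#'
#' @param n number of draws.
#' @param params a [cohort_params()].
#' @return numeric vector of symptom durations in hours.
#' @export
sample_symptom_duration <- function(n, params = cohort_params()) {
  pmax(stats::rlnorm(n, params$trajectory$duration_meanlog,
                     params$trajectory$duration_sdlog), 0.5)
}

jitter_round <- function(k, lo, hi) round(stats::runif(k, lo, hi), 1L)

#' Generate one infant's symptom trajectory
#'
#' Builds an observation timeline over 0-48 h realizing an intended grade
#' path: symptoms start at the onset time (drawn within the onset class),
#' last for a log-normal duration, may progress from minor to major, and
#' resolve to a normal final observation if resolution falls inside the
#' window. Charted vitals are sampled so that each observation reproduces
#' the intended grade under [grade_observation()] (inverse-grading
#' consistency).
#'
#' @param context list with `onset_class` (`"at_birth"`, `"h1_6"`,
#'   `"after_6"`) and optionally `force_major` (used for latent true-EOS
#'   infants).
#' @param params a [cohort_params()].
#' @param seed optional integer seed of this record's stream.
#' @param keep_intended attach the intended grade as column `.intended`.
#' @param as_columns return a plain list of column vectors instead of a
#'   data frame (used by [generate_cohort()] to assemble many timelines
#'   cheaply).
#' @return data frame of observations (the timeline of one record), or a
#'   list of columns when `as_columns = TRUE`.
#' @export
generate_timeline <- function(context, params = cohort_params(),
                              seed = NULL, keep_intended = FALSE,
                              as_columns = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(context$onset_class %in% c("at_birth", "h1_6", "after_6"))
  tr <- params$trajectory
  t0 <- switch(context$onset_class,
               at_birth = 0,
               h1_6 = round(stats::runif(1L, 1, 6), 2L),
               after_6 = round(stats::runif(1L, 6, 24), 2L))
  dur <- sample_symptom_duration(1L, params)
  t_end_sym <- t0 + dur
  t_last <- min(t_end_sym, 48)
  major_onset <- isTRUE(context$force_major) ||
    stats::runif(1L) < tr$p_major_onset
  progresses <- !major_onset && stats::runif(1L) < tr$p_progression
  t_prog <- if (progresses)
    t0 + stats::runif(1L, 0.3, 0.7) * (t_last - t0) else Inf
  support <- sample(names(tr$support_probs), 1L, prob = tr$support_probs)
  febrile <- stats::runif(1L) < 0.5
  minor_type <- sample(names(tr$minor_type_probs), 1L,
                       prob = tr$minor_type_probs)
  times <- sort(unique(round(c(seq(t0, t_last, by = 2), t_last), 2L)))
  k <- length(times)
  resolved <- t_end_sym <= 48 & times >= round(t_last, 2L) & times > t0
  grade <- ifelse(resolved, "none",
                  ifelse(major_onset | times >= t_prog, "major", "minor"))
  # reference normal vitals; the intended finding is superimposed per row
  hr <- rep(130, k); rr <- rep(45, k); temp <- rep(36.8, k)
  spo2 <- rep(98, k); be <- rep(NA_real_, k)
  sup <- rep("none", k); effort <- rep(FALSE, k)
  mi <- grade == "minor"
  if (any(mi)) {
    km <- sum(mi)
    switch(minor_type,
      tachypnea = { rr[mi] <- jitter_round(km, 63, 80) },
      tachycardia = { hr[mi] <- jitter_round(km, 163, 185) },
      fever = { temp[mi] <- jitter_round(km, 37.6, 37.9) },
      acidosis = { be[mi] <- jitter_round(km, -14, -10.5) })
  }
  ma <- grade == "major"
  if (any(ma)) {
    km <- sum(ma)
    if (support != "none") {
      # respiratory distress requiring support: tachypnea + effort
      sup[ma] <- support
      rr[ma] <- jitter_round(km, 62, 85)
      effort[ma] <- TRUE
      spo2[ma] <- jitter_round(km, 91, 96)
    } else if (febrile) {
      temp[ma] <- jitter_round(km, 38.1, 39.0)
    } else {
      # hypoxia while unsupported
      spo2[ma] <- jitter_round(km, 84, 88.9)
    }
  }
  flag_off <- rep(FALSE, k)
  cols <- list(
    age_hours = times,
    heart_rate_bpm = hr, resp_rate_bpm = rr, temp_c = temp,
    spo2_pct = spo2, base_excess_mmol_l = be,
    capillary_refill_s = rep(NA_real_, k),
    respiratory_support = sup,
    increased_effort = effort,
    vasoactive_drugs = flag_off, seizure = flag_off, apnoea = flag_off,
    lethargy = flag_off, irritability = flag_off,
    poor_perfusion_or_shock = flag_off, abnormal_skin_color = flag_off,
    worsening_wellbeing = flag_off
  )
  if (keep_intended) cols$.intended <- grade
  if (as_columns) return(cols)
  tl <- as.data.frame(cols, stringsAsFactors = FALSE)
  rownames(tl) <- NULL
  tl
}

#' Generate a synthetic neonate cohort
#'
#' Draws `n` records with the configured risk-factor prevalences,
#' gestational-age and maternal-temperature distributions, symptom
#' incidence and onset timing, and attaches symptom trajectories built by
#' [generate_timeline()]. Identical parameters and seed yield an identical
#' cohort (and therefore byte-identical CSV output).
#'
#' @param params a [cohort_params()].
#' @return a validated `eos_cohort`; records carry `true_eos`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  n <- params$n
  if (!is.null(params$seed)) set.seed(params$seed)
  master_seed <- if (!is.null(params$seed)) params$seed else
    sample.int(2147483646L, 1L)
  if (n == 0L) return(eos_cohort())
  late <- stats::runif(n) < params$p_late_preterm
  ga <- numeric(n)
  draw_ga <- function(spec, k) {
    round(rtrunc_norm(k, spec$median, ga_sd(spec),
                      spec$range[1L], spec$range[2L]), 2L)
  }
  ga[late] <- draw_ga(params$ga_late, sum(late))
  ga[!late] <- draw_ga(params$ga_term, sum(!late))
  vaginal <- stats::runif(n) < params$p_vaginal
  screened <- stats::runif(n) < params$p_screened
  gbs_pos <- screened & stats::runif(n) < params$p_gbs_pos_given_screened
  gbs_status <- ifelse(!screened, "unknown",
                       ifelse(gbs_pos, "positive", "negative"))
  gbs_bact <- stats::runif(n) < params$p_gbs_bacteriuria
  prior_gbs <- stats::runif(n) < params$p_prior_gbs_infant
  p_prom_i <- ifelse(late, params$p_prom[["late_preterm"]],
                     params$p_prom[["term"]])
  prom <- stats::runif(n) < p_prom_i
  rom <- numeric(n)
  rom[prom] <- round(18 + stats::rexp(sum(prom), rate = 1 / 8), 1L)
  # short ruptures: exponential truncated below the 18-h prolonged cutoff
  u <- stats::runif(sum(!prom), 0, stats::pexp(18, rate = 1 / 5))
  rom[!prom] <- round(stats::qexp(u, rate = 1 / 5), 1L)
  tm <- temp_model_coefs(params)
  temp <- round(pmin(params$temp_shift_c +
                       stats::rlnorm(n, tm[["meanlog"]], tm[["sdlog"]]),
                     42.9), 2L)
  p_iap_i <- ifelse(late, params$p_iap[["late_preterm"]],
                    params$p_iap[["term"]])
  iap <- stats::runif(n) < p_iap_i
  iap_adequate <- iap & stats::runif(n) < params$p_iap_adequate_given_iap
  true_eos <- stats::runif(n) < params$eos_incidence_per_1000 / 1000
  symptomatic <- true_eos | stats::runif(n) < params$p_symptomatic
  onset <- rep(NA_character_, n)
  ns <- sum(symptomatic)
  if (ns) {
    onset[symptomatic] <- sample(names(params$onset_split), ns,
                                 replace = TRUE, prob = params$onset_split)
    # latent infection presents early
    onset[true_eos] <- "at_birth"
  }
  # 5-min Apgar: overwhelmingly 9-10 in asymptomatic infants; depressed
  # scores (including < 5) only among symptomatic infants
  apgar <- integer(n)
  asym <- !symptomatic
  apgar[asym] <- sample(c(10L, 9L, 8L, 7L), sum(asym), replace = TRUE,
                        prob = c(0.55, 0.40, 0.04, 0.01))
  if (ns)
    apgar[symptomatic] <- sample(c(10L, 9L, 8L, 7L, 6L, 5L, 4L, 3L), ns,
                                 replace = TRUE,
                                 prob = c(0.10, 0.45, 0.25, 0.10, 0.04,
                                          0.03, 0.02, 0.01))
  ids <- sprintf("N%06d", seq_len(n))
  rec <- data.frame(
    id = ids,
    gestational_age_weeks = ga,
    delivery_mode = ifelse(vaginal, "vaginal", "cesarean"),
    gbs_status = gbs_status,
    gbs_bacteriuria = gbs_bact,
    prior_gbs_infant = prior_gbs,
    rom_hours = rom,
    max_intrapartum_temp_c = temp,
    iap_given = iap,
    iap_adequate = iap_adequate,
    apgar_5min = apgar,
    delivery_room_support_only = FALSE,
    prior_override_per_1000 = NA_real_,
    true_eos = true_eos,
    stringsAsFactors = FALSE
  )
  obs <- empty_frame(OBSERVATION_COLUMNS)
  if (ns) {
    sym_idx <- which(symptomatic)
    tls <- lapply(sym_idx, function(i) {
      generate_timeline(
        list(onset_class = onset[i], force_major = true_eos[i]),
        params, seed = derive_stream_seed(master_seed, i),
        as_columns = TRUE)
    })
    lens <- vapply(tls, function(x) length(x$age_hours), integer(1L))
    cols <- c(list(id = rep(ids[sym_idx], lens)),
              lapply(names(tls[[1L]]), function(nm)
                unlist(lapply(tls, `[[`, nm), use.names = FALSE)))
    names(cols) <- c("id", names(tls[[1L]]))
    obs <- as.data.frame(cols, stringsAsFactors = FALSE)
  }
  new_cohort_from_frames(rec, obs)
}
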