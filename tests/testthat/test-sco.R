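test_that("observations are graded by the minor/major criteria", {
  g <- grade_observation(observation(2, resp_rate_bpm = 65))
  expect_equal(g$value, "minor")
  expect_equal(g$findings, "tachypnea_minor")

  expect_equal(grade_observation(observation(2, temp_c = 38.2))$value,
               "major")
  g_be <- grade_observation(observation(2, base_excess_mmol_l = -12))
  expect_equal(g_be$value, "minor")
  expect_equal(g_be$findings, "metabolic_acidosis")

  g_none <- grade_observation(observation(2, heart_rate_bpm = 140,
                                          resp_rate_bpm = 50,
                                          temp_c = 36.9, spo2_pct = 98))
  expect_equal(g_none$value, "none")
  expect_length(g_none$findings, 0L)

  # grade none iff findings empty; major dominates minor
  g_mix <- grade_observation(observation(2, resp_rate_bpm = 70,
                                         temp_c = 38.5))
  expect_equal(g_mix$value, "major")

  # respiratory distress requiring support
  expect_equal(grade_observation(
    observation(1, respiratory_support = "nCPAP"))$value, "major")
  expect_equal(grade_observation(
    observation(1, resp_rate_bpm = 70, increased_effort = TRUE,
                respiratory_support = "HFNC"))$value, "major")
  # hypoxia while unsupported; supported low SpO2 is captured by support
  expect_equal(grade_observation(observation(1, spo2_pct = 87))$value,
               "major")
  # refill time and perfusion
  expect_equal(grade_observation(
    observation(1, capillary_refill_s = 3.5))$value, "major")
  # temperature bands: 36.0-37.5 is normal, 37.6-37.9 minor, >= 38 major
  expect_equal(grade_observation(observation(1, temp_c = 36.5))$value, "none")
  expect_equal(grade_observation(observation(1, temp_c = 37.7))$value,
               "minor")
  expect_equal(grade_observation(observation(1, temp_c = 35.8))$value,
               "minor")
  # tachycardia is minor under this framework
  expect_equal(grade_observation(observation(1, heart_rate_bpm = 175))$value,
               "minor")
  # absent vitals are never abnormal
  expect_equal(grade_observation(observation(1))$value, "none")
})

test_that("grading is a pure per-observation function", {
  obs <- observation(3, resp_rate_bpm = 72, temp_c = 37.8)
  g1 <- grade_observation(obs)
  g2 <- grade_observation(obs)
  expect_identical(g1, g2)
  expect_setequal(g1$findings, c("tachypnea_minor", "fever_minor"))
})

test_that("the examination schedule inserts 2-h re-evaluations for minor symptoms", {
  expect_equal(schedule_observations(make_record()),
               c(1, 3, 6, 12, 18, 24, 36, 48))
  # minor at 3 h resolved by 5 h: a 5-h re-evaluation is inserted
  tl <- make_timeline(observation(2.5, resp_rate_bpm = 66),
                      observation(4.8, resp_rate_bpm = 45))
  sched <- schedule_observations(make_record(timeline = tl))
  expect_true(5 %in% sched)
  expect_true(all(c(1, 3, 6, 12) %in% sched))
  expect_error(
    schedule_observations(make_record(),
                          sco_config(schedule_hours = numeric(0))),
    "non-empty")
})

test_that("asymptomatic infants with risk factors are never evaluated or treated", {
  rec <- make_record(gbs_status = "positive", iap_given = FALSE,
                     rom_hours = 30)
  d <- run_sco(rec)
  expect_false(d$evaluated)
  expect_false(d$antibiotics)
  expect_equal(d$triage, "rooming_in")
})

test_that("mild non-progressive symptoms resolve without evaluation", {
  tl <- make_timeline(observation(2, resp_rate_bpm = 66),
                      observation(4, resp_rate_bpm = 64),
                      observation(6, resp_rate_bpm = 48))
  d <- run_sco(make_record(timeline = tl))
  expect_true(d$symptomatic)
  expect_false(d$evaluated)
  expect_false(d$antibiotics)
})

test_that("major findings trigger immediate evaluation and treatment", {
  tl <- make_timeline(observation(1, temp_c = 37.0),
                      observation(3, temp_c = 38.5),
                      observation(5, temp_c = 37.6))
  d <- run_sco(make_record(timeline = tl))
  expect_true(d$evaluated)
  expect_equal(d$evaluation_time_hours, 3)
  expect_true(d$antibiotics)
  expect_equal(d$antibiotics_time_hours, 3)
  expect_equal(d$trigger, "major")
})

test_that("persistent minor symptoms escalate at the persistence threshold", {
  tl <- vital_run(0, 14, by = 1, resp_rate_bpm = 66)
  d <- run_sco(make_record(timeline = tl))
  expect_true(d$evaluated)
  expect_equal(d$evaluation_time_hours, 12)
  expect_equal(d$trigger, "persistence")
  expect_false(d$antibiotics)  # no major finding, major_only policy
  # a higher configured persistence delays evaluation
  d24 <- run_sco(make_record(timeline = tl),
                 sco_config(minor_persistence_hours = 24))
  expect_false(d24$evaluated)
})

test_that("worsening means more distinct minor findings than the previous exam", {
  tl <- make_timeline(observation(1, resp_rate_bpm = 66),
                      observation(3, resp_rate_bpm = 66,
                                  heart_rate_bpm = 170))
  d <- run_sco(make_record(timeline = tl))
  expect_true(d$evaluated)
  expect_equal(d$evaluation_time_hours, 3)
  expect_equal(d$trigger, "worsening")
})

test_that("triage follows support level and gestational age", {
  hfnc <- make_record(timeline = make_timeline(
    observation(4, respiratory_support = "HFNC", resp_rate_bpm = 70,
                increased_effort = TRUE)))
  expect_equal(run_sco(hfnc)$triage, "intermediate_care")
  ncpap <- make_record(timeline = make_timeline(
    observation(1, respiratory_support = "nCPAP")))
  expect_equal(run_sco(ncpap)$triage, "NICU")
  expect_equal(run_sco(make_record(ga = 39))$triage, "rooming_in")
  expect_equal(run_sco(make_record(ga = 34.5))$triage, "intermediate_care")
  seiz <- make_record(timeline = make_timeline(observation(2, seizure = TRUE)))
  expect_equal(run_sco(seiz)$triage, "NICU")
})

test_that("no-false-alarm and monotonicity invariants hold over random timelines", {
  set.seed(202)
  n_cases <- 1000
  for (i in seq_len(n_cases)) {
    k <- sample(1:6, 1)
    ages <- sort(round(runif(k, 0, 48), 2))
    ages <- unique(ages)
    normal <- do.call(rbind, lapply(ages, function(t)
      observation(t, heart_rate_bpm = round(runif(1, 100, 160)),
                  resp_rate_bpm = round(runif(1, 30, 60)),
                  temp_c = round(runif(1, 36.0, 37.5), 1),
                  spo2_pct = round(runif(1, 91, 100)))))
    rec <- make_record(ga = round(runif(1, 35, 42), 1), timeline = normal)
    d <- run_sco(rec)
    expect_false(d$evaluated)
    expect_false(d$antibiotics)
    expect_equal(d$triage, "rooming_in")
    # adding a major finding never prevents or delays evaluation
    t_major <- round(runif(1, 0, 48), 2)
    if (!t_major %in% ages) {
      tl2 <- rbind(normal, observation(t_major, temp_c = 38.6))
      tl2 <- tl2[order(tl2$age_hours), ]
      d2 <- run_sco(make_record(timeline = tl2))
      expect_true(d2$evaluated)
      expect_lte(d2$evaluation_time_hours, t_major)
      # under major_only, antibiotics imply a major finding exists
      expect_true(!d2$antibiotics ||
                    !is.na(d2$first_major_time))
    }
  }
})

test_that("persistence is invariant to subdividing symptomatic intervals", {
  coarse <- make_timeline(observation(0, resp_rate_bpm = 66),
                          observation(13, resp_rate_bpm = 66),
                          observation(14, resp_rate_bpm = 45))
  fine <- rbind(vital_run(0, 13, by = 1, resp_rate_bpm = 66),
                observation(14, resp_rate_bpm = 45))
  dc <- run_sco(make_record(timeline = coarse))
  df <- run_sco(make_record(timeline = fine))
  expect_equal(dc$evaluated, df$evaluated)
  expect_equal(dc$evaluation_time_hours, df$evaluation_time_hours)
})

test_that("treatment policies behave as configured", {
  tl <- vital_run(0, 14, by = 1, resp_rate_bpm = 66)
  rec <- make_record(timeline = tl)
  expect_false(run_sco(rec)$antibiotics)
  d_always <- run_sco(rec, sco_config(treat_policy = "always_on_eval"))
  expect_true(d_always$antibiotics)
  set.seed(9)
  d_prob <- run_sco(rec, sco_config(treat_policy = "probabilistic",
                                    treat_prob = 1))
  expect_true(d_prob$antibiotics)
})
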