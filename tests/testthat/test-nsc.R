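# Expected posteriors frozen from exact odds arithmetic:
# odds = (p/1000)/(1 - p/1000); posterior = 1000 * odds*LR / (1 + odds*LR).

test_that("the prior defaults to the baseline incidence and honours overrides", {
  cfg <- nsc_config()
  m <- maternal_profile(39)
  expect_equal(compute_prior(m, cfg), 0.6)
  expect_equal(compute_prior(m, cfg, override = 2.5), 2.5)
  expect_error(compute_prior(m, cfg, override = -1), "override")
})

test_that("configured covariate multipliers rescale the prior on the odds scale", {
  cfg <- nsc_config(prior_coefficients = c(iap_given = 2.0))
  m_no <- maternal_profile(39, iap_given = FALSE)
  m_yes <- maternal_profile(39, iap_given = TRUE, iap_adequate = TRUE)
  expect_equal(compute_prior(m_no, cfg), 0.6)
  # odds(0.0006) * 2 back-converted = 1.19928 per 1,000 (hand arithmetic)
  expect_equal(compute_prior(m_yes, cfg), 1.1992805, tolerance = 1e-6)
  # gbs_positive pseudo-covariate keys on gbs_status
  cfg2 <- nsc_config(prior_coefficients = c(gbs_positive = 3.0))
  expect_equal(compute_prior(maternal_profile(39, gbs_status = "positive"),
                             cfg2),
               1000 * 0.0006 / 0.9994 * 3 / (1 + 0.0006 / 0.9994 * 3),
               tolerance = 1e-10)
})

test_that("the likelihood-ratio update reproduces exact odds arithmetic", {
  cfg <- nsc_config()
  # LR = 1 is the identity at machine precision
  cfg1 <- nsc_config(lr_well = 1)
  e <- bayes_posterior(0.6, "well_appearing", cfg1)
  expect_equal(e$posterior_per_1000, 0.6, tolerance = 1e-12)

  e_well <- bayes_posterior(0.6, "well_appearing", cfg)
  expect_equal(e_well$posterior_per_1000, 0.2460871, tolerance = 1e-6)
  expect_equal(e_well$stratum, "low")

  e_eq <- bayes_posterior(0.6, "equivocal", cfg)
  expect_equal(e_eq$posterior_per_1000, 2.9928173, tolerance = 1e-6)
  expect_equal(e_eq$stratum, "high")

  e_ill <- bayes_posterior(0.6, "clinical_illness", cfg)
  expect_equal(e_ill$posterior_per_1000, 12.5676789, tolerance = 1e-6)
  expect_equal(e_ill$stratum, "high")

  expect_error(bayes_posterior(0.6, "odd_category", cfg), "unknown")
  expect_error(bayes_posterior(0, "equivocal", cfg), "prior")
})

test_that("risk strata are cut at 0.65 and 1.54 with inclusive middle bin", {
  cfg <- nsc_config()
  cuts <- function(p) eoscompare:::stratum_for(p, cfg$strata_cutoffs_per_1000)
  expect_equal(cuts(c(0.64, 0.65, 1.54, 1.55)),
               c("low", "middle", "middle", "high"))
})

test_that("presentation classification follows the temporal criteria", {
  cfg <- nsc_config()
  # perinatal depression: 5-min Apgar below 5
  expect_equal(classify_presentation(make_record(apgar = 4))$value,
               "clinical_illness")
  # persistent single abnormality > 4 h
  rr_run <- vital_run(0, 4.5, resp_rate_bpm = 70)
  expect_equal(classify_presentation(make_record(timeline = rr_run))$value,
               "equivocal")
  # exactly 4 h of abnormality is not persistent (> 4 h is strict)
  rr_4h <- vital_run(0, 4, resp_rate_bpm = 70)
  expect_equal(classify_presentation(make_record(timeline = rr_4h))$value,
               "well_appearing")
  # two abnormalities each > 2 h
  two <- vital_run(0, 2.5, by = 0.5, heart_rate_bpm = 170,
                   resp_rate_bpm = 65)
  expect_equal(classify_presentation(make_record(timeline = two))$value,
               "equivocal")
  # empty timeline, normal birth context
  expect_equal(classify_presentation(make_record())$value, "well_appearing")
  # persistent respiratory support outside the delivery room
  ncpap <- make_timeline(observation(1, respiratory_support = "nCPAP"))
  expect_equal(classify_presentation(make_record(timeline = ncpap))$value,
               "clinical_illness")
  # ... but not when support ceased before leaving the delivery room
  expect_equal(classify_presentation(
    make_record(timeline = ncpap, dr_support_only = TRUE))$value,
    "well_appearing")
  # supplemental O2 beyond 2 h cumulative
  o2 <- vital_run(0, 3, by = 1, respiratory_support = "supplemental_O2")
  expect_equal(classify_presentation(make_record(timeline = o2))$value,
               "clinical_illness")
  # abnormality starting after the 4-h scoring window does not count
  late_rr <- vital_run(5, 10, resp_rate_bpm = 70)
  expect_equal(classify_presentation(make_record(timeline = late_rr))$value,
               "well_appearing")
})

test_that("classification is invariant to subdividing an abnormal interval", {
  coarse <- make_timeline(observation(0, resp_rate_bpm = 70),
                          observation(4.5, resp_rate_bpm = 70))
  fine <- vital_run(0, 4.5, by = 0.25, resp_rate_bpm = 70)
  expect_equal(classify_presentation(make_record(timeline = coarse))$value,
               classify_presentation(make_record(timeline = fine))$value)
  # and accumulates over intermittent intervals (union semantics)
  intermittent <- make_timeline(
    observation(0, heart_rate_bpm = 170, resp_rate_bpm = 65),
    observation(1.5, heart_rate_bpm = 140, resp_rate_bpm = 50),
    observation(2.5, heart_rate_bpm = 170, resp_rate_bpm = 65),
    observation(4.0, heart_rate_bpm = 170, resp_rate_bpm = 65),
    observation(4.2, heart_rate_bpm = 140, resp_rate_bpm = 50))
  # each abnormality is held over [0,1.5] and [2.5,4.2]: 3.2 h > 2 h, twice
  expect_equal(
    classify_presentation(make_record(timeline = intermittent))$value,
    "equivocal")
})

test_that("the management decision table matches the five published categories", {
  cfg <- nsc_config()
  rec_of <- function(prior, category) {
    est <- bayes_posterior(prior, category, cfg)
    nsc_recommend(est, cfg)
  }
  r1 <- rec_of(0.6, "well_appearing")
  expect_equal(r1$value, "routine_vitals")
  expect_false(r1$implies_evaluation)
  expect_false(r1$implies_antibiotics)

  r2 <- rec_of(2.0, "well_appearing")  # posterior 0.82, prior > 1
  expect_equal(r2$value, "enhanced_vitals")

  r3 <- rec_of(5.0, "well_appearing")  # posterior 2.02 in [1, 3]
  expect_equal(r3$value, "culture_and_vitals")
  expect_true(r3$implies_evaluation)
  expect_false(r3$implies_antibiotics)

  r4 <- rec_of(0.6, "equivocal")  # posterior 2.99 <= 3, equivocal
  expect_equal(r4$value, "strongly_consider_antibiotics")
  expect_true(r4$implies_antibiotics)

  r5 <- rec_of(0.6, "clinical_illness")
  expect_equal(r5$value, "empiric_antibiotics")
  expect_true(r5$implies_antibiotics)
  # clinical illness forces antibiotics at any posterior
  cfg_low <- nsc_config(lr_clinical = 0.5)
  est <- bayes_posterior(0.6, "clinical_illness", cfg_low)
  expect_equal(nsc_recommend(est, cfg_low)$value, "empiric_antibiotics")
})

test_that("posterior is monotone in prior and LR, and matches naive scaling at low risk", {
  cfg <- nsc_config()
  priors <- c(0.05, 0.2, 0.6, 1, 2, 5, 10, 20)
  for (cat in c("well_appearing", "equivocal", "clinical_illness")) {
    post <- vapply(priors, function(p)
      bayes_posterior(p, cat, cfg)$posterior_per_1000, numeric(1))
    expect_true(all(diff(post) > 0))
  }
  lrs <- c(0.1, 0.41, 1, 2, 5, 21.2, 50)
  post_lr <- vapply(lrs, function(l)
    bayes_posterior(0.6, "well_appearing",
                    nsc_config(lr_well = l))$posterior_per_1000, numeric(1))
  expect_true(all(diff(post_lr) > 0))
  # odds-scale and naive multiplication agree within 3% relative for
  # posteriors in the clinically relevant range (<= 20 per 1,000)
  grid <- expand.grid(prior = priors, lr = lrs)
  for (i in seq_len(nrow(grid))) {
    p <- grid$prior[i]; l <- grid$lr[i]
    odds_post <- eoscompare:::posterior_from_prior(p, l, "odds")
    naive <- p * l
    if (naive <= 20)
      expect_lt(abs(odds_post - naive) / naive, 0.03)
  }
})

test_that("recommendation severity is non-decreasing in posterior", {
  cfg <- nsc_config()
  severity <- c(routine_vitals = 1, enhanced_vitals = 2,
                culture_and_vitals = 3, strongly_consider_antibiotics = 4,
                empiric_antibiotics = 5)
  for (cat in c("well_appearing", "equivocal")) {
    for (prior in c(0.6, 2, 8)) {
      posts <- seq(0.1, 10, by = 0.1)
      sev <- severity[eoscompare:::recommend_vec(prior, posts,
                                                 rep(cat, length(posts)),
                                                 cfg)]
      expect_true(all(diff(sev) >= 0))
    }
  }
})

test_that("run_nsc agrees with the per-record operations", {
  co <- generate_cohort(cohort_params(n = 300, seed = 5))
  cfg <- nsc_config()
  res <- run_nsc(co, cfg)
  for (id in sample(co$records$id, 40)) {
    r <- cohort_record(co, id)
    cat_i <- classify_presentation(r, cfg)
    est <- bayes_posterior(compute_prior(r, cfg,
                                         r$prior_override_per_1000),
                           cat_i, cfg)
    rec_i <- nsc_recommend(est, cfg)
    row <- res[res$id == id, ]
    expect_equal(row$category, cat_i$value)
    expect_equal(row$posterior_per_1000, est$posterior_per_1000)
    expect_equal(row$recommendation, rec_i$value)
  }
})
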