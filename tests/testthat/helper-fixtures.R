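# Shared fixture builders: records, timelines, and the published paired
# decision tables used across the comparison tests.

make_record <- function(id = "r1", ga = 39.5, apgar = 9,
                        timeline = empty_timeline(),
                        dr_support_only = FALSE, ...) {
  neonate_record(id, maternal_profile(ga, ...), apgar_5min = apgar,
                 delivery_room_support_only = dr_support_only,
                 timeline = timeline)
}

make_timeline <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# sustained single-vital timelines: one observation of the vital every
# `by` hours over [from, to]
vital_run <- function(from, to, by = 0.5, ...) {
  do.call(rbind, lapply(seq(from, to, by = by), function(t)
    observation(t, ...)))
}

# published whole-cohort and late-preterm paired decision tables
table_antibiotics_all <- function() paired_table(3254, 126, 5, 60)
table_evaluations_all <- function() paired_table(3231, 76, 20, 118)
table_antibiotics_lp <- function() paired_table(130, 33, 0, 15)
table_evaluations_lp <- function() paired_table(127, 18, 1, 32)

# a small fully-specified cohort exercising optional fields
small_mixed_cohort <- function() {
  r1 <- make_record("a1", ga = 39.2, gbs_status = "positive",
                    iap_given = TRUE, iap_adequate = TRUE, rom_hours = 20.5)
  r2 <- neonate_record("a2", maternal_profile(34.6, delivery_mode = "cesarean"),
                       apgar_5min = 7L,
                       timeline = make_timeline(
                         observation(1, resp_rate_bpm = 66),
                         observation(3, resp_rate_bpm = 52)),
                       prior_override_per_1000 = 2.5,
                       true_eos = FALSE)
  r3 <- make_record("a3", ga = 41.0,
                    timeline = make_timeline(
                      observation(0, temp_c = 38.4,
                                  respiratory_support = "nCPAP",
                                  increased_effort = TRUE,
                                  resp_rate_bpm = 74),
                      observation(2.5, temp_c = 37.4)))
  eos_cohort(list(r1, r2, r3))
}
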