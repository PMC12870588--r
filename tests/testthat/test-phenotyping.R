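test_that("episodes split on gaps above the 14-day allowance", {
  ep <- build_episodes(rx_table("s1", c(0, 10, 30)))
  expect_identical(nrow(ep), 2L)
  expect_equal(ep$start_date, c(0, 30))
  expect_equal(ep$end_date, c(10, 30))
  expect_equal(ep$n_prescriptions, c(2L, 1L))

  # boundary: a gap of exactly 14 days stays within the episode
  ep14 <- build_episodes(rx_table("s1", c(0, 14, 28)))
  expect_identical(nrow(ep14), 1L)
  expect_equal(ep14$end_date, 28)

  # single fill -> degenerate one-day episode
  ep1 <- build_episodes(rx_table("s1", 5))
  expect_equal(c(ep1$start_date, ep1$end_date), c(5, 5))

  # empty input is not an error
  expect_identical(nrow(build_episodes(rx_table("s1", integer(0)))), 0L)
})

test_that("every prescription belongs to exactly one covering episode", {
  set.seed(7)
  days <- sort(sample(0:400, 40))
  ep <- build_episodes(rx_table("s1", days))
  expect_equal(sum(ep$n_prescriptions), length(days))
  inside <- vapply(days, function(d) sum(d >= ep$start_date & d <= ep$end_date),
                   numeric(1))
  expect_true(all(inside == 1))
})

test_that("baseline selection applies the window and drug-free rules", {
  w <- window_config()
  m <- meas_table("s1", c(-900, -100, -60, 0), c(4, 4.1, 4.2, 4.3))
  # drug-naive subject, initiation at day 0
  sel <- select_baseline(m, integer(0), 0, w)
  expect_equal(sel$delta, c(100, 60))        # -900 too far, day 0 excluded
  # a same-disease fill 20 days before the -60 measurement knocks it out
  # (but not the earlier -100 measurement, which precedes the fill)
  sel2 <- select_baseline(m, -80, 0, w)
  expect_equal(sel2$delta, 100)
  # fill exactly 180 days before the measurement still violates drug-free
  sel3 <- select_baseline(meas_table("s1", -100, 4), -280, 0, w)
  expect_identical(nrow(sel3), 0L)
  sel4 <- select_baseline(meas_table("s1", -100, 4), -281, 0, w)
  expect_identical(nrow(sel4), 1L)
})

test_that("on-drug selection applies the 28-730 window, episode end and co-medication", {
  w <- window_config()
  ep <- list(start_date = 0, end_date = 300)
  m <- meas_table("s1", c(10, 20, 28, 100, 301, 500), 3 + 1:6 / 10)
  sel <- select_ondrug(m, ep, NULL, w)
  expect_equal(sel$delta, c(28, 100))        # <28 and past episode end excluded
  # concurrent same-disease episode of another class blanks its interval
  other <- data.frame(start_date = 90, end_date = 120)
  sel2 <- select_ondrug(m, ep, other, w)
  expect_equal(sel2$delta, 28)
})

test_that("weighted average favours measurements close to initiation", {
  expect_equal(weighted_average(4, 10, 730), 4)
  expect_equal(weighted_average(c(4, 3), c(100, 350), 730),
               (631 * 4 + 381 * 3) / 1012)
  expect_equal(weighted_average(c(4, 3), c(100, 350), 730), 3.6235, tolerance = 1e-4)
  expect_equal(weighted_average(c(4, 3), c(200, 200), 730), 3.5)  # plain mean
  expect_error(weighted_average(numeric(0), numeric(0), 730), "no eligible")
})

test_that("phenotype derivation composes the filters and counts survivors exactly", {
  # 5 subjects: s1/s2/s3 analyzable, s4 baseline too old, s5 on-drug too early
  rx <- rbind(rx_table("s1", seq(0, 200, 14)), rx_table("s2", seq(0, 200, 14)),
              rx_table("s3", seq(0, 200, 14)), rx_table("s4", seq(0, 200, 14)),
              rx_table("s5", seq(0, 200, 14)))
  m <- rbind(meas_table("s1", c(-100, 50), c(4, 3)),
             meas_table("s2", c(-350, 100), c(5, 4)),
             meas_table("s3", c(-60, 190), c(4.4, 3.2)),
             meas_table("s4", c(-800, 60), c(4, 3)),
             meas_table("s5", c(-90, 10), c(4, 3)))
  ph <- derive_response_phenotypes(rx, m, "C10AA")
  expect_identical(nrow(ph), 3L)
  expect_setequal(ph$subject_id, c("s1", "s2", "s3"))
  expect_true(all(ph$baseline > 0 & ph$ondrug > 0))
  expect_true(all(ph$n_baseline_meas >= 1 & ph$n_ondrug_meas >= 1))

  # all measurements pre-initiation -> empty
  ph0 <- derive_response_phenotypes(rx_table("s1", seq(0, 100, 14)),
                                    meas_table("s1", c(-30, -60), c(4, 4)), "C10AA")
  expect_identical(nrow(ph0), 0L)
})

test_that("derivation is invariant to row order and duplicate measurement rows", {
  rx <- rx_table("s1", seq(0, 200, 14))
  m <- meas_table("s1", c(-100, -40, 60, 120), c(4, 4.4, 3, 3.3))
  ph <- derive_response_phenotypes(rx, m, "C10AA")
  set.seed(5)
  ph_shuf <- derive_response_phenotypes(rx[sample(nrow(rx)), ],
                                        m[sample(nrow(m)), ], "C10AA")
  expect_equal(ph_shuf, ph)
  ph_dup <- derive_response_phenotypes(rx, rbind(m, m[2, ], m[3, ]), "C10AA")
  expect_equal(ph_dup, ph)
})

test_that("phenotyping the default synthetic cohort matches planted bookkeeping", {
  sim <- simulate_cohort(small_sim(seed = 3))
  ph <- derive_response_phenotypes(
    sim$records$prescriptions, sim$records$measurements, "C10AA",
    same_disease_classes = c("C10AA", "C10AX09"))
  planted <- sim$records$planted
  expect_identical(nrow(ph), sum(planted$eligible))
  expect_setequal(ph$subject_id, planted$subject_id[planted$eligible])
  expect_equal(ph$initiation_date,
               planted$initiation_date[match(ph$subject_id, planted$subject_id)])
})

test_that("disease status combines thresholds, units and diagnosis codes", {
  m <- data.frame(subject_id = c("a", "b", "c", "d"),
                  biomarker = c("LDLC", "HDLC", "SBP", "LDLC"),
                  value = c(5.2, 0.9, 165, 3.0))
  dy <- derive_disease_status(m, disease = "dyslipidemia", lipid_units = "mmol/L")
  expect_true(dy$diseased[dy$subject_id == "a"])   # 5.2 mmol/L ~ 201 mg/dL
  expect_true(dy$diseased[dy$subject_id == "b"])   # HDL 0.9 mmol/L ~ 34.8 mg/dL
  expect_false(dy$diseased[dy$subject_id == "d"])
  hy <- derive_disease_status(m, disease = "hypertension")
  expect_true(hy$diseased[hy$subject_id == "c"])   # SBP 165 >= 160
  expect_false(hy$diseased[hy$subject_id == "a"])
  # diagnosis alone is sufficient
  dg <- data.frame(subject_id = "d", code = "E78.0")
  dy2 <- derive_disease_status(m, dg, disease = "dyslipidemia")
  expect_true(dy2$diseased[dy2$subject_id == "d"])
  # mg/dL input interpreted without conversion
  m_mg <- data.frame(subject_id = "e", biomarker = "LDLC", value = 195)
  expect_true(derive_disease_status(m_mg, disease = "dyslipidemia",
                                    lipid_units = "mg/dL")$diseased)
  expect_error(derive_disease_status(m, disease = "dyslipidemia",
                                     lipid_units = "mol/gallon"))
})

test_that("choice labels restrict to diseased subjects", {
  st <- data.frame(subject_id = c("a", "b", "c", "d"),
                   diseased = c(TRUE, TRUE, FALSE, TRUE))
  lab <- derive_choice_labels(st, users = c("a", "c"))
  expect_setequal(lab$subject_id, c("a", "b", "d"))  # healthy user c excluded
  expect_identical(lab$choice[lab$subject_id == "a"], 1L)
  expect_identical(lab$choice[lab$subject_id == "b"], 0L)
})
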