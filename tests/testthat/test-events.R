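grec <- function(time, grade, pid = "P1", analyte = "BIL") {
  data.frame(patient_id = pid, time_months = time, analyte = analyte,
             grade = grade, stringsAsFactors = FALSE)
}

test_that("reference grade takes the latest pre-treatment test in window", {
  d <- 30.4375
  pre <- grec(c(-10, -3) / d, c(2, 1))
  expect_equal(reference_grade(pre), 1L)            # latest within a week
  # exactly day -7 is outside the open week window, caught by the fallback
  pre7 <- grec(-7 / d, 3)
  expect_equal(reference_grade(pre7), 3L)
  expect_equal(reference_grade(pre7, fallback_months = NULL), NA_integer_)
  # nothing within the prior month
  expect_equal(reference_grade(grec(-2, 2)), NA_integer_)
  expect_equal(reference_grade(data.frame(time_months = numeric(0),
                                          grade = integer(0))), NA_integer_)
})

test_that("upgrade events follow the hand-traced comparator rule", {
  s <- grec(1:5, c(1, 1, 2, 0, 3))
  ev <- derive_individual_events(s, reference = 1L, analyte = "BIL")
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$time_months, c(3, 5))
  expect_equal(ev$prev_grade, c(1L, 0L))
  expect_equal(ev$new_grade, c(2L, 3L))
  expect_equal(ev$delta, c(1L, 3L))
  expect_equal(ev$magnitude, c("one_grade", "gt_one_grade"))
  # monotone non-increasing grades produce no events
  expect_equal(nrow(derive_individual_events(grec(1:4, c(3, 2, 2, 0)), 3L)), 0L)
  # a single visit jumping reference 0 -> 2 is one event of delta 2
  ev2 <- derive_individual_events(grec(1, 2), 0L)
  expect_equal(ev2$delta, 2L)
  expect_equal(ev2$magnitude, "gt_one_grade")
  # missing reference: first visit initializes without event eligibility
  ev3 <- derive_individual_events(grec(1:2, c(2, 3)), NA)
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$time_months, 2)
  expect_error(derive_individual_events(grec(c(2, 1), c(0, 1)), 0L), "sorted")
})

test_that("event derivation is deterministic and yields only upgrades", {
  s1 <- grec(1:6, c(1, 2, 1, 2, 0, 1))
  ev_a <- derive_individual_events(s1, 1L)
  ev_b <- derive_individual_events(s1, 1L)
  expect_identical(ev_a, ev_b)
  # every fluctuation upward against the running comparator is an event,
  # downgrades never are
  expect_equal(ev_a$time_months, c(2, 4, 6))
  expect_true(all(ev_a$delta >= 1))
  expect_true(all(ev_a$new_grade > ev_a$prev_grade))
})

test_that("synchrony is flagged per patient and calendar day", {
  d <- 30.4375
  ev <- rbind(
    grec(30 / d, 1, analyte = "BIL"), grec(30 / d, 1, analyte = "ALT"),
    grec(31 / d, 1, analyte = "AST"), grec(60 / d, 1, analyte = "INR"))
  names(ev)[4] <- "grade"
  events <- data.frame(patient_id = ev$patient_id,
                       time_months = ev$time_months, scope = ev$analyte,
                       prev_grade = 0L, new_grade = 1L, delta = 1L,
                       synchronous = NA, magnitude = "one_grade",
                       stringsAsFactors = FALSE)
  out <- classify_synchrony(events)
  expect_equal(out$synchronous, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("combined events aggregate same-day member events", {
  day <- 30 / 30.4375
  mk <- function(scope, t, delta) data.frame(
    patient_id = "P1", time_months = t, scope = scope, prev_grade = 0L,
    new_grade = delta, delta = as.integer(delta), synchronous = NA,
    magnitude = ifelse(delta > 1, "gt_one_grade", "one_grade"),
    stringsAsFactors = FALSE)
  ev <- rbind(mk("BIL", day, 1), mk("AST", day, 1))
  comb <- derive_combined_events(ev)
  expect_equal(nrow(comb), 1L)
  expect_true(comb$synchronous)
  expect_equal(comb$delta, 2L)
  expect_equal(comb$magnitude, "gt_one_grade")
  # max rule alternative
  combmax <- derive_combined_events(ev, combine_rule = "max")
  expect_equal(combmax$delta, 1L)
  expect_equal(combmax$magnitude, "one_grade")
  # a lone ALB event maps to a single one-grade composite event
  lone <- derive_combined_events(mk("ALB", day, 1))
  expect_false(lone$synchronous)
  expect_equal(lone$magnitude, "one_grade")
  # member filter: non-member events yield nothing
  expect_equal(nrow(derive_combined_events(mk("ALB", day, 1),
                                           composite_definition("ALL3"))), 0L)
  expect_equal(nrow(derive_combined_events(mk("BIL", day, 1)[0, ])), 0L)
})

test_that("composite events never outnumber their member events", {
  sp <- cohort_spec(n_patients = 25, seed = 5, max_months = 12)
  cv <- simulate_covariates(sp)
  labs <- simulate_lab_trajectories(sp, cv)$labs
  g <- grade_series(labs)
  ind <- derive_events(g)
  comb <- derive_combined_events(ind)
  expect_lte(nrow(comb), nrow(ind))
  expect_true(all(comb$time_months > 0))
  # single + synchronous = total within every scope
  summ <- summarize_events(rbind(ind, comb))
  expect_equal(summ$single + summ$synchronous, summ$total)
  expect_equal(summ$one_grade + summ$gt_one_grade, summ$total)
})

test_that("person-months run to the last visit carrying the scope's test", {
  v <- rbind(grec(c(1, 12.3), c(0, 0), analyte = "BIL"),
             grec(c(1, 9), c(0, 0), analyte = "ALB"),
             grec(-0.2, 0, analyte = "BIL"))
  fu_bil <- person_months(v, "BIL")
  expect_equal(fu_bil$person_months, 12.3)
  fu_alb <- person_months(v, "ALB")
  expect_equal(fu_alb$person_months, 9)      # censor dates differ per scope
  fu_all <- person_months(v, composite_definition("ALL6"))
  expect_equal(fu_all$person_months, 12.3)
  none <- person_months(v, "INR", patients = "P1")
  expect_equal(none$person_months, 0)
  expect_false(none$observed)
})

test_that("incidence rates divide events by stratum person-months", {
  fu <- data.frame(patient_id = c("A", "B"), censor_time = c(4, 3),
                   person_months = c(4, 3), observed = TRUE)
  ev <- data.frame(patient_id = "A", time_months = 2)
  strata <- data.frame(patient_id = c("A", "B"), stratum = c("s1", "s2"))
  ir <- incidence_rates(ev, fu, strata)
  expect_equal(ir$rate[ir$stratum == "s1"], 0.25)
  expect_equal(ir$rate[ir$stratum == "s2"], 0)
  # zero person-months stratum is undefined, not zero
  fu0 <- rbind(fu, data.frame(patient_id = "C", censor_time = 0,
                              person_months = 0, observed = FALSE))
  strata0 <- rbind(strata, data.frame(patient_id = "C", stratum = "s3"))
  ir0 <- incidence_rates(ev, fu0, strata0)
  expect_true(is.na(ir0$rate[ir0$stratum == "s3"]))
})
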