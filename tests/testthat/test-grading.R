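test_that("default scales reproduce the printed cutoff ladders", {
  sc <- default_scales()
  expect_equal(sc$BIL$cutoffs, c(1.5, 2.25, 4.5, 15))
  expect_equal(sc$AST$cutoffs, c(35, 105, 175, 700))
  expect_equal(sc$ALT$cutoffs, c(35, 105, 175, 700))
  expect_equal(sc$ALKP$cutoffs, c(120, 300, 600, 2400))
  expect_equal(sc$INR$cutoffs, c(1.2, 1.5, 2.5))
  expect_equal(sc$ALB$cutoffs, c(3.5, 3, 2))
  expect_equal(sc$ALB$direction, "low_is_worse")
  expect_equal(vapply(sc, `[[`, 1, "max_grade"),
               c(BIL = 4, AST = 4, ALT = 4, ALKP = 4, INR = 3, ALB = 3))
})

test_that("grading follows the printed interval semantics, boundaries included", {
  sc <- default_scales()
  expect_equal(grade_value(sc$BIL, 3.0), 2L)
  expect_equal(grade_value(sc$BIL, 1.5), 0L)   # <= 1.5 is grade 0
  expect_equal(grade_value(sc$BIL, 2.25), 1L)  # > 1.5 - 2.25 is grade 1
  expect_equal(grade_value(sc$BIL, 16), 4L)
  expect_equal(grade_value(sc$AST, 150), 2L)
  expect_equal(grade_value(sc$ALT, 40), 1L)
  expect_equal(grade_value(sc$ALKP, 1000), 3L)
  expect_equal(grade_value(sc$INR, 1.35), 1L)
  expect_equal(grade_value(sc$INR, 5.0), 3L)
  # albumin: low is worse, >= on the grade-0 side, half-open bands
  expect_equal(grade_value(sc$ALB, 3.5), 0L)
  expect_equal(grade_value(sc$ALB, 3.0), 1L)   # [3, 3.5) is grade 1
  expect_equal(grade_value(sc$ALB, 2.5), 2L)
  expect_equal(grade_value(sc$ALB, 1.9), 3L)
  expect_error(grade_value(sc$BIL, -1), "BIL")
  expect_error(grade_value(sc$AST, NaN), "AST")
})

test_that("cutoff scaling multiplies elementwise and preserves monotonicity", {
  sc <- default_scales()
  expect_equal(scale_cutoffs(sc$BIL, 1.0)$cutoffs, sc$BIL$cutoffs)
  expect_equal(scale_cutoffs(sc$BIL, 0.7)$cutoffs[1], 1.05)
  alb13 <- scale_cutoffs(sc$ALB, 1.3)
  expect_equal(alb13$cutoffs, c(4.55, 3.9, 2.6))
  expect_true(all(diff(alb13$cutoffs) < 0))
  expect_equal(alb13$scale_factor, 1.3)
  expect_error(scale_cutoffs(sc$BIL, 0), "positive")
  expect_error(scale_cutoffs(sc$BIL, -0.5), "positive")
})

test_that("grading is monotone in value for every sensitivity factor", {
  for (f in seq(0.7, 1.3, by = 0.1)) {
    sc <- default_scales(f)
    v <- sort(exp(seq(log(0.05), log(5000), length.out = 300)))
    for (a in c("BIL", "AST", "ALKP", "INR")) {
      g <- grade_value(sc[[a]], v)
      expect_true(all(diff(g) >= 0), info = paste(a, f))
    }
    galb <- grade_value(sc$ALB, sort(runif(200, 0.5, 6)))
    expect_true(all(diff(galb) <= 0), info = paste("ALB", f))
  }
})

test_that("values sampled inside a grade band regrade to that band", {
  set.seed(11)
  sc <- default_scales()
  for (a in names(sc)) {
    g <- rep(0:sc[[a]]$max_grade, each = 40)
    v <- sample_in_band(sc[[a]], g)
    expect_equal(grade_value(sc[[a]], v), as.integer(g), info = a)
  }
})

test_that("composite scores sum member grades and respect missingness", {
  g <- c(BIL = 2, AST = 2, ALT = 1, ALKP = 3, INR = 1, ALB = 2)
  # the panel graded from 3.0 mg/dL, 150 IU/L, 40 IU/L, 1000 IU/L, 1.35, 2.5 g/dL
  sc <- default_scales()
  graded <- c(BIL = grade_value(sc$BIL, 3.0), AST = grade_value(sc$AST, 150),
              ALT = grade_value(sc$ALT, 40), ALKP = grade_value(sc$ALKP, 1000),
              INR = grade_value(sc$INR, 1.35), ALB = grade_value(sc$ALB, 2.5))
  expect_equal(unname(graded), unname(g))
  expect_equal(as.integer(composite_score(g, composite_definition("ALL6"))), 11L)
  expect_equal(as.integer(composite_score(g, composite_definition("ALL3"))), 5L)
  zero <- setNames(rep(0, 6), names(g))
  expect_equal(as.integer(composite_score(zero)), 0L)
  # additivity: ALL6 = ALL3 + the ALKP/INR/ALB remainder
  rest <- sum(g[c("ALKP", "INR", "ALB")])
  expect_equal(as.integer(composite_score(g)),
               as.integer(composite_score(g, composite_definition("ALL3"))) +
                 as.integer(rest))
  # missing member
  gm <- g; gm["INR"] <- NA
  expect_true(is.na(composite_score(gm, composite_definition("ALL6"))))
  s <- composite_score(gm, composite_definition("ALL6", "sum_available"))
  expect_equal(as.integer(s), 10L)
  expect_false(attr(s, "complete"))
  expect_error(composite_score(c(g[-1], BIL = 9)), "range")
})

test_that("grade_series collapses same-day duplicates to the worst grade", {
  labs <- data.frame(
    patient_id = "P1",
    time_months = c(2.00, 2.01, 5, -0.1),   # two BIL tests on day 60/61?
    analyte = "BIL", value = c(2.0, 3.0, 1.0, 2.0))
  # force the first two onto the same day
  labs$time_months[2] <- labs$time_months[1] + 0.01 / 30.4375
  g <- grade_series(labs)
  same_day <- g[g$time_months > 1 & g$time_months < 3, ]
  expect_equal(nrow(same_day), 1L)
  expect_equal(same_day$grade, 2L)           # worst of grades 1 and 2
  expect_true(any(g$time_months < 0))        # pre-treatment passes through
  expect_equal(nrow(grade_series(labs[0, ])), 0L)
  expect_error(grade_series(data.frame(patient_id = "P", time_months = 1,
                                       analyte = "GGT", value = 1)),
               "unknown analyte")
  labs$unit <- "mg/L"
  expect_error(grade_series(labs), "unit mismatch")
})
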