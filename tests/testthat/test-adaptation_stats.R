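test_that("measurement table rejects malformed input", {
  tab <- toy_table(list(control.baseline = c(58, 59, 60),
                        hyperglycemia.baseline = c(58, 59, 60)))
  expect_s3_class(tab, "measurement_table")
  expect_error(measurement_table(rbind(tab, tab[1, ])), "duplicate")
  bad <- tab; bad$condition[1] <- "fasting"
  expect_error(measurement_table(bad), "condition")
  expect_error(measurement_table(tab[, -6]), "missing columns")
})

test_that("paired differences implement glucose - control on change-from-baseline", {
  tab <- toy_table(list(
    control.baseline = c(58, 59, 60), control.dark = c(57, 58, 59),
    hyperglycemia.baseline = c(58.5, 59.5, 60.5),
    hyperglycemia.dark = c(57.0, 58.0, 59.0)))
  # control change: -1 each; glucose change: -1.5 each; difference -0.5
  d <- paired_differences(tab, "dark", "0-6", "CVI")
  expect_equal(d$diff, rep(-0.5, 3))
  # at baseline the difference is the raw between-condition difference
  d0 <- paired_differences(tab, "baseline", "0-6", "CVI")
  expect_equal(d0$diff, rep(0.5, 3))
  # identical conditions give zero differences
  tab2 <- toy_table(list(control.baseline = c(1, 2, 3),
                         hyperglycemia.baseline = c(1, 2, 3)))
  expect_equal(paired_differences(tab2, "baseline", "0-6", "CVI")$diff, rep(0, 3))
})

test_that("subjects with incomplete sessions are dropped, few pairs error out", {
  tab <- toy_table(list(
    control.baseline = c(58, 59, 60), control.dark = c(57, 58, 59),
    hyperglycemia.baseline = c(58, 59, 60),
    hyperglycemia.dark = c(57, 58, 59)))
  tab_m <- measurement_table(tab[!(tab$subject_id == "S3" &
                                     tab$condition == "control" &
                                     tab$timepoint == "dark"), ])
  expect_warning(d <- paired_differences(tab_m, "dark", "0-6", "CVI"), "dropped")
  expect_equal(nrow(d), 2)
  tab1 <- toy_table(list(control.baseline = c(1, 2),
                         hyperglycemia.baseline = c(1, 2)))
  tab1 <- measurement_table(tab1[tab1$subject_id == "S1" |
                                   tab1$condition == "control", ])
  expect_warning(expect_error(paired_differences(tab1, "baseline", "0-6", "CVI"),
                              "fewer than 2"))
})

test_that("with no covariates the adjusted difference is exactly the paired t-test", {
  set.seed(8)
  d <- data.frame(diff = rnorm(24, 0.3, 1))
  fit <- adjusted_mean_difference(d, character(0))
  tt <- stats::t.test(d$diff)
  expect_equal(fit$estimate, unname(tt$estimate))
  expect_equal(fit$statistic, unname(tt$statistic))
  expect_equal(fit$df, unname(tt$parameter))
  expect_equal(fit$p_value, tt$p.value)
})

test_that("covariate adjustment recovers a built-in effect and handles degenerate design", {
  set.seed(99)
  reps <- 100; delta <- 0.5; n <- 24
  ests <- ses <- numeric(reps)
  for (r in seq_len(reps)) {
    al <- rnorm(n, 25.5, 1.2)
    d <- data.frame(diff = delta + 0.4 * (al - mean(al)) + rnorm(n, 0, 0.4),
                    axial_length_mm = al, age_years = rnorm(n, 25, 2))
    fit <- adjusted_mean_difference(d)
    ests[r] <- fit$estimate; ses[r] <- fit$se
  }
  expect_lt(abs(mean(ests) - delta), 2 * mean(ses) / sqrt(reps) * 3)
  # constant covariate falls back to the unadjusted analysis with a warning
  d <- data.frame(diff = rnorm(10), axial_length_mm = 24, age_years = 25)
  expect_warning(fit <- adjusted_mean_difference(d), "collinear")
  expect_equal(fit$df, 9)
  # zero-variance differences: exact estimate, degenerate p
  dz <- data.frame(diff = rep(0.7, 6))
  fz <- adjusted_mean_difference(dz, character(0))
  expect_equal(fz$estimate, 0.7)
  expect_equal(fz$se, 0)
  expect_equal(fz$p_value, 0)
})

test_that("within-condition change reduces to the paired t-test and handles identity", {
  tab <- toy_table(list(control.baseline = c(58, 59, 60, 61),
                        control.dark = c(57.2, 58.1, 59.4, 60.0),
                        hyperglycemia.baseline = c(58, 59, 60, 61),
                        hyperglycemia.dark = c(58, 59, 60, 61)))
  w <- within_condition_change(tab, "control", "baseline", "dark", "0-6", "CVI")
  tt <- stats::t.test(c(57.2, 58.1, 59.4, 60.0) - c(58, 59, 60, 61))
  expect_equal(w$estimate, unname(tt$estimate))
  expect_equal(w$p_value, tt$p.value)
  # to == from: identical pairs, p = 1 by convention
  w0 <- within_condition_change(tab, "control", "baseline", "baseline", "0-6", "CVI")
  expect_equal(w0$estimate, 0)
  expect_equal(w0$p_value, 1)
})

test_that("the report grid detects a built-in dark CVI effect and stays empty on empty input", {
  tab <- simulate_cohort(n_subjects = 24, effects = list(CVI = c(dark = -0.36)),
                         seed = 5)
  rep <- build_report(tab)
  cell <- rep[rep$parameter == "CVI" & rep$timepoint == "dark", ]
  expect_lt(cell$p_value, 0.05)
  expect_lt(cell$mean_diff, 0)
  expect_match(cell$label, "\\*$")
  expect_equal(nrow(rep), 4 * 4)  # 4 parameters x 4 post-baseline timepoints
  empty <- build_report(measurement_table(tab[0, ]))
  expect_equal(nrow(empty), 0)
  # Holm correction is available and never stars more cells
  rep_h <- build_report(tab, p_adjust = "holm")
  expect_lte(sum(rep_h$significant), sum(rep$significant))
})

test_that("cohort simulator is deterministic and carries its design", {
  a <- simulate_cohort(n_subjects = 6, seed = 2)
  b <- simulate_cohort(n_subjects = 6, seed = 2)
  expect_identical(a, b)
  expect_equal(nrow(a), 6 * 2 * 5 * 4)
  expect_equal(sort(unique(a$timepoint)), sort(cq_timepoints()))
})
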