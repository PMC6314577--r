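# Synthetic-cohort generator: inversion, determinism, calibration structure.

test_that("invert_to_psv_edv solves the linear system and rejects infeasible PI", {
  v <- invert_to_psv_edv(60, 0.75)
  expect_equal(v$psv, 90)
  expect_equal(v$edv, 45)
  v0 <- invert_to_psv_edv(50, 0)
  expect_equal(v0$psv, 50)
  expect_equal(v0$edv, 50)
  expect_error(invert_to_psv_edv(50, 3),
               class = "mcasym_infeasible_inversion_error")
  expect_error(invert_to_psv_edv(0, 1), class = "mcasym_validation_error")
})

test_that("round-trip through compute_mv/compute_pi is the identity to 1e-9", {
  set.seed(51)
  mv <- runif(2000, 5, 150)
  pi <- runif(2000, 0, 2.99)
  v <- invert_to_psv_edv(mv, pi)
  expect_equal(compute_mv(v$psv, v$edv), mv, tolerance = 1e-9)
  expect_equal(compute_pi(v$psv, v$edv), pi, tolerance = 1e-9)
})

test_that("default_params carries the documented cohort calibration", {
  p <- default_params()
  expect_identical(p$n_total, 377L)
  expect_equal(p$poor_fraction, 52 / 377)
  # log-normal parameters reproduce the quartile targets analytically
  expect_equal(exp(p$tcd$meanlog), p$tcd$median)
  q75 <- exp(p$tcd$meanlog + qnorm(0.75) * p$tcd$sdlog)
  q25 <- exp(p$tcd$meanlog - qnorm(0.75) * p$tcd$sdlog)
  expect_equal(q75 / q25, p$tcd$q75 / p$tcd$q25, tolerance = 1e-12)
  good_rm1 <- p$tcd[p$tcd$param == "mv" & p$tcd$group == "good" &
                      p$tcd$side == "R" & p$tcd$segment == "M1", ]
  expect_equal(good_rm1$median, 56.0)
  expect_error(cohort_params(poor_fraction = 1.4))
})

test_that("same seed gives byte-identical cohorts, different seeds differ", {
  p <- cohort_params(n_total = 60)
  c1 <- generate_cohort(p, seed = 99)
  c2 <- generate_cohort(p, seed = 99)
  expect_identical(c1$patients, c2$patients)
  expect_identical(c1$samples, c2$samples)
  c3 <- generate_cohort(p, seed = 100)
  expect_false(identical(c1$samples, c3$samples))
})

test_that("perfect between-side correlation collapses asymmetry toward zero", {
  p <- cohort_params(n_total = 250,
                     rho_side = list(mv = c(good = 1 - 1e-9, poor = 1 - 1e-9),
                                     pi = c(good = 1 - 1e-9, poor = 1 - 1e-9)))
  # also need equal left/right marginal parameters for exact symmetry
  tcd <- p$tcd
  for (pa in c("mv", "pi")) {
    for (g in c("good", "poor")) {
      for (sg in c("M1", "M2")) {
        i_r <- which(tcd$param == pa & tcd$group == g & tcd$side == "R" &
                       tcd$segment == sg)
        i_l <- which(tcd$param == pa & tcd$group == g & tcd$side == "L" &
                       tcd$segment == sg)
        tcd[i_l, c("meanlog", "sdlog")] <- tcd[i_r, c("meanlog", "sdlog")]
      }
    }
  }
  p$tcd <- tcd
  coh <- generate_cohort(p, seed = 52)
  prof <- patient_profiles(coh$samples)
  asym <- prof$idx_asym_overall[!is.na(prof$idx_asym_overall)]
  # velocities are rounded to 0.1 cm/s on output, so near-zero not exact zero
  expect_lt(stats::median(asym), 0.5)
})

test_that("poor group has higher overall MCA asymmetry at large n (group_first)", {
  coh <- generate_cohort(cohort_params(n_total = 4000), seed = 53)
  af <- build_analysis_frame(coh)
  med <- tapply(af$idx_asym_overall, af$poor, median, na.rm = TRUE)
  expect_gt(med[["TRUE"]], med[["FALSE"]])
})

test_that("generator marginal medians track the calibration targets (scaled-down check)", {
  # full 5% criterion at n = 1e5 runs in the acceptance suite; this is a
  # quick 10% guard at n = 2e4
  p <- cohort_params(n_total = 20000)
  coh <- generate_cohort(p, seed = 54)
  s <- coh$samples
  s$segment <- segment_from_depth(s$depth_mm)
  s$mv <- compute_mv(s$psv_cms, s$edv_cms)
  poor <- dichotomize_outcome(coh$patients$mrs_3mo)
  s$group <- ifelse(poor[s$patient_id], "poor", "good")
  med <- aggregate(mv ~ group + side + segment, s, median)
  targets <- p$tcd[p$tcd$param == "mv", ]
  m <- merge(med, targets, by.x = c("group", "side", "segment"),
             by.y = c("group", "side", "segment"))
  expect_true(all(abs(m$mv / m$median - 1) < 0.10))
})

test_that("logistic mode plants a recoverable positive asymmetry effect", {
  p <- cohort_params(n_total = 2000, mode = "logistic")
  reps <- 25  # the full 100-replicate check runs in the acceptance suite
  pos <- 0
  for (r in seq_len(reps)) {
    coh <- generate_cohort(p, seed = 5400 + r)
    af <- build_analysis_frame(coh)
    af <- af[af$complete & !is.na(af$idx_asym_overall), ]
    fit <- fit_logistic(af$poor,
                        af[, c("idx_asym_overall", adjustment_covariates())])
    pos <- pos + (fit$coefficients[["idx_asym_overall"]] > 0)
  }
  expect_gte(pos, ceiling(0.95 * reps))
})

test_that("generated cohorts pass their own validators and poor fraction is calibrated", {
  p <- cohort_params(n_total = 5000, mode = "logistic")
  coh <- generate_cohort(p, seed = 55)
  expect_silent(validate_samples(coh$samples))
  poor <- dichotomize_outcome(coh$patients$mrs_3mo)
  expect_equal(mean(poor), 52 / 377, tolerance = 0.25)
  expect_identical(nrow(coh$samples), 4L * nrow(coh$patients))
  expect_lt(coh$meta$invalid_index_rate, 0.10)
})

test_that("two-rater mode duplicates samples and yields high MV ICC", {
  coh <- generate_cohort(cohort_params(n_total = 120, two_raters = TRUE),
                         seed = 56)
  expect_identical(nrow(coh$samples), 8L * 120L)
  s <- coh$samples
  s$segment <- segment_from_depth(s$depth_mm)
  s$mv <- compute_mv(s$psv_cms, s$edv_cms)
  cell <- s[s$side == "R" & s$segment == "M1", ]
  wide <- merge(cell[cell$rater == "A", c("patient_id", "mv")],
                cell[cell$rater == "B", c("patient_id", "mv")],
                by = "patient_id")
  r <- icc(as.matrix(wide[, -1]))
  expect_gt(r$icc, 0.9)
  expect_lt(r$p_value, 0.001)
})
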