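# Seeded synthetic cryptogenic-stroke cohort generator.
#
# The generator is a stated world: log-normal MV and PI per group, side and
# segment whose marginal medians/IQRs are the published two-group summary
# values; between-side log-scale correlation is lower in the poor-outcome
# group, which is what raises its asymmetry indices (no systematic side
# dominance is simulated). Within a side, M1 and M2 share a patient-level
# random effect (correlation 0.7). Covariates follow the published group
# summaries. See the package vignette for every derivation.

# calibration targets: printed group medians and quartiles ------------------
tcd_calibration <- function() {
  g <- expand.grid(group = c("good", "poor"), side = c("R", "L"),
                   segment = c("M1", "M2"), stringsAsFactors = FALSE)
  key <- paste(g$group, g$side, g$segment)
  mv <- list(
    "good R M1" = c(56.0, 46.0, 69.0), "good L M1" = c(57.0, 47.0, 74.0),
    "good R M2" = c(54.0, 43.0, 69.0), "good L M2" = c(56.0, 46.0, 70.0),
    "poor R M1" = c(52.5, 42.0, 63.3), "poor L M1" = c(55.0, 41.0, 70.0),
    "poor R M2" = c(55.0, 40.3, 70.5), "poor L M2" = c(57.0, 43.5, 69.0))
  pi_ <- list(
    "good R M1" = c(0.87, 0.76, 1.00), "good L M1" = c(0.85, 0.73, 1.00),
    "good R M2" = c(0.84, 0.73, 1.00), "good L M2" = c(0.84, 0.71, 1.00),
    "poor R M1" = c(0.91, 0.77, 1.00), "poor L M1" = c(0.89, 0.76, 1.00),
    "poor R M2" = c(0.90, 0.78, 1.10), "poor L M2" = c(0.88, 0.62, 1.08))
  mk <- function(lst, param) {
    m <- do.call(rbind, lst[key])
    data.frame(param = param, g, median = m[, 1], q25 = m[, 2], q75 = m[, 3],
               row.names = NULL)
  }
  rbind(mk(mv, "mv"), mk(pi_, "pi"))
}

# log-normal parameters matching a (median, q25, q75) target:
# meanlog = log(median), sdlog = log(q75/q25) / (2 * qnorm(0.75))
lognormal_from_quartiles <- function(median, q25, q75) {
  list(meanlog = log(median), sdlog = log(q75 / q25) / (2 * qnorm(0.75)))
}

#' Default synthetic-cohort parameters
#'
#' The documented calibration: 377 patients with poor fraction 52/377;
#' log-normal MV and PI per group/side/segment with `meanlog = log(median)`
#' and `sdlog = log(q75/q25) / 1.349` from the published group quartiles;
#' between-side log-scale correlations 0.72/0.59 (MV, good/poor) and
#' 0.77/0.71 (PI), derived once from the published asymmetry-index medians;
#' within-side M1-M2 correlation 0.7; covariate distributions from the
#' published group summaries; planted logistic effects equal to the published
#' univariable odds ratios.
#'
#' @return A `cohort_params` list; see [cohort_params()] for the fields.
#' @examples
#' default_params()$n_total  # 377
#' @export
default_params <- function() {
  calib <- tcd_calibration()
  ln <- lognormal_from_quartiles(calib$median, calib$q25, calib$q75)
  calib$meanlog <- ln$meanlog
  calib$sdlog <- ln$sdlog
  structure(list(
    schema_version = 1L,
    n_total = 377L,
    poor_fraction = 52 / 377,
    mode = "group_first",           # or "logistic"
    seed = NULL,
    tcd = calib,
    rho_side = list(mv = c(good = 0.72, poor = 0.59),
                    pi = c(good = 0.77, poor = 0.71)),
    rho_segment = 0.7,
    covariates = list(
      good = list(age_mean = 61.24, age_sd = 12.19, male_frac = 243 / 325,
                  nihss_meanlog = log(2), nihss_sdlog = log(4 / 1) / 1.349,
                  hgb_mean = 14.5, hgb_sd = (15.5 - 13.3) / 1.349,
                  esr_meanlog = log(13), esr_sdlog = log(26 / 7) / 1.349,
                  ddimer_meanlog = log(129), ddimer_sdlog = log(271.3 / 75) / 1.349,
                  ttcd_meanlog = log(3), ttcd_sdlog = log(4 / 2) / 1.349,
                  htn = 242 / 325, dm = 95 / 325, chol = 51 / 325,
                  smoker = 110 / 325, cad = 57 / 325, pad = 7 / 325,
                  mrs_probs = c(`0` = 0.40, `1` = 0.35, `2` = 0.25)),
      poor = list(age_mean = 67.46, age_sd = 11.83, male_frac = 32 / 52,
                  nihss_meanlog = log(8), nihss_sdlog = log(15 / 4) / 1.349,
                  hgb_mean = 13.6, hgb_sd = (14.9 - 11.7) / 1.349,
                  esr_meanlog = log(20.5), esr_sdlog = log(39.3 / 8) / 1.349,
                  ddimer_meanlog = log(298.5), ddimer_sdlog = log(1206.8 / 127.8) / 1.349,
                  ttcd_meanlog = log(4), ttcd_sdlog = log(6 / 3) / 1.349,
                  htn = 34 / 52, dm = 13 / 52, chol = 11 / 52,
                  smoker = 13 / 52, cad = 9 / 52, pad = 0,
                  mrs_probs = c(`3` = 0.45, `4` = 0.25, `5` = 0.17, `6` = 0.13))),
    effects = list(
      # planted log-odds (logistic mode): published univariable ORs
      beta_asym = log(1.055),        # per % overall MCA asymmetry
      indicator = NULL,              # e.g. list(threshold = 9, log_or = log(3.5))
      beta_cov = c(male = log(0.540), age = log(1.048), nihss = log(1.285),
                   hemoglobin = log(0.796), esr = log(1.017),
                   d_dimer = 2e-4, time_to_tcd = log(1.193)),
      centers = c(age = 62.10, nihss = 2, hemoglobin = 14.3, esr = 13.5,
                  d_dimer = 151.5, time_to_tcd = 3, asym = 7)),
    two_raters = FALSE,
    rater_noise_sdlog = 0.05
  ), class = "cohort_params")
}

#' Construct synthetic-cohort parameters
#'
#' Starts from [default_params()] and applies named overrides (recursively
#' merged, so `cohort_params(n_total = 2000, mode = "logistic")` or
#' `cohort_params(effects = list(beta_asym = 0))` touch only those fields).
#'
#' @param ... Named overrides of the default fields: `n_total`,
#'   `poor_fraction`, `mode` (`"group_first"` draws the outcome then
#'   group-specific TCD distributions; `"logistic"` draws TCD then the
#'   outcome through the planted coefficients), `seed`, `tcd` (calibration
#'   table), `rho_side`, `rho_segment`, `covariates`, `effects`,
#'   `two_raters`, `rater_noise_sdlog`.
#' @return Validated `cohort_params` list.
#' @export
cohort_params <- function(...) {
  p <- modifyList(unclass(default_params()), list(...))
  stopifnot(p$n_total >= 1,
            p$poor_fraction > 0, p$poor_fraction < 1,
            p$mode %in% c("group_first", "logistic"),
            all(abs(unlist(p$rho_side)) < 1), abs(p$rho_segment) < 1,
            all(p$tcd$sdlog > 0))
  structure(p, class = "cohort_params")
}

#' Invert MV and PI to a consistent velocity pair
#'
#' Solves `MV = EDV + (PSV - EDV)/3` and `PI = (PSV - EDV)/MV` for the
#' spectral velocities: `PSV = MV (1 + 2 PI / 3)`, `EDV = MV (1 - PI / 3)`.
#' Feasible only for `0 <= PI < 3` (PI of 3 would force `EDV = 0` exactly,
#' excluded). Round-tripping through [compute_mv()] / [compute_pi()]
#' reproduces the inputs to machine precision.
#'
#' @param mv Mean flow velocity, cm/s (`> 0`).
#' @param pi Pulsatility index in `[0, 3)`.
#' @return List with numeric `psv` and `edv` (cm/s).
#' @examples
#' invert_to_psv_edv(60, 0.75)  # psv 90, edv 45
#' @export
invert_to_psv_edv <- function(mv, pi) {
  check_numeric(mv, "mv")
  check_numeric(pi, "pi")
  if (any(mv <= 0)) {
    stop_mcasym("mv must be > 0", "mcasym_validation_error")
  }
  if (any(pi < 0 | pi >= 3)) {
    stop_mcasym("infeasible inversion: need 0 <= pi < 3 (pi >= 3 implies edv <= 0)",
                "mcasym_infeasible_inversion_error")
  }
  list(psv = mv * (1 + 2 * pi / 3), edv = mv * (1 - pi / 3))
}

# correlated log-normal draws for one group: n x 4 matrices (R.M1, R.M2,
# L.M1, L.M2) for one parameter (mv or pi)
draw_lognormal_cells <- function(n, param, group, params) {
  rho_s <- params$rho_side[[param]][[group]]
  s_side <- matrix(c(1, rho_s, rho_s, 1), 2)
  s_seg <- matrix(c(1, params$rho_segment, params$rho_segment, 1), 2)
  cl <- chol(kronecker(s_side, s_seg))  # cols: R.M1, R.M2, L.M1, L.M2
  tab <- params$tcd[params$tcd$param == param & params$tcd$group == group, ]
  key <- paste(tab$side, tab$segment)
  ord <- match(c("R M1", "R M2", "L M1", "L M2"), key)
  mu <- tab$meanlog[ord]
  sdl <- tab$sdlog[ord]
  z <- matrix(rnorm(n * 4), n, 4) %*% cl
  x <- sweep(sweep(z, 2, sdl, `*`), 2, mu, `+`)
  m <- exp(x)
  colnames(m) <- c("r_m1", "r_m2", "l_m1", "l_m2")
  m
}

draw_group_tcd <- function(n, group, params) {
  mv <- draw_lognormal_cells(n, "mv", group, params)
  pi <- draw_lognormal_cells(n, "pi", group, params)
  redraws <- 0L
  repeat {  # PI >= 3 is infeasible for the velocity inversion: redraw
    bad <- which(apply(pi >= 3, 1, any))
    if (!length(bad)) break
    redraws <- redraws + length(bad)
    pi[bad, ] <- draw_lognormal_cells(length(bad), "pi", group, params)
  }
  list(mv = mv, pi = pi, redraws = redraws)
}

draw_covariates <- function(n, group, params) {
  cv <- params$covariates[[group]]
  data.frame(
    age = round(pmin(100, pmax(18, rnorm(n, cv$age_mean, cv$age_sd))), 1),
    sex = ifelse(runif(n) < cv$male_frac, "male", "female"),
    nihss = pmin(42, pmax(0, round(exp(rnorm(n, cv$nihss_meanlog, cv$nihss_sdlog))))),
    hemoglobin = round(pmax(4, rnorm(n, cv$hgb_mean, cv$hgb_sd)), 1),
    esr = round(exp(rnorm(n, cv$esr_meanlog, cv$esr_sdlog)), 1),
    d_dimer = round(exp(rnorm(n, cv$ddimer_meanlog, cv$ddimer_sdlog)), 1),
    time_to_tcd = pmin(14, pmax(1, round(exp(rnorm(n, cv$ttcd_meanlog, cv$ttcd_sdlog))))),
    htn = runif(n) < cv$htn, dm = runif(n) < cv$dm, chol = runif(n) < cv$chol,
    smoker = runif(n) < cv$smoker, cad = runif(n) < cv$cad,
    pad = runif(n) < cv$pad,
    stringsAsFactors = FALSE)
}

draw_mrs <- function(n, group, params) {
  pr <- params$covariates[[group]]$mrs_probs
  as.integer(sample(as.integer(names(pr)), n, replace = TRUE, prob = pr))
}

# overall MCA asymmetry index straight from the mv/pi cell matrices
overall_asym_from_cells <- function(mv, pi) {
  idx <- matrix(mca_index(as.vector(mv), as.vector(pi), invalid = "na"),
                nrow(mv), 4, dimnames = list(NULL, colnames(mv)))
  r_mean <- (idx[, "r_m1"] + idx[, "r_m2"]) / 2
  l_mean <- (idx[, "l_m1"] + idx[, "l_m2"]) / 2
  out <- rep(NA_real_, nrow(mv))
  ok <- !is.na(r_mean) & !is.na(l_mean)
  out[ok] <- asymmetry_index(r_mean[ok], l_mean[ok])
  out
}

#' Generate a synthetic cryptogenic-stroke cohort
#'
#' Draws a seeded cohort of patient records plus bilateral velocity samples
#' (2 sides x 2 segments per patient per rater). In `"group_first"` mode the
#' outcome group is drawn first and TCD/covariates follow the group-specific
#' calibrated distributions (for calibration tests). In `"logistic"` mode
#' TCD and covariates are drawn from the good-outcome distributions for
#' everyone and the outcome follows the planted logistic model on the overall
#' MCA asymmetry index (continuous and/or `> threshold` indicator effect) and
#' covariates, with the intercept solved so the expected poor fraction equals
#' `params$poor_fraction` (for parameter-recovery tests).
#'
#' Velocity samples are produced by inverting each cell's (MV, PI) pair back
#' to (PSV, EDV) via [invert_to_psv_edv()]; draws with PI >= 3 (infeasible
#' inversion) are rejected and redrawn with the count recorded in
#' `meta$pi_redraws`. If more than 10% of draws have an undefined MCA index
#' (`mv <= 10 pi`) a warning reports the rate.
#'
#' @param params A `cohort_params` list.
#' @param seed Integer seed; defaults to `params$seed`. The seed fixes the
#'   full output exactly.
#' @return A `tcd_cohort` list: `patients`, `samples`, and `meta`
#'   (`seed`, `pi_redraws`, `invalid_index_rate`, `mode`).
#' @examples
#' coh <- generate_cohort(cohort_params(n_total = 50), seed = 1)
#' nrow(coh$patients)
#' @export
generate_cohort <- function(params = default_params(), seed = params$seed) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_total

  if (params$mode == "group_first") {
    poor <- runif(n) < params$poor_fraction
    mv <- matrix(NA_real_, n, 4); pi <- matrix(NA_real_, n, 4)
    colnames(mv) <- colnames(pi) <- c("r_m1", "r_m2", "l_m1", "l_m2")
    cov_df <- NULL; mrs <- integer(n)
    redraws <- 0L
    for (grp in c("good", "poor")) {
      rows <- if (grp == "poor") which(poor) else which(!poor)
      if (!length(rows)) next
      tcd <- draw_group_tcd(length(rows), grp, params)
      mv[rows, ] <- tcd$mv; pi[rows, ] <- tcd$pi
      redraws <- redraws + tcd$redraws
      cv <- draw_covariates(length(rows), grp, params)
      if (is.null(cov_df)) {
        cov_df <- cv[rep(1L, n), , drop = FALSE]  # template, overwritten below
      }
      cov_df[rows, ] <- cv
      mrs[rows] <- draw_mrs(length(rows), grp, params)
    }
  } else {
    tcd <- draw_group_tcd(n, "good", params)
    mv <- tcd$mv; pi <- tcd$pi
    redraws <- tcd$redraws
    cov_df <- draw_covariates(n, "good", params)
    asym <- overall_asym_from_cells(mv, pi)
    asym[is.na(asym)] <- median(asym, na.rm = TRUE)
    ef <- params$effects
    ctr <- ef$centers
    lp <- ef$beta_asym * (asym - ctr[["asym"]]) +
      ef$beta_cov[["male"]] * (cov_df$sex == "male") +
      ef$beta_cov[["age"]] * (cov_df$age - ctr[["age"]]) +
      ef$beta_cov[["nihss"]] * (cov_df$nihss - ctr[["nihss"]]) +
      ef$beta_cov[["hemoglobin"]] * (cov_df$hemoglobin - ctr[["hemoglobin"]]) +
      ef$beta_cov[["esr"]] * (cov_df$esr - ctr[["esr"]]) +
      ef$beta_cov[["d_dimer"]] * (cov_df$d_dimer - ctr[["d_dimer"]]) +
      ef$beta_cov[["time_to_tcd"]] * (cov_df$time_to_tcd - ctr[["time_to_tcd"]])
    if (!is.null(ef$indicator)) {
      lp <- lp + ef$indicator$log_or * (asym > ef$indicator$threshold)
    }
    b0 <- uniroot(function(b) mean(plogis(b + lp)) - params$poor_fraction,
                  c(-30, 30))$root
    poor <- runif(n) < plogis(b0 + lp)
    mrs <- integer(n)
    if (any(poor)) mrs[poor] <- draw_mrs(sum(poor), "poor", params)
    if (any(!poor)) mrs[!poor] <- draw_mrs(sum(!poor), "good", params)
  }

  invalid_rate <- mean(mv <= 10 * pi)
  if (invalid_rate > 0.10) {
    warning(sprintf(
      "%.1f%% of draws have an undefined MCA index (mv <= 10 pi); check parameters",
      100 * invalid_rate))
  }

  patients <- cbind(data.frame(patient_id = seq_len(n)), cov_df,
                    data.frame(mrs_3mo = mrs))
  patients <- patients[, PATIENT_COLS]
  rownames(patients) <- NULL

  samples <- build_samples(mv, pi, params)
  structure(list(patients = patients, samples = samples,
                 meta = list(seed = seed, pi_redraws = redraws,
                             invalid_index_rate = invalid_rate,
                             mode = params$mode)),
            class = "tcd_cohort")
}

build_samples <- function(mv, pi, params) {
  n <- nrow(mv)
  cells <- data.frame(col = c("r_m1", "r_m2", "l_m1", "l_m2"),
                      side = c("R", "R", "L", "L"),
                      segment = c("M1", "M2", "M1", "M2"),
                      stringsAsFactors = FALSE)
  one_rater <- function(mv, pi, rater) {
    rows <- lapply(seq_len(nrow(cells)), function(k) {
      depth <- if (cells$segment[k] == "M1") sample(58:68, n, replace = TRUE)
               else sample(44:56, n, replace = TRUE)
      ve <- invert_to_psv_edv(mv[, cells$col[k]], pi[, cells$col[k]])
      data.frame(patient_id = seq_len(n), side = cells$side[k],
                 depth_mm = depth, psv_cms = round(ve$psv, 1),
                 edv_cms = round(ve$edv, 1), rater = rater,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  if (isTRUE(params$two_raters)) {
    noise <- params$rater_noise_sdlog
    mv_b <- mv * exp(matrix(rnorm(n * 4, 0, noise), n, 4))
    pi_b <- pmin(pi * exp(matrix(rnorm(n * 4, 0, noise), n, 4)), 2.99)
    out <- rbind(one_rater(mv, pi, "A"), one_rater(mv_b, pi_b, "B"))
  } else {
    out <- one_rater(mv, pi, NA_character_)
  }
  out <- out[order(out$patient_id, out$side, -out$depth_mm), ]
  rownames(out) <- NULL
  out
}
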