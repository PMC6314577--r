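# Per-patient index profiles from long-format velocity samples.

SIDES <- c("R", "L")
SEGMENTS <- c("M1", "M2")

side_word <- c(R = "right", L = "left")
seg_word <- c(M1 = "proximal", M2 = "distal")

#' Validate a long-format velocity-sample table
#'
#' Required columns: `patient_id`, `side` (`"R"`/`"L"`), `depth_mm`,
#' `psv_cms`, `edv_cms`; optional `rater`. Enforces `psv >= edv >= 0` and
#' `depth > 0` on every row.
#'
#' @param samples `data.frame` of velocity samples.
#' @return The validated `data.frame`, invisibly normalised (`side` upper
#'   case, `rater` column present).
#' @export
validate_samples <- function(samples) {
  need <- c("patient_id", "side", "depth_mm", "psv_cms", "edv_cms")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop_mcasym(paste0("velocity-sample table is missing column(s): ",
                       paste(miss, collapse = ", ")),
                "mcasym_validation_error")
  }
  samples$side <- toupper(as.character(samples$side))
  if (!all(samples$side %in% SIDES)) {
    stop_mcasym("`side` must be 'R' or 'L'", "mcasym_validation_error")
  }
  bad <- which(!is.finite(samples$psv_cms) | !is.finite(samples$edv_cms) |
                 samples$edv_cms < 0 | samples$psv_cms < samples$edv_cms |
                 !is.finite(samples$depth_mm) | samples$depth_mm <= 0)
  if (length(bad)) {
    stop_mcasym(sprintf(
      "corrupted velocity sample(s) at row(s) %s: need psv >= edv >= 0 and depth > 0",
      paste(utils::head(bad, 5L), collapse = ", ")),
      "mcasym_validation_error")
  }
  if (is.null(samples$rater)) samples$rater <- NA_character_
  samples
}

#' Per-patient MCA index profile(s)
#'
#' Aggregates long-format bilateral velocity samples into one row per patient
#' holding every derived quantity of the analysis: per-side/segment mean flow
#' velocity (MV) and pulsatility index (PI), per-side/segment MCA indices,
#' per-side mean indices, and the MV, PI and MCA-index asymmetry indices
#' (proximal, distal, overall).
#'
#' Aggregation rules:
#' * depths are classified with [segment_from_depth()]; out-of-window depths
#'   are dropped (never reassigned);
#' * several in-window samples of one side/segment are combined by the
#'   arithmetic mean of their MV values and of their PI values (PI is averaged
#'   directly, not recomputed from averaged velocities);
#' * an MCA index with non-positive denominator (`mv <= 10 * pi`) is set `NA`
#'   and flagged invalid; derived means/asymmetries involving it are `NA`;
#' * overall MV and PI asymmetries use the per-side mean of the proximal and
#'   distal MV (resp. PI); the overall MCA asymmetry index uses only the two
#'   per-side mean MCA indices;
#' * a patient missing any side/segment window is marked `complete = FALSE`
#'   with an explicit `incomplete_reason` (e.g. `"no left proximal window"`),
#'   mirroring the exclusion of poor-temporal-window patients.
#'
#' @param samples Long-format sample table, see [validate_samples()]. Samples
#'   from multiple raters are pooled; use [icc()] on per-rater aggregates for
#'   reliability analysis.
#' @return `data.frame`, one row per patient: MV/PI cells `mv_r_m1`, ...,
#'   `pi_l_m2`; indices `idx_r_m1`, ..., `idx_l_mean`; validity flags
#'   `idx_valid_r_m1`, ...; asymmetries `idx_asym_m1`, `idx_asym_m2`,
#'   `idx_asym_overall`, `mv_asym_*`, `pi_asym_*`; `complete`;
#'   `incomplete_reason`.
#' @examples
#' s <- data.frame(patient_id = 1, side = c("R", "R", "L", "L"),
#'                 depth_mm = c(60, 50, 60, 50),
#'                 psv_cms = c(90, 84, 75, 72), edv_cms = c(45, 42, 45, 42))
#' patient_profiles(s)$idx_asym_overall  # 4.9450
#' @export
patient_profiles <- function(samples) {
  samples <- validate_samples(samples)
  ids <- unique(samples$patient_id)
  seg <- segment_from_depth(samples$depth_mm)
  keep <- seg != "out_of_window"
  d <- samples[keep, , drop = FALSE]
  dseg <- seg[keep]

  mv_s <- compute_mv(d$psv_cms, d$edv_cms)
  pi_s <- compute_pi(d$psv_cms, d$edv_cms)

  fac <- list(pid = factor(d$patient_id, levels = ids),
              side = factor(d$side, levels = SIDES),
              seg = factor(dseg, levels = SEGMENTS))
  mvA <- tapply(mv_s, fac, mean)   # ids x side x segment, NA where unobserved
  piA <- tapply(pi_s, fac, mean)

  prof <- data.frame(patient_id = ids)
  for (sd_ in SIDES) {
    for (sg in SEGMENTS) {
      prof[[sprintf("mv_%s_%s", tolower(sd_), tolower(sg))]] <-
        as.vector(mvA[, sd_, sg])
      prof[[sprintf("pi_%s_%s", tolower(sd_), tolower(sg))]] <-
        as.vector(piA[, sd_, sg])
    }
  }

  for (sd_ in tolower(SIDES)) {
    for (sg in tolower(SEGMENTS)) {
      mv <- prof[[sprintf("mv_%s_%s", sd_, sg)]]
      pi <- prof[[sprintf("pi_%s_%s", sd_, sg)]]
      idx <- mca_index(mv, pi, invalid = "na")
      prof[[sprintf("idx_%s_%s", sd_, sg)]] <- idx
      prof[[sprintf("idx_valid_%s_%s", sd_, sg)]] <- !is.na(mv) & !is.na(idx)
    }
    prof[[sprintf("idx_%s_mean", sd_)]] <-
      mean_mca_index(prof[[sprintf("idx_%s_m1", sd_)]],
                     prof[[sprintf("idx_%s_m2", sd_)]])
  }

  asym <- function(r, l) {
    out <- rep(NA_real_, length(r))
    ok <- !is.na(r) & !is.na(l)
    out[ok] <- asymmetry_index(r[ok], l[ok])
    out
  }
  for (sg in tolower(SEGMENTS)) {
    prof[[sprintf("idx_asym_%s", sg)]] <-
      asym(prof[[sprintf("idx_r_%s", sg)]], prof[[sprintf("idx_l_%s", sg)]])
    prof[[sprintf("mv_asym_%s", sg)]] <-
      asym(prof[[sprintf("mv_r_%s", sg)]], prof[[sprintf("mv_l_%s", sg)]])
    prof[[sprintf("pi_asym_%s", sg)]] <-
      asym(prof[[sprintf("pi_r_%s", sg)]], prof[[sprintf("pi_l_%s", sg)]])
  }
  prof$idx_asym_overall <- asym(prof$idx_r_mean, prof$idx_l_mean)
  prof$mv_asym_overall <- asym((prof$mv_r_m1 + prof$mv_r_m2) / 2,
                               (prof$mv_l_m1 + prof$mv_l_m2) / 2)
  prof$pi_asym_overall <- asym((prof$pi_r_m1 + prof$pi_r_m2) / 2,
                               (prof$pi_l_m1 + prof$pi_l_m2) / 2)

  # completeness: every side x segment window must be observed
  missing_cell <- matrix(FALSE, length(ids), 4L)
  labs <- character(4L); k <- 1L
  for (sd_ in SIDES) {
    for (sg in SEGMENTS) {
      missing_cell[, k] <- is.na(mvA[, sd_, sg])
      labs[k] <- sprintf("no %s %s window", side_word[[sd_]], seg_word[[sg]])
      k <- k + 1L
    }
  }
  prof$complete <- rowSums(missing_cell) == 0L
  prof$incomplete_reason <- apply(missing_cell, 1L, function(m) {
    if (!any(m)) NA_character_ else paste(labs[m], collapse = "; ")
  })
  rownames(prof) <- NULL
  prof
}

#' Profile a single patient's samples
#'
#' Convenience wrapper around [patient_profiles()] for the samples of one
#' patient; a `patient_id` column is optional.
#'
#' @inheritParams patient_profiles
#' @return One-row profile `data.frame`.
#' @export
patient_profile <- function(samples) {
  if (is.null(samples$patient_id)) samples$patient_id <- 1L
  if (length(unique(samples$patient_id)) != 1L) {
    stop_mcasym("patient_profile() expects samples of a single patient; use patient_profiles()",
                "mcasym_validation_error")
  }
  patient_profiles(samples)
}

#' Read a velocity-sample CSV
#'
#' Expects the long-format header
#' `patient_id,side,depth_mm,psv_cms,edv_cms,rater` (rater optional),
#' validated with [validate_samples()].
#'
#' @param path CSV path.
#' @return Validated sample `data.frame`.
#' @export
read_velocity_samples <- function(path) {
  validate_samples(read.csv(path, stringsAsFactors = FALSE))
}

#' Write per-patient profiles to CSV
#'
#' Index and asymmetry columns (percent scale) are rounded to 2 decimals at
#' report time; MV/PI aggregates are written at full precision.
#'
#' @param profiles Output of [patient_profiles()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles
  pct <- grep("^idx_(r|l)_|_asym_", names(out), value = TRUE)
  pct <- pct[!grepl("valid", pct)]
  for (cc in pct) out[[cc]] <- round(out[[cc]], 2)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
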