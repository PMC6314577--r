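# Elementary transcranial-Doppler hemodynamics.
#
# All velocities are spectral-envelope velocities in cm/s, insonation depths
# in mm. Functions are vectorised and recycle scalar arguments.

#' Mean flow velocity from the spectral envelope
#'
#' Time-averaged mean flow velocity of a Doppler spectral waveform,
#' `MV = EDV + (PSV - EDV) / 3`, the standard one-third-pulse-amplitude rule
#' used by clinical TCD machines.
#'
#' @param psv Peak systolic velocity, cm/s. Must satisfy `psv >= edv >= 0`.
#' @param edv End-diastolic velocity, cm/s.
#' @return Mean flow velocity in cm/s; always within `[edv, psv]`.
#' @examples
#' compute_mv(90, 45)  # 60
#' @seealso [compute_pi()], [mca_index()]
#' @export
compute_mv <- function(psv, edv) {
  check_velocity_pair(psv, edv)
  edv + (psv - edv) / 3
}

#' Gosling pulsatility index
#'
#' `PI = (PSV - EDV) / MV` with MV from [compute_mv()]. PI is dimensionless
#' and proxies distal cerebrovascular resistance.
#'
#' @inheritParams compute_mv
#' @return Pulsatility index (dimensionless, `>= 0`).
#' @examples
#' compute_pi(90, 45)  # 0.75
#' @export
compute_pi <- function(psv, edv) {
  check_velocity_pair(psv, edv)
  mv <- edv + (psv - edv) / 3
  if (any(mv <= 0)) {
    stop_mcasym("pulsatility index undefined: MV = 0 (PSV = EDV = 0)",
                "mcasym_undefined_pi_error")
  }
  (psv - edv) / mv
}

check_velocity_pair <- function(psv, edv) {
  check_numeric(psv, "psv", allow_na = TRUE)
  check_numeric(edv, "edv", allow_na = TRUE)
  ok <- !is.na(psv) & !is.na(edv)
  if (any(edv[ok] < 0) || any(psv[ok] < edv[ok])) {
    stop_mcasym("corrupted velocity sample: need psv >= edv >= 0",
                "mcasym_validation_error")
  }
  invisible(NULL)
}

#' Classify an insonation depth into an MCA segment
#'
#' Depth windows through the trans-temporal window: proximal MCA stem
#' (M1) at 58-68 mm, distal MCA (M2) at 44-56 mm. Depths in the 56-58 mm gap
#' or outside 44-68 mm belong to neither segment and are returned as
#' `"out_of_window"` (a value, not an error); they are never assigned to the
#' nearer window.
#'
#' @param depth Insonation depth in mm, `> 0`.
#' @return Character vector in `c("M1", "M2", "out_of_window")`.
#' @examples
#' segment_from_depth(c(60, 44, 57))
#' @export
segment_from_depth <- function(depth) {
  check_numeric(depth, "depth")
  if (any(depth <= 0)) {
    stop_mcasym("insonation depth must be > 0 mm", "mcasym_validation_error")
  }
  out <- rep("out_of_window", length(depth))
  out[depth >= 58 & depth <= 68] <- "M1"
  out[depth >= 44 & depth <= 56] <- "M2"
  out
}

#' The composite MCA index
#'
#' A single-vessel composite of mean flow velocity and pulsatility index,
#' `100 * (MV + m * PI) / (MV - m * PI)` with multiplier `m = 10`. The index
#' rises when MV falls or PI rises, amplifying hemodynamic derangement that
#' either parameter alone reflects weakly. It is undefined (denominator
#' `<= 0`) when `MV <= m * PI`.
#'
#' @param mv Mean flow velocity, cm/s (`> 0`).
#' @param pi Pulsatility index (`>= 0`).
#' @param multiplier Weight on PI; 10 by default (the value that best spreads
#'   between-patient differences, see the package vignette).
#' @param invalid `"error"` (default) to fail on an undefined index,
#'   `"na"` to return `NA` for undefined elements so callers can flag them.
#' @return Index in percent; `> 100` whenever `pi > 0`, exactly 100 at
#'   `pi = 0`.
#' @examples
#' mca_index(50, 1.0)        # 150
#' mca_index(56, 0.87)       # 136.786...
#' @export
mca_index <- function(mv, pi, multiplier = 10, invalid = c("error", "na")) {
  invalid <- match.arg(invalid)
  check_numeric(mv, "mv", allow_na = TRUE)
  check_numeric(pi, "pi", allow_na = TRUE)
  ok <- !is.na(mv) & !is.na(pi)
  if (any(mv[ok] <= 0) || any(pi[ok] < 0)) {
    stop_mcasym("mca_index requires mv > 0 and pi >= 0",
                "mcasym_validation_error")
  }
  denom <- mv - multiplier * pi
  bad <- ok & denom <= 0
  if (any(bad)) {
    if (invalid == "error") {
      stop_mcasym(
        sprintf("MCA index undefined for %d element(s): mv <= %g * pi",
                sum(bad), multiplier),
        "mcasym_invalid_index_error")
    }
  }
  res <- 100 * (mv + multiplier * pi) / denom
  res[bad] <- NA_real_
  res
}

#' Mean MCA index across segments
#'
#' Arithmetic mean of the proximal (M1) and distal (M2) MCA indices of one
#' side. `NA` in either input (an invalid index) propagates.
#'
#' @param proximal_index,distal_index MCA indices in percent.
#' @return Mean index in percent.
#' @export
mean_mca_index <- function(proximal_index, distal_index) {
  check_numeric(proximal_index, "proximal_index", allow_na = TRUE)
  check_numeric(distal_index, "distal_index", allow_na = TRUE)
  (proximal_index + distal_index) / 2
}

#' Left-right asymmetry index
#'
#' Normalised absolute side difference of a bilateral quantity, expressed as
#' percent of the bilateral mean: `200 * |R - L| / (R + L)`. This is the
#' standard asymmetry-index convention (difference over the mean of the two
#' sides); `convention = "literal"` gives the 4x smaller
#' `50 * |R - L| / (R + L)` for auditability against a strict left-to-right
#' reading of the formula string.
#'
#' @param right,left Positive bilateral quantities (`NA` propagates).
#' @param convention `"bilateral_mean"` (default) or `"literal"`.
#' @return Asymmetry in percent; 0 iff `right == left`; `< 200` (or `< 50`
#'   under the literal convention); symmetric and scale-invariant in its
#'   arguments.
#' @examples
#' asymmetry_index(150, 130)  # 14.2857...
#' @export
asymmetry_index <- function(right, left,
                            convention = c("bilateral_mean", "literal")) {
  convention <- match.arg(convention)
  check_numeric(right, "right", allow_na = TRUE)
  check_numeric(left, "left", allow_na = TRUE)
  ok <- !is.na(right) & !is.na(left)
  if (any(right[ok] <= 0) || any(left[ok] <= 0)) {
    stop_mcasym("asymmetry_index requires positive inputs",
                "mcasym_validation_error")
  }
  scale <- if (convention == "bilateral_mean") 200 else 50
  scale * abs(right - left) / (right + left)
}

#' MCA-index sensitivity grid over PI multipliers
#'
#' Evaluates `100 * (mv + k * pi) / (mv - k * pi)` over the Cartesian grid of
#' `mv_values`, `pi_values` and `multipliers`, to compare how strongly each
#' multiplier spreads differences between hemodynamic states. Undefined cells
#' (`mv <= k * pi`) are flagged, not errors.
#'
#' @param mv_values Mean flow velocities, cm/s (`> 0`).
#' @param pi_values Pulsatility indices (`>= 0`).
#' @param multipliers Positive PI weights, e.g. `c(1, 10)`.
#' @return `data.frame` with columns `mv`, `pi`, `multiplier`, `index`
#'   (`NA` where undefined) and logical `defined`.
#' @examples
#' index_sensitivity_grid(50, 0.8, c(1, 10))
#' @export
index_sensitivity_grid <- function(mv_values, pi_values, multipliers) {
  check_numeric(mv_values, "mv_values")
  check_numeric(pi_values, "pi_values")
  check_numeric(multipliers, "multipliers")
  if (any(mv_values <= 0) || any(pi_values < 0) || any(multipliers <= 0)) {
    stop_mcasym("need mv > 0, pi >= 0, multipliers > 0",
                "mcasym_validation_error")
  }
  g <- expand.grid(mv = mv_values, pi = pi_values, multiplier = multipliers,
                   KEEP.OUT.ATTRS = FALSE)
  denom <- g$mv - g$multiplier * g$pi
  g$defined <- denom > 0
  g$index <- ifelse(g$defined, 100 * (g$mv + g$multiplier * g$pi) / denom,
                    NA_real_)
  g
}
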