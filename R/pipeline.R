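# End-to-end analysis pipeline and file-based entry points.

TCD_INDEX_VARS <- c("idx_r_m1", "idx_l_m1", "idx_asym_m1",
                    "idx_r_m2", "idx_l_m2", "idx_asym_m2",
                    "idx_r_mean", "idx_l_mean", "idx_asym_overall")

TCD_TABLE_VARS <- c("mv_r_m1", "mv_l_m1", "mv_asym_m1",
                    "mv_r_m2", "mv_l_m2", "mv_asym_m2", "mv_asym_overall",
                    "pi_r_m1", "pi_l_m1", "pi_asym_m1",
                    "pi_r_m2", "pi_l_m2", "pi_asym_m2", "pi_asym_overall",
                    TCD_INDEX_VARS)

COVARIATE_TABLE_VARS <- c("age", "male", "nihss", "time_to_tcd", "htn", "dm",
                          "chol", "smoker", "cad", "pad", "hemoglobin",
                          "esr", "d_dimer")

#' Run the full outcome-prediction pipeline
#'
#' Profiles every patient, dichotomises the 3-month outcome, produces the
#' descriptive comparison tables (covariates and TCD quantities), the
#' univariable logistic screen, covariate-adjusted fits for each MCA index
#' quantity, the ROC/Youden cutoff for the overall MCA asymmetry index, and
#' the adjusted model for the dichotomised (`> cutoff`) index. Patients with
#' incomplete profiles (missing insonation windows) are excluded from the
#' analysis, mirroring the handling of poor temporal windows.
#'
#' @param cohort A `tcd_cohort`.
#' @param out_dir Optional directory; when given, writes `profiles.csv`,
#'   `comparison_covariates.csv`, `comparison_tcd.csv`, `roc_points.csv` and
#'   `models.json` (full float precision).
#' @param threshold mRS dichotomisation threshold (3 primary, 2 sensitivity).
#' @param cutoff Asymmetry cutoff in percent for the dichotomised model;
#'   default is the Youden-optimal cutoff from the data.
#' @return List: `analysis_frame`, `descriptives` (covariate and TCD
#'   tables), `screen`, `adjusted` (list of `logistic_fit`), `roc`,
#'   `cutoff`, `cutoff_fit`, `n_excluded_incomplete`.
#' @export
run_pipeline <- function(cohort, out_dir = NULL, threshold = 3,
                         cutoff = NULL) {
  af <- build_analysis_frame(cohort, threshold = threshold)
  n_excl <- sum(!af$complete)
  af_c <- af[af$complete, , drop = FALSE]

  desc_cov <- descriptive_table(af_c, af_c$poor,
                                variables = COVARIATE_TABLE_VARS)
  desc_tcd <- descriptive_table(af_c, af_c$poor, variables = TCD_TABLE_VARS)

  screen <- univariable_screen(
    af_c, c(setdiff(COVARIATE_TABLE_VARS, "male"), "male", TCD_INDEX_VARS))

  covars <- adjustment_covariates()
  adjusted <- lapply(setNames(TCD_INDEX_VARS, TCD_INDEX_VARS), function(v) {
    tryCatch(fit_logistic(af_c$poor, af_c[, c(v, covars), drop = FALSE]),
             error = function(e) e)
  })

  roc <- roc_youden(af_c$idx_asym_overall[!is.na(af_c$idx_asym_overall)],
                    af_c$poor[!is.na(af_c$idx_asym_overall)])
  cutoff <- cutoff %||% roc$youden_cutoff
  cutoff_fit <- tryCatch(dichotomized_fit(af_c, cutoff),
                         error = function(e) e)

  res <- list(analysis_frame = af, descriptives = list(covariates = desc_cov,
                                                       tcd = desc_tcd),
              screen = screen, adjusted = adjusted, roc = roc,
              cutoff = cutoff, cutoff_fit = cutoff_fit,
              n_excluded_incomplete = n_excl)
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_profiles(res$analysis_frame[, c("patient_id",
                                        grep("^(mv|pi|idx)_|complete|incomplete",
                                             names(res$analysis_frame),
                                             value = TRUE))],
                 file.path(out_dir, "profiles.csv"))
  write.csv(res$descriptives$covariates,
            file.path(out_dir, "comparison_covariates.csv"),
            row.names = FALSE, na = "")
  write.csv(res$descriptives$tcd, file.path(out_dir, "comparison_tcd.csv"),
            row.names = FALSE, na = "")
  roc_pts <- data.frame(threshold = res$roc$thresholds,
                        sensitivity = res$roc$sensitivity,
                        specificity = res$roc$specificity)
  write.csv(roc_pts, file.path(out_dir, "roc_points.csv"),
            row.names = FALSE, na = "")
  fit_or_error <- function(f) {
    if (inherits(f, "error")) list(error = conditionMessage(f))
    else logistic_table(f)
  }
  models <- list(
    univariable = lapply(res$screen$fits, logistic_table),
    screen_selected = res$screen$selected,
    screen_skipped = as.list(res$screen$skipped),
    adjusted = lapply(res$adjusted, fit_or_error),
    roc = list(auc = res$roc$auc, youden_cutoff = res$roc$youden_cutoff,
               youden_value = res$roc$youden_value),
    cutoff = res$cutoff,
    cutoff_fit = fit_or_error(res$cutoff_fit),
    n_excluded_incomplete = res$n_excluded_incomplete)
  jsonlite::write_json(models, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", na = "null")
  invisible(out_dir)
}

#' Simulate a cohort to CSV files
#'
#' Generates a seeded synthetic cohort and writes `patients.csv`,
#' `samples.csv` and the versioned `params.json` used, to `out_dir`.
#'
#' @param out_dir Destination directory.
#' @param params `cohort_params` (default [default_params()]).
#' @param seed Integer seed (required for a reproducible file set).
#' @return `out_dir`, invisibly.
#' @export
simulate_cohort_files <- function(out_dir, params = default_params(), seed) {
  coh <- generate_cohort(params, seed = seed)
  write_cohort(coh, out_dir)
  pj <- unclass(params)
  pj$seed <- seed
  jsonlite::write_json(pj, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' Analyse a cohort directory to result files
#'
#' File-level wrapper: [read_cohort()] then [run_pipeline()] with outputs
#' written to `out_dir`.
#'
#' @param cohort_dir Directory holding `patients.csv` and `samples.csv`.
#' @param out_dir Destination directory for result files.
#' @param threshold,cutoff Passed to [run_pipeline()].
#' @return The [run_pipeline()] result list, invisibly.
#' @export
analyze_cohort_files <- function(cohort_dir, out_dir, threshold = 3,
                                 cutoff = NULL) {
  coh <- read_cohort(cohort_dir)
  invisible(run_pipeline(coh, out_dir = out_dir, threshold = threshold,
                         cutoff = cutoff))
}

#' Command-line entry point
#'
#' Dispatches the `simulate` and `analyze` subcommands used by the
#' `inst/cli/mcasym.R` script:
#' \preformatted{
#' Rscript inst/cli/mcasym.R simulate --seed 42 --out cohort_dir [--params params.json]
#' Rscript inst/cli/mcasym.R analyze --cohort cohort_dir --out results_dir [--threshold 3]
#' }
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the result of the dispatched function.
#' @export
mcasym_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: mcasym.R simulate|analyze [--options]", call. = FALSE)
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  if (cmd == "simulate") {
    params <- if (!is.null(opts$params)) {
      do.call(cohort_params, jsonlite::read_json(opts$params, simplifyVector = TRUE))
    } else default_params()
    if (is.null(opts$seed)) stop("simulate requires --seed", call. = FALSE)
    simulate_cohort_files(opts$out, params, seed = as.integer(opts$seed))
  } else if (cmd == "analyze") {
    analyze_cohort_files(opts$cohort, opts$out,
                         threshold = as.integer(opts$threshold %||% 3))
  } else {
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
  }
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--") || i == length(args)) {
      stop(sprintf("malformed option '%s'", a), call. = FALSE)
    }
    opts[[substring(a, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
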