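# Patient-level data model, outcome dichotomisation and the descriptive
# group-comparison machinery.

PATIENT_COLS <- c("patient_id", "age", "sex", "nihss", "mrs_3mo", "hemoglobin",
                  "esr", "d_dimer", "time_to_tcd", "htn", "dm", "chol",
                  "smoker", "cad", "pad")

#' Dichotomise the 3-month modified Rankin Scale
#'
#' Poor functional outcome is `mRS >= threshold`; the primary analysis uses
#' threshold 3 (mRS 3-6 poor), the conservative sensitivity analysis
#' threshold 2.
#'
#' @param mrs Integer mRS scores in 0-6.
#' @param threshold 3 (default) or 2.
#' @return Logical vector `poor`, with the threshold kept as an attribute.
#' @examples
#' dichotomize_outcome(c(0, 2, 3, 6))         # FALSE FALSE TRUE TRUE
#' dichotomize_outcome(2, threshold = 2)      # TRUE
#' @export
dichotomize_outcome <- function(mrs, threshold = 3) {
  check_numeric(mrs, "mrs")
  if (any(mrs < 0 | mrs > 6 | mrs != round(mrs))) {
    stop_mcasym("mRS scores must be integers in 0-6", "mcasym_validation_error")
  }
  if (length(threshold) != 1L || !threshold %in% c(2, 3)) {
    stop_mcasym("threshold must be 2 or 3", "mcasym_validation_error")
  }
  structure(mrs >= threshold, threshold = threshold)
}

# Mann-Whitney U two-sided test. Exact null via the Wilcoxon distribution when
# the combined sample is small and tie-free; otherwise normal approximation
# with tie-corrected variance (no continuity correction, SPSS-style).
mann_whitney <- function(x, y, exact_max_n = 20L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  if (!has_ties && n <= exact_max_n) {
    p_le <- pwilcox(u, n1, n2)
    p_ge <- 1 - pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      warning("all observations tied; Mann-Whitney p-value set to 1")
      return(list(statistic = u, p_value = 1, method = "degenerate"))
    }
    p <- 2 * pnorm(-abs(u - mu) / sqrt(sigma2))
    method <- "normal_approx"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Compare a continuous variable between two groups
#'
#' Two-sided comparison of independent samples. `method = "auto"` applies a
#' Shapiro-Wilk normality screen (alpha = 0.05) in both groups and uses the
#' Welch t test only when both pass (and are large enough to screen,
#' 3-5000 observations); otherwise the Mann-Whitney U test. The Mann-Whitney
#' p-value is exact (Wilcoxon null distribution) when the combined sample has
#' at most 20 tie-free observations, else a tie-corrected normal
#' approximation.
#'
#' @param values_a,values_b Numeric vectors, each with at least 2 non-missing
#'   values (missing values are dropped per comparison).
#' @param method `"auto"`, `"t_test"` or `"mann_whitney"`.
#' @return A `group_comparison` list: `method`, `statistic`, `p_value`,
#'   group sizes and formatted per-group summaries (`mean +/- SD` for the
#'   t test, `median [IQR]` for Mann-Whitney).
#' @examples
#' compare_continuous(c(1, 2, 3), c(4, 5, 6), method = "mann_whitney")$p_value
#' @export
compare_continuous <- function(values_a, values_b,
                               method = c("auto", "t_test", "mann_whitney")) {
  method <- match.arg(method)
  x <- values_a[!is.na(values_a)]
  y <- values_b[!is.na(values_b)]
  if (length(x) < 2L || length(y) < 2L) {
    stop_mcasym("each group needs at least 2 non-missing values",
                "mcasym_validation_error")
  }
  if (method == "auto") {
    method <- if (groups_pass_normality(x, y)) "t_test" else "mann_whitney"
  }
  if (method == "t_test") {
    tt <- t.test(x, y)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value)
    summ <- c(fmt_mean_sd(x), fmt_mean_sd(y))
  } else {
    mw <- mann_whitney(x, y)
    res <- list(statistic = mw$statistic, p_value = mw$p_value)
    summ <- c(fmt_median_iqr(x), fmt_median_iqr(y))
  }
  structure(list(kind = method, statistic = res$statistic,
                 p_value = res$p_value, n_a = length(x), n_b = length(y),
                 summary_a = summ[1], summary_b = summ[2]),
            class = "group_comparison")
}

groups_pass_normality <- function(x, y, alpha = 0.05) {
  screen <- function(v) {
    if (length(v) < 3L || length(v) > 5000L) return(FALSE)
    if (sd(v) == 0) return(FALSE)
    shapiro.test(v)$p.value > alpha
  }
  screen(x) && screen(y)
}

fmt_mean_sd <- function(v) sprintf("%.2f ± %.2f", mean(v), sd(v))
# quantile type 7: linear interpolation between order statistics
fmt_median_iqr <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
}
fmt_n_pct <- function(k, n) sprintf("%d (%.1f)", k, 100 * k / n)

#' Compare a categorical variable between groups
#'
#' Contingency-table test for a `2 x k` count table (groups in rows).
#' `method = "auto"` routes to Fisher's exact test when any expected cell
#' count is below 5, else the Pearson chi-square test without continuity
#' correction. The two-sided Fisher p-value is the sum of probabilities of
#' all tables (at fixed margins) no more probable than the observed one.
#'
#' @param table Matrix of non-negative integer counts with positive margins.
#' @param method `"auto"`, `"chi2"` or `"fisher"`.
#' @param correct Continuity correction for the chi-square branch
#'   (default `FALSE`).
#' @return A `group_comparison` list with `kind`, `statistic` (chi-square
#'   statistic, `NA` for Fisher) and `p_value`.
#' @examples
#' compare_categorical(matrix(c(5, 0, 0, 5), 2), method = "fisher")$p_value
#' @export
compare_categorical <- function(table, method = c("auto", "chi2", "fisher"),
                                correct = FALSE) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_mcasym("counts must be non-negative integers",
                "mcasym_validation_error")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_mcasym("contingency table has a zero margin",
                "mcasym_validation_error")
  }
  if (method == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    method <- if (any(expected < 5)) "fisher" else "chi2"
  }
  if (method == "fisher") {
    p <- fisher.test(tab)$p.value
    stat <- NA_real_
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    p <- ct$p.value
    stat <- unname(ct$statistic)
  }
  structure(list(kind = method, statistic = stat, p_value = p,
                 n_a = sum(tab[1, ]), n_b = sum(tab[2, ]),
                 summary_a = NA_character_, summary_b = NA_character_),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %.4g (n = %d vs %d)\n", x$kind,
              ifelse(is.na(x$statistic), "-", format(x$statistic)),
              x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Descriptive group-comparison table
#'
#' One row per variable comparing the two outcome groups: formatted per-group
#' summaries (`median [IQR]`, `mean +/- SD`, or `n (%)`) and the two-sided
#' p-value, with test routing per [compare_continuous()] /
#' [compare_categorical()]. Missing values are dropped per comparison
#' (complete-case per variable) and counted in `n_missing`.
#'
#' @param records `data.frame` of per-patient variables.
#' @param grouping Logical vector (e.g. from [dichotomize_outcome()]); `TRUE`
#'   rows form the "poor" group.
#' @param variables Character vector of column names to compare; default all
#'   columns except `patient_id`. Unknown names error, listing the available
#'   ones.
#' @param methods Optional named character vector of per-variable overrides
#'   (`"t_test"`, `"mann_whitney"`, `"chi2"`, `"fisher"`).
#' @return `data.frame` with columns `variable`, `type`, `summary_good`,
#'   `summary_poor`, `test`, `statistic`, `p_value`, `n_missing`.
#' @export
descriptive_table <- function(records, grouping, variables = NULL,
                              methods = NULL) {
  if (length(grouping) != nrow(records) || anyNA(grouping)) {
    stop_mcasym("grouping must be a complete logical vector matching records",
                "mcasym_validation_error")
  }
  grouping <- as.logical(grouping)
  if (!any(grouping) || all(grouping)) {
    stop_mcasym("one outcome group is empty", "mcasym_validation_error")
  }
  if (is.null(variables)) {
    variables <- setdiff(names(records), "patient_id")
  }
  unknown <- setdiff(variables, names(records))
  if (length(unknown)) {
    stop_mcasym(sprintf("unknown variable(s): %s. Available: %s",
                        paste(unknown, collapse = ", "),
                        paste(names(records), collapse = ", ")),
                "mcasym_validation_error")
  }
  rows <- lapply(variables, function(v) {
    val <- records[[v]]
    miss <- sum(is.na(val))
    good <- val[!grouping & !is.na(val)]
    poor <- val[grouping & !is.na(val)]
    m <- if (!is.null(methods) && v %in% names(methods)) methods[[v]] else "auto"
    categorical <- is.logical(val) || is.character(val) || is.factor(val) ||
      (is.numeric(val) && all(val %in% c(0, 1, NA)))
    if (categorical) {
      val_f <- factor(val)
      tab <- rbind(good = table(factor(good, levels = levels(val_f))),
                   poor = table(factor(poor, levels = levels(val_f))))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      cmp <- if (ncol(tab) < 2L) {
        # variable constant in the pooled sample: no test possible
        list(kind = "none", statistic = NA_real_, p_value = NA_real_)
      } else {
        compare_categorical(tab, method = if (m == "auto") "auto" else m)
      }
      # "TRUE"/"1"/last factor level is the reported category
      lev_hi <- utils::tail(levels(val_f), 1)
      cnt <- function(row) if (lev_hi %in% colnames(tab)) tab[row, lev_hi] else 0L
      s_good <- fmt_n_pct(cnt(1), sum(tab[1, ]))
      s_poor <- fmt_n_pct(cnt(2), sum(tab[2, ]))
      type <- "categorical"
    } else {
      cmp <- compare_continuous(good, poor, method = m)
      s_good <- cmp$summary_a
      s_poor <- cmp$summary_b
      type <- "continuous"
    }
    data.frame(variable = v, type = type, summary_good = s_good,
               summary_poor = s_poor, test = cmp$kind,
               statistic = cmp$statistic, p_value = cmp$p_value,
               n_missing = miss, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a patient-record CSV
#'
#' Expects the header `patient_id,age,sex,nihss,mrs_3mo,hemoglobin,esr,
#' d_dimer,time_to_tcd,htn,dm,chol,smoker,cad,pad`; `sex` coded
#' `male`/`female`, risk flags 0/1.
#'
#' @param path CSV path.
#' @return Validated `data.frame` with logical risk flags.
#' @export
read_patient_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(PATIENT_COLS, names(df))
  if (length(miss)) {
    stop_mcasym(paste0("patient table is missing column(s): ",
                       paste(miss, collapse = ", ")),
                "mcasym_validation_error")
  }
  if (!all(df$sex %in% c("male", "female"))) {
    stop_mcasym("sex must be 'male' or 'female'", "mcasym_validation_error")
  }
  for (fl in c("htn", "dm", "chol", "smoker", "cad", "pad")) {
    df[[fl]] <- as.logical(df[[fl]])
  }
  dichotomize_outcome(df$mrs_3mo)  # validates mRS range
  if (any(df$nihss < 0) || any(df[c("hemoglobin", "esr", "d_dimer")] < 0)) {
    stop_mcasym("NIHSS and laboratory values must be >= 0",
                "mcasym_validation_error")
  }
  df
}

#' Read a cohort directory
#'
#' Loads `patients.csv` and `samples.csv` (as written by [write_cohort()])
#' and checks that every velocity sample joins to a patient.
#'
#' @param dir Directory containing the two CSVs.
#' @return A `tcd_cohort` list with elements `patients` and `samples`.
#' @export
read_cohort <- function(dir) {
  patients <- read_patient_records(file.path(dir, "patients.csv"))
  samples <- read_velocity_samples(file.path(dir, "samples.csv"))
  orphan <- setdiff(samples$patient_id, patients$patient_id)
  if (length(orphan)) {
    stop_mcasym(sprintf("samples reference unknown patient_id(s): %s",
                        paste(utils::head(orphan, 5L), collapse = ", ")),
                "mcasym_validation_error")
  }
  structure(list(patients = patients, samples = samples),
            class = "tcd_cohort")
}

#' Write a cohort to a directory
#'
#' Writes `patients.csv` and `samples.csv` in the package's interchange
#' format (risk flags as 0/1).
#'
#' @param cohort A `tcd_cohort` (e.g. from [generate_cohort()]).
#' @param dir Destination directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$patients
  for (fl in c("htn", "dm", "chol", "smoker", "cad", "pad")) {
    p[[fl]] <- as.integer(p[[fl]])
  }
  write.csv(p, file.path(dir, "patients.csv"), row.names = FALSE, na = "")
  write.csv(cohort$samples, file.path(dir, "samples.csv"),
            row.names = FALSE, na = "")
  invisible(dir)
}

#' @export
print.tcd_cohort <- function(x, ...) {
  cat(sprintf("TCD cohort: %d patients, %d velocity samples\n",
              nrow(x$patients), nrow(x$samples)))
  invisible(x)
}

#' Build the flat analysis frame
#'
#' Joins patient covariates with per-patient profiles and the dichotomised
#' outcome into the single `data.frame` consumed by the modelling stage.
#' `sex` becomes the logical indicator `male`.
#'
#' @param cohort A `tcd_cohort`.
#' @param threshold mRS dichotomisation threshold (3 primary, 2 sensitivity).
#' @return `data.frame` of covariates, profile columns and logical `poor`.
#' @export
build_analysis_frame <- function(cohort, threshold = 3) {
  prof <- patient_profiles(cohort$samples)
  af <- merge(cohort$patients, prof, by = "patient_id", all.x = TRUE,
              sort = FALSE)
  af <- af[match(cohort$patients$patient_id, af$patient_id), , drop = FALSE]
  af$male <- af$sex == "male"
  af$poor <- as.logical(dichotomize_outcome(af$mrs_3mo, threshold))
  rownames(af) <- NULL
  af
}
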