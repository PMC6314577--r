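# Inferential stages: logistic outcome models, ROC/Youden cutoff, ICC.

#' Covariate set of the adjusted outcome models
#'
#' The fixed adjustment set used by every "adjusted" model: sex (as the
#' `male` indicator), age, admission NIHSS, hemoglobin, ESR, D-dimer and
#' time from admission to TCD. Additional covariates enter only by explicit
#' argument.
#'
#' @return Character vector of analysis-frame column names.
#' @export
adjustment_covariates <- function() {
  c("male", "age", "nihss", "hemoglobin", "esr", "d_dimer", "time_to_tcd")
}

#' Maximum-likelihood logistic regression with Wald inference
#'
#' Binomial GLM (iteratively reweighted least squares) of a binary outcome on
#' a numeric predictor matrix, reporting odds ratios with Wald 95% confidence
#' intervals `exp(beta +/- 1.96 * SE)` and Wald p-values. Fails loudly, never
#' silently: constant predictors, rank-deficient designs (naming the
#' collinear columns) and (quasi-)perfect separation (naming the separating
#' predictor) are errors.
#'
#' @param outcome Logical or 0/1 vector; both classes must be present and
#'   `n >= 10`.
#' @param predictors Named numeric matrix or `data.frame` (logical columns
#'   are coerced to 0/1).
#' @return A `logistic_fit`: `predictors`, `coefficients` (log-odds, incl.
#'   intercept), `se`, `or`, `ci_lower`, `ci_upper`, `p_value`, `converged`,
#'   `n`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- runif(200) < plogis(-1 + x)
#' fit_logistic(y, data.frame(x = x))
#' @export
fit_logistic <- function(outcome, predictors) {
  y <- as.numeric(outcome)
  X <- as.data.frame(predictors)
  if (ncol(X) == 0L) {
    stop_mcasym("no predictors supplied", "mcasym_validation_error")
  }
  for (j in seq_along(X)) X[[j]] <- as.numeric(X[[j]])
  keep <- complete.cases(X) & !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n < 10L) {
    stop_mcasym("logistic fit requires at least 10 complete observations",
                "mcasym_validation_error")
  }
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2L) {
    stop_mcasym("outcome must be binary with both classes present",
                "mcasym_validation_error")
  }
  const <- vapply(X, function(v) sd(v) == 0, logical(1))
  if (any(const)) {
    stop_mcasym(sprintf("constant predictor(s): %s",
                        paste(names(X)[const], collapse = ", ")),
                "mcasym_constant_predictor_error")
  }
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop_mcasym(sprintf("singular design; collinear column(s): %s",
                        paste(dropped, collapse = ", ")),
                "mcasym_singular_design_error")
  }
  dat <- cbind(.y = y, X)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  scaled <- abs(beta[-1]) * vapply(X, sd, numeric(1))
  if ((sep_warn && max(scaled) > 10) || !fit$converged || any(!is.finite(se))) {
    worst <- names(X)[which.max(scaled)]
    stop_mcasym(sprintf(
      "logistic model did not converge: (quasi-)perfect separation on predictor '%s'",
      worst), "mcasym_separation_error")
  }
  z <- beta / se
  structure(list(
    predictors = names(X),
    coefficients = beta,
    se = se,
    or = exp(beta),
    ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se),
    p_value = 2 * pnorm(-abs(z)),
    converged = TRUE,
    n = n), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic fit (n = %d)\n", x$n))
  tab <- data.frame(OR = x$or, `CI 2.5` = x$ci_lower, `CI 97.5` = x$ci_upper,
                    p = signif(x$p_value, digits), check.names = FALSE)
  print(round(tab[-1, , drop = FALSE], digits))
  invisible(x)
}

#' Coefficient table of a logistic fit
#'
#' @param fit A `logistic_fit`.
#' @return `data.frame` with one row per predictor (intercept excluded):
#'   `predictor`, `or`, `ci_lower`, `ci_upper`, `p_value`.
#' @export
logistic_table <- function(fit) {
  idx <- seq_along(fit$coefficients)[-1]
  data.frame(predictor = fit$predictors,
             or = unname(fit$or[idx]),
             ci_lower = unname(fit$ci_lower[idx]),
             ci_upper = unname(fit$ci_upper[idx]),
             p_value = unname(fit$p_value[idx]),
             stringsAsFactors = FALSE)
}

#' Univariable logistic screen
#'
#' One single-predictor logistic fit per variable against the binary outcome.
#' Returns every fit, the subset passing `p < alpha` (plus sex/age, which are
#' always retained for the adjusted model), and the variables skipped with a
#' reason (zero variance, fit failure); a failing variable never aborts the
#' screen.
#'
#' @param records Analysis frame with outcome column and variables.
#' @param variables Character vector of predictor column names.
#' @param outcome Name of the logical outcome column (default `"poor"`).
#' @param alpha Entry threshold (default 0.05).
#' @param always Variables retained regardless of p-value (default
#'   `c("male", "age")`, intersected with `variables` and the frame).
#' @return List with `fits` (named list of `logistic_fit`), `selected`
#'   (character) and `skipped` (named character of reasons).
#' @export
univariable_screen <- function(records, variables, outcome = "poor",
                               alpha = 0.05, always = c("male", "age")) {
  fits <- list()
  skipped <- character(0)
  pvals <- setNames(rep(NA_real_, length(variables)), variables)
  for (v in variables) {
    val <- records[[v]]
    if (is.null(val)) {
      skipped[v] <- "not present"
      next
    }
    if (sd(as.numeric(val), na.rm = TRUE) %in% c(0, NA)) {
      skipped[v] <- "zero variance"
      next
    }
    res <- tryCatch(
      fit_logistic(records[[outcome]], setNames(data.frame(val), v)),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[v] <- conditionMessage(res)
    } else {
      fits[[v]] <- res
      pvals[v] <- res$p_value[2L]
    }
  }
  selected <- union(intersect(always, intersect(variables, names(records))),
                    names(pvals)[!is.na(pvals) & pvals < alpha])
  list(fits = fits, selected = selected, skipped = skipped)
}

#' ROC curve with Youden-optimal cutoff
#'
#' Builds the empirical ROC of a continuous score against binary labels
#' under the classification rule `score > threshold` predicts the positive
#' (poor-outcome) class. Candidate thresholds are the unique observed scores;
#' AUC is the trapezoidal area under the (FPR, TPR) polygon including its
#' (0,0) and (1,1) endpoints; the reported cutoff maximises the Youden index
#' `J = sensitivity + specificity - 1`, ties broken toward the smallest
#' (most sensitive) threshold.
#'
#' @param scores Finite numeric scores (higher = more likely positive).
#' @param labels Logical or 0/1 labels; both classes required.
#' @return A `roc_result`: `thresholds`, `sensitivity`, `specificity`,
#'   `auc`, `youden_cutoff`, `youden_value`, `n_pos`, `n_neg`.
#' @examples
#' roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_youden <- function(scores, labels) {
  check_numeric(scores, "scores")
  if (any(!is.finite(scores))) {
    stop_mcasym("scores must be finite", "mcasym_validation_error")
  }
  y <- as.logical(labels)
  if (anyNA(y) || length(y) != length(scores)) {
    stop_mcasym("labels must be a complete binary vector matching scores",
                "mcasym_validation_error")
  }
  if (all(y) || !any(y)) {
    stop_mcasym("both outcome classes must be present",
                "mcasym_validation_error")
  }
  pos <- scores[y]; neg <- scores[!y]
  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
  # sweep thresholds from +Inf (0,0) to -Inf (1,1); fpr/tpr are
  # non-increasing in thr, so reverse for the integration order
  xs <- c(0, rev(fpr), 1)
  ys <- c(0, rev(tpr), 1)
  auc <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  j <- tpr + (1 - fpr) - 1
  # distinct J values differ by >= 1/(n_pos * n_neg); the 1e-9 band only
  # absorbs floating-point noise in genuine ties, broken toward the smallest
  # (most sensitive) threshold
  best <- which(j >= max(j) - 1e-9)[1L]
  structure(list(thresholds = thr, sensitivity = tpr, specificity = 1 - fpr,
                 auc = auc, youden_cutoff = thr[best], youden_value = j[best],
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f; Youden cutoff > %g (J = %.3f, sens %.3f, spec %.3f); %d pos / %d neg\n",
    x$auc, x$youden_cutoff, x$youden_value,
    x$sensitivity[match(x$youden_cutoff, x$thresholds)],
    x$specificity[match(x$youden_cutoff, x$thresholds)], x$n_pos, x$n_neg))
  invisible(x)
}

#' Adjusted model for the dichotomised asymmetry index
#'
#' Replaces the continuous overall MCA asymmetry index by the indicator
#' `overall asymmetry > cutoff` (strict inequality, higher asymmetry =
#' predicted poor) and fits the covariate-adjusted logistic model.
#'
#' @param records Analysis frame containing the asymmetry and covariate
#'   columns plus the outcome.
#' @param cutoff Cutoff in percent (e.g. the [roc_youden()] cutoff).
#' @param covariates Adjustment covariates (default [adjustment_covariates()]).
#' @param asym_col Asymmetry column name (default `"idx_asym_overall"`).
#' @param outcome Outcome column name (default `"poor"`).
#' @return A `logistic_fit`; the indicator predictor is named
#'   `asym_gt_cutoff`.
#' @export
dichotomized_fit <- function(records, cutoff,
                             covariates = adjustment_covariates(),
                             asym_col = "idx_asym_overall",
                             outcome = "poor") {
  if (is.null(records[[asym_col]])) {
    stop_mcasym(sprintf("column '%s' not found", asym_col),
                "mcasym_validation_error")
  }
  X <- records[, covariates, drop = FALSE]
  X <- cbind(asym_gt_cutoff = as.numeric(records[[asym_col]] > cutoff), X)
  fit_logistic(records[[outcome]], X)
}

#' Inter-rater intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC from the
#' standard two-way ANOVA mean squares of a subjects x raters matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. The p-value
#' tests ICC = 0 via `F = MSR / MSE` on `(n - 1, (n - 1)(k - 1))` degrees of
#' freedom.
#'
#' @param ratings Numeric matrix, `n >= 3` subjects in rows, exactly 2 raters
#'   in columns, no missing cells.
#' @return An `icc_result`: `icc`, `p_value`, `model` descriptor and the
#'   ANOVA mean squares.
#' @examples
#' icc(cbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))  # 10/13
#' @export
icc <- function(ratings) {
  m <- as.matrix(ratings)
  if (!is.numeric(m) || anyNA(m)) {
    stop_mcasym("ratings must be a complete numeric matrix",
                "mcasym_validation_error")
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k != 2L) {
    stop_mcasym("need >= 3 subjects and exactly 2 raters",
                "mcasym_validation_error")
  }
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0) {
    stop_mcasym("ICC undefined: zero between-subject variance",
                "mcasym_degenerate_icc_error")
  }
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  p <- if (mse == 0) 0 else pf(msr / mse, n - 1, (n - 1) * (k - 1),
                               lower.tail = FALSE)
  structure(list(icc = est, p_value = p,
                 model = "two-way random, absolute agreement, single measures",
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (p = %.4g; %s; n = %d subjects)\n",
              x$icc, x$p_value, x$model, x$n))
  invisible(x)
}
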