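# Logistic fits, ROC/Youden, ICC.

# expand a 2x2 table (rows: exposed/unexposed, cols: poor/good) into vectors
table_to_vectors <- function(tab) {
  y <- c(rep(1, tab[1, 1]), rep(0, tab[1, 2]), rep(1, tab[2, 1]),
         rep(0, tab[2, 2]))
  x <- c(rep(1, sum(tab[1, ])), rep(0, sum(tab[2, ])))
  list(y = y, x = x)
}

test_that("single-binary-predictor logistic OR equals the closed-form ad/bc", {
  for (tab in list(rbind(c(10, 5), c(5, 10)), rbind(c(8, 2), c(2, 8)))) {
    v <- table_to_vectors(tab)
    fit <- fit_logistic(v$y, data.frame(x = v$x))
    expect_equal(unname(fit$or["x"]),
                 (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
                 tolerance = 1e-7)
  }
  # null predictor: identical distribution in both classes -> OR = 1
  v <- table_to_vectors(rbind(c(10, 10), c(10, 10)))
  fit <- fit_logistic(v$y, data.frame(x = v$x))
  expect_equal(unname(fit$or["x"]), 1, tolerance = 1e-7)
})

test_that("logistic OR equals ad/bc on 100 random 2x2 tables to 6 significant figures", {
  set.seed(41)
  done <- 0
  while (done < 100) {
    tab <- matrix(sample(2:25, 4, replace = TRUE), 2)
    v <- table_to_vectors(tab)
    fit <- fit_logistic(v$y, data.frame(x = v$x))
    expect_equal(unname(fit$or["x"]),
                 (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
                 tolerance = 1e-6)
    done <- done + 1
  }
})

test_that("Wald intervals bracket the OR and use exp(beta +/- 1.96 se)", {
  set.seed(42)
  x <- rnorm(300)
  y <- runif(300) < plogis(-1 + 0.8 * x)
  fit <- fit_logistic(y, data.frame(x = x))
  expect_true(all(fit$ci_lower < fit$or & fit$or < fit$ci_upper))
  expect_equal(unname(fit$ci_upper["x"]),
               exp(unname(fit$coefficients["x"] + 1.96 * fit$se["x"])))
  expect_equal(fit$or, exp(fit$coefficients))
  expect_equal(fit$n, 300)
})

test_that("logistic preconditions and failure modes are explicit errors", {
  y <- rep(c(0, 1), 10)
  expect_error(fit_logistic(y[1:8], data.frame(x = rnorm(8))),
               class = "mcasym_validation_error")
  expect_error(fit_logistic(rep(1, 20), data.frame(x = rnorm(20))),
               class = "mcasym_validation_error")
  expect_error(fit_logistic(y, data.frame(x = rep(2, 20))),
               class = "mcasym_constant_predictor_error")
  x <- rnorm(20)
  expect_error(fit_logistic(y, data.frame(a = x, b = 2 * x)),
               regexp = "collinear.*b", class = "mcasym_singular_design_error")
  # perfect separation names the separating predictor
  xs <- c(rnorm(10, -5), rnorm(10, 5))
  ys <- xs > 0
  expect_error(fit_logistic(ys, data.frame(sep = xs, noise = rnorm(20))),
               regexp = "'sep'", class = "mcasym_separation_error")
})

test_that("univariable screen flags planted predictors, keeps sex/age, skips degenerate ones", {
  set.seed(43)
  n <- 400
  df <- data.frame(male = runif(n) < 0.5, age = rnorm(n, 60, 10),
                   planted = rnorm(n), noise = rnorm(n),
                   flat = rep(1, n))
  df$poor <- runif(n) < plogis(-1.5 + 1.2 * df$planted)
  sc <- univariable_screen(df, c("age", "planted", "noise", "flat", "male"))
  expect_true("planted" %in% sc$selected)
  expect_false("noise" %in% sc$selected)
  expect_true(all(c("male", "age") %in% sc$selected))
  expect_identical(sc$skipped[["flat"]], "zero variance")
  expect_identical(univariable_screen(df, character(0))$fits, list())
})

test_that("roc_youden reproduces worked examples", {
  r <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_cutoff, 2)
  expect_equal(r$youden_value, 1)
  expect_equal(roc_youden(c(1, 2, 3, 4), c(1, 0, 1, 0))$auc, 0.25)
  expect_error(roc_youden(1:4, rep(1, 4)), class = "mcasym_validation_error")
  expect_error(roc_youden(c(1, Inf), c(0, 1)),
               class = "mcasym_validation_error")
})

test_that("roc_youden matches the brute-force oracle on random instances (ties included)", {
  set.seed(44)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(seq_len(12), n, replace = TRUE) / 2  # many ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    r <- roc_youden(scores, labels)
    o <- oracle_roc(scores, labels)
    expect_equal(r$auc, o$auc)
    expect_equal(r$youden_cutoff, o$youden_cutoff)
    expect_equal(r$youden_value, o$youden_value)
  }
})

test_that("AUC and cutoff ordering are invariant under monotone score transforms", {
  set.seed(45)
  scores <- rnorm(60)
  labels <- runif(60) < plogis(scores)
  if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
  r1 <- roc_youden(scores, labels)
  r2 <- roc_youden(exp(2 * scores) + 5, labels)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$youden_value, r2$youden_value)
  expect_equal(exp(2 * r1$youden_cutoff) + 5, r2$youden_cutoff)
})

test_that("null-score AUC approaches 1/2 at large n", {
  set.seed(46)
  r <- roc_youden(rnorm(4000), runif(4000) < 0.3)
  expect_equal(r$auc, 0.5, tolerance = 0.05)
})

test_that("dichotomized_fit collapses to the closed-form 2x2 OR on a hand-built toy set", {
  # 8 exposed (asym > 9): 4 poor; 8 unexposed: 1 poor -> OR = (4*7)/(4*1) = 7
  df <- data.frame(idx_asym_overall = c(rep(12, 8), rep(3, 8)),
                   poor = c(rep(TRUE, 4), rep(FALSE, 4),
                            TRUE, rep(FALSE, 7)))
  fit <- dichotomized_fit(df, cutoff = 9, covariates = character(0))
  expect_equal(unname(fit$or["asym_gt_cutoff"]), 7, tolerance = 1e-6)
  # cutoff below the sample minimum -> constant indicator -> explicit error
  expect_error(dichotomized_fit(df, cutoff = 1, covariates = character(0)),
               class = "mcasym_constant_predictor_error")
})

test_that("icc reproduces the ANOVA oracle and worked examples", {
  expect_equal(icc(cbind(1:4, 1:4))$icc, 1)
  r <- icc(cbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  expect_equal(r$icc, 10 / 13)  # hand-derived ANOVA arithmetic
  expect_equal(r$p_value, 0)    # MSE = 0: perfect consistency
  set.seed(47)
  for (i in 1:20) {
    m <- matrix(rnorm(2 * sample(5:30, 1)), ncol = 2)
    m[, 2] <- m[, 1] + rnorm(nrow(m), 0.2, 0.4)
    expect_equal(icc(m)$icc, oracle_icc_a1(m), tolerance = 1e-10)
    expect_lt(icc(m)$icc, 1 + 1e-12)
  }
})

test_that("icc properties: constant shift invariance, null behaviour, errors", {
  set.seed(48)
  m <- matrix(rnorm(40), ncol = 2)
  m[, 2] <- m[, 1] + rnorm(20, 0, 0.3)
  expect_equal(icc(m + 7.3)$icc, icc(m)$icc, tolerance = 1e-10)
  big <- cbind(rnorm(400), rnorm(400))  # independent raters -> ICC near 0
  expect_lt(abs(icc(big)$icc), 0.15)
  expect_error(icc(cbind(rep(1, 5), rep(1, 5))),
               class = "mcasym_degenerate_icc_error")
  expect_error(icc(cbind(1:2, 1:2)), class = "mcasym_validation_error")
  expect_error(icc(matrix(rnorm(9), 3)), class = "mcasym_validation_error")
})
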