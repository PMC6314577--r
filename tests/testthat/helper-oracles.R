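# Independent brute-force oracles. These deliberately avoid the package's
# code paths: enumeration over rank subsets / hypergeometric tables /
# thresholds, and ANOVA mean squares via stats::aov.

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# combined tie-free sample into groups of the observed sizes.
oracle_mw_exact <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  stopifnot(!anyNA(r), length(unique(r)) == length(r))  # tie-free
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subs <- utils::combn(length(r), n1)
  u_all <- colSums(matrix(r[subs], nrow = n1)) - n1 * (n1 + 1) / 2
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided Fisher p for a 2x2 table: sum of hypergeometric probabilities of
# all tables with the observed margins that are no more probable.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  a_all <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(a_all, c1, n - c1, r1)
  p_obs <- stats::dhyper(a_obs, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# ROC by direct counting at every unique threshold (rule: score > t).
oracle_roc <- function(scores, labels) {
  y <- as.logical(labels)
  thr <- sort(unique(scores))
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores > thr[i]
    sens[i] <- sum(pred & y) / sum(y)
    spec[i] <- sum(!pred & !y) / sum(!y)
  }
  j <- sens + spec - 1
  # trapezoid over the (FPR, TPR) polygon, sweeping threshold downward
  fpr <- c(0, rev(1 - spec), 1)
  tpr <- c(0, rev(sens), 1)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, youden_cutoff = thr[which(j >= max(j) - 1e-9)[1]],
       youden_value = max(j))
}

# ICC(A,1) from aov() mean squares (independent of the package's direct
# sum-of-squares arithmetic).
oracle_icc_a1 <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# The 4-sample worked profile chain, recomputed with literal arithmetic.
oracle_toy_profile <- function() {
  mv <- function(p, e) e + (p - e) / 3
  pii <- function(p, e) (p - e) / mv(p, e)
  idx <- function(m, p) 100 * (m + 10 * p) / (m - 10 * p)
  r1 <- idx(mv(90, 45), pii(90, 45))
  r2 <- idx(mv(84, 42), pii(84, 42))
  l1 <- idx(mv(75, 45), pii(75, 45))
  l2 <- idx(mv(72, 42), pii(72, 42))
  rm <- (r1 + r2) / 2; lm <- (l1 + l2) / 2
  list(r1 = r1, r2 = r2, l1 = l1, l2 = l2,
       overall = 200 * abs(rm - lm) / (rm + lm))
}

toy_samples <- function() {
  data.frame(patient_id = 1,
             side = c("R", "R", "L", "L"),
             depth_mm = c(60, 50, 60, 50),
             psv_cms = c(90, 84, 75, 72),
             edv_cms = c(45, 42, 45, 42))
}
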