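# Inferential layer: Spearman correlations with Fisher-z confidence
# intervals, Meng's test for overlapping dependent correlations, one-sample
# and paired t-tests, one-way repeated-measures ANOVA, BCa-bootstrap linear
# mediation, and the within-subject block-wise regression.

#' Spearman correlation with confidence interval
#'
#' Spearman's rho computed as the Pearson correlation of average ranks;
#' two-tailed p from the t approximation with n-2 degrees of freedom; CI
#' from the Fisher transform of rho with variance `1.06/(n-3)`.
#'
#' @param x,y numeric vectors of equal length (n >= 4, no missing values).
#' @param conf confidence level (default 0.95).
#' @return list with `rho`, `ci_low`, `ci_high`, `df`, `p`, `n`.
#' @export
spearman_ci <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stopf("missing values not allowed")
  n <- length(x)
  if (n < 4L) stopf("need n >= 4")
  if (sd(x) == 0 || sd(y) == 0) stopf("constant input vector")
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  se <- sqrt(1.06 / (n - 3))
  zc <- qnorm(1 - (1 - conf) / 2)
  ci <- tanh(fisher_z(rho) + c(-1, 1) * zc * se)
  list(rho = rho, ci_low = ci[1], ci_high = ci[2], df = n - 2L,
       p = min(p, 1), n = n)
}

#' Meng's z-test for two overlapping dependent correlations
#'
#' Compares rho(x, y1) with rho(x, y2) measured on the same n cases, given
#' the correlation between y1 and y2. Uses the Meng-Rosenthal-Rubin
#' statistic on Fisher-transformed correlations with the f/h adjustment
#' terms, and a CI for the Fisher-scale difference z1 - z2.
#'
#' @param ry1 correlation of x with y1.
#' @param ry2 correlation of x with y2.
#' @param r12 correlation of y1 with y2.
#' @param n sample size (> 3).
#' @param conf confidence level (default 0.95).
#' @return list with `z`, `p`, `diff` (z1 - z2 on the Fisher scale),
#'   `ci_low`, `ci_high`.
#' @export
meng_compare <- function(ry1, ry2, r12, n, conf = 0.95) {
  if (any(abs(c(ry1, ry2, r12)) >= 1)) {
    stopf("degenerate input: |r| must be < 1")
  }
  if (n <= 3) stopf("need n > 3")
  z1 <- atanh(ry1)
  z2 <- atanh(ry2)
  r2bar <- (ry1^2 + ry2^2) / 2
  f <- min((1 - r12) / (2 * (1 - r2bar)), 1)
  h <- (1 - f * r2bar) / (1 - r2bar)
  se <- sqrt(2 * (1 - r12) * h / (n - 3))
  z <- (z1 - z2) / se
  zc <- qnorm(1 - (1 - conf) / 2)
  list(z = z, p = 2 * pnorm(-abs(z)), diff = z1 - z2,
       ci_low = z1 - z2 - zc * se, ci_high = z1 - z2 + zc * se)
}

#' One-sample t-test
#'
#' @param x numeric vector (n >= 2, nonzero variance).
#' @param mu0 null value (default 0).
#' @return list with `t`, `df`, `p`, `mean`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  n <- length(x)
  if (n < 2L) stopf("need n >= 2")
  s <- sd(x)
  if (s == 0) stopf("zero variance")
  tstat <- (mean(x) - mu0) / (s / sqrt(n))
  list(t = tstat, df = n - 1L, p = 2 * pt(-abs(tstat), n - 1),
       mean = mean(x))
}

#' Paired t-test
#'
#' @param x,y paired numeric vectors.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  r <- one_sample_t(x - y, 0)
  list(t = r$t, df = r$df, p = r$p, mean_diff = r$mean)
}

#' One-way repeated-measures ANOVA
#'
#' Classical sums-of-squares decomposition for a complete subject x
#' condition matrix: F = MS(condition) / MS(condition x subject), with
#' df1 = k-1 and df2 = (k-1)(n-1). Sphericity is assumed (no correction).
#'
#' @param m numeric matrix, rows = subjects, columns = conditions (no
#'   missing cells, >= 2 conditions).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stopf("missing cells not allowed")
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2L) stopf("need >= 2 conditions")
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  # no condition effect at all (possibly with a saturating subject
  # effect): F is 0 by convention rather than 0/0
  fstat <- if (ss_cond <= 1e-14 * max(ss_tot, 1)) 0
           else (ss_cond / df1) / (ss_err / df2)
  list(F = fstat, df1 = df1, df2 = df2,
       p = stats::pf(fstat, df1, df2, lower.tail = FALSE))
}

# Closed-form OLS pieces for the linear mediation model, from centred
# cross-products. Returns c(a, b, cprime): a from m ~ t, (cprime, b) from
# y ~ t + m.
mediation_coefs <- function(stt, smm, stm, sty, smy) {
  det <- stt * smm - stm^2
  a <- stm / stt
  b <- (stt * smy - stm * sty) / det
  cprime <- (smm * sty - stm * smy) / det
  c(a = a, b = b, cprime = cprime)
}

# BCa interval endpoints and the smallest alpha excluding zero.
bca_ci <- function(boot, est, jack, conf) {
  alpha <- 1 - conf
  z0 <- qnorm(mean(boot < est) + 0.5 * mean(boot == est))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  acc <- if (den == 0) 0 else num / den
  adj <- function(a) {
    zq <- qnorm(a)
    pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
  }
  ci <- quantile(boot, c(adj(alpha / 2), adj(1 - alpha / 2)),
                 names = FALSE, type = 6)
  # p-value: smallest alpha at which the BCa interval excludes zero,
  # inverted analytically from the proportion of bootstrap mass below 0
  p0 <- mean(boot < 0) + 0.5 * mean(boot == 0)
  p0 <- min(max(p0, 1 / (length(boot) + 1)),
            1 - 1 / (length(boot) + 1))
  w <- qnorm(p0)
  zq <- (w - z0) / (1 + acc * (w - z0)) - z0
  p_one <- pnorm(zq)
  list(ci_low = ci[1], ci_high = ci[2],
       p = min(2 * min(p_one, 1 - p_one), 1), z0 = z0, acc = acc)
}

#' Linear mediation analysis with BCa bootstrap
#'
#' Fits `mediator ~ treatment` (coefficient a) and
#' `outcome ~ treatment + mediator` (coefficients c', b) by OLS; the
#' average causal mediation effect is ACME = a*b, the average direct
#' effect ADE = c', and total = a*b + c' (an identity that holds per
#' bootstrap draw in this linear model). Confidence intervals are
#' nonparametric case-resampling bootstrap with bias-corrected and
#' accelerated (BCa) endpoints (bias correction from the proportion of
#' bootstrap estimates below the point estimate, acceleration from the
#' jackknife); the p-value is the smallest alpha at which the BCa interval
#' excludes zero.
#'
#' @param treatment,mediator,outcome numeric vectors of equal length
#'   (n >= 10).
#' @param n_boot bootstrap draws (the emulated analysis used 10000;
#'   tests use 999).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return object of class `mediation`: list with `acme`, `ade`, `total`,
#'   `prop_mediated`, each a list (`est`, `ci_low`, `ci_high`, `p`), plus
#'   `n`, `n_boot` and the per-draw identity residual
#'   `max_decomp_error`.
#' @export
mediation_bootstrap <- function(treatment, mediator, outcome,
                                n_boot = 999L, seed = 1L, conf = 0.95) {
  n <- length(treatment)
  if (length(mediator) != n || length(outcome) != n) {
    stopf("treatment, mediator and outcome must have equal length")
  }
  if (n < 10L) stopf("need n >= 10")
  cross <- function(t, m, y) {
    tc <- t - mean(t); mc <- m - mean(m); yc <- y - mean(y)
    stt <- sum(tc^2)
    smm <- sum(mc^2)
    stm <- sum(tc * mc)
    if (stt == 0 || smm == 0 || stt * smm - stm^2 <= 1e-12 * stt * smm) {
      stopf("collinear or constant predictors in mediation model")
    }
    mediation_coefs(stt, smm, stm, sum(tc * yc), sum(mc * yc))
  }
  est <- cross(treatment, mediator, outcome)
  # case-resampling bootstrap, vectorised over draws via column sums
  idx <- with_seed(seed,
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n))
  Tb <- matrix(treatment[idx], nrow = n)
  Mb <- matrix(mediator[idx], nrow = n)
  Yb <- matrix(outcome[idx], nrow = n)
  st <- colSums(Tb); sm <- colSums(Mb); sy <- colSums(Yb)
  stt <- colSums(Tb^2) - st^2 / n
  smm <- colSums(Mb^2) - sm^2 / n
  stm <- colSums(Tb * Mb) - st * sm / n
  sty <- colSums(Tb * Yb) - st * sy / n
  smy <- colSums(Mb * Yb) - sm * sy / n
  det <- stt * smm - stm^2
  a_b <- stm / stt
  b_b <- (stt * smy - stm * sty) / det
  c_b <- (smm * sty - stm * smy) / det
  boot <- list(acme = a_b * b_b, ade = c_b, total = a_b * b_b + c_b)
  # jackknife (leave-one-out closed form) for the acceleration constant
  st <- sum(treatment); sm <- sum(mediator); sy <- sum(outcome)
  s_tt <- sum(treatment^2); s_mm <- sum(mediator^2)
  s_tm <- sum(treatment * mediator)
  s_ty <- sum(treatment * outcome); s_my <- sum(mediator * outcome)
  n1 <- n - 1
  jt <- st - treatment; jm <- sm - mediator; jy <- sy - outcome
  jtt <- s_tt - treatment^2 - jt^2 / n1
  jmm <- s_mm - mediator^2 - jm^2 / n1
  jtm <- s_tm - treatment * mediator - jt * jm / n1
  jty <- s_ty - treatment * outcome - jt * jy / n1
  jmy <- s_my - mediator * outcome - jm * jy / n1
  jdet <- jtt * jmm - jtm^2
  ja <- jtm / jtt
  jb <- (jtt * jmy - jtm * jty) / jdet
  jc <- (jmm * jty - jtm * jmy) / jdet
  jack <- list(acme = ja * jb, ade = jc, total = ja * jb + jc)
  point <- list(acme = unname(est["a"] * est["b"]),
                ade = unname(est["cprime"]),
                total = unname(est["a"] * est["b"] + est["cprime"]))
  out <- lapply(c(acme = "acme", ade = "ade", total = "total"),
                function(k) {
    ci <- bca_ci(boot[[k]], point[[k]], jack[[k]], conf)
    list(est = point[[k]], ci_low = ci$ci_low, ci_high = ci$ci_high,
         p = ci$p)
  })
  out$prop_mediated <- list(
    est = if (point$total == 0) NA_real_ else point$acme / point$total)
  out$a <- unname(est["a"])
  out$b <- unname(est["b"])
  out$n <- n
  out$n_boot <- as.integer(n_boot)
  out$max_decomp_error <- max(abs(boot$acme + boot$ade - boot$total))
  class(out) <- "mediation"
  out
}

#' @export
print.mediation <- function(x, ...) {
  fmt <- function(e, nm) {
    cat(sprintf("  %-6s %8.4f  [%7.4f, %7.4f]  p = %.4g\n", nm, e$est,
                e$ci_low, e$ci_high, e$p))
  }
  cat(sprintf("Causal mediation (linear, BCa bootstrap, %d draws, n = %d)\n",
              x$n_boot, x$n))
  fmt(x$acme, "ACME")
  fmt(x$ade, "ADE")
  fmt(x$total, "Total")
  invisible(x)
}

#' Within-subject block-wise regression
#'
#' Per subject, fits the two block-level models
#' `pRT_i = w0 + w1 * DMN_strength_i` and
#' `pRT_i = w0 + w1 * load_i + w2 * DMN_strength_i` over the task blocks,
#' and tests the DMN-strength coefficient against zero across subjects
#' with a one-sample t-test.
#'
#' @param block_prt list (one element per subject) of block-wise pRT
#'   vectors, or a subjects x blocks matrix.
#' @param block_strength block-wise DMN strengths, same shape.
#' @param block_load block-wise load levels, same shape (or a single
#'   vector shared by all subjects).
#' @return list with `per_subject` (data frame of coefficients
#'   `w1_simple`, `w1_load`, `w2_adjusted`) and `group` (one-sample t on
#'   each coefficient).
#' @export
within_subject_regression <- function(block_prt, block_strength,
                                      block_load) {
  as_rows <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
    else if (is.list(x)) x
    else list(x)
  }
  prt <- as_rows(block_prt)
  str <- as_rows(block_strength)
  if (!is.list(block_load) && !is.matrix(block_load)) {
    load <- rep(list(block_load), length(prt))
  } else {
    load <- as_rows(block_load)
  }
  per <- do.call(rbind, lapply(seq_along(prt), function(i) {
    y <- prt[[i]]; s <- str[[i]]; L <- load[[i]]
    if (length(y) != length(s) || length(y) != length(L)) {
      stopf("subject %d: block vectors differ in length", i)
    }
    X <- cbind(1, L, s)
    if (qr(X)$rank < 3L) stopf("subject %d: rank-deficient design", i)
    simple <- lm.fit(cbind(1, s), y)$coefficients
    full <- lm.fit(X, y)$coefficients
    data.frame(subject = i, w1_simple = unname(simple[2]),
               w1_load = unname(full[2]), w2_adjusted = unname(full[3]))
  }))
  group <- if (nrow(per) >= 2L) {
    list(simple = one_sample_t(per$w1_simple),
         adjusted = one_sample_t(per$w2_adjusted),
         load = one_sample_t(per$w1_load))
  } else {
    NULL
  }
  list(per_subject = per, group = group)
}
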