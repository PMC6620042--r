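# Inferential layer: Spearman CI, Meng comparison, t-tests, RM-ANOVA,
# BCa mediation, within-subject regression.

test_that("Spearman rho matches rank-Pearson and base R", {
  expect_equal(spearman_ci(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_ci(1:5, rev(1:5))$rho, -1)
  r <- spearman_ci(1:5, c(1, 3, 2, 5, 4))
  expect_equal(r$rho, cor(1:5, c(1, 3, 2, 5, 4), method = "spearman"))
  expect_equal(r$rho, 0.8)
  expect_equal(r$df, 3L)
  # ties handled with average ranks, agreeing with base R
  set.seed(41)
  x <- sample(1:5, 30, replace = TRUE)
  y <- x + sample(0:2, 30, replace = TRUE)
  expect_equal(spearman_ci(x, y)$rho, cor(x, y, method = "spearman"))
  # CI brackets the point estimate
  rr <- spearman_ci(rnorm(30), rnorm(30))
  expect_true(rr$ci_low <= rr$rho && rr$rho <= rr$ci_high)
  expect_true(rr$p >= 0 && rr$p <= 1)
  expect_error(spearman_ci(rep(1, 10), 1:10), "constant")
  expect_error(spearman_ci(1:3, 1:3), "n >= 4")
})

test_that("Meng comparison is antisymmetric and null at equality", {
  m0 <- meng_compare(0.4, 0.4, 0.3, 50)
  expect_equal(m0$z, 0)
  expect_equal(m0$p, 1)
  m1 <- meng_compare(0.5, 0.2, 0.3, 50)
  m2 <- meng_compare(0.2, 0.5, 0.3, 50)
  expect_equal(m1$z, -m2$z)
  expect_equal(m1$p, m2$p)
  expect_true(m1$ci_low <= m1$diff && m1$diff <= m1$ci_high)
  expect_error(meng_compare(1, 0.5, 0.3, 50), "degenerate")
})

test_that("Meng rejection decisions agree with a case-bootstrap oracle", {
  # trivariate Gaussians at n = 2000; decisions are clear-cut away from
  # the boundary, so the analytic test and a percentile bootstrap of
  # z1 - z2 must agree
  boot_decide <- function(x, y1, y2, B = 800) {
    n <- length(x)
    d <- vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      atanh(cor(x[i], y1[i])) - atanh(cor(x[i], y2[i]))
    }, numeric(1))
    q <- quantile(d, c(0.025, 0.975))
    q[1] > 0 || q[2] < 0
  }
  configs <- list(c(b1 = 0.5, b2 = 0.1), c(b1 = 0.45, b2 = 0.45),
                  c(b1 = 0.0, b2 = 0.4), c(b1 = 0.3, b2 = 0.3))
  set.seed(42)
  for (cfg in configs) {
    n <- 2000
    x <- rnorm(n)
    y1 <- cfg["b1"] * x + rnorm(n)
    y2 <- cfg["b2"] * x + rnorm(n)
    mg <- meng_compare(cor(x, y1), cor(x, y2), cor(y1, y2), n)
    expect_equal(mg$p < 0.05, boot_decide(x, y1, y2),
                 label = paste(cfg, collapse = "/"))
  }
})

test_that("one-sample and paired t match hand computation", {
  expect_equal(one_sample_t(c(1, 2, 3))$t, 2 / (1 / sqrt(3)),
               tolerance = 1e-12)
  expect_equal(one_sample_t(c(1, 2, 3))$df, 2L)
  expect_equal(one_sample_t(c(-1, 0, 1))$t, 0)
  expect_equal(one_sample_t(rnorm(51))$df, 50L)
  # agreement with stats::t.test
  set.seed(43)
  x <- rnorm(20, 0.3)
  y <- rnorm(20)
  tt <- t.test(x, mu = 0.1)
  r <- one_sample_t(x, 0.1)
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)
  pt_ <- paired_t(x, y)
  tt2 <- t.test(x, y, paired = TRUE)
  expect_equal(pt_$t, unname(tt2$statistic))
  expect_equal(pt_$p, tt2$p.value)
  expect_error(one_sample_t(rep(2, 5)), "zero variance")
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  # 4-subject toy table, from-scratch SS decomposition
  m <- rbind(c(1.0, 1.2, 1.9), c(0.8, 1.1, 1.4), c(1.1, 1.0, 1.7),
             c(0.9, 1.4, 1.6))
  r <- rm_anova(m)
  expect_equal(r$df1, 2L)
  expect_equal(r$df2, 6L)
  # independent oracle via aov's Error(subject) stratum
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(1:4, 3)),
                   cond = factor(rep(1:3, each = 4)))
  a <- summary(stats::aov(y ~ cond + Error(subj), data = df))
  tab <- a[["Error: Within"]][[1]]
  expect_equal(r$F, tab["cond", "F value"], tolerance = 1e-10)
  expect_equal(r$p, tab["cond", "Pr(>F)"], tolerance = 1e-10)
  # identical patterns -> F = 0
  flat <- matrix(rep(c(1, 2, 1.5), each = 4), 4)
  flat_f <- rm_anova(flat + 0)
  expect_gt(flat_f$F, 0) # condition effect present
  same <- matrix(1:4, 4, 3) # no condition effect at all
  expect_equal(rm_anova(same)$F, 0)
  # 51 x 3 gives the df pair (2, 100)
  big <- matrix(rnorm(153), 51, 3)
  rb <- rm_anova(big)
  expect_equal(c(rb$df1, rb$df2), c(2L, 100L))
  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("mediation estimates the product of coefficients", {
  set.seed(44)
  n <- 10000
  t <- rnorm(n)
  m <- 0.5 * t + rnorm(n)
  y <- 0.4 * m + rnorm(n)
  fit <- mediation_bootstrap(t, m, y, n_boot = 199, seed = 1)
  expect_lt(abs(fit$acme$est - 0.2), 0.02)
  expect_lt(abs(fit$ade$est), 0.03)
  # per-draw linear decomposition holds exactly
  expect_lt(fit$max_decomp_error, 1e-10)
  expect_equal(fit$total$est, fit$acme$est + fit$ade$est,
               tolerance = 1e-12)
  # OLS coefficients agree with lm
  small_t <- t[1:100]; small_m <- m[1:100]; small_y <- y[1:100]
  f2 <- mediation_bootstrap(small_t, small_m, small_y, n_boot = 99,
                            seed = 2)
  expect_equal(f2$a, unname(coef(lm(small_m ~ small_t))[2]),
               tolerance = 1e-10)
  co <- coef(lm(small_y ~ small_t + small_m))
  expect_equal(f2$ade$est, unname(co[2]), tolerance = 1e-10)
  expect_equal(f2$b, unname(co[3]), tolerance = 1e-10)
  expect_error(mediation_bootstrap(small_t, small_t, small_y),
               "collinear")
})

test_that("null mediation path keeps the ACME interval around zero", {
  # outcome independent of the mediator given treatment: the ACME CI
  # should cover 0 at roughly the nominal rate (checked loosely over 40
  # replicates)
  set.seed(45)
  cover <- vapply(1:40, function(r) {
    n <- 300
    t <- rnorm(n)
    m <- 0.5 * t + rnorm(n)
    y <- 0.3 * t + rnorm(n) # b = 0
    fit <- mediation_bootstrap(t, m, y, n_boot = 299, seed = r)
    fit$acme$ci_low <= 0 && 0 <= fit$acme$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("within-subject regression identities hold", {
  # exact recovery on noise-free linear data
  strength <- c(scale(rnorm(18, 0, 1), scale = FALSE))
  prt <- 1 - 0.1 * strength
  load <- rep(0:2, 6)
  fit <- within_subject_regression(list(prt), list(strength), load)
  expect_equal(fit$per_subject$w1_simple, -0.1, tolerance = 1e-10)
  # orthogonal strength and load: simple and adjusted coefficients equal
  set.seed(46)
  load_c <- load - mean(load)
  s_orth <- c(scale(residuals(lm(rnorm(18) ~ load_c)), scale = FALSE))
  y <- 0.5 + 0.2 * load + rnorm(18, 0, 0.1)
  f2 <- within_subject_regression(list(y), list(s_orth), load)
  expect_equal(f2$per_subject$w1_simple, f2$per_subject$w2_adjusted,
               tolerance = 1e-10)
  # rank-deficient design is an error
  expect_error(
    within_subject_regression(list(y), list(load), load),
    "rank-deficient")
  # group test: planted negative coupling across subjects is detected
  subs <- lapply(1:20, function(i) {
    s <- rnorm(18)
    list(prt = 0.8 - 0.1 * s + rnorm(18, 0, 0.05), strength = s)
  })
  g <- within_subject_regression(lapply(subs, `[[`, "prt"),
                                 lapply(subs, `[[`, "strength"),
                                 load)
  expect_lt(g$group$simple$t, 0)
  expect_lt(g$group$simple$p, 0.01)
})
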