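test_that("Kaplan-Meier product-limit matches hand computation", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 1 / 3)   # (2/3)*(1/2)
  # no censoring: 1 - empirical CDF
  km2 <- kaplan_meier(1:4, rep(1, 4))
  expect_equal(km2$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1
  km3 <- kaplan_meier(1:4, rep(0, 4))
  expect_true(all(km3$surv == 1))
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank is symmetric, null on identical groups, and matches a
          permutation oracle", {
  t0 <- c(2, 4, 6, 8, 10, 12)
  # identical survival experience in both groups
  lr0 <- logrank_test(rep(t0, 2), rep(1, 12), rep(c("a", "b"), each = 6))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-10)

  set.seed(29)
  times <- c(3, 5, 7, 9, 11, 13, 2, 4, 4, 6, 8, 20)
  events <- c(1, 1, 0, 1, 1, 1, 1, 1, 1, 0, 1, 1)
  grp <- rep(c("a", "b"), each = 6)
  lr <- logrank_test(times, events, grp)
  expect_equal(lr$p, logrank_test(times, events,
                                  ifelse(grp == "a", "b", "a"))$p)
  obs <- logrank_stat_oracle(times, events, grp)
  perm <- replicate(4000, logrank_stat_oracle(times, events, sample(grp)))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(lr$p - p_perm), 0.07)
})

test_that("Cox hazard ratios: invariance, null and recovery", {
  set.seed(43)
  # duplication leaves the partial-likelihood estimate unchanged
  tm <- rexp(30); ev <- rbinom(30, 1, 0.8); x <- rnorm(30)
  h1 <- cox_hr(tm, ev, data.frame(x = x))
  h2 <- cox_hr(rep(tm, 2), rep(ev, 2), data.frame(x = rep(x, 2)))
  expect_equal(h1$hr, h2$hr, tolerance = 1e-6)
  # independent covariate: HR ~ 1 and CI covers 1
  n <- 400
  tm2 <- rexp(n); x2 <- rnorm(n)
  h3 <- cox_hr(tm2, rep(1, n), data.frame(x = x2))
  expect_true(h3$ci_low < 1 && h3$ci_high > 1)
  expect_equal(h3$hr, 1, tolerance = 0.25)
  # true HR 2 via exponential times with rate exp(log(2) x)
  n <- 500
  x3 <- rnorm(n)
  tm3 <- rexp(n, rate = exp(log(2) * x3))
  h4 <- cox_hr(tm3, rep(1, n), data.frame(x = x3))
  expect_true(h4$ci_low < 2 && h4$ci_high > 2)
  expect_equal(h4$hr, 2, tolerance = 0.2)
  expect_error(cox_hr(c(1, 2), c(0, 0), data.frame(x = c(1, 2))), "events")
})

test_that("Mann-Whitney: exact small-sample p and the U identity", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 1 / 3)    # 2/C(4,2)
  same <- mann_whitney(rep(1, 4), rep(1, 4))
  expect_equal(same$p, 1)
  set.seed(47)
  a <- rnorm(9); b <- rnorm(7)
  ua <- mann_whitney(a, b)$u
  ub <- mann_whitney(b, a)$u
  expect_equal(ua + ub, 9 * 7)
})

test_that("bootstrap logistic AUC: degenerate and calibrated cases", {
  set.seed(53)
  y <- rep(c(0, 1), each = 10)
  flat <- bootstrap_logistic_auc(rep(1, 20), y, B = 50)
  expect_equal(flat$auc, 0.5, tolerance = 1e-9)
  sep <- bootstrap_logistic_auc(c(rnorm(10, 0), rnorm(10, 50)), y, B = 50)
  expect_equal(sep$auc_apparent, 1.0)
  expect_error(bootstrap_logistic_auc(rnorm(10), rep(1, 10), B = 10),
               "single class")
  # large-sample: bootstrap AUC near the closed-form population AUC for a
  # logistic model with slope 2 on a standard-normal feature, computed by
  # numerical integration (independent of the package helper)
  beta <- 2
  zg <- seq(-8, 8, length.out = 8001)
  w <- dnorm(zg); w <- w / sum(w)
  pi_ <- plogis(beta * zg)
  w1 <- w * pi_; w0 <- w * (1 - pi_)
  c0 <- cumsum(w0)
  auc_true <- sum(w1 * (c0 - 0.5 * w0)) / (sum(w1) * sum(w0))
  n <- 200
  x <- rnorm(n)
  yy <- rbinom(n, 1, plogis(beta * x))
  est <- bootstrap_logistic_auc(x, yy, B = 200, seed = 7)
  expect_lt(abs(est$auc - auc_true), 0.03)
  expect_true(est$specificity > 0 && est$specificity < 1)
})

test_that("Benjamini-Hochberg adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(59)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Spearman redundancy filter keeps the most significant of each
          correlated cluster", {
  set.seed(61)
  n <- 30
  a <- rnorm(n)
  dt <- data.frame(A = a, B = a + rnorm(n, 0, 0.05), C = rnorm(n))
  pv <- c(A = 0.01, B = 0.2, C = 0.03)
  expect_setequal(spearman_redundancy_filter(dt, pv), c("A", "C"))
  # two identical features: the lower-p one is kept
  dt2 <- data.frame(A = a, B = a)
  expect_identical(spearman_redundancy_filter(dt2, c(A = 0.5, B = 0.01)), "B")
  # chain correlation A~B, B~C only, built deterministically from ranks:
  # each swap of two entries 10 apart costs 6*200/(20*399) of Spearman rho
  A <- 1:20
  B <- A; B[c(1, 11)] <- B[c(11, 1)]     # rho(A,B) ~ 0.85
  C <- B; C[c(5, 15)] <- C[c(15, 5)]     # rho(B,C) ~ 0.85, rho(A,C) ~ 0.70
  dt3 <- data.frame(A = A, B = B, C = C)
  rho <- cor(dt3, method = "spearman")
  expect_gt(rho["A", "B"], 0.8)
  expect_gt(rho["B", "C"], 0.8)
  expect_lt(rho["A", "C"], 0.8)
  kept <- spearman_redundancy_filter(dt3, c(A = 0.001, B = 0.01, C = 0.5))
  expect_setequal(kept, c("A", "C"))
})

test_that("two-time-point confirmation requires significance at W2 and W5", {
  r2 <- data.frame(feature = c("f1", "f2", "f3"), endpoint = "lr",
                   p_raw = c(0.001, 0.002, 0.5),
                   p_adjusted = c(0.003, 0.006, 0.9),
                   auc = NA, specificity = NA)
  r5 <- data.frame(feature = c("f1", "f2", "f3"), endpoint = "lr",
                   p_raw = c(0.001, 0.2, 0.4),
                   p_adjusted = c(0.003, 0.4, 0.8),
                   auc = NA, specificity = NA)
  cf <- two_timepoint_confirmation(r2, r5, alpha = 0.05)
  expect_identical(cf$confirmed_w5, c(TRUE, FALSE, FALSE))
  r5bad <- r5; r5bad$feature <- c("f1", "f2", "g9")
  expect_error(two_timepoint_confirmation(r2, r5bad, 0.05), "differ")
})

test_that("an engineered cohort reproduces a 17-vs-15 confirmation pattern", {
  set.seed(67)
  n <- 60
  lab <- rep(c(0, 1), each = n / 2)
  # 17 features strongly predictive at W2; 15 of them keep the signal at W5
  f_names <- sprintf("f%02d", 1:25)
  d2 <- as.data.frame(setNames(lapply(1:25, function(i)
    if (i <= 17) c(rnorm(n / 2), rnorm(n / 2, 3)) else rnorm(n)), f_names))
  d5 <- as.data.frame(setNames(lapply(1:25, function(i)
    if (i <= 15) c(rnorm(n / 2), rnorm(n / 2, 3)) else rnorm(n)), f_names))
  outc <- data.frame(local_recurrence = lab)
  r2 <- predict_outcomes(d2, outc, endpoints = "lr", compute_auc = FALSE)
  r5 <- predict_outcomes(d5, outc, endpoints = "lr", compute_auc = FALSE)
  expect_equal(sum(r2$p_adjusted < 0.05, na.rm = TRUE), 17)
  cf <- two_timepoint_confirmation(r2, r5, alpha = 0.05)
  expect_equal(sum(cf$confirmed_w5), 15)
})

test_that("prediction tables are invariant to patient ordering", {
  set.seed(71)
  sim <- simulate_feature_cohort(n_patients = 24, n_features = 6,
                                 link_feature = 1)
  r1 <- predict_outcomes(sim$delta_w2, sim$outcomes, endpoints = c("lr", "pfs"),
                         compute_auc = FALSE)
  perm <- sample(24)
  r2 <- predict_outcomes(sim$delta_w2[perm, ], sim$outcomes[perm, ],
                         endpoints = c("lr", "pfs"), compute_auc = FALSE)
  expect_equal(r1$p_raw, r2$p_raw, tolerance = 1e-12)
})

test_that("the internal empirical AUC agrees with an independent ROC package", {
  set.seed(79)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(1.5 * x))
  if (length(unique(y)) == 2) {
    got <- hypoxrad:::empirical_auc(x, y)
    want <- as.numeric(suppressMessages(pROC::auc(y, x, direction = "<")))
    expect_equal(got, want, tolerance = 1e-12)
  }
})
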