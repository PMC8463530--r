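test_that("binary trial effects follow the 2x2 closed form with continuity correction", {
  trials <- data.frame(study_id = c("s1", "s2", "s3"), compound = "c",
                       outcome = "CVD", type = "binary",
                       t_events = c(10, 0, 0), t_total = c(100, 50, 80),
                       c_events = c(20, 5, 0), c_total = c(100, 50, 80),
                       md = NA, ci_low = NA, ci_high = NA, se = NA,
                       followup_months = 24)
  eff <- effect_from_trial(trials)

  # 10/100 vs 20/100: log-OR = ln((10*80)/(90*20)), se from cell reciprocals
  expect_equal(eff$effect[1], log((10 * 80) / (90 * 20)), tolerance = 1e-12)
  expect_equal(round(eff$effect[1], 4), -0.8109)
  expect_equal(eff$se[1], sqrt(1 / 10 + 1 / 90 + 1 / 20 + 1 / 80), tolerance = 1e-12)
  expect_equal(round(eff$se[1], 4), 0.4167)

  # one zero cell: 0.5 added to all four cells
  expect_equal(eff$effect[2], log((0.5 * 45.5) / (50.5 * 5.5)), tolerance = 1e-12)

  # zero events in both arms: excluded with a reason, not an error
  expect_equal(nrow(eff), 2)
  excl <- attr(eff, "exclusions")
  expect_equal(excl$study_id, "s3")
  expect_equal(excl$reason, "zero_events_both_arms")
})

test_that("continuous effects take MD with SE back-transformed from the CI", {
  trials <- data.frame(study_id = "s1", compound = "c", outcome = "HDL",
                       type = "continuous", t_events = NA, t_total = 500,
                       c_events = NA, c_total = 500, md = 130,
                       ci_low = 127, ci_high = 133, se = NA,
                       followup_months = 24)
  eff <- effect_from_trial(trials)
  expect_equal(eff$effect, 130)
  expect_equal(eff$se, (133 - 127) / (2 * 1.959964), tolerance = 1e-12)
  expect_equal(eff$scale, "MD")
})

test_that("a reported OR confidence interval back-transforms to the log-OR SE", {
  # torcetrapib all-cause mortality: OR 1.56 (95% CI 1.14-2.12)
  se <- se_from_ci(1.14, 2.12, log = TRUE)
  expect_equal(se, (log(2.12) - log(1.14)) / 3.919928, tolerance = 1e-6)
  expect_equal(round(se, 3), 0.158)
})

test_that("fixed-effect pooling is the precision-weighted mean", {
  one <- pool_fixed(0.3, 0.1)
  expect_equal(one$effect, 0.3)
  expect_equal(one$se, 0.1)

  two <- pool_fixed(c(0.4, 0.4), c(0.1, 0.1))
  expect_equal(two$effect, 0.4)
  expect_equal(two$se, 0.1 / sqrt(2))
  expect_equal(two$Q, 0)

  toy <- pool_fixed(c(0.2, 0.5), c(0.1, 0.2))
  expect_equal(toy$effect, 0.26, tolerance = 1e-12)   # (100*.2 + 25*.5)/125
  expect_equal(toy$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(round(toy$se, 4), 0.0894)

  expect_error(pool_fixed(c(0.1, 0.2), c(0.1, 0.1), scale = c("logOR", "MD")),
               "mixed scales")
})

test_that("DerSimonian-Laird pooling matches the moment formula and metafor", {
  # homogeneous data: tau2 = 0 and the random pool equals the fixed pool
  e <- c(0.1, 0.12, 0.11); s <- c(0.3, 0.3, 0.3)
  fx <- pool_fixed(e, s); rnd <- pool_random(e, s)
  expect_equal(rnd$tau2, 0)
  expect_equal(rnd$effect, fx$effect)
  expect_equal(rnd$se, fx$se)

  # heterogeneous toy against the DL formula written out independently
  e2 <- c(0.5, -0.2, 0.9, 0.1); s2 <- c(0.1, 0.15, 0.2, 0.12)
  w <- 1 / s2^2
  mu_f <- sum(w * e2) / sum(w)
  Q <- sum(w * (e2 - mu_f)^2)
  tau2 <- max(0, (Q - 3) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (s2^2 + tau2)
  rnd2 <- pool_random(e2, s2)
  expect_equal(rnd2$tau2, tau2, tolerance = 1e-12)
  expect_equal(rnd2$effect, sum(w_star * e2) / sum(w_star), tolerance = 1e-12)
  expect_equal(rnd2$se, 1 / sqrt(sum(w_star)), tolerance = 1e-12)

  skip_if_not_installed("metafor")
  mf <- metafor::rma(yi = e2, sei = s2, method = "DL")
  expect_equal(rnd2$effect, unname(coef(mf)), tolerance = 1e-10)
  expect_equal(rnd2$se, unname(mf$se), tolerance = 1e-10)
  expect_equal(rnd2$tau2, unname(mf$tau2), tolerance = 1e-10)
  ff <- metafor::rma(yi = e2, sei = s2, method = "FE")
  fx2 <- pool_fixed(e2, s2)
  expect_equal(fx2$effect, unname(coef(ff)), tolerance = 1e-10)
  expect_equal(fx2$se, unname(ff$se), tolerance = 1e-10)

  # single study warns and returns itself
  expect_warning(single <- pool_random(0.2, 0.1), "single study")
  expect_equal(single$effect, 0.2)
  expect_equal(single$tau2, 0)
})

test_that("pooling is order-invariant, bounded by its inputs, and RE se >= FE se", {
  set.seed(53)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    e <- rnorm(k); s <- runif(k, 0.05, 0.5)
    fx <- pool_fixed(e, s)
    perm <- sample(k)
    expect_equal(pool_fixed(e[perm], s[perm])$effect, fx$effect, tolerance = 1e-12)
    expect_gte(fx$effect, min(e)); expect_lte(fx$effect, max(e))
    rnd <- pool_random(e, s)
    expect_gte(rnd$tau2, 0)
    expect_gte(rnd$se, fx$se - 1e-15)
  }
})

test_that("between-compound Q treats each compound pool as one unit", {
  a <- pool_fixed(c(0.2, 0.2), c(0.1, 0.1), scale = "logOR")
  expect_equal(between_compound_q(list(a, a))$Q, 0)
  expect_equal(between_compound_q(list(a, a))$p, 1)

  # two printed compound estimates (log-OR scale)
  est <- data.frame(effect = c(0.4447, -0.1744), se = c(0.1583, 0.0874))
  w <- 1 / est$se^2
  overall <- sum(w * est$effect) / sum(w)
  q_hand <- sum(w * (est$effect - overall)^2)
  got <- between_compound_q(est)
  expect_equal(got$Q, q_hand, tolerance = 1e-12)
  expect_equal(got$df, 1)
  expect_equal(got$p, pchisq(q_hand, 1, lower.tail = FALSE), tolerance = 1e-12)

  # four-compound toy against the same brute-force expansion
  set.seed(59)
  est4 <- data.frame(effect = rnorm(4), se = runif(4, 0.05, 0.3))
  w4 <- 1 / est4$se^2
  ov4 <- sum(w4 * est4$effect) / sum(w4)
  expect_equal(between_compound_q(est4)$Q, sum(w4 * (est4$effect - ov4)^2),
               tolerance = 1e-12)

  expect_error(between_compound_q(est[1, , drop = FALSE]), ">= 2 compounds")
})

test_that("meta-regression recovers exact linear structure and matches WLS", {
  x <- c(1, 2, 3, 4)
  e <- 0.1 + 0.5 * x
  s <- c(0.1, 0.12, 0.09, 0.2)
  fit <- meta_regress(e, s, x)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$tau2, 0)

  # noisy k = 3 toy against independent weighted normal equations (tau2 = 0
  # because the moment estimate floors at zero for an exact-df fit check)
  e2 <- c(0.2, 0.9, 0.4); s2 <- c(0.1, 0.2, 0.15); x2 <- c(0, 1, 2)
  fit2 <- meta_regress(e2, s2, x2)
  w <- 1 / (s2^2 + fit2$tau2)
  X <- cbind(1, x2)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * e2))
  expect_equal(fit2$slope, beta[2], tolerance = 1e-10)

  # slope is invariant to covariate centering
  fit3 <- meta_regress(e2, s2, x2 - mean(x2))
  expect_equal(fit3$slope, fit2$slope, tolerance = 1e-10)

  expect_error(meta_regress(e2, s2, c(1, 1, 1)), "constant")

  skip_if_not_installed("metafor")
  set.seed(61)
  k <- 9; xx <- rnorm(k); ss <- runif(k, 0.1, 0.3)
  ee <- 0.2 + 0.4 * xx + rnorm(k, 0, 0.25)
  mine <- meta_regress(ee, ss, xx)
  mf <- metafor::rma(yi = ee, sei = ss, mods = ~xx, method = "DL")
  expect_equal(mine$slope, unname(coef(mf)[2]), tolerance = 1e-8)
  expect_equal(mine$se, unname(mf$se[2]), tolerance = 1e-8)
  expect_equal(mine$tau2, unname(mf$tau2), tolerance = 1e-8)
})

test_that("funnel coordinates pair each study with the pseudo-95% region", {
  e <- c(0.1, 0.3, 0.5); s <- c(0.05, 0.1, 0.2)
  pooled <- pool_fixed(e, s)
  fc <- funnel_coords(e, s, pooled)
  expect_equal(nrow(fc$points), 3)
  expect_equal(fc$boundary$lower[1], pooled$effect)   # se = 0
  expect_equal(fc$boundary$upper[1], pooled$effect)
  at02 <- which.min(abs(fc$boundary$se - 0.2))
  expect_equal(fc$boundary$upper[at02] - pooled$effect, 1.959964 * 0.2,
               tolerance = 1e-6)
})

test_that("compound-stratified analysis pools per compound and tests heterogeneity", {
  set.seed(67)
  trials <- gen_trialset(trial_sim_config(seed = 67))
  res <- meta_by_compound(trials, "CVD")
  expect_setequal(names(res$per_compound),
                  c("anacetrapib", "dalcetrapib", "torcetrapib", "evacetrapib"))
  expect_equal(res$per_compound$anacetrapib$fixed$k_studies, 6)
  expect_true(res$between$df == 3)
  expect_true(res$between$p >= 0 && res$between$p <= 1)
})
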