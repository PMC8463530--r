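test_that("single-instrument GLS-IVW is the Wald ratio", {
  inp <- mr_input(b_x = 0.5, s_x = 0.05, b_y = 0.1, s_y = 0.05)
  res <- gls_ivw(inp)
  expect_equal(res$theta, 0.2)
  expect_equal(res$se, 0.1)
  expect_equal(res$m_used, 1)
})

test_that("with identity LD, GLS-IVW equals the textbook IVW and origin-WLS", {
  set.seed(101)
  for (rep in 1:1000) {
    m <- sample(2:8, 1)
    b_x <- rnorm(m, 0, 0.2)
    b_y <- rnorm(m, 0, 0.1)
    s_y <- runif(m, 0.01, 0.2)
    res <- gls_ivw(mr_input(b_x, rep(0.01, m), b_y, s_y))
    ivw <- sum(b_x * b_y / s_y^2) / sum(b_x^2 / s_y^2)
    expect_equal(res$theta, ivw, tolerance = 1e-10)
    expect_equal(res$se, sqrt(1 / sum(b_x^2 / s_y^2)), tolerance = 1e-10)
  }
  # independent weighted-regression-through-origin oracle on one draw
  m <- 6; b_x <- rnorm(m); b_y <- rnorm(m); s_y <- runif(m, 0.05, 0.3)
  fit <- lm(b_y ~ 0 + b_x, weights = 1 / s_y^2)
  res <- gls_ivw(mr_input(b_x, rep(0.01, m), b_y, s_y))
  expect_equal(res$theta, unname(coef(fit)), tolerance = 1e-10)
})

test_that("correlated-instrument estimates match direct matrix inversion", {
  # m = 2, rho12 = 0.6 fixture against the 2x2 closed form
  b_x <- c(0.3, 0.5); b_y <- c(0.06, 0.11); s_y <- c(0.02, 0.03)
  rho <- matrix(c(1, 0.6, 0.6, 1), 2)
  res <- gls_ivw(mr_input(b_x, c(0.01, 0.01), b_y, s_y, rho))
  oracle <- oracle_gls(matrix(b_x, ncol = 1), b_y, s_y, rho)
  expect_equal(res$theta, oracle$theta, tolerance = 1e-12)
  expect_equal(res$se, oracle$se, tolerance = 1e-12)

  # random correlated instances
  set.seed(7)
  for (rep in 1:50) {
    m <- sample(3:8, 1)
    rho <- gen_ld_ar1(m, runif(1, -0.9, 0.9))
    b_x <- rnorm(m); b_y <- rnorm(m); s_y <- runif(m, 0.05, 0.3)
    res <- gls_ivw(mr_input(b_x, rep(0.01, m), b_y, s_y, rho))
    oracle <- oracle_gls(matrix(b_x, ncol = 1), b_y, s_y, rho)
    expect_equal(res$theta, oracle$theta, tolerance = 1e-10)
    expect_equal(res$se, oracle$se, tolerance = 1e-10)
  }
})

test_that("MVMR reduces to univariable GLS at k = 1 and solves the normal equations", {
  set.seed(13)
  m <- 7
  rho <- gen_ld_ar1(m, 0.5)
  b_x <- rnorm(m); b_y <- rnorm(m); s_y <- runif(m, 0.05, 0.2)
  uni <- gls_ivw(mr_input(b_x, rep(0.01, m), b_y, s_y, rho))
  mv1 <- mvmr_gls(mvmr_input(matrix(b_x, ncol = 1), b_y, s_y, rho))
  expect_equal(unname(mv1$theta), uni$theta, tolerance = 1e-12)
  expect_equal(unname(mv1$se), uni$se, tolerance = 1e-12)

  # k = 2 toy against the brute-force normal-equations oracle
  B <- cbind(rnorm(m), rnorm(m))
  mv2 <- mvmr_gls(mvmr_input(B, b_y, s_y, rho,
                             exposure_names = c("LDL", "HDL")))
  oracle <- oracle_gls(B, b_y, s_y, rho)
  expect_equal(unname(mv2$theta), oracle$theta, tolerance = 1e-10)
  expect_equal(unname(mv2$se), oracle$se, tolerance = 1e-10)
  expect_named(mv2$theta, c("LDL", "HDL"))
  expect_true(all(mv2$diagnostics$vif >= 1))
})

test_that("weighted-orthogonal exposures decouple into their univariable estimates", {
  set.seed(17)
  m <- 10
  s_y <- runif(m, 0.05, 0.2)
  w <- 1 / s_y^2
  x1 <- rnorm(m)
  x2 <- rnorm(m)
  x2 <- x2 - sum(w * x1 * x2) / sum(w * x1^2) * x1  # orthogonal under W
  b_y <- rnorm(m)
  mv <- mvmr_gls(mvmr_input(cbind(x1, x2), b_y, s_y))
  u1 <- gls_ivw(mr_input(x1, rep(0.01, m), b_y, s_y))
  u2 <- gls_ivw(mr_input(x2, rep(0.01, m), b_y, s_y))
  expect_equal(unname(mv$theta), c(u1$theta, u2$theta), tolerance = 1e-10)
})

test_that("collinear exposure columns are rejected with their names", {
  x <- rnorm(6)
  expect_error(mvmr_input(cbind(a = x, b = 2 * x), rnorm(6), rep(0.1, 6)),
               "collinear")
})

test_that("heterogeneity Q is zero at a perfect fit and matches the diagonal sum", {
  b_x <- c(0.2, 0.4, 0.6)
  inp <- mr_input(b_x, rep(0.01, 3), 0.5 * b_x, c(0.05, 0.1, 0.2))
  res <- gls_ivw(inp)
  q <- heterogeneity_q(inp, res$theta)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$p, 1)

  set.seed(23)
  m <- 5
  inp2 <- mr_input(rnorm(m), rep(0.01, m), rnorm(m), runif(m, 0.05, 0.2))
  th <- gls_ivw(inp2)$theta
  q2 <- heterogeneity_q(inp2, th)
  expect_equal(q2$Q, sum(((inp2$b_y - th * inp2$b_x) / inp2$s_y)^2),
               tolerance = 1e-10)
  expect_equal(q2$df, 4)

  # df < 1: Q reported, p withheld
  q1 <- heterogeneity_q(mr_input(0.5, 0.01, 0.1, 0.05), 0.2)
  expect_true(is.na(q1$p))
})

test_that("leverage/outlier pruning flags planted contamination and spares clean data", {
  set.seed(29)
  m <- 20
  # comparable instrument strengths: no variant dominates the design
  b_x <- rnorm(m, 0.2, 0.02)
  s_y <- runif(m, 0.04, 0.05)
  theta <- 0.4

  # homogeneous data: nothing excluded
  b_y <- theta * b_x + rnorm(m, 0, 0.2 * s_y)
  clean <- prune_leverage_outliers(mr_input(b_x, rep(0.01, m), b_y, s_y))
  expect_equal(nrow(clean$exclusions), 0)

  # one outcome beta shifted by 10 SEs -> outlier
  b_y_out <- b_y
  b_y_out[7] <- b_y[7] + 10 * s_y[7]
  pr <- prune_leverage_outliers(mr_input(b_x, rep(0.01, m), b_y_out, s_y))
  expect_true("v7" %in% pr$exclusions$key)
  expect_equal(pr$exclusions$reason[pr$exclusions$key == "v7"], "outlier")

  # one exposure beta ten-fold larger -> leverage
  b_x_lev <- b_x
  b_x_lev[3] <- 10 * max(abs(b_x))
  b_y_lev <- theta * b_x_lev + rnorm(m, 0, 0.2 * s_y)
  pr2 <- prune_leverage_outliers(mr_input(b_x_lev, rep(0.01, m), b_y_lev, s_y))
  expect_true("v3" %in% pr2$exclusions$key)
  expect_equal(pr2$exclusions$reason[pr2$exclusions$key == "v3"], "leverage")

  # the floor is never crossed
  tiny <- mr_input(c(1, 2, 30), rep(0.01, 3), c(5, -5, 90), rep(0.1, 3))
  pr3 <- prune_leverage_outliers(tiny)
  expect_gte(pr3$input$keys |> length(), 3)
})

test_that("canonical orientation flips 'decrease' targets and is idempotent", {
  inp <- mr_input(0.5, 0.05, 0.04, 0.05, exposure = "CETP")
  res <- gls_ivw(inp)
  expect_equal(res$theta, 0.08)
  # per unit LOWER CETP the LDL-C effect reads negative
  dec <- orient_canonical(res, c(CETP = "decrease"))
  expect_equal(dec$theta, -0.08)
  expect_equal(dec$z, -res$z)
  expect_equal(dec$ci_low, -res$ci_high)
  # orienting twice with the same spec is the identity
  dec2 <- orient_canonical(dec, c(CETP = "decrease"))
  expect_equal(dec2$theta, dec$theta)
  # an "increase" target is unchanged
  inc <- orient_canonical(res, c(CETP = "increase"))
  expect_equal(inc$theta, res$theta)
  # missing direction errors
  expect_error(orient_canonical(res, c(PCSK9 = "decrease")), "CETP")
})

test_that("scale equivariance and permutation invariance hold", {
  set.seed(37)
  for (rep in 1:20) {
    m <- sample(3:8, 1)
    rho <- gen_ld_ar1(m, runif(1, -0.8, 0.8))
    b_x <- rnorm(m); b_y <- rnorm(m); s_y <- runif(m, 0.05, 0.3)
    base <- gls_ivw(mr_input(b_x, rep(0.01, m), b_y, s_y, rho))

    c_ <- runif(1, 0.2, 5)
    scaled <- gls_ivw(mr_input(c_ * b_x, rep(0.01, m), b_y, s_y, rho))
    expect_equal(scaled$theta, base$theta / c_, tolerance = 1e-10)
    expect_equal(scaled$Q, base$Q, tolerance = 1e-10)

    perm <- sample(m)
    permed <- gls_ivw(mr_input(b_x[perm], rep(0.01, m), b_y[perm], s_y[perm],
                               rho[perm, perm]))
    expect_equal(permed$theta, base$theta, tolerance = 1e-10)
    expect_equal(permed$se, base$se, tolerance = 1e-10)
    expect_equal(permed$Q, base$Q, tolerance = 1e-10)
  }
})

test_that("overdispersion inflation multiplies the SE by sqrt(max(1, Q/df))", {
  set.seed(43)
  m <- 8
  b_x <- rnorm(m); b_y <- rnorm(m); s_y <- runif(m, 0.02, 0.05)
  plain <- gls_ivw(mr_input(b_x, rep(0.01, m), b_y, s_y))
  infl <- gls_ivw(mr_input(b_x, rep(0.01, m), b_y, s_y), overdispersion = TRUE)
  expect_equal(infl$se, plain$se * sqrt(max(1, plain$Q / (m - 1))),
               tolerance = 1e-12)
})
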