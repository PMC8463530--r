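# Correlated-instrument GLS-IVW estimation. Genetic associations with the
# outcome are regressed on genetic associations with the exposure(s),
# weighting by the inverse of Omega = diag(s_y) %*% rho %*% diag(s_y), the
# LD-induced covariance of the outcome betas. Exposure SEs are carried but
# not propagated: in the two-sample design residual weak-instrument bias
# attenuates the slope toward the null, so first-order weighting by outcome
# SEs is the conservative convention.

#' Univariable MR input
#'
#' @param b_x,s_x exposure betas and SEs (length m).
#' @param b_y,s_y outcome betas and SEs (length m), `s_y > 0`.
#' @param rho m x m signed LD correlation matrix (identity if omitted).
#' @param keys optional variant keys.
#' @param exposure_unit,outcome_unit,exposure,outcome labels.
#' @return An object of class `mr_input`.
#' @export
mr_input <- function(b_x, s_x, b_y, s_y, rho = NULL, keys = NULL,
                     exposure = "exposure", outcome = "outcome",
                     exposure_unit = "", outcome_unit = "") {
  m <- length(b_x)
  stopifnot(length(s_x) == m, length(b_y) == m, length(s_y) == m, m >= 1,
            all(s_y > 0))
  if (is.null(rho)) rho <- diag(m)
  rho <- as.matrix(rho)
  stopifnot(nrow(rho) == m, ncol(rho) == m)
  if (is.null(keys)) keys <- paste0("v", seq_len(m))
  structure(list(b_x = as.numeric(b_x), s_x = as.numeric(s_x),
                 b_y = as.numeric(b_y), s_y = as.numeric(s_y),
                 rho = unclass(rho), keys = keys,
                 exposure = exposure, outcome = outcome,
                 exposure_unit = exposure_unit, outcome_unit = outcome_unit),
            class = "mr_input")
}

#' Multivariable MR input
#'
#' @param B_x m x k matrix of exposure betas (columns = exposures).
#' @param exposure_names length-k labels.
#' @inheritParams mr_input
#' @param condition_max condition-number threshold above which the exposure
#'   columns are declared collinear.
#' @return An object of class `mvmr_input`.
#' @export
mvmr_input <- function(B_x, b_y, s_y, rho = NULL, exposure_names = NULL,
                       keys = NULL, outcome = "outcome",
                       outcome_unit = "", condition_max = 1e8) {
  B_x <- as.matrix(B_x)
  m <- nrow(B_x); k <- ncol(B_x)
  stopifnot(k >= 1, k < m, length(b_y) == m, length(s_y) == m, all(s_y > 0))
  if (is.null(rho)) rho <- diag(m)
  rho <- as.matrix(rho)
  if (is.null(exposure_names)) {
    exposure_names <- colnames(B_x)
    if (is.null(exposure_names)) exposure_names <- paste0("exposure", seq_len(k))
  }
  if (is.null(keys)) keys <- paste0("v", seq_len(m))
  cn <- kappa(B_x, exact = TRUE)
  if (cn > condition_max) {
    stop("mvmr_input: exposure columns are collinear (",
         paste(exposure_names, collapse = ", "),
         sprintf("; condition number %.3g)", cn))
  }
  structure(list(B_x = B_x, b_y = as.numeric(b_y), s_y = as.numeric(s_y),
                 rho = unclass(rho), keys = keys,
                 exposure_names = exposure_names,
                 outcome = outcome, outcome_unit = outcome_unit),
            class = "mvmr_input")
}

omega_of <- function(s_y, rho) {
  (s_y %o% s_y) * rho
}

solve_spd <- function(A, b) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    stop("singular weighting matrix Omega: instruments are too correlated; ",
         "re-clump at a lower r^2 threshold")
  }
  backsolve(ch, forwardsolve(t(ch), b))
}

#' Generalized least squares IVW estimate
#'
#' Fits theta in b_y = theta * b_x through the origin by GLS with weight
#' matrix Omega^-1, Omega = diag(s_y) rho diag(s_y):
#' theta = (b_x' O^-1 b_x)^-1 b_x' O^-1 b_y,
#' se = sqrt((b_x' O^-1 b_x)^-1). With identity rho this is the textbook
#' inverse-variance weighted estimator; with m = 1 the Wald ratio. The
#' heterogeneity Q (residual weighted sum of squares, df = m - 1) is always
#' reported; setting `overdispersion = TRUE` additionally inflates the SE by
#' sqrt(max(1, Q / (m - 1))).
#'
#' @param input an [mr_input()].
#' @param overdispersion inflate SE by the multiplicative Q-based factor;
#'   off by default.
#' @return An object of class `mr_result` with `theta`, `se`, `z`, `p`,
#'   `Q`, `df_Q`, `p_Q`, `m_used`, `excluded`, `orientation`.
#' @export
gls_ivw <- function(input, overdispersion = FALSE) {
  stopifnot(inherits(input, "mr_input"))
  m <- length(input$b_x)
  Om <- omega_of(input$s_y, input$rho)
  oix <- solve_spd(Om, cbind(input$b_x, input$b_y))
  xtox <- sum(input$b_x * oix[, 1])
  xtoy <- sum(input$b_x * oix[, 2])
  theta <- xtoy / xtox
  se <- sqrt(1 / xtox)
  q <- heterogeneity_q_raw(input$b_y, matrix(input$b_x, ncol = 1), Om, theta)
  if (overdispersion && m > 1) se <- se * sqrt(max(1, q / (m - 1)))
  z <- theta / se
  p <- 2 * stats::pnorm(-abs(z))
  new_mr_result(theta = theta, se = se, z = z, p = p,
                Q = q, df_Q = m - 1, m_used = m,
                exposure = input$exposure, outcome = input$outcome,
                exposure_unit = input$exposure_unit,
                outcome_unit = input$outcome_unit,
                overdispersion = overdispersion)
}

#' Multivariable GLS-IVW estimate
#'
#' Joint GLS regression of outcome betas on the beta matrix of k exposures:
#' theta = (B' O^-1 B)^-1 B' O^-1 b_y with per-exposure SEs from the
#' diagonal of (B' O^-1 B)^-1. With k = 1 this reduces exactly to
#' [gls_ivw()]. Conditional instrument-strength diagnostics are reported per
#' exposure as variance inflation factors in the whitened design, alongside
#' the whitened-design condition number.
#'
#' @param input an [mvmr_input()].
#' @return An `mr_result` with vector-valued `theta`, `se`, `z`, `p` (named
#'   by exposure) and a `diagnostics` element.
#' @export
mvmr_gls <- function(input) {
  stopifnot(inherits(input, "mvmr_input"))
  B <- input$B_x
  m <- nrow(B); k <- ncol(B)
  Om <- omega_of(input$s_y, input$rho)
  oiB <- solve_spd(Om, cbind(B, input$b_y))
  BtoB <- crossprod(B, oiB[, seq_len(k), drop = FALSE])
  Btoy <- crossprod(B, oiB[, k + 1])
  BtoB <- (BtoB + t(BtoB)) / 2
  V <- solve(BtoB)
  theta <- drop(V %*% Btoy)
  se <- sqrt(diag(V))
  names(theta) <- names(se) <- input$exposure_names
  z <- theta / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- heterogeneity_q_raw(input$b_y, B, Om, theta)

  # whitened-design diagnostics: VIF per exposure + condition number
  W <- inv_sqrt_spd(Om)
  Xw <- W %*% B
  R <- stats::cor(Xw)
  vif <- if (k > 1) diag(solve(R)) else stats::setNames(1, input$exposure_names)
  names(vif) <- input$exposure_names
  new_mr_result(theta = theta, se = se, z = z, p = p,
                Q = q, df_Q = m - k, m_used = m,
                exposure = input$exposure_names, outcome = input$outcome,
                outcome_unit = input$outcome_unit,
                diagnostics = list(vif = vif,
                                   condition_number = kappa(Xw, exact = TRUE)))
}

heterogeneity_q_raw <- function(b_y, X, Om, theta) {
  resid <- b_y - drop(X %*% theta)
  drop(crossprod(resid, solve_spd(Om, resid)))
}

#' Heterogeneity Q statistic
#'
#' Q = (b_y - X theta)' Omega^-1 (b_y - X theta), chi-square with
#' df = m - k under instrument validity; used to flag residual pleiotropy.
#' With df < 1 the statistic is reported but p withheld.
#'
#' @param input an [mr_input()] or [mvmr_input()].
#' @param theta estimate(s) fitted from the same input.
#' @return list with `Q`, `df`, `p` (`p = NA` when df < 1).
#' @export
heterogeneity_q <- function(input, theta) {
  X <- if (inherits(input, "mvmr_input")) input$B_x else matrix(input$b_x, ncol = 1)
  Om <- omega_of(input$s_y, input$rho)
  q <- heterogeneity_q_raw(input$b_y, X, Om, theta)
  df <- nrow(X) - ncol(X)
  p <- if (df >= 1) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_
  list(Q = q, df = df, p = p)
}

inv_sqrt_spd <- function(A) {
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, max(eg$values) * 1e-12)
  eg$vectors %*% (t(eg$vectors) / sqrt(vals))
}

#' Iterative leverage/outlier pruning
#'
#' In the whitened design (pre-multiplied by the symmetric square root of
#' Omega^-1) the fit is ordinary least squares; variants are flagged when
#' their hat value exceeds `leverage_mult * k / m` or when the chi-square(1)
#' upper-tail p of their squared standardized residual falls below
#' `alpha / m` (Bonferroni). Flagged variants are removed, the model refit,
#' and the cycle repeated until nothing is flagged or only
#' max(3, k + 1) variants remain (never fewer; a warning signals the floor).
#'
#' @param input an [mr_input()] or [mvmr_input()].
#' @param leverage_mult hat-value multiplier, default 3.
#' @param alpha familywise outlier level, default 0.05.
#' @return list with `input` (pruned) and `exclusions` (data.frame of key,
#'   reason, statistic).
#' @export
prune_leverage_outliers <- function(input, leverage_mult = 3, alpha = 0.05) {
  mv <- inherits(input, "mvmr_input")
  X_full <- if (mv) input$B_x else matrix(input$b_x, ncol = 1)
  k <- ncol(X_full)
  m0 <- nrow(X_full)
  stopifnot(m0 >= 3)
  floor_m <- max(3, k + 1)
  active <- seq_len(m0)
  exclusions <- data.frame(key = character(0), reason = character(0),
                           statistic = numeric(0), stringsAsFactors = FALSE)

  repeat {
    m <- length(active)
    if (m <= floor_m) break
    X <- X_full[active, , drop = FALSE]
    y <- input$b_y[active]
    Om <- omega_of(input$s_y[active], input$rho[active, active, drop = FALSE])
    W <- inv_sqrt_spd(Om)
    Xw <- W %*% X
    yw <- drop(W %*% y)
    XtX <- crossprod(Xw)
    H <- Xw %*% solve(XtX, t(Xw))
    h <- diag(H)
    theta <- solve(XtX, crossprod(Xw, yw))
    e <- yw - drop(Xw %*% theta)
    r_std <- e / sqrt(pmax(1 - h, 1e-12))
    p_out <- stats::pchisq(r_std^2, df = 1, lower.tail = FALSE)

    lev_flag <- h > leverage_mult * k / m
    out_flag <- p_out < alpha / m
    flag <- lev_flag | out_flag
    if (!any(flag)) break

    # remove the single worst offender per pass, so the floor is respected
    score <- ifelse(out_flag, r_std^2, 0) + ifelse(lev_flag, h * m / k, 0)
    worst <- which.max(ifelse(flag, score, -Inf))
    reason <- if (out_flag[worst]) "outlier" else "leverage"
    statistic <- if (out_flag[worst]) r_std[worst]^2 else h[worst]
    exclusions <- rbind(exclusions, data.frame(
      key = input$keys[active[worst]], reason = reason, statistic = statistic,
      stringsAsFactors = FALSE))
    active <- active[-worst]
  }
  if (length(active) <= floor_m && nrow(exclusions) > 0) {
    warning("prune_leverage_outliers: stopped at the variant floor (",
            floor_m, ")")
  }

  pruned <- if (mv) {
    mvmr_input(input$B_x[active, , drop = FALSE], input$b_y[active],
               input$s_y[active], input$rho[active, active, drop = FALSE],
               exposure_names = input$exposure_names,
               keys = input$keys[active], outcome = input$outcome,
               outcome_unit = input$outcome_unit)
  } else {
    mr_input(input$b_x[active], input$s_x[active], input$b_y[active],
             input$s_y[active], input$rho[active, active, drop = FALSE],
             keys = input$keys[active], exposure = input$exposure,
             outcome = input$outcome, exposure_unit = input$exposure_unit,
             outcome_unit = input$outcome_unit)
  }
  list(input = pruned, exclusions = exclusions)
}

new_mr_result <- function(theta, se, z, p, Q, df_Q, m_used,
                          exposure, outcome, exposure_unit = "",
                          outcome_unit = "", orientation = "increase",
                          excluded = NULL, diagnostics = NULL,
                          overdispersion = FALSE) {
  p_Q <- if (df_Q >= 1) stats::pchisq(Q, df_Q, lower.tail = FALSE) else NA_real_
  structure(list(theta = theta, se = se, z = z, p = p,
                 ci_low = theta - 1.959964 * se, ci_high = theta + 1.959964 * se,
                 Q = Q, df_Q = df_Q, p_Q = p_Q, m_used = m_used,
                 exposure = exposure, outcome = outcome,
                 exposure_unit = exposure_unit, outcome_unit = outcome_unit,
                 orientation = orientation,
                 excluded = if (is.null(excluded))
                   data.frame(key = character(0), reason = character(0))
                 else excluded,
                 diagnostics = diagnostics,
                 overdispersion = overdispersion),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat("MR estimate (", paste(x$exposure, collapse = ", "), " -> ", x$outcome,
      ")\n", sep = "")
  est <- data.frame(exposure = x$exposure, theta = x$theta, se = x$se,
                    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p)
  print(est, row.names = FALSE, digits = 4)
  cat(sprintf("Q = %.3f on %d df (p = %.3g); m = %d; orientation: %s\n",
              x$Q, x$df_Q, x$p_Q, x$m_used, x$orientation))
  invisible(x)
}

#' Orient an MR result to the canonical drug-target direction
#'
#' Estimates are reported per unit change in the pharmacologically intended
#' direction: "decrease" for protein concentration (CETP, PCSK9), LDL-C and
#' TG weighting, "increase" for HDL-C. A "decrease" orientation negates
#' theta and z (and swaps the CI) so the result reads per unit LOWER
#' exposure. Orienting an already-oriented result with the same direction is
#' the identity.
#'
#' @param result an `mr_result`.
#' @param direction named character vector (or single string) giving
#'   "increase"/"decrease" per exposure.
#' @return The oriented `mr_result` (orientation tag recorded).
#' @export
orient_canonical <- function(result, direction) {
  stopifnot(inherits(result, "mr_result"))
  exposures <- result$exposure
  if (length(direction) == 1 && is.null(names(direction))) {
    direction <- stats::setNames(rep(direction, length(exposures)), exposures)
  }
  missing <- setdiff(exposures, names(direction))
  if (length(missing) > 0) {
    stop("orient_canonical: no direction specified for exposure(s): ",
         paste(missing, collapse = ", "))
  }
  direction <- direction[exposures]
  stopifnot(all(direction %in% c("increase", "decrease")))
  current <- result$orientation
  if (length(current) == 1) current <- rep(current, length(exposures))
  flip <- unname(direction != current)
  sgn <- ifelse(flip, -1, 1)
  out <- result
  out$theta <- result$theta * sgn
  out$z <- result$z * sgn
  lo <- ifelse(flip, -result$ci_high, result$ci_low)
  hi <- ifelse(flip, -result$ci_low, result$ci_high)
  out$ci_low <- lo
  out$ci_high <- hi
  out$orientation <- unname(direction)
  out
}
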