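# Compound-stratified meta-analysis of randomized-trial effects. Binary
# endpoints are pooled as log odds ratios; continuous traits as the
# between-group difference in percentage change from baseline, pooled on
# the reported % scale.

Z95 <- 1.959964

#' Read a trial-effects table
#'
#' CSV schema: study_id, compound, outcome, type (binary/continuous),
#' t_events, t_total, c_events, c_total, md, ci_low, ci_high, se,
#' followup_months — unused cells empty.
#'
#' @param path CSV file path.
#' @return data.frame of trial outcomes.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("study_id", "compound", "outcome", "type")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0) {
    stop("read_trials: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("t_events", "t_total", "c_events", "c_total", "md",
                "ci_low", "ci_high", "se", "followup_months")) {
    if (!col %in% names(d)) d[[col]] <- NA_real_
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  }
  d
}

#' Point estimate and SE from one trial outcome
#'
#' Binary outcomes: log-OR = ln(a d / (b c)) with
#' se = sqrt(1/a + 1/b + 1/c + 1/d) from the 2x2 table; if any cell is
#' zero, 0.5 is added to all four cells (continuity correction); trials
#' with zero events in both arms are excluded with a reason. Continuous
#' outcomes: the mean difference is taken as reported, with
#' se = (ci_high - ci_low) / (2 * 1.959964) when a 95% CI is given, or the
#' reported SE directly.
#'
#' @param trials data.frame in the [read_trials()] schema (one or more rows).
#' @return data.frame with columns study_id, compound, outcome, effect, se,
#'   scale ("logOR" or "MD"); excluded trials are reported in the
#'   `exclusions` attribute.
#' @export
effect_from_trial <- function(trials) {
  n <- nrow(trials)
  effect <- se <- rep(NA_real_, n)
  scale <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (trials$type[i] == "binary") {
      a <- trials$t_events[i]; nt <- trials$t_total[i]
      c_ <- trials$c_events[i]; nc <- trials$c_total[i]
      stopifnot(a <= nt, c_ <= nc)
      b <- nt - a; d <- nc - c_
      if (a + c_ == 0) { reason[i] <- "zero_events_both_arms"; next }
      if (b + d == 0) { reason[i] <- "all_events_both_arms"; next }
      if (min(a, b, c_, d) == 0) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
      effect[i] <- log((a * d) / (b * c_))
      se[i] <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
      scale[i] <- "logOR"
    } else {
      effect[i] <- trials$md[i]
      if (!is.na(trials$ci_low[i]) && !is.na(trials$ci_high[i])) {
        stopifnot(trials$ci_low[i] < trials$ci_high[i])
        se[i] <- (trials$ci_high[i] - trials$ci_low[i]) / (2 * Z95)
      } else {
        se[i] <- trials$se[i]
      }
      if (is.na(effect[i]) || is.na(se[i]) || se[i] <= 0) {
        reason[i] <- "missing_effect_or_se"
        effect[i] <- se[i] <- NA_real_
        next
      }
      scale[i] <- "MD"
    }
  }
  keep <- is.na(reason)
  out <- data.frame(study_id = trials$study_id[keep],
                    compound = trials$compound[keep],
                    outcome = trials$outcome[keep],
                    effect = effect[keep], se = se[keep], scale = scale[keep],
                    stringsAsFactors = FALSE)
  attr(out, "exclusions") <- data.frame(
    study_id = trials$study_id[!keep], outcome = trials$outcome[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE)
  out
}

#' Standard error from a reported 95% confidence interval
#'
#' se = (hi - lo) / (2 * 1.959964); with `log = TRUE` the bounds are
#' log-transformed first (back-transforming a reported OR CI to the log-OR
#' scale).
#'
#' @param ci_low,ci_high reported 95% CI bounds.
#' @param log back-transform from a ratio scale.
#' @return standard error on the (log) scale.
#' @export
se_from_ci <- function(ci_low, ci_high, log = FALSE) {
  stopifnot(all(ci_low < ci_high))
  if (log) { ci_low <- base::log(ci_low); ci_high <- base::log(ci_high) }
  (ci_high - ci_low) / (2 * Z95)
}

check_common_scale <- function(scale) {
  u <- unique(scale[!is.na(scale)])
  if (length(u) > 1) {
    stop("estimates are on mixed scales (", paste(u, collapse = ", "),
         "); pool per scale")
  }
  if (length(u) == 1) u else NA_character_
}

new_meta_estimate <- function(effect, se, Q, df, tau2, k, model, scale) {
  p_Q <- if (!is.na(df) && df >= 1) stats::pchisq(Q, df, lower.tail = FALSE)
         else NA_real_
  structure(list(effect = effect, se = se,
                 ci_low = effect - Z95 * se, ci_high = effect + Z95 * se,
                 Q = Q, df = df, p_Q = p_Q, tau2 = tau2, k_studies = k,
                 model = model, scale = scale),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf("%s-effect pool of %d studies (%s): %.4f (95%% CI %.4f, %.4f)\n",
              x$model, x$k_studies, x$scale, x$effect, x$ci_low, x$ci_high))
  cat(sprintf("  Q = %.3f on %d df; tau2 = %.4g\n", x$Q, x$df, x$tau2))
  invisible(x)
}

#' Fixed-effect inverse-variance pooling
#'
#' weights w_i = 1/se_i^2; pooled = sum(w e) / sum(w); se = 1/sqrt(sum w);
#' within-group Q = sum(w (e - pooled)^2) on k - 1 df.
#'
#' @param effect,se study effects and SEs on a common scale.
#' @param scale scale tag carried through (`"logOR"` or `"MD"`).
#' @return A `meta_estimate` with `model = "fixed"` and `tau2 = 0`.
#' @export
pool_fixed <- function(effect, se, scale = NA_character_) {
  stopifnot(length(effect) >= 1, length(effect) == length(se), all(se > 0))
  scale <- check_common_scale(rep(scale, length.out = length(effect)))
  w <- 1 / se^2
  pooled <- sum(w * effect) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  q <- sum(w * (effect - pooled)^2)
  new_meta_estimate(pooled, pooled_se, q, length(effect) - 1, 0,
                    length(effect), "fixed", scale)
}

#' DerSimonian-Laird random-effects pooling
#'
#' tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w))) from the
#' fixed-effect Q, then re-weighting by 1/(se^2 + tau2). When Q <= df,
#' tau2 = 0 and the result coincides with [pool_fixed()]. A single study is
#' returned as-is with tau2 = 0 and a warning.
#'
#' @inheritParams pool_fixed
#' @return A `meta_estimate` with `model = "random"`.
#' @export
pool_random <- function(effect, se, scale = NA_character_) {
  stopifnot(length(effect) >= 1, length(effect) == length(se), all(se > 0))
  scale <- check_common_scale(rep(scale, length.out = length(effect)))
  k <- length(effect)
  if (k == 1) {
    warning("pool_random: single study; returning it with tau2 = 0")
    return(new_meta_estimate(effect, se, 0, 0, 0, 1, "random", scale))
  }
  fixed <- pool_fixed(effect, se, scale)
  w <- 1 / se^2
  tau2 <- max(0, (fixed$Q - fixed$df) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (se^2 + tau2)
  pooled <- sum(w_star * effect) / sum(w_star)
  pooled_se <- 1 / sqrt(sum(w_star))
  new_meta_estimate(pooled, pooled_se, fixed$Q, fixed$df, tau2, k,
                    "random", scale)
}

#' Between-compound heterogeneity Q
#'
#' Treats each compound's pooled estimate as one unit:
#' Q = sum(w_j (theta_j - theta_overall)^2), w_j = 1/se_j^2, with
#' theta_overall the fixed pool of the compound estimates; df = J - 1;
#' p from the chi-square upper tail.
#'
#' @param estimates list of `meta_estimate` objects (one per compound), all
#'   on one scale, or a data.frame with columns `effect` and `se`.
#' @return list with `Q`, `df`, `p`.
#' @export
between_compound_q <- function(estimates) {
  if (is.data.frame(estimates)) {
    eff <- estimates$effect; se <- estimates$se
    scale <- if ("scale" %in% names(estimates)) estimates$scale else NA
  } else {
    eff <- vapply(estimates, `[[`, numeric(1), "effect")
    se <- vapply(estimates, `[[`, numeric(1), "se")
    scale <- vapply(estimates, function(e) as.character(e$scale %||% NA),
                    character(1))
  }
  if (length(eff) < 2) stop("between_compound_q: need >= 2 compounds")
  check_common_scale(scale)
  w <- 1 / se^2
  overall <- sum(w * eff) / sum(w)
  q <- sum(w * (eff - overall)^2)
  df <- length(eff) - 1
  list(Q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random-effects meta-regression
#'
#' Weighted least squares of study effects on a trial-level covariate with
#' an intercept. The between-study variance is estimated by the method of
#' moments on the fixed-effect regression residuals,
#' tau2 = max(0, (Q_E - (k - 2)) / (tr(W) - tr((X'WX)^-1 X'W^2 X))),
#' then the regression is refit with weights 1/(se^2 + tau2).
#'
#' @param effect,se per-trial estimates on one scale.
#' @param covariate per-trial numeric covariate; must vary.
#' @return list with `slope`, `se`, `z`, `p`, `intercept`, `tau2`.
#' @export
meta_regress <- function(effect, se, covariate) {
  k <- length(effect)
  stopifnot(k >= 3, length(se) == k, length(covariate) == k, all(se > 0))
  if (stats::sd(covariate) == 0) stop("meta_regress: covariate is constant")
  X <- cbind(1, covariate)
  p_ <- ncol(X)
  wls <- function(w) {
    XtWX <- crossprod(X, w * X)
    beta <- solve(XtWX, crossprod(X, w * effect))
    list(beta = drop(beta), cov = solve(XtWX))
  }
  w0 <- 1 / se^2
  fit0 <- wls(w0)
  resid0 <- effect - drop(X %*% fit0$beta)
  QE <- sum(w0 * resid0^2)
  trP <- sum(w0) - sum(diag(solve(crossprod(X, w0 * X), crossprod(X, w0^2 * X))))
  tau2 <- max(0, (QE - (k - p_)) / trP)
  w <- 1 / (se^2 + tau2)
  fit <- wls(w)
  slope <- unname(fit$beta[2])
  slope_se <- sqrt(fit$cov[2, 2])
  z <- slope / slope_se
  list(slope = slope, se = slope_se, z = z, p = 2 * stats::pnorm(-abs(z)),
       intercept = fit$beta[1], tau2 = tau2)
}

#' Funnel-plot coordinates
#'
#' One (effect, se) point per study plus the pseudo-95% region boundary
#' pooled +/- 1.959964 * se over an SE grid from 0 to max(se).
#'
#' @param effect,se per-study estimates.
#' @param pooled a `meta_estimate` computed from the same studies.
#' @param grid_n number of boundary grid points.
#' @return list with `points` (data.frame effect, se) and `boundary`
#'   (data.frame se, lower, upper).
#' @export
funnel_coords <- function(effect, se, pooled, grid_n = 50) {
  stopifnot(inherits(pooled, "meta_estimate"))
  se_grid <- seq(0, max(se), length.out = grid_n)
  list(points = data.frame(effect = effect, se = se),
       boundary = data.frame(se = se_grid,
                             lower = pooled$effect - Z95 * se_grid,
                             upper = pooled$effect + Z95 * se_grid))
}

#' Compound-stratified meta-analysis of a trial table
#'
#' Extracts per-trial effects, pools them per compound (fixed and random),
#' and tests between-compound heterogeneity, for one outcome at a time.
#'
#' @param trials data.frame in the [read_trials()] schema.
#' @param outcome outcome label to analyse.
#' @param model pooling model for the per-compound estimates used in the
#'   between-compound test.
#' @return list with `per_compound` (named list of lists with fixed/random
#'   `meta_estimate`s), `between` (Q, df, p), `effects` (per-trial table),
#'   `exclusions`.
#' @export
meta_by_compound <- function(trials, outcome, model = c("fixed", "random")) {
  model <- match.arg(model)
  sub <- trials[trials$outcome == outcome, , drop = FALSE]
  if (nrow(sub) == 0) stop("meta_by_compound: no trials for outcome ", outcome)
  eff <- effect_from_trial(sub)
  per_compound <- lapply(split(eff, eff$compound), function(d) {
    list(fixed = pool_fixed(d$effect, d$se, d$scale),
         random = if (nrow(d) > 1) pool_random(d$effect, d$se, d$scale)
                  else suppressWarnings(pool_random(d$effect, d$se, d$scale)))
  })
  between <- if (length(per_compound) >= 2) {
    between_compound_q(lapply(per_compound, `[[`, model))
  } else NULL
  list(per_compound = per_compound, between = between, effects = eff,
       exclusions = attr(eff, "exclusions"), outcome = outcome, model = model)
}
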