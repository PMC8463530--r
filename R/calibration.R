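# Simulation studies over the synthetic-data generator: end-to-end
# parameter recovery of the causal effect, CI coverage, null calibration of
# the MR z-statistic, and type-I error of the between-compound Q test.

#' End-to-end parameter recovery study
#'
#' For each replicate: generate two-sample summary statistics at the given
#' configuration (continuous outcome, so the protein effect is the direct
#' estimand), run the full instrument chain (harmonize, MAF + F filters, LD
#' from the reference panel, greedy clumping) and GLS-IVW, and record the
#' estimate, its SE, and whether the 95% CI covers the generating effect.
#'
#' @param n_rep number of replicates.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param m,ld_rho,n_exposure,n_outcome,n_reference,theta generator settings
#'   passed to [sim_config()].
#' @param maf_min,f_min,r2_max instrument thresholds.
#' @return data.frame with one row per replicate: `theta_hat`, `se`,
#'   `covered`, `m_used`, plus the true effect in the `theta` attribute.
#' @export
recovery_study <- function(n_rep = 200, seed = 1, m = 50, ld_rho = 0.8,
                           n_exposure = 10000, n_outcome = 50000,
                           n_reference = 5000, theta = 0.2,
                           maf_min = 0.01, f_min = 15, r2_max = 0.40) {
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(m = m, ld_rho = ld_rho, n_exposure = n_exposure,
                      n_outcome = n_outcome, n_reference = n_reference,
                      theta = theta, seed = seed + r)
    sim <- gen_two_sample_summary(cfg)
    res <- run_mr(sim$exposure, sim$outcome, sim$reference,
                  maf_min = maf_min, f_min = f_min, r2_max = r2_max,
                  prune = FALSE, direction = "increase")
    rows[[r]] <- data.frame(theta_hat = res$theta, se = res$se,
                            covered = res$ci_low <= theta & theta <= res$ci_high,
                            m_used = res$m_used)
  }
  out <- do.call(rbind, rows)
  attr(out, "theta") <- theta
  out
}

#' Null calibration of the pipeline z-statistic
#'
#' Replicates [recovery_study()] with a zero causal effect on a binary
#' outcome and records the GLS-IVW |z|; under the null roughly 95% of
#' replicates should fall below 1.96.
#'
#' @inheritParams recovery_study
#' @param outcome_prevalence case fraction for the liability threshold.
#' @return data.frame with `z` per replicate.
#' @export
null_z_study <- function(n_rep = 200, seed = 1, m = 50, ld_rho = 0.8,
                         n_exposure = 10000, n_outcome = 20000,
                         n_reference = 5000, outcome_prevalence = 0.1) {
  z <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(m = m, ld_rho = ld_rho, n_exposure = n_exposure,
                      n_outcome = n_outcome, n_reference = n_reference,
                      theta = 0, outcome_prevalence = outcome_prevalence,
                      seed = seed + r)
    sim <- gen_two_sample_summary(cfg)
    res <- run_mr(sim$exposure, sim$outcome, sim$reference, prune = FALSE,
                  direction = "increase")
    z[r] <- res$z
  }
  data.frame(z = z)
}

#' Type-I error of the between-compound Q test
#'
#' Simulates trial sets in which every compound shares one true effect on a
#' continuous endpoint, pools per compound (fixed effect), and applies the
#' between-compound Q test; returns the per-dataset p-values, whose
#' rejection rate at 0.05 should sit at the nominal level.
#'
#' @param n_rep number of simulated datasets.
#' @param seed base seed.
#' @param n_compounds compounds per dataset.
#' @param trials_per_compound trials per compound.
#' @param true_md shared true mean difference (% change from baseline).
#' @param arm_size,md_sd trial geometry, see [trial_sim_config()].
#' @return data.frame with `p` per simulated dataset.
#' @export
q_null_study <- function(n_rep = 2000, seed = 1, n_compounds = 3,
                         trials_per_compound = 4, true_md = -20,
                         arm_size = 500, md_sd = 40) {
  se_trial <- md_sd * sqrt(2 / arm_size)
  p <- numeric(n_rep)
  set.seed(seed)
  for (r in seq_len(n_rep)) {
    pooled <- lapply(seq_len(n_compounds), function(j) {
      e <- stats::rnorm(trials_per_compound, true_md, se_trial)
      pool_fixed(e, rep(se_trial, trials_per_compound), scale = "MD")
    })
    p[r] <- between_compound_q(pooled)$p
  }
  data.frame(p = p)
}

#' MVMR mediation recovery study
#'
#' Generates data in which the protein affects the outcome only through the
#' first of two mediators, fits the multivariable GLS model on both
#' mediators, and records both estimates with their CIs — the second
#' mediator's CI should cover zero at the nominal rate and the first should
#' recover its generating effect.
#'
#' @inheritParams recovery_study
#' @param alpha1,beta1 protein -> mediator-1 and mediator-1 -> outcome
#'   effects (the active path).
#' @param alpha2 protein -> mediator-2 effect (no outcome effect).
#' @return data.frame per replicate: `theta1`, `se1`, `cover1`, `theta2`,
#'   `se2`, `cover2_null`.
#' @export
mvmr_recovery_study <- function(n_rep = 200, seed = 1, m = 50, ld_rho = 0.8,
                                n_exposure = 10000, n_outcome = 50000,
                                n_reference = 5000, alpha1 = 0.5,
                                beta1 = 0.4, alpha2 = 0.5) {
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(m = m, ld_rho = ld_rho, n_exposure = n_exposure,
                      n_outcome = n_outcome, n_reference = n_reference,
                      theta = 0,
                      mediation = list(
                        M1 = list(alpha = alpha1, beta_med = beta1),
                        M2 = list(alpha = alpha2, beta_med = 0)),
                      seed = seed + r)
    sim <- gen_two_sample_summary(cfg)
    pairs <- harmonize(sim$exposure, sim$outcome)
    ld <- ld_from_reference(sim$reference[, pair_keys(pairs), drop = FALSE])
    iset <- select_instruments(pairs, ld)
    keys <- pair_keys(iset$pairs)
    B <- sapply(sim$mediators, function(tb) {
      rec <- tb$records
      idx <- match(keys, variant_key(rec$chrom, rec$pos, rec$effect_allele,
                                     rec$other_allele))
      rec$beta[idx]
    })
    fit <- mvmr_gls(mvmr_input(B, iset$pairs$b_y, iset$pairs$s_y, iset$ld,
                               exposure_names = colnames(B), keys = keys))
    ci_lo <- fit$theta - 1.959964 * fit$se
    ci_hi <- fit$theta + 1.959964 * fit$se
    rows[[r]] <- data.frame(
      theta1 = fit$theta[["M1"]], se1 = fit$se[["M1"]],
      cover1 = ci_lo[["M1"]] <= beta1 & beta1 <= ci_hi[["M1"]],
      theta2 = fit$theta[["M2"]], se2 = fit$se[["M2"]],
      cover2_null = ci_lo[["M2"]] <= 0 & 0 <= ci_hi[["M2"]])
  }
  out <- do.call(rbind, rows)
  attr(out, "beta1") <- beta1
  out
}
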