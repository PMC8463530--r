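# Synthetic two-sample GWAS and trial data. Genotypes are continuous
# multivariate-normal dosage scores with AR(1) cis LD (adequate for
# summary-statistic structure); an optional discrete mode rounds the latent
# scores to {0,1,2} through Hardy-Weinberg thresholds at the target MAF.
# Exposure, outcome, and reference samples are always drawn independently,
# so the two-sample design holds by construction.

#' AR(1) linkage-disequilibrium matrix
#'
#' r\[i, j\] = ld_rho^|i - j|; positive definite for any |ld_rho| < 1.
#'
#' @param m number of variants.
#' @param ld_rho AR(1) parameter, |ld_rho| < 1.
#' @return m x m signed correlation matrix.
#' @export
gen_ld_ar1 <- function(m, ld_rho) {
  if (abs(ld_rho) >= 1) stop("gen_ld_ar1: |ld_rho| must be < 1")
  ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

#' Simulation configuration for two-sample summary statistics
#'
#' Defaults describe a single cis region of 50 variants with moderately
#' strong AR(1) LD, a protein exposure instrumented by five causal variants,
#' and GWAS sample sizes of 10,000 (exposure), 50,000 (outcome) and a
#' 5,000-individual reference panel.
#'
#' @param m number of cis variants.
#' @param ld_rho AR(1) LD parameter.
#' @param maf_range range the per-variant allele frequencies are drawn from.
#' @param n_exposure,n_outcome,n_reference sample sizes (non-overlapping).
#' @param n_mediator sample size of the mediator (biomarker) GWAS, drawn as
#'   a fourth independent sample; biomarker GWAS are typically much larger
#'   than pQTL GWAS, and joint mediation modelling needs precise mediator
#'   betas.
#' @param gamma per-variant causal effects on the protein; default places
#'   an effect of 0.15 on every 10th variant.
#' @param theta true causal effect of the protein on the outcome (direct
#'   path; on the liability scale when the outcome is binary).
#' @param mediation optional named list of mediators, each
#'   `list(alpha = protein->mediator, beta_med = mediator->outcome)` with an
#'   optional `gamma` (length-m direct variant effects on the mediator;
#'   default a sparse pattern offset from the protein's causal variants, so
#'   mediators carry distinguishable genetic signatures — without distinct
#'   signatures joint mediation is unidentifiable); mediated paths add
#'   `alpha * beta_med` each to the total protein effect.
#' @param outcome_prevalence `NULL` for a continuous outcome; a fraction in
#'   (0, 1) thresholds the liability to a binary outcome at that prevalence.
#' @param discrete_dosage round genotype scores to {0,1,2} dosages.
#' @param window cis window the simulated positions are placed in.
#' @param seed mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m = 50, ld_rho = 0.8, maf_range = c(0.05, 0.5),
                       n_exposure = 10000, n_outcome = 50000,
                       n_reference = 5000, n_mediator = 50000,
                       gamma = NULL, theta = 0.2,
                       mediation = NULL, outcome_prevalence = NULL,
                       discrete_dosage = FALSE, window = cetp_window(),
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(m >= 2, abs(ld_rho) < 1, n_exposure >= 2, n_outcome >= 2,
            n_reference >= 2)
  if (is.null(gamma)) {
    gamma <- numeric(m)
    gamma[seq(1, m, by = 10)] <- 0.15
  }
  stopifnot(length(gamma) == m)
  if (!is.null(outcome_prevalence)) {
    stopifnot(outcome_prevalence > 0, outcome_prevalence < 1)
  }
  # each mediator gets a modest direct genetic signature of its own (cis
  # biomarker associations are mostly protein-mediated, but joint mediation
  # modelling is unidentifiable when mediator betas are exactly
  # proportional)
  for (j in seq_along(mediation)) {
    if (is.null(mediation[[j]]$gamma)) {
      delta <- numeric(m)
      delta[seq(min(3 + 2 * j, m), m, by = 10)] <- 0.15
      mediation[[j]]$gamma <- delta
    }
    stopifnot(length(mediation[[j]]$gamma) == m)
  }
  structure(list(m = m, ld_rho = ld_rho, maf_range = maf_range,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 n_reference = n_reference, n_mediator = n_mediator,
                 gamma = gamma, theta = theta,
                 mediation = mediation,
                 outcome_prevalence = outcome_prevalence,
                 discrete_dosage = discrete_dosage, window = window,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# standardized MVN genotype scores with correlation R (via its Cholesky root)
draw_scores <- function(n, chol_R) {
  m <- ncol(chol_R)
  matrix(stats::rnorm(n * m), n, m) %*% chol_R
}

# continuous scores -> [0, 2] dosage surrogates by one affine map (same
# scale for every column, so all pairwise correlations are preserved
# exactly)
scores_to_continuous_dosage <- function(scores) {
  1 + scores / max(abs(scores))
}

# latent scores -> {0,1,2} dosages through HWE thresholds at allele freq eaf
scores_to_dosage <- function(scores, eaf) {
  d <- matrix(0, nrow(scores), ncol(scores))
  for (j in seq_len(ncol(scores))) {
    p <- eaf[j]
    # genotype probabilities (1-p)^2, 2p(1-p), p^2 for dosage 0/1/2
    cut1 <- stats::qnorm((1 - p)^2)
    cut2 <- stats::qnorm((1 - p)^2 + 2 * p * (1 - p))
    d[, j] <- (scores[, j] > cut1) + (scores[, j] > cut2)
  }
  d
}

# vectorized per-variant marginal regressions
marginal_stats <- function(G, y, binary = FALSE) {
  n <- nrow(G)
  Gc <- sweep(G, 2, colMeans(G))
  if (binary) {
    # one-step score estimator with logistic link: beta = U / V, se = V^-1/2
    ybar <- mean(y)
    U <- drop(crossprod(Gc, y - ybar))
    V <- ybar * (1 - ybar) * colSums(Gc^2)
    beta <- U / V
    se <- 1 / sqrt(V)
  } else {
    yc <- y - mean(y)
    Sxx <- colSums(Gc^2)
    Sxy <- drop(crossprod(Gc, yc))
    Syy <- sum(yc^2)
    beta <- Sxy / Sxx
    rss <- pmax(Syy - beta^2 * Sxx, 0)
    se <- sqrt(rss / (n - 2) / Sxx)
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin)
  data.frame(beta = beta, se = se, pvalue = p, n = n)
}

sim_variant_frame <- function(cfg, stats_df, eaf) {
  w <- cfg$window
  pos <- w$start + round(seq(0, w$end - w$start, length.out = cfg$m))
  data.frame(variant_id = sprintf("sim%03d", seq_len(cfg$m)),
             chrom = w$chrom, pos = pos,
             effect_allele = "A", other_allele = "G",
             eaf = eaf, beta = stats_df$beta, se = stats_df$se,
             pvalue = stats_df$pvalue, n = stats_df$n,
             stringsAsFactors = FALSE)
}

#' Generate two-sample GWAS summary statistics with a reference panel
#'
#' Draws three independent samples. In the exposure sample the protein is
#' G gamma + noise and each configured mediator is alpha * protein + noise;
#' per-variant marginal regressions give the exposure and mediator summary
#' tables. In the outcome sample the outcome liability is
#' theta * protein + sum(beta_med * mediator) + noise, analysed continuous
#' or thresholded to the configured prevalence and analysed by per-variant
#' logistic score regression (log-odds betas). The reference sample is
#' emitted as a {0,1,2} dosage panel for LD estimation.
#'
#' @param cfg a [sim_config()].
#' @return list with `exposure` (protein [summary_table()]), `mediators`
#'   (named list of summary tables), `outcome` (summary table), `reference`
#'   (dosage matrix, individuals x variants, columns keyed), `truth`
#'   (generating parameters, incl. the total protein-on-outcome effect).
#' @export
gen_two_sample_summary <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$m
  R <- gen_ld_ar1(m, cfg$ld_rho)
  chol_R <- chol(R)
  eaf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])

  prep <- function(n) {
    sc <- draw_scores(n, chol_R)
    if (cfg$discrete_dosage) {
      d <- scores_to_dosage(sc, eaf)
      scale(d)
    } else sc
  }

  med_names <- names(cfg$mediation)
  alpha <- vapply(cfg$mediation, `[[`, numeric(1), "alpha")
  beta_med <- vapply(cfg$mediation, `[[`, numeric(1), "beta_med")
  delta <- lapply(cfg$mediation, `[[`, "gamma")

  # exposure sample: protein GWAS
  Gx <- prep(cfg$n_exposure)
  protein_x <- drop(Gx %*% cfg$gamma) + stats::rnorm(cfg$n_exposure)
  exp_stats <- marginal_stats(Gx, protein_x)

  # mediator (biomarker) GWAS in their own, larger, independent sample
  mediator_tables <- list()
  if (length(med_names) > 0) {
    Gm <- prep(cfg$n_mediator)
    protein_m <- drop(Gm %*% cfg$gamma) + stats::rnorm(cfg$n_mediator)
    for (j in seq_along(med_names)) {
      med_m <- alpha[j] * protein_m + drop(Gm %*% delta[[j]]) +
        stats::rnorm(cfg$n_mediator)
      ms <- marginal_stats(Gm, med_m)
      mediator_tables[[med_names[j]]] <- summary_table(
        sim_variant_frame(cfg, ms, eaf), trait_name = med_names[j],
        trait_type = "continuous", unit = "SD", build = cfg$window$build)
    }
  }

  # outcome sample (independent individuals)
  Gy <- prep(cfg$n_outcome)
  protein_y <- drop(Gy %*% cfg$gamma) + stats::rnorm(cfg$n_outcome)
  liab <- cfg$theta * protein_y + stats::rnorm(cfg$n_outcome)
  for (j in seq_along(med_names)) {
    med_y <- alpha[j] * protein_y + drop(Gy %*% delta[[j]]) +
      stats::rnorm(cfg$n_outcome)
    liab <- liab + beta_med[j] * med_y
  }
  binary <- !is.null(cfg$outcome_prevalence)
  if (binary) {
    thr <- stats::quantile(liab, 1 - cfg$outcome_prevalence)
    y <- as.numeric(liab > thr)
    if (sum(y) < 2 || sum(y) > length(y) - 2) {
      stop("gen_two_sample_summary: infeasible outcome prevalence")
    }
  } else {
    y <- liab
  }
  out_stats <- marginal_stats(Gy, y, binary = binary)

  # reference panel, emitted as dosages in [0, 2]; in continuous mode an
  # affine rescaling keeps the panel's correlations identical to the
  # genotype scores the GWAS samples used
  ref_scores <- draw_scores(cfg$n_reference, chol_R)
  reference <- if (cfg$discrete_dosage) scores_to_dosage(ref_scores, eaf)
               else scores_to_continuous_dosage(ref_scores)

  exposure <- summary_table(sim_variant_frame(cfg, exp_stats, eaf),
                            trait_name = "protein", trait_type = "continuous",
                            unit = "SD", build = cfg$window$build)
  outcome <- summary_table(
    sim_variant_frame(cfg, out_stats, eaf),
    trait_name = "outcome",
    trait_type = if (binary) "binary" else "continuous",
    unit = if (binary) "logOR" else "SD", build = cfg$window$build)
  rec <- exposure$records
  colnames(reference) <- variant_key(rec$chrom, rec$pos, rec$effect_allele,
                                     rec$other_allele)

  theta_total <- cfg$theta + if (length(med_names)) sum(alpha * beta_med) else 0
  list(exposure = exposure, mediators = mediator_tables, outcome = outcome,
       reference = reference,
       truth = list(config = cfg, ld = R, eaf = eaf, gamma = cfg$gamma,
                    theta = cfg$theta, theta_total = theta_total,
                    mediation = cfg$mediation))
}

#' Trial-set simulation configuration
#'
#' Default compounds emulate the four CETP inhibitors taken to phase 3:
#' per-compound true mean differences in percent change from baseline for
#' HDL-C and LDL-C and true log-ORs on a composite cardiovascular endpoint,
#' with study counts 6/4/4/1 (anacetrapib, dalcetrapib, torcetrapib,
#' evacetrapib).
#'
#' @param compounds named list; each element
#'   `list(md = c(outcome = true MD%), logor = c(outcome = true log-OR),
#'   n_trials = count)`.
#' @param arm_size participants per arm (>= 10).
#' @param control_risk control-arm event risk for binary outcomes.
#' @param md_sd subject-level SD of percent change (drives MD standard
#'   errors as `md_sd * sqrt(2 / arm_size)`).
#' @param seed mandatory RNG seed.
#' @return A `trial_sim_config` list.
#' @export
trial_sim_config <- function(compounds = NULL, arm_size = 2500,
                             control_risk = 0.08, md_sd = 40, seed) {
  if (missing(seed)) stop("trial_sim_config: seed is mandatory")
  if (is.null(compounds)) {
    compounds <- list(
      anacetrapib = list(md = c(HDL = 130, LDL = -38),
                         logor = c(CVD = log(0.93)), n_trials = 6),
      dalcetrapib = list(md = c(HDL = 29, LDL = -1),
                         logor = c(CVD = 0), n_trials = 4),
      torcetrapib = list(md = c(HDL = 52, LDL = -20),
                         logor = c(CVD = log(1.22)), n_trials = 4),
      evacetrapib = list(md = c(HDL = 132, LDL = -37),
                         logor = c(CVD = log(0.91)), n_trials = 1)
    )
  }
  stopifnot(arm_size >= 10, control_risk > 0, control_risk < 1)
  structure(list(compounds = compounds, arm_size = arm_size,
                 control_risk = control_risk, md_sd = md_sd,
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

#' Generate a multi-compound trial dataset
#'
#' Per trial, binary events are drawn binomially in both arms with the
#' treatment-arm risk set by the compound's true log-OR; continuous
#' outcomes are drawn normally around the compound's true MD with
#' se = md_sd * sqrt(2 / arm_size) and reported with a 95% CI. The output
#' conforms to the [read_trials()] CSV schema.
#'
#' @param cfg a [trial_sim_config()].
#' @return data.frame of trial outcomes with a `truth` attribute.
#' @export
gen_trialset <- function(cfg) {
  stopifnot(inherits(cfg, "trial_sim_config"))
  set.seed(cfg$seed)
  rows <- list()
  for (cname in names(cfg$compounds)) {
    comp <- cfg$compounds[[cname]]
    for (t in seq_len(comp$n_trials)) {
      study <- sprintf("%s_trial%02d", cname, t)
      for (oc in names(comp$md)) {
        se <- cfg$md_sd * sqrt(2 / cfg$arm_size)
        md <- stats::rnorm(1, comp$md[[oc]], se)
        rows[[length(rows) + 1]] <- data.frame(
          study_id = study, compound = cname, outcome = oc,
          type = "continuous", t_events = NA, t_total = cfg$arm_size,
          c_events = NA, c_total = cfg$arm_size, md = md,
          ci_low = md - 1.959964 * se, ci_high = md + 1.959964 * se,
          se = se, followup_months = 24, stringsAsFactors = FALSE)
      }
      for (oc in names(comp$logor)) {
        p0 <- cfg$control_risk
        p1 <- stats::plogis(stats::qlogis(p0) + comp$logor[[oc]])
        rows[[length(rows) + 1]] <- data.frame(
          study_id = study, compound = cname, outcome = oc,
          type = "binary",
          t_events = stats::rbinom(1, cfg$arm_size, p1),
          t_total = cfg$arm_size,
          c_events = stats::rbinom(1, cfg$arm_size, p0),
          c_total = cfg$arm_size, md = NA, ci_low = NA, ci_high = NA,
          se = NA, followup_months = 24, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- cfg
  out
}
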