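# End-to-end orchestration: simulate -> instruments -> MR/MVMR -> trial
# meta-analysis -> concordance, driven by one YAML config, with a run
# manifest capturing every threshold, seed, record count, and output
# checksum.

#' Run drug-target MR for one exposure/outcome pair
#'
#' The full per-outcome chain: harmonize, MAF + F filters, LD from the
#' reference panel, greedy clumping (re-run per outcome on the harmonized
#' intersection), optional leverage/outlier pruning, GLS-IVW, canonical
#' orientation.
#'
#' @param exposure cis-windowed exposure [summary_table()].
#' @param outcome outcome [summary_table()].
#' @param reference dosage matrix (individuals x variants, keyed columns)
#'   or a precomputed signed LD matrix with keyed dimnames.
#' @param maf_min,f_min,r2_max instrument thresholds (defaults 0.01, 15,
#'   0.40).
#' @param prune apply [prune_leverage_outliers()] before estimation.
#' @param leverage_mult,alpha pruning thresholds.
#' @param direction canonical orientation for the exposure
#'   (`"decrease"`/`"increase"`).
#' @param overdispersion see [gls_ivw()].
#' @return An oriented `mr_result`; instrument bookkeeping in its
#'   `excluded` element and `instruments` attribute.
#' @export
run_mr <- function(exposure, outcome, reference, maf_min = 0.01, f_min = 15,
                   r2_max = 0.40, prune = TRUE, leverage_mult = 3,
                   alpha = 0.05, direction = "decrease",
                   overdispersion = FALSE) {
  pairs <- harmonize(exposure, outcome)
  if (nrow(pairs) == 0) stop("run_mr: no variants survived harmonization")
  ld <- if (is.matrix(reference) && nrow(reference) == ncol(reference) &&
            isTRUE(all.equal(unname(diag(reference)), rep(1, ncol(reference))))) {
    reference
  } else {
    ld_from_reference(reference[, pair_keys(pairs), drop = FALSE])
  }
  iset <- select_instruments(pairs, ld, maf_min = maf_min, f_min = f_min,
                             r2_max = r2_max)
  if (nrow(iset$pairs) == 0) stop("run_mr: no instruments left after filters")
  input <- mr_input(iset$pairs$b_x, iset$pairs$s_x, iset$pairs$b_y,
                    iset$pairs$s_y, iset$ld, keys = pair_keys(iset$pairs),
                    exposure = exposure$trait_name,
                    outcome = outcome$trait_name,
                    exposure_unit = exposure$unit,
                    outcome_unit = outcome$unit)
  pruned_log <- data.frame(key = character(0), reason = character(0),
                           statistic = numeric(0))
  if (prune && length(input$b_x) >= 3) {
    pr <- prune_leverage_outliers(input, leverage_mult = leverage_mult,
                                  alpha = alpha)
    input <- pr$input
    pruned_log <- pr$exclusions
  }
  res <- gls_ivw(input, overdispersion = overdispersion)
  removed <- iset$filter_log$flag != "kept"
  res$excluded <- rbind(
    data.frame(key = iset$filter_log$key[removed],
               reason = iset$filter_log$flag[removed],
               statistic = rep(NA_real_, sum(removed)),
               stringsAsFactors = FALSE),
    pruned_log)
  res <- orient_canonical(res, direction)
  attr(res, "instruments") <- iset
  res
}

default_config <- function() {
  list(
    seed = 1L,
    gwas = list(m = 50, ld_rho = 0.8, n_exposure = 10000, n_outcome = 50000,
                n_reference = 5000, theta = 0.15, outcome_prevalence = 0.1,
                mediation = list(HDL = list(alpha = -0.5, beta_med = -0.2),
                                 LDL = list(alpha = 0.4, beta_med = 0.4))),
    instruments = list(maf_min = 0.01, f_min = 15, r2_max = 0.40),
    mr = list(overdispersion = FALSE, prune = TRUE, leverage_mult = 3,
              alpha = 0.05, direction = "decrease"),
    trials = list(arm_size = 2500, control_risk = 0.08, md_sd = 40),
    concordance = list(floor = 1e-60, transform = "sqrt_signed",
                       metric = "euclidean", linkage = "complete"),
    stages = c("simulate", "mr", "meta", "concord")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  known <- names(default_config())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("config error: unknown top-level key(s): ",
         paste(unknown, collapse = ", "))
  }
  stopifnot(is.numeric(cfg$seed),
            cfg$instruments$r2_max > 0, cfg$instruments$r2_max <= 1,
            cfg$mr$direction %in% c("increase", "decrease"))
  invisible(cfg)
}

#' Run the full pipeline from a YAML config
#'
#' Stages (`simulate`, `mr`, `meta`, `concord`) execute in order; each
#' stage's tables are flushed to `out_dir` as it completes, so a failure
#' preserves everything upstream. Identical config + seed gives bit-identical
#' outputs. Defaults for every unset key are filled in and echoed into the
#' manifest — nothing is silently implicit.
#'
#' @param config path to a YAML config, or an equivalent named list.
#' @param out_dir output directory (created); default a tempdir subdir.
#' @return list with `sim`, `mr_results`, `mvmr`, `meta`, `concord`,
#'   `manifest` (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("targetmr_run")) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(default_config(), cfg)
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package_version = as.character(utils::packageVersion("targetmr")),
                   config = cfg, seed = cfg$seed, counts = list(),
                   stages_run = character(0))
  results <- list()
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  # ---- simulate ----
  if ("simulate" %in% cfg$stages) {
    g <- cfg$gwas
    # demo semantics: biomarkers are purely protein-mediated unless the
    # config plants explicit direct variant effects, so the univariable
    # biomarker-outcome MRs are correctly specified
    for (j in seq_along(g$mediation)) {
      if (is.null(g$mediation[[j]]$gamma)) g$mediation[[j]]$gamma <- numeric(g$m)
    }
    scfg <- sim_config(m = g$m, ld_rho = g$ld_rho,
                       n_exposure = g$n_exposure, n_outcome = g$n_outcome,
                       n_reference = g$n_reference, theta = g$theta,
                       mediation = g$mediation,
                       outcome_prevalence = g$outcome_prevalence,
                       seed = cfg$seed)
    sim <- gen_two_sample_summary(scfg)
    tcfg <- trial_sim_config(arm_size = cfg$trials$arm_size,
                             control_risk = cfg$trials$control_risk,
                             md_sd = cfg$trials$md_sd,
                             seed = cfg$seed + 1L)
    trials <- gen_trialset(tcfg)
    write_summary_stats(sim$exposure, file.path(out_dir, "exposure.tsv"))
    write_summary_stats(sim$outcome, file.path(out_dir, "outcome.tsv"))
    for (nm in names(sim$mediators)) {
      write_summary_stats(sim$mediators[[nm]],
                          file.path(out_dir, paste0("mediator_", nm, ".tsv")))
    }
    write_dosages(sim$reference, file.path(out_dir, "reference_dosages.tsv"))
    utils::write.csv(trials, file.path(out_dir, "trials.csv"), row.names = FALSE)
    results$sim <- sim
    results$trials <- trials
    manifest$counts$simulated_variants <- nrow(sim$exposure$records)
    manifest$counts$simulated_trial_rows <- nrow(trials)
    manifest$stages_run <- c(manifest$stages_run, "simulate")
    flush_manifest()
  }

  # ---- mr ----
  if ("mr" %in% cfg$stages) {
    sim <- results$sim
    if (is.null(sim)) stop("mr stage requires the simulate stage (or local files)")
    ins <- cfg$instruments
    outcomes <- c(list(CVD = sim$outcome),
                  stats::setNames(sim$mediators, names(sim$mediators)))
    mr_results <- lapply(outcomes, function(oc) {
      run_mr(sim$exposure, oc, sim$reference,
             maf_min = ins$maf_min, f_min = ins$f_min, r2_max = ins$r2_max,
             prune = cfg$mr$prune, leverage_mult = cfg$mr$leverage_mult,
             alpha = cfg$mr$alpha, direction = cfg$mr$direction,
             overdispersion = cfg$mr$overdispersion)
    })
    names(mr_results) <- names(outcomes)
    mr_table <- do.call(rbind, lapply(names(mr_results), function(nm) {
      r <- mr_results[[nm]]
      data.frame(exposure = r$exposure, outcome = nm, theta = r$theta,
                 se = r$se, p = r$p, Q = r$Q, df_Q = r$df_Q,
                 m_used = r$m_used, orientation = r$orientation,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(mr_table, file.path(out_dir, "mr_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    excl <- do.call(rbind, lapply(names(mr_results), function(nm) {
      e <- mr_results[[nm]]$excluded
      if (nrow(e) == 0) return(NULL)
      cbind(outcome = nm, e)
    }))
    if (!is.null(excl)) {
      utils::write.table(excl, file.path(out_dir, "mr_exclusions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # MVMR over the mediators, when at least two are present
    if (length(sim$mediators) >= 2) {
      pairs_y <- harmonize(sim$exposure, sim$outcome)
      ld <- ld_from_reference(sim$reference[, pair_keys(pairs_y), drop = FALSE])
      iset <- select_instruments(pairs_y, ld, maf_min = ins$maf_min,
                                 f_min = ins$f_min, r2_max = ins$r2_max)
      keys <- pair_keys(iset$pairs)
      B <- sapply(sim$mediators, function(tb) {
        idx <- match(keys, variant_key(tb$records$chrom, tb$records$pos,
                                       tb$records$effect_allele,
                                       tb$records$other_allele))
        tb$records$beta[idx]
      })
      mv <- mvmr_input(B, iset$pairs$b_y, iset$pairs$s_y, iset$ld,
                       exposure_names = names(sim$mediators), keys = keys,
                       outcome = "CVD")
      results$mvmr <- mvmr_gls(mv)
    }
    results$mr_results <- mr_results
    results$mr_table <- mr_table
    manifest$counts$mr_instruments <-
      stats::setNames(vapply(mr_results, `[[`, numeric(1), "m_used"),
                      names(mr_results))
    manifest$thresholds <- c(ins, cfg$mr[c("leverage_mult", "alpha")])
    manifest$stages_run <- c(manifest$stages_run, "mr")
    flush_manifest()
  }

  # ---- meta ----
  if ("meta" %in% cfg$stages) {
    trials <- results$trials
    if (is.null(trials)) stop("meta stage requires trials")
    outcomes <- unique(trials$outcome)
    meta <- lapply(outcomes, function(oc) meta_by_compound(trials, oc))
    names(meta) <- outcomes
    meta_table <- do.call(rbind, lapply(outcomes, function(oc) {
      pc <- meta[[oc]]$per_compound
      do.call(rbind, lapply(names(pc), function(cn) {
        f <- pc[[cn]]$fixed
        data.frame(outcome = oc, compound = cn, effect = f$effect, se = f$se,
                   ci_low = f$ci_low, ci_high = f$ci_high, Q = f$Q,
                   k = f$k_studies, scale = f$scale, stringsAsFactors = FALSE)
      }))
    }))
    utils::write.table(meta_table, file.path(out_dir, "meta_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$meta <- meta
    results$meta_table <- meta_table
    manifest$counts$meta_outcomes <- length(outcomes)
    manifest$stages_run <- c(manifest$stages_run, "meta")
    flush_manifest()
  }

  # ---- concord ----
  if ("concord" %in% cfg$stages) {
    if (is.null(results$mr_table) || is.null(results$meta_table)) {
      stop("concord stage requires mr and meta stages")
    }
    mr_src <- data.frame(outcome = results$mr_table$outcome,
                         effect = results$mr_table$theta,
                         se = results$mr_table$se, stringsAsFactors = FALSE)
    sources <- list(`MR target` = mr_src)
    for (cn in unique(results$meta_table$compound)) {
      d <- results$meta_table[results$meta_table$compound == cn, ]
      sources[[cn]] <- data.frame(outcome = d$outcome, effect = d$effect,
                                  se = d$se, stringsAsFactors = FALSE)
    }
    em <- build_evidence_matrix(sources, floor = cfg$concordance$floor)
    cl <- cluster_matrix(em, transform = cfg$concordance$transform,
                         metric = cfg$concordance$metric,
                         linkage = cfg$concordance$linkage)
    write_evidence_matrix(em, file.path(out_dir, "evidence_matrix.tsv"))
    if (!is.null(cl$col_hclust)) {
      writeLines(dendrogram_newick(cl$col_hclust),
                 file.path(out_dir, "columns.nwk"))
    }
    if (!is.null(cl$row_hclust)) {
      writeLines(dendrogram_newick(cl$row_hclust),
                 file.path(out_dir, "rows.nwk"))
    }
    results$evidence <- em
    results$concord <- cl
    manifest$counts$evidence_cells <- sum(!em$mask)
    manifest$stages_run <- c(manifest$stages_run, "concord")
    flush_manifest()
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$checksums <- as.list(tools::md5sum(files))
  names(manifest$checksums) <- basename(files)
  flush_manifest()
  results$manifest <- manifest
  results$out_dir <- out_dir
  results
}
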