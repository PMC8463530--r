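# Instrument selection: MAF / F filters, LD estimation from a reference
# dosage panel, greedy clumping. The LD matrix stores signed r oriented to
# the harmonized effect alleles; clumping consumes r^2, GLS consumes r.

#' Project a correlation matrix to the non-negative-definite cone
#'
#' Floors eigenvalues at zero (tolerance `tol`) and restores the unit
#' diagonal; warns when a repair was needed, reporting its magnitude.
#'
#' @param r symmetric correlation matrix.
#' @param tol eigenvalues below `-tol` trigger a repair.
#' @return A non-negative-definite correlation matrix.
#' @export
make_psd <- function(r, tol = 1e-8) {
  eg <- eigen(r, symmetric = TRUE)
  if (min(eg$values) >= -tol) return(r)
  vals <- pmax(eg$values, 0)
  out <- eg$vectors %*% (vals * t(eg$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(r)
  warning(sprintf("LD matrix repaired to PSD (smallest eigenvalue was %.3g)",
                  min(eg$values)))
  out
}

#' MAF and F-statistic instrument filters
#'
#' Per-variant instrument strength is the squared Wald ratio
#' F = (b_x / s_x)^2. Variants are retained when F >= `f_min` and
#' min(eaf, 1 - eaf) >= `maf_min`. Defaults follow the weak-instrument
#' policy of F >= 15 and MAF >= 0.01. Each removed variant is logged with
#' its first failing filter (MAF checked first).
#'
#' @param pairs a `harmonized_pairs` object (see [harmonize()]).
#' @param maf_min minimum minor-allele frequency; requires EAF when > 0.
#' @param f_min minimum single-variant F-statistic.
#' @return Filtered `harmonized_pairs` with attributes `filter_log`
#'   (data.frame key/flag) and `f_stats` (named F per input variant).
#' @export
apply_instrument_filters <- function(pairs, maf_min = 0.01, f_min = 15) {
  keys <- pair_keys(pairs)
  f <- (pairs$b_x / pairs$s_x)^2
  names(f) <- keys
  if (maf_min > 0 && anyNA(pairs$eaf)) {
    stop("apply_instrument_filters: maf_min > 0 but EAF is missing for ",
         sum(is.na(pairs$eaf)), " variant(s)")
  }
  maf_ok <- if (maf_min > 0) pmin(pairs$eaf, 1 - pairs$eaf) >= maf_min
            else rep(TRUE, nrow(pairs))
  f_ok <- f >= f_min
  flag <- ifelse(!maf_ok, "maf_fail", ifelse(!f_ok, "f_fail", "kept"))
  out <- pairs[maf_ok & f_ok, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(pairs)
  for (a in c("actions", "exposure_trait", "outcome_trait",
              "exposure_unit", "outcome_unit")) {
    attr(out, a) <- attrs[[a]]
  }
  class(out) <- class(pairs)
  attr(out, "filter_log") <- data.frame(key = keys, flag = flag,
                                        stringsAsFactors = FALSE)
  attr(out, "f_stats") <- f
  out
}

#' Signed LD matrix from a reference dosage panel
#'
#' Pairwise Pearson correlation of effect-allele dosage columns. Columns
#' whose reference effect allele differs from the harmonized effect allele
#' are reflected (d -> 2 - d) before correlating, so the matrix is oriented
#' to the harmonized alleles. The result is repaired to non-negative
#' definiteness by eigenvalue flooring when sampling noise pushes it outside
#' the cone.
#'
#' @param dosages numeric matrix, individuals x variants, entries in
#'   \[0, 2\]; column names are variant keys.
#' @param flip logical per-column vector: `TRUE` where the reference panel's
#'   effect allele differs from the harmonized effect allele.
#' @return Signed correlation matrix (class `ld_matrix`) with the dosage
#'   column names.
#' @export
ld_from_reference <- function(dosages, flip = rep(FALSE, ncol(dosages))) {
  stopifnot(is.matrix(dosages), nrow(dosages) >= 2, length(flip) == ncol(dosages))
  v <- apply(dosages, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(dosages)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("ld_from_reference: zero-variance dosage column(s): ",
         paste(bad, collapse = ", "))
  }
  d <- dosages
  d[, flip] <- 2 - d[, flip, drop = FALSE]
  r <- stats::cor(d)
  r <- make_psd(r)
  class(r) <- c("ld_matrix", class(r))
  r
}

#' Read a reference dosage matrix
#'
#' Tab-delimited dialect: first row holds the variant keys, subsequent rows
#' per-individual effect-allele dosages in \[0, 2\].
#'
#' @param path file path.
#' @return Numeric matrix, individuals x variants.
#' @export
read_dosages <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  as.matrix(d)
}

#' @rdname read_dosages
#' @param dosages matrix to write.
#' @export
write_dosages <- function(dosages, path) {
  utils::write.table(dosages, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Greedy LD clumping
#'
#' Variants are ranked by the clumping p-value ascending (ties broken by
#' smaller position); the top-ranked unprocessed variant is kept and every
#' remaining variant with r^2 strictly greater than `r2_max` against ANY
#' kept variant is removed. Boundary r^2 exactly equal to `r2_max` is
#' retained. Output is invariant to input order.
#'
#' @param pairs a `harmonized_pairs` object.
#' @param ld signed LD matrix covering all of `pairs` (keyed like
#'   [pair_keys()]).
#' @param r2_max clumping threshold, default 0.40.
#' @param rank_p p-values used for ranking; defaults to the exposure p
#'   (`pairs$p_x`). Biomarker-weighted analyses pass the weighting trait's p.
#' @return An `instrument_set`: list with `pairs` (survivors), `ld`
#'   (restricted, ordered to survivors), `filter_log`, `f_stats`.
#' @export
greedy_clump <- function(pairs, ld, r2_max = 0.40, rank_p = pairs$p_x) {
  stopifnot(r2_max > 0, r2_max <= 1)
  keys <- pair_keys(pairs)
  m <- nrow(pairs)
  if (m == 0) {
    return(structure(list(pairs = pairs, ld = matrix(numeric(0), 0, 0),
                          filter_log = data.frame(key = character(0),
                                                  flag = character(0)),
                          f_stats = numeric(0)),
                     class = "instrument_set"))
  }
  if (!all(keys %in% colnames(ld))) {
    stop("greedy_clump: LD matrix does not cover all variants")
  }
  r <- ld[keys, keys, drop = FALSE]
  ord <- order(rank_p, pairs$pos)
  kept <- logical(m)
  removed <- logical(m)
  for (i in ord) {
    if (removed[i]) next
    kept[i] <- TRUE
    r2 <- r[i, ]^2
    prune <- r2 > r2_max & !kept
    removed[prune] <- TRUE
  }
  flag <- ifelse(kept, "kept", "clump_removed")
  out_pairs <- pairs[kept, , drop = FALSE]
  rownames(out_pairs) <- NULL
  out_ld <- r[kept, kept, drop = FALSE]
  prior_log <- attr(pairs, "filter_log")
  f <- attr(pairs, "f_stats")
  if (is.null(f)) f <- stats::setNames((pairs$b_x / pairs$s_x)^2, keys)
  log_now <- data.frame(key = keys, flag = flag, stringsAsFactors = FALSE)
  if (!is.null(prior_log)) {
    log_now <- rbind(prior_log[prior_log$flag != "kept", , drop = FALSE], log_now)
  }
  # each removed variant carries exactly one (first-failing) reason
  structure(list(pairs = out_pairs, ld = out_ld, filter_log = log_now,
                 f_stats = f[keys[kept]]),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", nrow(x$pairs), "variants")
  if (nrow(x$pairs) > 1) {
    off <- x$ld[upper.tri(x$ld)]
    cat(sprintf("; max off-diagonal r^2 = %.3f", max(off^2)))
  }
  cat("\n")
  invisible(x)
}

#' Filter, clump, and package instruments in one call
#'
#' Convenience composition of [apply_instrument_filters()] and
#' [greedy_clump()].
#'
#' @inheritParams apply_instrument_filters
#' @inheritParams greedy_clump
#' @return An `instrument_set`.
#' @export
select_instruments <- function(pairs, ld, maf_min = 0.01, f_min = 15,
                               r2_max = 0.40, rank_p = NULL) {
  filtered <- apply_instrument_filters(pairs, maf_min = maf_min, f_min = f_min)
  if (is.null(rank_p)) rank_p <- filtered$p_x
  else rank_p <- rank_p[pair_keys(pairs) %in% pair_keys(filtered)]
  greedy_clump(filtered, ld, r2_max = r2_max, rank_p = rank_p)
}
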