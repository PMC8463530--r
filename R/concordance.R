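# Direction-signed -log10(p) evidence scores and the outcomes x sources
# matrix they populate, compared across genetic (MR) and trial
# (per-compound) evidence by hierarchical clustering.

#' Direction-signed -log10(p) evidence score
#'
#' z = effect / se; p is the two-sided normal tail, floored at `floor`;
#' the score is sign(effect) * (-log10 p). A p of 0.05 maps to 1.3 (|z| =
#' 1.96). Two conventional floors: 1e-16 for heatmap exports and 1e-60 for
#' the clustering matrix. A zero effect scores 0.
#'
#' @param effect oriented effect estimate(s).
#' @param se positive SE(s).
#' @param floor p-value truncation floor in (0, 1).
#' @return signed -log10(p), vectorized.
#' @export
signed_logp <- function(effect, se, floor = 1e-60) {
  stopifnot(all(se > 0), floor > 0, floor < 1)
  z <- abs(effect) / se
  # log-scale tail keeps precision for extreme z before the floor bites
  log10p <- (stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
  val <- pmin(-log10p, -log10(floor))
  out <- sign(effect) * val
  out[effect == 0] <- 0
  out
}

#' Assemble the outcomes x evidence-sources matrix
#'
#' One column per evidence source (MR target estimates, per-compound meta
#' estimates), one row per outcome appearing in any source. Cells hold
#' [signed_logp()] of the source's oriented estimate. Rows with missing
#' cells are retained (with a missingness mask) but excluded from
#' clustering.
#'
#' @param sources named list; each element a data.frame with columns
#'   `outcome`, `effect`, `se` (oriented to the canonical direction).
#' @param outcome_whitelist optional character vector restricting the rows.
#' @param floor p truncation floor, default 1e-60 (the clustering floor).
#' @return An `evidence_matrix`: list with `values` (matrix, NA where
#'   missing), `mask` (logical matrix of missingness), `floor`.
#' @export
build_evidence_matrix <- function(sources, outcome_whitelist = NULL,
                                  floor = 1e-60) {
  stopifnot(is.list(sources), length(sources) >= 1, !is.null(names(sources)))
  outcomes <- unique(unlist(lapply(sources, function(s) s$outcome)))
  if (!is.null(outcome_whitelist)) outcomes <- intersect(outcomes, outcome_whitelist)
  shared <- Reduce(intersect, lapply(sources, function(s) s$outcome))
  if (!is.null(outcome_whitelist)) shared <- intersect(shared, outcome_whitelist)
  if (length(shared) == 0) {
    stop("build_evidence_matrix: no outcome is shared by all sources")
  }
  values <- matrix(NA_real_, length(outcomes), length(sources),
                   dimnames = list(outcomes, names(sources)))
  for (src in names(sources)) {
    s <- sources[[src]]
    idx <- match(s$outcome, outcomes)
    ok <- !is.na(idx)
    values[idx[ok], src] <- signed_logp(s$effect[ok], s$se[ok], floor = floor)
  }
  structure(list(values = values, mask = is.na(values), floor = floor),
            class = "evidence_matrix")
}

#' @export
print.evidence_matrix <- function(x, ...) {
  cat("Evidence matrix:", nrow(x$values), "outcomes x", ncol(x$values),
      "sources; p floor", format(x$floor), "\n")
  print(round(x$values, 2))
  invisible(x)
}

#' Hierarchically cluster an evidence matrix
#'
#' Rows with any missing cell are dropped (logged in the result) before
#' clustering. The `sqrt_signed` transform maps v to sign(v) * sqrt(|v|)
#' (the clustering is done on the square root of the signed -log10 p),
#' `none` leaves the scores untouched. Rows and columns are clustered
#' agglomeratively with the configured distance metric and linkage.
#'
#' @param m an `evidence_matrix` or plain numeric matrix.
#' @param transform `"sqrt_signed"` (default) or `"none"`.
#' @param metric distance metric for [stats::dist()], default `"euclidean"`.
#' @param linkage agglomeration method for [stats::hclust()], default
#'   `"complete"`.
#' @return list with `row_hclust`, `col_hclust` (NULL when degenerate),
#'   `row_order`, `col_order` (leaf label orders), `matrix` (the transformed
#'   clustered submatrix), `dropped_rows`.
#' @export
cluster_matrix <- function(m, transform = c("sqrt_signed", "none"),
                           metric = "euclidean", linkage = "complete") {
  transform <- match.arg(transform)
  values <- if (inherits(m, "evidence_matrix")) m$values else as.matrix(m)
  complete <- stats::complete.cases(values)
  dropped <- rownames(values)[!complete]
  v <- values[complete, , drop = FALSE]
  if (transform == "sqrt_signed") v <- sign(v) * sqrt(abs(v))
  cl <- function(x) {
    if (nrow(x) < 2) return(NULL)
    stats::hclust(stats::dist(x, method = metric), method = linkage)
  }
  row_hc <- cl(v)
  col_hc <- cl(t(v))
  list(row_hclust = row_hc, col_hclust = col_hc,
       row_order = if (is.null(row_hc)) rownames(v) else rownames(v)[row_hc$order],
       col_order = if (is.null(col_hc)) colnames(v) else colnames(v)[col_hc$order],
       matrix = v, dropped_rows = dropped,
       metric = metric, linkage = linkage, transform = transform)
}

#' Dendrogram as a Newick string
#'
#' @param hc an `hclust` object (e.g. from [cluster_matrix()]).
#' @return single Newick-format string with branch lengths.
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Write an evidence matrix to a tab-delimited file
#'
#' @param m an `evidence_matrix`.
#' @param path output path.
#' @export
write_evidence_matrix <- function(m, path) {
  stopifnot(inherits(m, "evidence_matrix"))
  d <- data.frame(outcome = rownames(m$values), m$values, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
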