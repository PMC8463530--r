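# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's code paths: clumping is re-derived from the rule's
# wording, hierarchical clustering by naive agglomeration, GLS by direct
# matrix inversion.

make_records <- function(n, chrom = "16", pos = NULL, eaf = NULL,
                         effect = "A", other = "G", beta = NULL, se = NULL,
                         pvalue = NULL) {
  if (is.null(pos)) pos <- 56961923 + seq_len(n) * 100
  if (is.null(beta)) beta <- seq(0.1, 0.1 * n, length.out = n)
  if (is.null(se)) se <- rep(0.02, n)
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  if (is.null(eaf)) eaf <- rep(0.3, n)
  data.frame(variant_id = paste0("rs", seq_len(n)), chrom = chrom, pos = pos,
             effect_allele = rep(effect, length.out = n),
             other_allele = rep(other, length.out = n),
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = 10000,
             stringsAsFactors = FALSE)
}

make_table <- function(records, trait = "trait", type = "continuous",
                       unit = "SD", build = "GRCh38") {
  summary_table(records, trait_name = trait, trait_type = type, unit = unit,
                build = build)
}

# swap effect/other alleles of a summary table, negating beta and
# complementing eaf (the allele-swap transform harmonization undoes)
swap_alleles <- function(table, idx = seq_len(nrow(table$records))) {
  r <- table$records
  tmp <- r$effect_allele[idx]
  r$effect_allele[idx] <- r$other_allele[idx]
  r$other_allele[idx] <- tmp
  r$beta[idx] <- -r$beta[idx]
  r$eaf[idx] <- 1 - r$eaf[idx]
  table$records <- r
  table
}

# exhaustive restatement of the greedy clumping rule: repeatedly promote the
# remaining variant with the smallest p (ties: smallest position), then
# strike out every remaining variant exceeding r2_max against any promoted
# variant
oracle_clump <- function(p, pos, r, r2_max) {
  m <- length(p)
  status <- rep("candidate", m)
  while (any(status == "candidate")) {
    cand <- which(status == "candidate")
    best <- cand[order(p[cand], pos[cand])][1]
    status[best] <- "kept"
    kept <- which(status == "kept")
    for (j in which(status == "candidate")) {
      if (any(r[j, kept]^2 > r2_max)) status[j] <- "removed"
    }
  }
  which(status == "kept")
}

# naive agglomerative clustering returning the cophenetic distance matrix
oracle_complete_linkage_cophenetic <- function(x, metric = "euclidean") {
  n <- nrow(x)
  d <- as.matrix(dist(x, method = metric))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[2]]] <- c(a, b)
    clusters[[best[1]]] <- NULL
  }
  coph
}

# direct GLS through matrix inversion (no Cholesky, no shared helpers)
oracle_gls <- function(X, y, s_y, rho) {
  Om <- diag(s_y) %*% rho %*% diag(s_y)
  Oi <- solve(Om)
  V <- solve(t(X) %*% Oi %*% X)
  theta <- V %*% t(X) %*% Oi %*% y
  list(theta = drop(theta), se = sqrt(diag(V)))
}
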