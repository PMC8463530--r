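# Variant identity is chrom + pos + unordered allele pair; rsIDs are carried
# but never used for matching.
variant_key <- function(chrom, pos, a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  paste(chrom, pos, pmin(a1, a2), pmax(a1, a2), sep = ":")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) {
  a <- toupper(a)
  out <- DNA_COMPLEMENT[a]
  # indels / multi-base alleles have no strand complement here
  out[is.na(out)] <- a[is.na(out)]
  unname(out)
}

is_palindromic <- function(a1, a2) {
  complement_allele(a1) == toupper(a2)
}

#' GWAS summary-statistic table
#'
#' Container for per-variant association records of a single trait. Rows
#' violating the record invariants (non-positive SE, identical alleles,
#' allele frequency outside (0,1), p outside (0,1], pos < 1) are dropped and
#' counted; duplicate variant keys keep the first occurrence.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, and optionally
#'   `eaf` and `n`.
#' @param trait_name trait label.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param unit unit label on the beta scale (e.g. `"ug/ml"`, `"logOR"`).
#' @param build genome build label; all coordinates in one table share it.
#' @return An object of class `summary_table` with elements `trait_name`,
#'   `trait_type`, `unit`, `build`, `records` and a `rejections` attribute
#'   (data.frame of dropped rows with reasons).
#' @export
summary_table <- function(records, trait_name, trait_type = c("continuous", "binary"),
                          unit = "", build = "GRCh38") {
  trait_type <- match.arg(trait_type)
  needed <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
              "beta", "se", "pvalue")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("summary_table: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"eaf" %in% names(records)) records$eaf <- rep(NA_real_, nrow(records))
  if (!"n" %in% names(records)) records$n <- rep(NA_real_, nrow(records))
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  reason <- rep(NA_character_, nrow(records))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- why
  }
  bad(!is.finite(records$beta) | !is.finite(records$se) | !is.finite(records$pos),
      "unparseable_numeric")
  bad(records$se <= 0, "nonpositive_se")
  bad(records$effect_allele == records$other_allele, "identical_alleles")
  bad(!is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1), "eaf_out_of_range")
  bad(!is.finite(records$pvalue) | records$pvalue <= 0 | records$pvalue > 1,
      "pvalue_out_of_range")
  bad(records$pos < 1, "nonpositive_pos")

  key <- variant_key(records$chrom, records$pos, records$effect_allele,
                     records$other_allele)
  bad(duplicated(key), "duplicate_key")

  dropped <- records[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL

  out <- structure(
    list(trait_name = trait_name, trait_type = trait_type, unit = unit,
         build = build, records = kept),
    class = "summary_table"
  )
  attr(out, "rejections") <- dropped
  out
}

#' @export
print.summary_table <- function(x, ...) {
  cat("GWAS summary table:", x$trait_name,
      sprintf("(%s, unit: %s, build: %s)\n", x$trait_type, x$unit, x$build))
  cat(" ", nrow(x$records), "variants;", nrow(attr(x, "rejections")),
      "rows rejected at load\n")
  invisible(x)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited file with a header and maps its columns
#' onto the standard record fields via `column_map`. Rows failing record
#' invariants are dropped (not an error) and reported in the `rejections`
#' attribute of the result.
#'
#' @param path file path.
#' @param column_map named character vector mapping field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pvalue`, optionally `eaf`, `n`) to the file's column names.
#'   Unmapped fields default to identically named columns when present.
#' @param trait_name,trait_type,unit,build trait metadata, see
#'   [summary_table()].
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A [summary_table()].
#' @export
read_summary_stats <- function(path, column_map = character(),
                               trait_name = "trait",
                               trait_type = c("continuous", "binary"),
                               unit = "", build = "GRCh38", sep = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (length(header) && grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  mandatory <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se", "pvalue")
  optional <- c("eaf", "n")
  records <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in c(mandatory, optional)) {
    src <- if (field %in% names(column_map)) column_map[[field]] else field
    if (src %in% names(raw)) {
      records[[field]] <- raw[[src]]
    } else if (field %in% mandatory) {
      stop("read_summary_stats: mandatory column for field '", field,
           "' not found (looked for '", src, "')")
    }
  }
  if (nrow(raw) == 0) {
    # header-only files still need the mapped columns checked above
    records <- as.data.frame(sapply(mandatory, function(f) character(0),
                                    simplify = FALSE))
  }
  summary_table(records, trait_name = trait_name, trait_type = trait_type,
                unit = unit, build = build)
}

#' Write a summary table back to disk
#'
#' Emits the same dialect [read_summary_stats()] reads; numeric fields are
#' written at full precision so a read/write/read round trip is lossless.
#'
#' @param table a [summary_table()].
#' @param path output file path.
#' @param sep field separator, tab by default.
#' @export
write_summary_stats <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "summary_table"))
  rec <- table$records
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    rec[[col]] <- formatC(rec[[col]], digits = 17, format = "g")
    rec[[col]][rec[[col]] %in% c("NA", " NA")] <- NA
  }
  utils::write.table(rec, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cis window around a drug-target gene
#'
#' 1-based coordinates, inclusive on both bounds, tied to a declared genome
#' build. [cetp_window()] and [pcsk9_window()] give the GRCh38 regions used
#' for the CETP and PCSK9 analyses.
#'
#' @param chrom chromosome label.
#' @param start,end inclusive bounds, `start < end`.
#' @param build genome build label.
#' @return An object of class `cis_window`.
#' @export
cis_window <- function(chrom, start, end, build = "GRCh38") {
  stopifnot(start >= 1, start < end)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 build = build), class = "cis_window")
}

#' @rdname cis_window
#' @export
cetp_window <- function() cis_window("16", 56961923, 56985845, "GRCh38")

#' @rdname cis_window
#' @export
pcsk9_window <- function() cis_window("1", 55037447, 55066852, "GRCh38")

#' Restrict a summary table to a cis window
#'
#' Keeps records with matching chromosome and `start <= pos <= end`
#' (inclusive both ends). A build mismatch between table and window is an
#' error: no silent liftover.
#'
#' @param table a [summary_table()].
#' @param window a [cis_window()].
#' @return A [summary_table()] with the windowed records.
#' @export
extract_cis_window <- function(table, window) {
  stopifnot(inherits(table, "summary_table"), inherits(window, "cis_window"))
  if (!identical(table$build, window$build)) {
    stop("extract_cis_window: build mismatch (table: ", table$build,
         ", window: ", window$build, "); liftover is not supported")
  }
  keep <- table$records$chrom == window$chrom &
    table$records$pos >= window$start & table$records$pos <= window$end
  out <- table
  out$records <- table$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  attr(out, "rejections") <- attr(table, "rejections")
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome table to the exposure's effect alleles per variant.
#' Variants are matched on chrom + pos + unordered allele pair, trying the
#' outcome alleles as listed, swapped, strand-complemented, and
#' complement-swapped. A swap negates the outcome beta and complements its
#' EAF. Palindromic variants (A/T or C/G) are orientation-ambiguous: they are
#' resolved by EAF concordance when both EAFs lie outside
#' (`palindrome_eaf_limit`, 1 - `palindrome_eaf_limit`), and dropped
#' otherwise (or always, with `drop_palindromic = TRUE`). Every action is
#' logged per variant.
#'
#' @param exposure cis-windowed exposure [summary_table()] (e.g. the pQTL).
#' @param outcome outcome [summary_table()] on the same build.
#' @param palindrome_eaf_limit EAF band half-width for palindromic
#'   resolution; default 0.42.
#' @param drop_palindromic if `TRUE`, drop all palindromic variants
#'   unconditionally (strict mode).
#' @return An object of class `harmonized_pairs`: a data.frame with columns
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `eaf_outcome`, `b_x`, `s_x`, `p_x`, `b_y`, `s_y`, `p_y`, `n_x`, `n_y`,
#'   plus an `actions` attribute logging
#'   kept-as-is / sign-flipped / strand-complemented / dropped-palindromic /
#'   dropped-unmatched per exposure variant.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42,
                      drop_palindromic = FALSE) {
  stopifnot(inherits(exposure, "summary_table"), inherits(outcome, "summary_table"))
  if (!identical(exposure$build, outcome$build)) {
    stop("harmonize: build mismatch (", exposure$build, " vs ", outcome$build, ")")
  }
  ex <- exposure$records
  oc <- outcome$records
  oc_key <- variant_key(oc$chrom, oc$pos, oc$effect_allele, oc$other_allele)
  oc_key_comp <- variant_key(oc$chrom, oc$pos,
                             complement_allele(oc$effect_allele),
                             complement_allele(oc$other_allele))

  n <- nrow(ex)
  action <- character(n)
  b_y <- s_y <- p_y <- eaf_y <- n_y <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    key <- variant_key(ex$chrom[i], ex$pos[i], ex$effect_allele[i], ex$other_allele[i])
    j <- match(key, oc_key)
    complemented <- FALSE
    if (is.na(j)) {
      j <- match(key, oc_key_comp)
      complemented <- TRUE
    }
    if (is.na(j)) {
      action[i] <- "dropped-unmatched"
      next
    }
    oc_ea <- if (complemented) complement_allele(oc$effect_allele[j]) else oc$effect_allele[j]
    palindromic <- is_palindromic(ex$effect_allele[i], ex$other_allele[i])

    if (palindromic) {
      if (drop_palindromic) {
        action[i] <- "dropped-palindromic"
        next
      }
      eaf_x <- ex$eaf[i]; eaf_o <- oc$eaf[j]
      lo <- palindrome_eaf_limit; hi <- 1 - palindrome_eaf_limit
      informative <- !is.na(eaf_x) && !is.na(eaf_o) &&
        (eaf_x < lo || eaf_x > hi) && (eaf_o < lo || eaf_o > hi)
      if (!informative) {
        action[i] <- "dropped-palindromic"
        next
      }
      flip <- sign(eaf_x - 0.5) != sign(eaf_o - 0.5)
      action[i] <- if (flip) "sign-flipped" else "kept-as-is"
      b_y[i] <- if (flip) -oc$beta[j] else oc$beta[j]
      eaf_y[i] <- if (flip) 1 - oc$eaf[j] else oc$eaf[j]
    } else {
      flip <- oc_ea != ex$effect_allele[i]
      action[i] <- if (complemented) "strand-complemented"
                   else if (flip) "sign-flipped" else "kept-as-is"
      b_y[i] <- if (flip) -oc$beta[j] else oc$beta[j]
      eaf_y[i] <- if (flip && !is.na(oc$eaf[j])) 1 - oc$eaf[j] else oc$eaf[j]
    }
    s_y[i] <- oc$se[j]
    p_y[i] <- oc$pvalue[j]
    n_y[i] <- oc$n[j]
  }

  kept <- !startsWith(action, "dropped")
  pairs <- data.frame(
    variant_id = ex$variant_id[kept], chrom = ex$chrom[kept], pos = ex$pos[kept],
    effect_allele = ex$effect_allele[kept], other_allele = ex$other_allele[kept],
    eaf = ex$eaf[kept], eaf_outcome = eaf_y[kept],
    b_x = ex$beta[kept], s_x = ex$se[kept], p_x = ex$pvalue[kept],
    b_y = b_y[kept], s_y = s_y[kept], p_y = p_y[kept],
    n_x = ex$n[kept], n_y = n_y[kept],
    stringsAsFactors = FALSE
  )
  rownames(pairs) <- NULL
  actions <- data.frame(
    key = variant_key(ex$chrom, ex$pos, ex$effect_allele, ex$other_allele),
    variant_id = ex$variant_id, action = action, stringsAsFactors = FALSE
  )
  structure(pairs, class = c("harmonized_pairs", "data.frame"),
            actions = actions,
            exposure_trait = exposure$trait_name,
            outcome_trait = outcome$trait_name,
            exposure_unit = exposure$unit, outcome_unit = outcome$unit)
}

#' Variant keys of harmonized pairs
#' @param pairs a `harmonized_pairs` object.
#' @return character vector of chrom:pos:allele keys.
#' @export
pair_keys <- function(pairs) {
  variant_key(pairs$chrom, pairs$pos, pairs$effect_allele, pairs$other_allele)
}

#' Write structured exclusion records
#'
#' Appends per-variant exclusion records (key, stage, reason) to a
#' machine-readable tab-delimited file.
#'
#' @param exclusions data.frame with at least `key` and `reason`.
#' @param stage pipeline stage label.
#' @param path exclusions file path.
#' @export
write_exclusions <- function(exclusions, stage, path) {
  if (nrow(exclusions) == 0) return(invisible(path))
  rec <- data.frame(key = exclusions$key, stage = stage,
                    reason = exclusions$reason, stringsAsFactors = FALSE)
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
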