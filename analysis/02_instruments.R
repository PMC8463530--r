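#!/usr/bin/env Rscript
# Select genetic instruments for the protein: harmonize the cis pQTL table
# against the outcome GWAS, apply the MAF >= 0.01 and F >= 15 filters,
# estimate signed LD from the reference panel, and clump greedily at
# r^2 <= 0.40. Writes the surviving instrument table, its LD matrix, and
# the per-variant exclusion log.

library(targetmr)

data_dir <- "results/data"
out <- "results/instruments"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

exposure <- read_summary_stats(file.path(data_dir, "protein_pqtl.tsv"),
                               trait_name = "protein", unit = "SD")
outcome <- read_summary_stats(file.path(data_dir, "cvd_gwas.tsv"),
                              trait_name = "CVD", trait_type = "binary",
                              unit = "logOR")
reference <- read_dosages(file.path(data_dir, "reference_dosages.tsv"))

pairs <- harmonize(exposure, outcome)
ld <- ld_from_reference(reference[, pair_keys(pairs)])
iset <- select_instruments(pairs, ld, maf_min = 0.01, f_min = 15, r2_max = 0.40)

write.table(iset$pairs, file.path(out, "instruments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(round(iset$ld, 6), file.path(out, "instrument_ld.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
removed <- iset$filter_log[iset$filter_log$flag != "kept", ]
write_exclusions(data.frame(key = removed$key, reason = removed$flag),
                 stage = "instruments", path = file.path(out, "exclusions.tsv"))

cat(nrow(pairs), "harmonized variants;", nrow(iset$pairs), "instruments kept",
    sprintf("(F range %.0f-%.0f; max post-clump r^2 = %.2f)\n",
            min(iset$f_stats), max(iset$f_stats),
            if (nrow(iset$pairs) > 1) max(iset$ld[upper.tri(iset$ld)]^2) else 0))
print(table(iset$filter_log$flag))
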