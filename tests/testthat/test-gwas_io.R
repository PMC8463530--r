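test_that("reading summary statistics maps columns, drops bad rows, handles empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")

  # header-only file -> empty table, no error
  writeLines(paste(c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "beta", "se", "pvalue"), collapse = "\t"),
             path)
  tab <- read_summary_stats(path)
  expect_s3_class(tab, "summary_table")
  expect_equal(nrow(tab$records), 0)

  # 3-row fixture with a renamed beta column
  fix <- data.frame(variant_id = c("rs1", "rs2", "rs3"), chrom = "16",
                    pos = c(56961923, 56970000, 56985845),
                    effect_allele = c("A", "C", "A"),
                    other_allele = c("G", "T", "C"),
                    effect_size = c(0.12, -0.05, 0.31),
                    se = c(0.02, 0.03, 0.04), pvalue = c(1e-9, 0.1, 1e-14))
  write.table(fix, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_summary_stats(path, column_map = c(beta = "effect_size"))
  expect_equal(tab$records$beta, c(0.12, -0.05, 0.31))

  # se = 0 row is dropped and counted, not fatal
  fix$se[2] <- 0
  write.table(fix, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_summary_stats(path, column_map = c(beta = "effect_size"))
  expect_equal(nrow(tab$records), 2)
  rej <- attr(tab, "rejections")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$reason, "nonpositive_se")

  # missing mandatory column names the field
  fix2 <- fix[, setdiff(names(fix), "pvalue")]
  write.table(fix2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path, column_map = c(beta = "effect_size")),
               "pvalue")
})

test_that("duplicate variant keys keep the first occurrence", {
  rec <- make_records(3)
  rec$pos[2] <- rec$pos[1]
  tab <- make_table(rec)
  expect_equal(nrow(tab$records), 2)
  expect_equal(attr(tab, "rejections")$reason, "duplicate_key")
  expect_equal(tab$records$beta[1], rec$beta[1])
})

test_that("cis-window extraction is inclusive, build-safe, and idempotent", {
  rec <- make_records(10, pos = c(56961923, 56950000, 56970000, 56985845,
                                  56985846, 56961922, 57000000, 56980000,
                                  10000, 56962000))
  tab <- make_table(rec)
  w <- cetp_window()
  out <- extract_cis_window(tab, w)
  # boundary positions retained on both ends; 5 of the 10 are inside
  expect_true(all(c(56961923, 56985845, 56970000) %in% out$records$pos))
  expect_false(any(c(56961922, 56985846) %in% out$records$pos))
  expect_equal(nrow(out$records), 5)

  # idempotence
  again <- extract_cis_window(out, w)
  expect_identical(again$records, out$records)

  # declared build mismatch is fatal, never silently lifted over
  tab37 <- make_table(rec, build = "GRCh37")
  expect_error(extract_cis_window(tab37, w), "build mismatch")
})

test_that("harmonization aligns alleles, flips swapped betas, resolves palindromes by EAF", {
  ex <- make_records(4, effect = c("A", "A", "A", "A"),
                     other = c("G", "G", "T", "T"),
                     beta = c(0.1, 0.1, 0.2, 0.2),
                     eaf = c(0.3, 0.3, 0.30, 0.45))
  oc <- ex
  # variant 2 listed with swapped alleles in the outcome
  tmp <- oc$effect_allele[2]; oc$effect_allele[2] <- oc$other_allele[2]
  oc$other_allele[2] <- tmp
  oc$beta <- c(0.2, 0.2, 0.15, 0.15)
  # palindromic variant 3: outcome EAF on the other side of 0.5 -> flip
  oc$eaf <- c(0.3, 0.7, 0.72, 0.48)

  h <- harmonize(make_table(ex, trait = "protein"),
                 make_table(oc, trait = "outcome"),
                 palindrome_eaf_limit = 0.42)
  acts <- attr(h, "actions")
  expect_equal(acts$action,
               c("kept-as-is", "sign-flipped", "sign-flipped",
                 "dropped-palindromic"))
  expect_equal(h$b_y, c(0.2, -0.2, -0.15))

  # strict mode drops every palindromic variant
  h2 <- harmonize(make_table(ex, trait = "protein"),
                  make_table(oc, trait = "outcome"), drop_palindromic = TRUE)
  expect_equal(sum(attr(h2, "actions")$action == "dropped-palindromic"), 2)

  # unmatched variants dropped with a reason
  oc3 <- oc[1:2, ]
  h3 <- harmonize(make_table(ex, trait = "protein"),
                  make_table(oc3, trait = "outcome"))
  expect_equal(sum(attr(h3, "actions")$action == "dropped-unmatched"), 2)
})

test_that("strand-complemented records harmonize onto the exposure alleles", {
  ex <- make_records(2, effect = "A", other = "G", beta = c(0.1, 0.1))
  oc <- ex
  oc$effect_allele <- c("T", "C")  # complement of A / complement-swap
  oc$other_allele <- c("C", "T")
  oc$beta <- c(0.3, 0.3)
  h <- harmonize(make_table(ex), make_table(oc))
  acts <- attr(h, "actions")$action
  expect_equal(acts[1], "strand-complemented")
  expect_equal(h$b_y[1], 0.3)       # same effect allele after complement
  expect_equal(h$b_y[2], -0.3)      # complement-swap implies a sign flip
})

test_that("the allele-swap transform is involutive under harmonization", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 8
    ex <- make_records(n, effect = sample(c("A", "C"), n, TRUE), other = "G",
                       beta = rnorm(n), eaf = runif(n, 0.05, 0.95))
    ex$other_allele[ex$effect_allele == "C"] <- "T"
    oc <- make_records(n, beta = rnorm(n), eaf = runif(n, 0.05, 0.95))
    oc$effect_allele <- ex$effect_allele; oc$other_allele <- ex$other_allele
    idx <- sample(n, 3)
    h_direct <- harmonize(make_table(ex), make_table(oc))
    h_double <- harmonize(make_table(ex),
                          swap_alleles(swap_alleles(make_table(oc), idx), idx))
    expect_equal(h_double$b_y, h_direct$b_y, tolerance = 1e-12)
    expect_equal(h_double$eaf_outcome, h_direct$eaf_outcome, tolerance = 1e-12)
    # single swap is undone by harmonization itself
    h_single <- harmonize(make_table(ex), swap_alleles(make_table(oc), idx))
    expect_equal(h_single$b_y, h_direct$b_y, tolerance = 1e-12)
  }
})

test_that("write/read round trip preserves all numeric fields to full precision", {
  set.seed(4)
  rec <- make_records(6, beta = rnorm(6) / 3, se = runif(6, 1e-4, 0.1),
                      eaf = runif(6, 0.01, 0.99))
  rec$pvalue <- 10^-runif(6, 0, 30)
  tab <- make_table(rec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(tab, path)
  back <- read_summary_stats(path, trait_name = tab$trait_name)
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    expect_equal(back$records[[col]], tab$records[[col]], tolerance = 1e-15,
                 label = col)
  }
})
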