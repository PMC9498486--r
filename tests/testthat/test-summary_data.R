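test_that("standard headers parse to an identity mapping and column maps
           reproduce the same records", {
  df <- rbind(gwas_row("rs1", "A", "G", 0.3, 0.10, 0.01),
              gwas_row("rs2", "C", "T", 0.6, -0.05, 0.02),
              gwas_row("rs3", "G", "A", 0.1, 0.02, 0.015))
  p1 <- write_gwas(df)
  x1 <- read_summary_stats(p1)
  expect_s3_class(x1, "summary_assoc")
  expect_equal(nrow(x1), 3L)
  expect_equal(x1$beta, df$beta)
  expect_equal(x1$snp_id, df$snp_id)

  # same table with exotic headers, declared through column_map
  df2 <- df
  names(df2) <- c("rsID", "EA", "OA", "frq", "effect_size", "stderr",
                  "p", "N")
  p2 <- write_gwas(df2)
  x2 <- read_summary_stats(p2, column_map = c(rsID = "snp_id",
                                              EA = "effect_allele",
                                              OA = "other_allele",
                                              frq = "eaf",
                                              effect_size = "beta"))
  expect_equal(x2, x1, ignore_attr = "skipped")

  # csv autodetection by extension
  pc <- tempfile(fileext = ".csv")
  write.table(df, pc, sep = ",", quote = FALSE, row.names = FALSE)
  expect_equal(read_summary_stats(pc)$beta, df$beta)
})

test_that("invalid rows are skipped with reasons; empty and misdeclared
           files are typed errors", {
  df <- rbind(gwas_row("ok", "A", "G", 0.3, 0.10, 0.01),
              gwas_row("zero_se", "A", "G", 0.3, 0.10, 0),
              gwas_row("same_alleles", "A", "A", 0.3, 0.10, 0.01),
              gwas_row("bad_eaf", "A", "G", 1.3, 0.10, 0.01),
              gwas_row("bad_allele", "A", "N", 0.3, 0.10, 0.01))
  x <- suppressMessages(read_summary_stats(write_gwas(df)))
  expect_equal(x$snp_id, "ok")
  skipped <- attr(x, "skipped")
  expect_equal(skipped$reason[skipped$snp_id == "zero_se"], "nonpositive SE")
  expect_setequal(skipped$snp_id,
                  c("zero_se", "same_alleles", "bad_eaf", "bad_allele"))

  # missing mandatory column names the column
  df_nobeta <- df[, setdiff(names(df), "beta")]
  expect_error(read_summary_stats(write_gwas(df_nobeta)),
               "beta", class = "tscmr_config_error")
  # zero parseable rows
  allbad <- gwas_row("x", "A", "G", 0.3, 0.1, -1)
  expect_error(suppressMessages(read_summary_stats(write_gwas(allbad))),
               class = "tscmr_input_error")
})

test_that("harmonization follows the allele truth table", {
  base <- gwas_row("s", "A", "G", 0.30, 0.10, 0.01)
  # every ordered allele pair the other study could report, with the action
  # it must produce against base A/G (EAFs unambiguous)
  truth <- list(
    list(c("A", "G"), "kept"),
    list(c("G", "A"), "flipped"),
    list(c("T", "C"), "kept"),        # opposite strand, same orientation
    list(c("C", "T"), "flipped"),     # opposite strand, swapped
    list(c("A", "C"), "dropped_incompatible"),
    list(c("A", "T"), "dropped_incompatible"),
    list(c("C", "G"), "dropped_incompatible"),
    list(c("C", "A"), "dropped_incompatible"),
    list(c("G", "C"), "dropped_incompatible"),
    list(c("G", "T"), "dropped_incompatible"),
    list(c("T", "A"), "dropped_incompatible"),
    list(c("T", "G"), "dropped_incompatible"),
    list(c("A", "A"), "dropped_incompatible"),
    list(c("C", "C"), "dropped_incompatible"),
    list(c("G", "G"), "dropped_incompatible"),
    list(c("T", "T"), "dropped_incompatible"))
  for (case in truth) {
    other <- gwas_row("s", case[[1]][1], case[[1]][2], 0.30, 0.05, 0.01)
    h <- harmonize(base, other)
    expect_equal(h$action, case[[2]],
                 label = paste("alleles", paste(case[[1]], collapse = "/")))
    if (case[[2]] == "flipped") {
      expect_equal(h$beta_other, -0.05)
      expect_equal(h$eaf_other, 0.70)
    }
    if (case[[2]] == "kept") expect_equal(h$beta_other, 0.05)
  }
})

test_that("palindromic variants resolve by allele frequency or drop", {
  base_pal <- gwas_row("p", "A", "T", 0.20, 0.10, 0.01)
  # ambiguous frequency in either study drops the variant
  h <- harmonize(gwas_row("p", "A", "T", 0.50, 0.10, 0.01),
                 gwas_row("p", "A", "T", 0.20, 0.05, 0.01))
  expect_equal(h$action, "dropped_palindromic")
  h <- harmonize(base_pal, gwas_row("p", "T", "A", 0.455, 0.05, 0.01))
  expect_equal(h$action, "dropped_palindromic")
  # missing EAF cannot resolve the strand
  h <- harmonize(base_pal, gwas_row("p", "A", "T", NA, 0.05, 0.01))
  expect_equal(h$action, "dropped_palindromic")
  # concordant frequencies keep the reported orientation
  h <- harmonize(base_pal, gwas_row("p", "A", "T", 0.22, 0.05, 0.01))
  expect_equal(h$action, "kept")
  expect_equal(h$beta_other, 0.05)
  # discordant frequencies imply a strand flip
  h <- harmonize(base_pal, gwas_row("p", "A", "T", 0.78, 0.05, 0.01))
  expect_equal(h$action, "flipped")
  expect_equal(h$beta_other, -0.05)
  expect_equal(h$eaf_other, 0.22)
  # the window is configurable
  h <- harmonize(base_pal, gwas_row("p", "A", "T", 0.455, 0.05, 0.01),
                 palindrome_eaf_window = 0.02)
  expect_equal(h$action, "kept")
})

test_that("harmonization is idempotent and a double flip restores the
           original record", {
  set.seed(4)
  base <- do.call(rbind, lapply(1:6, function(i)
    gwas_row(paste0("rs", i), c("A", "C", "G", "T", "A", "C")[i],
             c("G", "T", "A", "G", "C", "G")[i],
             runif(1, 0.1, 0.4), rnorm(1, 0, 0.1), runif(1, 0.005, 0.02))))
  other <- base
  # swap alleles on half the records (manual flip)
  flip_rows <- c(2, 4, 6)
  tmp <- other$effect_allele[flip_rows]
  other$effect_allele[flip_rows] <- other$other_allele[flip_rows]
  other$other_allele[flip_rows] <- tmp
  other$beta[flip_rows] <- -other$beta[flip_rows]
  other$eaf[flip_rows] <- 1 - other$eaf[flip_rows]

  h1 <- harmonize(base, other)
  expect_setequal(h1$action[flip_rows], "flipped")
  # the aligned other equals base's orientation: harmonizing again is a no-op
  other2 <- data.frame(snp_id = h1$snp_id, effect_allele = h1$effect_allele,
                       other_allele = h1$other_allele, eaf = h1$eaf_other,
                       beta = h1$beta_other, se = h1$se_other,
                       pval = NA, samplesize = NA)
  h2 <- harmonize(base, other2)
  expect_true(all(h2$action == "kept"))
  expect_equal(h2$beta_other, h1$beta_other)
  expect_equal(h2$eaf_other, h1$eaf_other)
  # double manual flip is the identity: aligned other equals original base
  expect_equal(h1$beta_other[flip_rows], base$beta[flip_rows])

  # duplicated ids are rejected
  expect_error(harmonize(rbind(base, base[1, ]), other),
               class = "tscmr_input_error")
})

test_that("instrument filtering is strict at the threshold and falls back
           to a normal p-value", {
  df <- rbind(gwas_row("just_in", "A", "G", 0.3, 0.1, 0.01, pval = 4e-8),
              gwas_row("boundary", "A", "G", 0.3, 0.1, 0.01, pval = 5e-8),
              gwas_row("no_pval", "A", "G", 0.3, 0.10, 0.05, pval = NA),
              gwas_row("strong", "A", "G", 0.3, 0.12, 0.01, pval = 1e-30))
  x <- suppressMessages(read_summary_stats(write_gwas(df)))
  kept <- filter_instruments(x, 5e-8)
  expect_equal(kept$snp_id, c("just_in", "strong"))  # order preserved

  # z = 2 gives the two-sided normal p ~= 0.0455, far above 5e-8
  expect_equal(2 * pnorm(-2), 0.04550026, tolerance = 1e-6)
  # threshold 1 returns every record with a computable p-value
  expect_equal(nrow(filter_instruments(x, 1)), nrow(x))
  # empty result is valid
  expect_equal(nrow(suppressMessages(filter_instruments(x, 1e-40))), 0L)
  expect_error(filter_instruments(x, 0), class = "tscmr_input_error")
})
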