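makePair <- function(exp_alleles, out_alleles, beta_out = 0.2,
                     eaf_exp = 0.3, eaf_out = 0.3) {
  exp_df <- data.frame(snp_id = "rs1", chrom = "1", pos = 100L,
                       effect_allele = exp_alleles[1],
                       other_allele = exp_alleles[2],
                       eaf = eaf_exp, beta = 0.1, se = 0.02, pval = 1e-6,
                       n = 1e4, stringsAsFactors = FALSE)
  out_df <- exp_df
  out_df$effect_allele <- out_alleles[1]
  out_df$other_allele <- out_alleles[2]
  out_df$beta <- beta_out
  out_df$eaf <- eaf_out
  harmonize(SummaryStats(exp_df), SummaryStats(out_df))
}

pairRow <- function(h) as.data.frame(h)[1, ]

test_that("allele configurations map to the documented statuses and transforms", {
  r <- pairRow(makePair(c("A", "G"), c("A", "G")))
  expect_equal(r$status, "aligned")
  expect_equal(r$beta_out, 0.2)

  r <- pairRow(makePair(c("A", "G"), c("G", "A"), eaf_out = 0.3))
  expect_equal(r$status, "swapped")
  expect_equal(r$beta_out, -0.2)
  expect_equal(r$eaf_out, 0.7)

  r <- pairRow(makePair(c("A", "G"), c("T", "C")))
  expect_equal(r$status, "strand_flipped")
  expect_equal(r$beta_out, 0.2)

  r <- pairRow(makePair(c("A", "G"), c("C", "T"), eaf_out = 0.3))
  expect_equal(r$status, "strand_flipped")
  expect_equal(r$beta_out, -0.2)
  expect_equal(r$eaf_out, 0.7)

  r <- pairRow(makePair(c("A", "G"), c("A", "C")))
  expect_equal(r$status, "dropped")
  expect_match(r$reason, "mismatch")

  # palindromic with maximal frequency ambiguity is dropped
  r <- pairRow(makePair(c("A", "T"), c("A", "T"), eaf_exp = 0.5,
                        eaf_out = 0.5))
  expect_equal(r$status, "dropped")
  expect_match(r$reason, "ambiguous")

  # palindromic with informative, agreeing frequencies is kept as-is
  r <- pairRow(makePair(c("A", "T"), c("A", "T"), eaf_exp = 0.2,
                        eaf_out = 0.25))
  expect_equal(r$status, "palindromic_kept")
  expect_equal(r$beta_out, 0.2)

  # informative frequencies on opposite sides imply a flip
  r <- pairRow(makePair(c("A", "T"), c("A", "T"), eaf_exp = 0.2,
                        eaf_out = 0.75))
  expect_equal(r$status, "palindromic_kept")
  expect_equal(r$beta_out, -0.2)
  expect_equal(r$eaf_out, 0.25)

  # palindromic with a missing frequency cannot be oriented
  r <- pairRow(makePair(c("C", "G"), c("C", "G"), eaf_out = NA))
  expect_equal(r$status, "dropped")
  expect_match(r$reason, "missing")
})

test_that("variants absent from the outcome are dropped; duplicates error", {
  exp_df <- makeSumstatsDF(4)
  out_df <- exp_df[1:2, ]
  h <- harmonize(SummaryStats(exp_df), SummaryStats(out_df))
  expect_length(h, 4)
  expect_equal(nrow(retained(h)), 2)
  expect_match(as.data.frame(h)$reason[3], "absent")

  dup <- rbind(exp_df, exp_df[1, ])
  expect_error(harmonize(new("SummaryStats",
                             stats = SummaryStats(exp_df)@stats[c(1, 1), ],
                             rejected = rejected(SummaryStats(exp_df))),
                         SummaryStats(out_df)),
               "duplicate")
})

test_that("harmonizing a table against itself is an involution", {
  sim <- simulateGWASPair(simulationConfig(n_snps = 60, seed = 17,
                                           frac_palindromic = 0.3,
                                           maf_range = c(0.05, 0.35)))
  ex <- sim$exposure
  h <- harmonize(ex, ex)
  df <- as.data.frame(h)
  pal <- df$snp_id %in% sim$truth$palindromic_snp_ids
  expect_true(all(df$status[!pal] == "aligned"))
  kept <- df$status != "dropped"
  expect_equal(df$beta_out[kept], as.data.frame(ex)$beta[kept])
  # palindromic variants with frequencies clear of 0.5 are kept unchanged
  expect_true(all(df$status[pal] %in% c("palindromic_kept", "dropped")))
})

test_that("swapping every outcome allele recovers the original effects exactly", {
  set.seed(33)
  exp_df <- makeSumstatsDF(20, seed = 33)
  out_df <- exp_df
  out_df$beta <- rnorm(20, 0, 0.05)
  base <- harmonize(SummaryStats(exp_df), SummaryStats(out_df))

  swapped <- out_df
  swapped$effect_allele <- out_df$other_allele
  swapped$other_allele <- out_df$effect_allele
  swapped$beta <- -out_df$beta
  swapped$eaf <- 1 - out_df$eaf
  h2 <- harmonize(SummaryStats(exp_df), SummaryStats(swapped))
  expect_equal(retained(h2)$beta_out, retained(base)$beta_out)
  expect_equal(retained(h2)$eaf_out, retained(base)$eaf_out)
})

test_that("downstream estimates are invariant to allele-order scrambling", {
  cfg0 <- simulationConfig(n_snps = 40, seed = 19, frac_flipped = 0,
                           frac_palindromic = 0)
  cfg1 <- simulationConfig(n_snps = 40, seed = 19, frac_flipped = 0.5,
                           frac_palindromic = 0)
  sim0 <- simulateGWASPair(cfg0)
  sim1 <- simulateGWASPair(cfg1)
  # same seed, same draws; only the outcome's allele bookkeeping differs
  r0 <- mrIVW(waldRatios(harmonize(sim0$exposure, sim0$outcome)))
  r1 <- mrIVW(waldRatios(harmonize(sim1$exposure, sim1$outcome)))
  expect_equal(estimate(r1), estimate(r0))
  expect_equal(stdError(r1), stdError(r0))
})
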