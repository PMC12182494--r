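test_that("p-value filtering is a strict-inequality threshold preserving order", {
  df <- makeSumstatsDF(3, pval = c(1e-6, 1e-4, 1e-5))
  ss <- SummaryStats(df)
  kept <- filterByPvalue(ss, 1e-5)
  expect_identical(snpIds(kept), "rs0001")

  expect_length(filterByPvalue(SummaryStats(makeSumstatsDF(3,
    pval = c(0.1, 0.5, 1e-5))), 1e-5), 0)

  # the five instrument p-values from the annotation table all clear 1e-5
  p_tab3 <- c(8.95466339032433e-07, 1.84509546544161e-06,
              4.08475070727283e-06, 4.23103750003848e-06,
              6.14583285242795e-06)
  ss3 <- SummaryStats(makeSumstatsDF(5, pval = p_tab3))
  expect_length(filterByPvalue(ss3, 1e-5), 5)
  expect_equal(max(p_tab3), 6.14583285242795e-06)
})

test_that("clumping retains independent variants and prunes by lowest p", {
  # identity LD keeps everything
  df <- makeSumstatsDF(10, seed = 3)
  ids <- df$snp_id
  ld <- LDMatrix(`dimnames<-`(diag(10), list(ids, ids)))
  kept <- clumpVariants(SummaryStats(df), ld)
  expect_setequal(snpIds(kept), ids)
  # output sorted by chromosome then position
  kdf <- as.data.frame(kept)
  expect_false(is.unsorted(order(as.numeric(kdf$chrom), kdf$pos)))

  # two correlated close variants: only the smaller p survives
  df2 <- makeSumstatsDF(2, chrom = c("1", "1"), pos = c(1000L, 2000L),
                        pval = c(1e-8, 1e-6))
  m <- matrix(c(1, 0.9, 0.9, 1), 2,
              dimnames = list(df2$snp_id, df2$snp_id))
  kept2 <- clumpVariants(SummaryStats(df2), LDMatrix(m))
  expect_identical(snpIds(kept2), "rs0001")

  # a variant missing from the LD matrix is an error naming it
  expect_error(clumpVariants(SummaryStats(makeSumstatsDF(3)), LDMatrix(m)),
               "rs0003")
})

test_that("clumping matches the exhaustive fixed-point oracle on random fixtures", {
  for (seed in 1:8) {
    set.seed(seed)
    k <- 12
    df <- data.frame(
      snp_id = sprintf("rs%03d", sample(k)),
      chrom = as.character(sample(1:2, k, replace = TRUE)),
      pos = sample.int(30000, k),
      effect_allele = "A", other_allele = "G",
      eaf = 0.3, beta = rnorm(k, 0, 0.1), se = 0.02,
      pval = signif(runif(k, 1e-9, 1e-4), 3), n = 1e4,
      stringsAsFactors = FALSE)
    base <- matrix(runif(k * k), k)
    r2 <- (base + t(base)) / 2
    r2[r2 < 0.4] <- 0            # sparsen so blocks exist
    diag(r2) <- 1
    dimnames(r2) <- list(df$snp_id, df$snp_id)
    ld <- LDMatrix(r2)

    kept <- snpIds(clumpVariants(SummaryStats(df), ld, clump_r2 = 0.3,
                                 clump_kb = 10))
    expect_identical(sort(kept), oracleClump(df, r2, 0.3, 10))

    # invariants: retained set pairwise independent within the window;
    # every removed variant conflicts with a retained, no-worse-p variant
    r2k <- r2[kept, kept, drop = FALSE]
    for (i in seq_along(kept)) for (j in seq_along(kept)) {
      if (i == j) next
      ri <- df[df$snp_id == kept[i], ]; rj <- df[df$snp_id == kept[j], ]
      if (ri$chrom == rj$chrom && abs(ri$pos - rj$pos) <= 10000)
        expect_lt(r2k[i, j], 0.3)
    }
    removed <- setdiff(df$snp_id, kept)
    for (s in removed) {
      rs <- df[df$snp_id == s, ]
      witness <- vapply(kept, function(t) {
        rt <- df[df$snp_id == t, ]
        rt$chrom == rs$chrom && abs(rt$pos - rs$pos) <= 10000 &&
          r2[s, t] >= 0.3 && rt$pval <= rs$pval
      }, logical(1))
      expect_true(any(witness))
    }

    # row-order invariance
    perm <- sample(k)
    kept_perm <- snpIds(clumpVariants(SummaryStats(df[perm, ]), ld,
                                      clump_r2 = 0.3, clump_kb = 10))
    expect_identical(kept_perm, kept)
  }
})

test_that("selectInstruments composes the filter and the clump", {
  sim <- simulateGWASPair(simulationConfig(n_snps = 30, seed = 21,
                                           ld_block_size = 3, ld_rho = 0.9))
  sel <- selectInstruments(sim$exposure, sim$ld, threshold = 1e-5,
                           clump_r2 = 0.5, clump_kb = 10000)
  expect_true(all(as.data.frame(sel)$pval < 1e-5))
  # at most one survivor per 3-SNP LD block
  blocks <- (match(snpIds(sel), sim$truth$snp_id) - 1) %/% 3
  expect_false(any(duplicated(blocks)))
})
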