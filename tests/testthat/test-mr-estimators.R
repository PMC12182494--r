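test_that("Wald ratios follow the first-order delta method", {
  pairs <- data.frame(snp_id = c("rs1", "rs2"), beta_exp = c(0.1, 0.2),
                      se_exp = 0.02, beta_out = c(0.05, 0), se_out = 0.02)
  wr <- waldRatios(pairs)
  expect_equal(wr$b, c(0.5, 0))
  expect_equal(wr$se, c(0.2, 0.1))
  expect_equal(wr$p[2], 1)

  zero <- transform(pairs, beta_exp = c(0.1, 0))
  expect_error(waldRatios(zero), "rs2")

  # a precise simulated pair recovers the causal slope
  sim <- simulateGWASPair(simulationConfig(n_snps = 5, theta = 0.4,
                                           n_exposure = 1e6, n_outcome = 1e6,
                                           seed = 2, frac_palindromic = 0))
  wr2 <- waldRatios(harmonize(sim$exposure, sim$outcome))
  expect_true(all(abs(wr2$b - 0.4) < 3 * wr2$se))
})

test_that("IVW equals weighted-least-squares through the origin and keeps its identities", {
  # algebraic oracle: normal equations of the origin regression of b on 1
  rt <- ratioTable(b = c(0.2, 0.5, -0.1, 0.4), se = c(0.1, 0.2, 0.15, 0.3))
  w <- 1 / rt$se^2
  b_oracle <- solve(t(w) %*% rep(1, 4) , sum(w * rt$b))[1]
  r <- mrIVW(rt, mode = "fixed")
  expect_equal(estimate(r), b_oracle, tolerance = 1e-12)
  expect_equal(stdError(r), sqrt(1 / sum(w)), tolerance = 1e-12)

  # convexity: the combined estimate lies inside the ratio range
  expect_gte(estimate(r), min(rt$b))
  expect_lte(estimate(r), max(rt$b))

  # single-ratio identity
  one <- mrIVW(ratioTable(0.5, 0.2))
  expect_equal(estimate(one), 0.5)
  expect_equal(stdError(one), 0.2)
  expect_equal(nsnp(one), 1L)

  # OR fields are exp-transform consistent for every method output
  expect_equal(oddsRatio(r), exp(estimate(r)))
  ci <- orCI(r)
  expect_equal(log(ci[["uci95"]]) - log(ci[["lci95"]]),
               2 * 1.959964 * stdError(r))

  # multiplicative random effects only ever widens the SE
  het <- ratioTable(b = c(-1, 0, 1, 2), se = rep(0.1, 4))
  expect_gt(stdError(mrIVW(het, mode = "random")),
            stdError(mrIVW(het, mode = "fixed")))
  # ... and reduces to fixed when Q <= k-1
  hom <- ratioTable(b = c(0.30, 0.32, 0.28, 0.31), se = rep(0.1, 4))
  expect_equal(stdError(mrIVW(hom, mode = "random")),
               stdError(mrIVW(hom, mode = "fixed")))

  expect_error(mrIVW(rt[0, ]), "at least 1")
})

test_that("MR-Egger matches the closed-form weighted normal equations", {
  set.seed(8)
  k <- 8
  pairs <- data.frame(snp_id = sprintf("rs%d", 1:k),
                      beta_exp = runif(k, 0.03, 0.2), se_exp = 0.01,
                      beta_out = NA, se_out = runif(k, 0.01, 0.05))
  pairs$beta_out <- 0.05 + 0.4 * pairs$beta_exp + rnorm(k, 0, 0.03)

  r <- mrEgger(pairs)
  # oracle: solve the 2x2 weighted normal equations directly
  w <- 1 / pairs$se_out^2
  X <- cbind(1, pairs$beta_exp)
  XtWX <- t(X) %*% (w * X)
  coefs <- solve(XtWX, t(X) %*% (w * pairs$beta_out))
  resid <- pairs$beta_out - X %*% coefs
  sigma2 <- sum(w * resid^2) / (k - 2)
  cov_u <- solve(XtWX) * max(1, sigma2)
  expect_equal(estimate(r), coefs[2], tolerance = 1e-10)
  expect_equal(eggerIntercept(r)[["intercept"]], coefs[1], tolerance = 1e-10)
  expect_equal(stdError(r), sqrt(cov_u[2, 2]), tolerance = 1e-10)
  expect_equal(eggerIntercept(r)[["se"]], sqrt(cov_u[1, 1]),
               tolerance = 1e-10)
  expect_equal(pvalue(r),
               2 * pt(-abs(estimate(r) / stdError(r)), df = k - 2))

  # exact collinear fit: slope recovered, intercept zero
  col <- data.frame(snp_id = sprintf("rs%d", 1:5),
                    beta_exp = c(0.05, 0.1, 0.15, 0.2, 0.25), se_exp = 0.01,
                    se_out = 0.02)
  col$beta_out <- 0.4 * col$beta_exp
  rc <- mrEgger(col)
  expect_equal(estimate(rc), 0.4, tolerance = 1e-10)
  expect_equal(eggerIntercept(rc)[["intercept"]], 0, tolerance = 1e-10)

  # orientation: negating an exposure effect must not change the fit
  flipped <- pairs
  flipped$beta_exp[1] <- -flipped$beta_exp[1]
  flipped$beta_out[1] <- -flipped$beta_out[1]
  expect_equal(estimate(mrEgger(flipped)), estimate(r))

  # minimal case has one residual df and finite SEs
  r3 <- mrEgger(pairs[1:3, ])
  expect_true(is.finite(stdError(r3)))
  expect_error(mrEgger(pairs[1:2, ]), "3")
})

test_that("weighted median interpolates the ordered ratios at half weight", {
  expect_equal(estimate(mrWeightedMedian(ratioTable(c(1, 2, 3), rep(1, 3)),
                                         n_boot = 100, seed = 1)), 2)

  # 60/40 weight split: the estimate stays with the heavier cluster
  set.seed(12)
  rt <- ratioTable(b = c(rnorm(6, 0.3, 0.01), rnorm(4, 1.5, 0.01)),
                   se = rep(0.1, 10))
  wm <- mrWeightedMedian(rt, n_boot = 500, seed = 4)
  expect_lt(abs(estimate(wm) - 0.3), 3 * stdError(wm))

  # seeded bootstrap is reproducible, and the guard rejects tiny n_boot
  wm2 <- mrWeightedMedian(rt, n_boot = 500, seed = 4)
  expect_identical(stdError(wm), stdError(wm2))
  expect_error(mrWeightedMedian(rt, n_boot = 50, seed = 1), "n_boot")
  expect_error(mrWeightedMedian(rt, n_boot = 500), "seed")
})

test_that("weighted mode finds the heaviest density peak", {
  # degenerate: identical ratios return the common value
  same <- ratioTable(rep(0.7, 4), rep(0.1, 4))
  m <- mrWeightedMode(same, n_boot = 100, seed = 2)
  expect_equal(estimate(m), 0.7)

  # bimodal: 70% of weight at 0.3, 30% at 1.5
  set.seed(5)
  rt <- ratioTable(b = c(rnorm(7, 0.3, 0.05), rnorm(3, 1.5, 0.05)),
                   se = rep(0.1, 10))
  m2 <- mrWeightedMode(rt, n_boot = 200, seed = 3)
  h <- microMR:::.modeBandwidth(rt$b, 1 / rt$se^2, 1)
  expect_lt(abs(estimate(m2) - 0.3), h)

  # grid-search oracle over the same weighted density
  w <- 1 / rt$se^2
  grid <- seq(min(rt$b) - 3 * h, max(rt$b) + 3 * h, length.out = 20000)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - rt$b) / h)), numeric(1))
  expect_equal(estimate(m2), grid[which.max(dens)], tolerance = 1e-3)

  m3 <- mrWeightedMode(rt, n_boot = 200, seed = 3)
  expect_identical(stdError(m2), stdError(m3))
})

test_that("mrEstimate derives per-method seeds from one master seed", {
  sim <- simulateGWASPair(simulationConfig(n_snps = 20, seed = 6))
  h <- harmonize(sim$exposure, sim$outcome)
  all4 <- mrEstimate(h, seed = 99, n_boot = 200)
  expect_named(all4, c("ivw", "egger", "wmedian", "wmode"))
  # dropping a method leaves the others' bootstrap draws untouched
  some <- mrEstimate(h, methods = c("ivw", "wmode"), seed = 99, n_boot = 200)
  expect_identical(stdError(some$wmode), stdError(all4$wmode))
  expect_error(mrEstimate(h, methods = "wmedian"), "seed")
})
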