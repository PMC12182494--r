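#' Per-variant Wald ratio estimates
#'
#' Computes, for each retained harmonized pair, the ratio estimate
#' \code{b = beta_out / beta_exp} with the first-order delta-method standard
#' error \code{se = se_out / |beta_exp|} and a two-sided normal p-value.
#' Higher-order terms of the ratio SE (involving \code{se_exp}) are
#' deliberately omitted; this is the conventional first-order Wald ratio.
#'
#' @param pairs a \linkS4class{HarmonizedPairs} or a data.frame with columns
#'   \code{snp_id}, \code{beta_exp}, \code{se_exp}, \code{beta_out},
#'   \code{se_out} (plus optional \code{chrom}, \code{pos},
#'   \code{effect_allele} carried through).
#' @return data.frame with columns \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{b}, \code{se}, \code{p}.
#' @export
waldRatios <- function(pairs) {
  df <- if (is(pairs, "HarmonizedPairs")) retained(pairs) else
    as.data.frame(pairs)
  zero <- df$beta_exp == 0
  if (any(zero))
    stop("beta_exp is zero for: ", paste(df$snp_id[zero], collapse = ", "))
  b <- df$beta_out / df$beta_exp
  se <- df$se_out / abs(df$beta_exp)
  data.frame(
    snp_id = df$snp_id,
    chrom = if (is.null(df$chrom)) NA_character_ else df$chrom,
    pos = if (is.null(df$pos)) NA_integer_ else df$pos,
    effect_allele = if (is.null(df$effect_allele)) NA_character_ else
      df$effect_allele,
    b = b, se = se, p = 2 * stats::pnorm(-abs(b / se)),
    stringsAsFactors = FALSE)
}

.checkRatios <- function(ratios, min_n = 1L) {
  stopifnot(is.data.frame(ratios), all(c("b", "se") %in% names(ratios)))
  if (nrow(ratios) < min_n)
    stop("need at least ", min_n, " Wald ratios, got ", nrow(ratios))
  if (any(ratios$se <= 0)) stop("Wald ratio with non-positive se")
  ratios
}

#' Inverse-variance-weighted estimate
#'
#' Combines Wald ratios by inverse-variance weighting, the meta-analytic
#' estimator \code{b = sum(w_j b_j) / sum(w_j)} with \code{w_j = 1/se_j^2}.
#' In \code{"fixed"} mode the standard error is \code{(sum w_j)^{-1/2}}; in
#' \code{"random"} (multiplicative random-effects) mode it is scaled by
#' \code{sqrt(max(1, Q/(k-1)))} with Cochran's Q, so the two modes coincide
#' when the instruments are homogeneous (Q <= k-1). A single ratio is
#' permitted and returns that ratio unchanged. P-values are two-sided normal.
#'
#' @param ratios data.frame of Wald ratios ([waldRatios()]).
#' @param mode \code{"random"} (default) or \code{"fixed"}.
#' @param exposure exposure label carried into the result.
#' @return An \linkS4class{MRResult} with method \code{"IVW"}.
#' @examples
#' mrIVW(erysipelotrichiaFixture(), mode = "fixed")
#' @export
mrIVW <- function(ratios, mode = c("random", "fixed"),
                  exposure = "exposure") {
  mode <- match.arg(mode)
  ratios <- .checkRatios(ratios, 1L)
  k <- nrow(ratios)
  w <- 1 / ratios$se^2
  b <- sum(w * ratios$b) / sum(w)
  se <- sqrt(1 / sum(w))
  if (mode == "random" && k >= 2) {
    Q <- sum(w * (ratios$b - b)^2)
    se <- se * sqrt(max(1, Q / (k - 1)))
  }
  MRResult("IVW", k, b, se, 2 * stats::pnorm(-abs(b / se)),
           exposure = exposure)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept: the slope is the causal estimate and the intercept captures
#' average directional pleiotropy (valid under the InSIDE condition, i.e.
#' instrument strengths independent of direct effects). Pairs are first
#' oriented so every exposure effect is non-negative (both betas of a pair are
#' negated when \code{beta_exp < 0}), weights are \code{1/se_out^2}, and
#' standard errors use a residual variance factor of \code{max(1, dispersion)}
#' so that under-dispersion never shrinks them below the fixed-effect scale.
#' P-values are two-sided from the t distribution with k-2 degrees of freedom.
#'
#' @param pairs a \linkS4class{HarmonizedPairs} or data.frame with
#'   \code{beta_exp}, \code{se_exp}, \code{beta_out}, \code{se_out}; at least
#'   3 pairs.
#' @param exposure exposure label.
#' @return An \linkS4class{MRResult} with method \code{"MR-Egger"} and the
#'   intercept slots populated.
#' @export
mrEgger <- function(pairs, exposure = "exposure") {
  df <- if (is(pairs, "HarmonizedPairs")) retained(pairs) else
    as.data.frame(pairs)
  if (nrow(df) < 3)
    stop("MR-Egger needs at least 3 pairs (model unidentified with ",
         nrow(df), ")")
  flip <- df$beta_exp < 0
  bx <- ifelse(flip, -df$beta_exp, df$beta_exp)
  by <- ifelse(flip, -df$beta_out, df$beta_out)
  w <- 1 / df$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  k <- nrow(df)
  # lm's coefficient SEs carry sigma; rescale to dispersion max(1, sigma^2).
  slope <- unname(stats::coef(fit)[2])
  slope_se <- sm$coefficients[2, 2] / sm$sigma * max(1, sm$sigma)
  int <- unname(stats::coef(fit)[1])
  int_se <- sm$coefficients[1, 2] / sm$sigma * max(1, sm$sigma)
  MRResult("MR-Egger", k, slope, slope_se,
           2 * stats::pt(-abs(slope / slope_se), df = k - 2),
           exposure = exposure,
           egger_intercept = int, egger_intercept_se = int_se,
           egger_intercept_p = 2 * stats::pt(-abs(int / int_se), df = k - 2))
}

# Weighted median of values `b` with weights `w` via the standardized
# cumulative-weight interpolation p_j = (S_j - w_j/2)/S_k.
.weightedMedian <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  S <- cumsum(w)
  p <- (S - w / 2) / S[length(S)]
  if (p[1] >= 0.5) return(b[1])
  if (p[length(p)] <= 0.5) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' The inverse-variance-weighted median of the Wald ratios: consistent when at
#' least half of the total weight comes from valid instruments, unlike IVW.
#' The point estimate interpolates the ordered ratios at standardized
#' cumulative weight 0.5; the standard error comes from a seeded parametric
#' bootstrap in which each ratio is redrawn from Normal(b_j, se_j) and the
#' weighted median recomputed.
#'
#' @param ratios data.frame of Wald ratios; at least 3.
#' @param n_boot bootstrap resamples (>= 100; default 5000).
#' @param seed integer seed for the bootstrap (required for reproducibility).
#' @param exposure exposure label.
#' @return An \linkS4class{MRResult} with method \code{"weighted-median"}.
#' @export
mrWeightedMedian <- function(ratios, n_boot = 5000, seed, exposure = "exposure") {
  ratios <- .checkRatios(ratios, 3L)
  if (n_boot < 100) stop("n_boot < 100 gives unstable bootstrap SEs")
  if (missing(seed)) stop("a bootstrap seed is required")
  w <- 1 / ratios$se^2
  b <- .weightedMedian(ratios$b, w)
  boot <- withSeed(seed, {
    vapply(seq_len(n_boot), function(i) {
      .weightedMedian(stats::rnorm(nrow(ratios), ratios$b, ratios$se), w)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  MRResult("weighted-median", nrow(ratios), b, se,
           2 * stats::pnorm(-abs(b / se)), exposure = exposure)
}

# Golden-section maximization of f on [lo, hi].
.goldenMax <- function(f, lo, hi, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol * max(1, abs(a) + abs(b))) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

# Mode of the weighted Gaussian kernel density over ratios b with weights w
# and bandwidth h: 512-point grid then golden-section refinement.
.weightedKdeMode <- function(b, w, h) {
  dens <- function(x)
    vapply(x, function(xi) sum(w * stats::dnorm((xi - b) / h)), numeric(1))
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512)
  fg <- dens(grid)
  i <- which.max(fg)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(512, i + 1)]
  .goldenMax(dens, lo, hi)
}

.modeBandwidth <- function(b, w, bandwidth_factor) {
  wm <- sum(w * b) / sum(w)
  wsd <- sqrt(sum(w * (b - wm)^2) / sum(w))
  wmed <- .weightedMedian(b, w)
  wmad <- .weightedMedian(abs(b - wmed), w) * 1.4826
  s <- min(wsd, if (wmad > 0) wmad else wsd)
  bandwidth_factor * 0.9 * s * length(b)^(-1 / 5)
}

#' Weighted-mode estimate
#'
#' Mode-based estimation: the causal estimate is the maximizer of a weighted
#' Gaussian kernel density over the Wald ratios (weights \code{1/se_j^2}),
#' consistent when the largest homogeneous subset of instruments is valid,
#' even if they contribute less than half of the weight. The bandwidth is
#' \code{bandwidth_factor} times a modified-Silverman scale (0.9 times the
#' smaller of the weighted SD and the scaled weighted MAD, times k^(-1/5));
#' the maximizer is located on a 512-point grid spanning the ratio range plus
#' or minus 3 bandwidths and refined by golden-section search. The standard
#' error uses the same seeded parametric bootstrap as [mrWeightedMedian()].
#' When all ratios coincide the bandwidth degenerates and the common value is
#' returned directly.
#'
#' @param ratios data.frame of Wald ratios; at least 3.
#' @param bandwidth_factor multiplier on the modified-Silverman bandwidth
#'   (default 1).
#' @param n_boot bootstrap resamples (>= 100; default 5000).
#' @param seed integer seed for the bootstrap.
#' @param exposure exposure label.
#' @return An \linkS4class{MRResult} with method \code{"weighted-mode"}.
#' @export
mrWeightedMode <- function(ratios, bandwidth_factor = 1, n_boot = 5000, seed,
                           exposure = "exposure") {
  ratios <- .checkRatios(ratios, 3L)
  if (n_boot < 100) stop("n_boot < 100 gives unstable bootstrap SEs")
  if (missing(seed)) stop("a bootstrap seed is required")
  w <- 1 / ratios$se^2
  point <- function(b) {
    h <- .modeBandwidth(b, w, bandwidth_factor)
    if (!is.finite(h) || h <= 0) return(.weightedMedian(b, w))
    .weightedKdeMode(b, w, h)
  }
  b <- if (length(unique(ratios$b)) == 1L) ratios$b[1] else point(ratios$b)
  boot <- withSeed(seed, {
    vapply(seq_len(n_boot), function(i)
      point(stats::rnorm(nrow(ratios), ratios$b, ratios$se)), numeric(1))
  })
  se <- stats::sd(boot)
  MRResult("weighted-mode", nrow(ratios), b, se,
           2 * stats::pnorm(-abs(b / se)), exposure = exposure)
}

#' Run all requested MR estimators
#'
#' @param pairs a \linkS4class{HarmonizedPairs}.
#' @param methods subset of \code{c("ivw", "egger", "wmedian", "wmode")}.
#' @param ivw_mode IVW variance mode, \code{"random"} or \code{"fixed"}.
#' @param n_boot,seed bootstrap settings for the median/mode estimators;
#'   method-specific seeds are derived from \code{seed} so adding a method
#'   does not perturb another's draws.
#' @param exposure exposure label.
#' @return named list of \linkS4class{MRResult} objects.
#' @export
mrEstimate <- function(pairs, methods = c("ivw", "egger", "wmedian", "wmode"),
                       ivw_mode = "random", n_boot = 5000, seed,
                       exposure = "exposure") {
  methods <- match.arg(methods, c("ivw", "egger", "wmedian", "wmode"),
                       several.ok = TRUE)
  if (any(c("wmedian", "wmode") %in% methods) && missing(seed))
    stop("a seed is required for bootstrap-based methods")
  ratios <- waldRatios(pairs)
  out <- list()
  if ("ivw" %in% methods)
    out$ivw <- mrIVW(ratios, mode = ivw_mode, exposure = exposure)
  if ("egger" %in% methods)
    out$egger <- mrEgger(pairs, exposure = exposure)
  if ("wmedian" %in% methods)
    out$wmedian <- mrWeightedMedian(ratios, n_boot = n_boot,
                                    seed = seed + 1L, exposure = exposure)
  if ("wmode" %in% methods)
    out$wmode <- mrWeightedMode(ratios, n_boot = n_boot, seed = seed + 2L,
                                exposure = exposure)
  out
}
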