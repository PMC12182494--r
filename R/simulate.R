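# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for the paired GWAS simulator
#'
#' Assembles and validates the parameters of [simulateGWASPair()]. Defaults
#' describe a microbiome-abundance exposure instrumented by moderately strong
#' common variants against a binary outcome, at sample sizes where instruments
#' can clear a p < 1e-5 selection threshold.
#'
#' @param n_snps number of candidate instruments.
#' @param n_exposure,n_outcome GWAS sample sizes of the two (non-overlapping)
#'   samples.
#' @param theta true causal effect of the exposure on the outcome (log-odds
#'   per exposure unit).
#' @param prop_invalid fraction in [0, 1) of instruments given a direct
#'   (pleiotropic) outcome effect.
#' @param pleiotropy_mean,pleiotropy_sd distribution of the direct effects;
#'   a nonzero mean makes pleiotropy directional.
#' @param inside_violation when \code{TRUE}, direct effects are generated as
#'   \code{kappa * gamma_j + noise} so that instrument strength and direct
#'   effect are correlated (violating the InSIDE condition MR-Egger needs).
#' @param kappa coupling used when \code{inside_violation} is \code{TRUE}.
#' @param maf_range range of minor-allele frequencies, within (0, 0.5].
#' @param ld_block_size,ld_rho variants are laid out in blocks of
#'   \code{ld_block_size} adjacent SNPs with constant within-block correlation
#'   \code{ld_rho} (the LD matrix reports r-squared).
#' @param frac_palindromic fraction of variants given complementary (A/T or
#'   C/G) allele pairs.
#' @param frac_flipped fraction of variants whose allele order is swapped in
#'   the outcome table (beta negated, eaf reflected), emulating
#'   allele-order discrepancies between consortia.
#' @param seed integer RNG seed; the same seed reproduces identical output.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_snps = 50, n_exposure = 20000,
                             n_outcome = 20000, theta = 0.3,
                             prop_invalid = 0, pleiotropy_mean = 0,
                             pleiotropy_sd = 0.05, inside_violation = FALSE,
                             kappa = 0.5, maf_range = c(0.05, 0.5),
                             ld_block_size = 1, ld_rho = 0,
                             frac_palindromic = 0.1, frac_flipped = 0.1,
                             seed = 1) {
  cfg <- list(n_snps = as.integer(n_snps), n_exposure = n_exposure,
              n_outcome = n_outcome, theta = theta,
              prop_invalid = prop_invalid,
              pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd,
              inside_violation = isTRUE(inside_violation), kappa = kappa,
              maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
              ld_rho = ld_rho, frac_palindromic = frac_palindromic,
              frac_flipped = frac_flipped, seed = as.integer(seed))
  stopifnot(cfg$n_snps >= 1, cfg$n_exposure > 0, cfg$n_outcome > 0,
            is.finite(cfg$theta),
            cfg$prop_invalid >= 0, cfg$prop_invalid < 1,
            cfg$pleiotropy_sd >= 0,
            length(cfg$maf_range) == 2, cfg$maf_range[1] > 0,
            cfg$maf_range[2] <= 0.5, cfg$maf_range[1] <= cfg$maf_range[2],
            cfg$ld_block_size >= 1, cfg$ld_rho >= 0, cfg$ld_rho < 1,
            cfg$frac_palindromic >= 0, cfg$frac_palindromic <= 1,
            cfg$frac_flipped >= 0, cfg$frac_flipped <= 1)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Read a simulation configuration from a YAML file
#' @param path YAML file whose keys match the arguments of
#'   [simulationConfig()].
#' @return A \code{"SimulationConfig"}.
#' @export
readSimulationConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(simulationConfig)))
  if (length(unknown))
    stop("unknown simulation key(s): ", paste(unknown, collapse = ", "))
  do.call(simulationConfig, vals)
}

# Non-complementary allele pairs for ordinary SNPs; complementary for
# palindromic ones.
.NONPALINDROMIC_PAIRS <- list(c("A", "C"), c("A", "G"), c("T", "C"),
                              c("T", "G"))
.PALINDROMIC_PAIRS <- list(c("A", "T"), c("C", "G"))
.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Simulate a paired exposure/outcome GWAS with known ground truth
#'
#' Generates matched exposure and outcome summary-statistics tables, an LD
#' matrix, and a truth record, on the summary-statistic scale (no
#' individual-level genotypes). Per SNP j with minor-allele frequency
#' \eqn{maf_j}: a true exposure effect \eqn{\gamma_j} is drawn from
#' Normal(0, 0.08^2) truncated away from zero at \eqn{|\gamma| \ge 0.02};
#' the observed exposure beta is \eqn{\gamma_j} plus Normal noise with
#' \eqn{se_{xj} = 1/\sqrt{2\,maf_j(1-maf_j)\,n_{exposure}}}; the outcome beta
#' is \eqn{\theta\gamma_j + \alpha_j} plus analogous noise, with direct
#' effect \eqn{\alpha_j = 0} for valid instruments. The LD matrix is
#' block-diagonal with constant within-block correlation \code{ld_rho}
#' (entries are r-squared); blocks are placed on separate chromosome stretches
#' far enough apart not to interact across blocks. A configured fraction of
#' variants receives complementary (palindromic) allele pairs, and a fraction
#' has its allele order swapped in the outcome table (beta negated, eaf
#' reflected) to exercise harmonization.
#'
#' @param config a \code{"SimulationConfig"} from [simulationConfig()].
#' @return list with elements \code{exposure} and \code{outcome}
#'   (\linkS4class{SummaryStats}), \code{ld} (\linkS4class{LDMatrix}) and
#'   \code{truth} (list: \code{theta}, \code{invalid_snp_ids}, per-SNP
#'   \code{gamma} and \code{alpha}, \code{flipped_snp_ids},
#'   \code{palindromic_snp_ids}).
#' @examples
#' sim <- simulateGWASPair(simulationConfig(n_snps = 20, seed = 7))
#' length(sim$exposure)
#' sim$truth$theta
#' @export
simulateGWASPair <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, {
    k <- config$n_snps
    snp_id <- sprintf("rs%07d", seq_len(k) * 13 + 1000000L)
    block <- (seq_len(k) - 1L) %/% config$ld_block_size
    chrom <- as.character((block %% 22L) + 1L)
    # Blocks sharing a chromosome sit 20 Mb apart, beyond any clumping window;
    # SNPs within a block are 1 kb apart.
    pos <- 1000000L + (block %/% 22L) * 20000000L +
      ((seq_len(k) - 1L) %% config$ld_block_size) * 1000L

    maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    gamma <- numeric(k)
    for (j in seq_len(k)) {
      g <- stats::rnorm(1, 0, 0.08)
      while (abs(g) < 0.02) g <- stats::rnorm(1, 0, 0.08)
      gamma[j] <- g
    }

    n_invalid <- round(config$prop_invalid * k)
    invalid <- sort(sample.int(k, n_invalid))
    alpha <- numeric(k)
    if (n_invalid > 0) {
      # Directional pleiotropy is defined on the exposure-increasing allele
      # coding (the effect-allele choice is arbitrary), hence sign(gamma).
      noise <- sign(gamma[invalid]) *
        stats::rnorm(n_invalid, config$pleiotropy_mean, config$pleiotropy_sd)
      alpha[invalid] <- if (config$inside_violation)
        config$kappa * gamma[invalid] + noise else noise
    }

    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)
    beta_x <- stats::rnorm(k, gamma, se_x)
    beta_y <- stats::rnorm(k, config$theta * gamma + alpha, se_y)

    n_pal <- round(config$frac_palindromic * k)
    pal <- sort(sample.int(k, n_pal))
    is_pal <- seq_len(k) %in% pal
    ea <- oa <- character(k)
    for (j in seq_len(k)) {
      pair <- if (is_pal[j])
        .PALINDROMIC_PAIRS[[sample.int(2, 1)]]
      else .NONPALINDROMIC_PAIRS[[sample.int(4, 1)]]
      if (stats::runif(1) < 0.5) pair <- rev(pair)
      ea[j] <- pair[1]; oa[j] <- pair[2]
    }

    exposure <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta_x, se = se_x,
      pval = pmax(2 * stats::pnorm(-abs(beta_x / se_x)), 1e-300),
      n = config$n_exposure, stringsAsFactors = FALSE)

    n_flip <- round(config$frac_flipped * k)
    flip <- sort(sample.int(k, n_flip))
    is_flip <- seq_len(k) %in% flip
    outcome <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = ifelse(is_flip, oa, ea),
      other_allele = ifelse(is_flip, ea, oa),
      eaf = ifelse(is_flip, 1 - maf, maf),
      beta = ifelse(is_flip, -beta_y, beta_y), se = se_y,
      pval = pmax(2 * stats::pnorm(-abs(beta_y / se_y)), 1e-300),
      n = config$n_outcome, stringsAsFactors = FALSE)

    r2 <- diag(k)
    if (config$ld_block_size > 1 && config$ld_rho > 0) {
      for (bl in unique(block)) {
        idx <- which(block == bl)
        r2[idx, idx] <- config$ld_rho^2
      }
      diag(r2) <- 1
    }
    dimnames(r2) <- list(snp_id, snp_id)

    list(exposure = SummaryStats(exposure),
         outcome = SummaryStats(outcome),
         ld = LDMatrix(r2),
         truth = list(theta = config$theta,
                      invalid_snp_ids = snp_id[invalid],
                      snp_id = snp_id, gamma = gamma, alpha = alpha,
                      flipped_snp_ids = snp_id[flip],
                      palindromic_snp_ids = snp_id[pal]))
  })
}

#' Worked per-SNP example: Erysipelotrichia instruments
#'
#' Returns the five per-SNP causal estimates (Wald ratios) for the
#' Erysipelotrichia class instruments against childhood neuroblastoma, as a
#' fixed reference fixture. Their fixed-effect inverse-variance-weighted
#' combination gives the headline protective estimate (OR about 0.371). The
#' table follows the per-SNP schema used throughout the package.
#'
#' @return data.frame with columns \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{b}, \code{se}, \code{p}; five rows, constant
#'   across calls.
#' @examples
#' fx <- erysipelotrichiaFixture()
#' mrIVW(fx, mode = "fixed")
#' @export
erysipelotrichiaFixture <- function() {
  data.frame(
    snp_id = c("rs1074800", "rs2300774", "rs35161940", "rs4078432",
               "rs8003149"),
    chrom = c("5", "3", "17", "14", "14"),
    pos = c(3004171L, 195800811L, 70334286L, 48997206L, 56160904L),
    effect_allele = c("A", "G", "T", "C", "C"),
    b = c(-1.226287714, -0.729916118, -1.625575773, -0.427570132,
          -0.8876358),
    se = c(0.881003827, 0.824245623, 0.84377268, 0.908389464, 0.895507031),
    p = c(0.163946327, 0.375856529, 0.054034919, 0.637861894, 0.321582898),
    stringsAsFactors = FALSE)
}
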