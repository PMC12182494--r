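.isPalindromic <- function(a1, a2) a2 == .COMPLEMENT[a1]

#' Harmonize outcome effects to the exposure's effect allele
#'
#' For each variant shared by the two tables, aligns the outcome-sample effect
#' to the exposure sample's effect allele:
#' \itemize{
#'   \item alleles equal in order: kept unchanged (\code{aligned});
#'   \item alleles equal with order swapped: outcome beta negated and eaf
#'     reflected (\code{swapped});
#'   \item alleles equal (directly or swapped) only after complementing the
#'     outcome alleles: treated as a strand flip, then re-checked
#'     (\code{strand_flipped});
#'   \item palindromic variants (A/T or C/G): orientation cannot be read from
#'     the alleles, so it is inferred from allele frequencies. When both eafs
#'     are present and both lie outside \code{0.5 +/- palindromic_eaf_window},
#'     frequencies on the same side of 0.5 indicate agreement (kept as-is) and
#'     opposite sides indicate a flip (beta negated, eaf reflected), status
#'     \code{palindromic_kept}; otherwise the variant is \code{dropped} as
#'     ambiguous;
#'   \item allele sets that cannot be reconciled, and variants present in only
#'     one table, are \code{dropped} with a reason.
#' }
#'
#' @param exposure,outcome \linkS4class{SummaryStats} tables; joined on
#'   \code{snp_id}.
#' @param palindromic_eaf_window half-width of the frequency ambiguity zone
#'   around 0.5 (default 0.08).
#' @return A \linkS4class{HarmonizedPairs}.
#' @examples
#' sim <- simulateGWASPair(simulationConfig(n_snps = 10, seed = 3))
#' h <- harmonize(sim$exposure, sim$outcome)
#' table(as.data.frame(h)$status)
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(is(exposure, "SummaryStats"), is(outcome, "SummaryStats"),
            palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5)
  ex <- exposure@stats
  ou <- outcome@stats
  if (anyDuplicated(ex$snp_id)) stop("duplicate snp_id in exposure table")
  if (anyDuplicated(ou$snp_id)) stop("duplicate snp_id in outcome table")
  m <- match(ex$snp_id, ou$snp_id)
  w <- palindromic_eaf_window

  k <- nrow(ex)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, k)
  status <- reason <- character(k)
  for (i in seq_len(k)) {
    j <- m[i]
    if (is.na(j)) {
      status[i] <- "dropped"; reason[i] <- "absent from outcome table"
      next
    }
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    b <- ou$beta[j]; s <- ou$se[j]; f <- ou$eaf[j]
    oea <- ou$effect_allele[j]; ooa <- ou$other_allele[j]

    if (.isPalindromic(ea, oa)) {
      same_set <- (oea == ea && ooa == oa) || (oea == oa && ooa == ea)
      if (!same_set) {
        status[i] <- "dropped"; reason[i] <- "allele mismatch"
      } else if (is.na(ex$eaf[i]) || is.na(f)) {
        status[i] <- "dropped"
        reason[i] <- "palindromic, eaf missing"
      } else if (abs(ex$eaf[i] - 0.5) <= w || abs(f - 0.5) <= w) {
        status[i] <- "dropped"
        reason[i] <- "palindromic, eaf ambiguous"
      } else {
        # Effect-allele frequency read on the outcome's own labelling; a
        # swapped labelling already reflects f, so compare sides directly
        # after undoing any label swap.
        f_ea <- if (oea == ea) f else 1 - f
        b_ea <- if (oea == ea) b else -b
        if ((ex$eaf[i] > 0.5) == (f_ea > 0.5)) {
          beta_out[i] <- b_ea; eaf_out[i] <- f_ea
        } else {
          beta_out[i] <- -b_ea; eaf_out[i] <- 1 - f_ea
        }
        se_out[i] <- s
        status[i] <- "palindromic_kept"
        reason[i] <- "orientation inferred from eaf"
      }
      next
    }

    aligned <- function(a1, a2) a1 == ea && a2 == oa
    swapped <- function(a1, a2) a1 == oa && a2 == ea
    cea <- unname(.COMPLEMENT[oea]); coa <- unname(.COMPLEMENT[ooa])
    if (aligned(oea, ooa)) {
      beta_out[i] <- b; eaf_out[i] <- f; se_out[i] <- s
      status[i] <- "aligned"
    } else if (swapped(oea, ooa)) {
      beta_out[i] <- -b
      eaf_out[i] <- if (is.na(f)) NA_real_ else 1 - f
      se_out[i] <- s
      status[i] <- "swapped"; reason[i] <- "allele order swapped"
    } else if (aligned(cea, coa)) {
      beta_out[i] <- b; eaf_out[i] <- f; se_out[i] <- s
      status[i] <- "strand_flipped"; reason[i] <- "strand flip"
    } else if (swapped(cea, coa)) {
      beta_out[i] <- -b
      eaf_out[i] <- if (is.na(f)) NA_real_ else 1 - f
      se_out[i] <- s
      status[i] <- "strand_flipped"; reason[i] <- "strand flip + swap"
    } else {
      status[i] <- "dropped"; reason[i] <- "allele mismatch"
    }
  }

  pairs <- data.frame(
    snp_id = ex$snp_id, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
    beta_out = beta_out, se_out = se_out, eaf_out = eaf_out,
    status = status, reason = reason, stringsAsFactors = FALSE)
  new("HarmonizedPairs", pairs = pairs)
}
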