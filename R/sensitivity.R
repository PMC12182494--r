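#' Cochran's Q heterogeneity test
#'
#' Computes \code{Q = sum w_j (b_j - b_ivw)^2} with inverse-variance weights
#' \code{w_j = 1/se_j^2} against the fixed-effect IVW estimate of the same
#' ratios, and the upper-tail chi-square p-value on k-1 degrees of freedom.
#' Large Q (small p) indicates that the per-SNP estimates disagree more than
#' their sampling errors allow — evidence of heterogeneity, e.g. from
#' pleiotropy.
#'
#' @param ratios data.frame of Wald ratios; at least 2.
#' @param b_ivw optional fixed-effect IVW estimate to test against; computed
#'   from \code{ratios} when omitted.
#' @return data.frame with columns \code{method}, \code{Q}, \code{df},
#'   \code{p}.
#' @examples
#' cochranQ(erysipelotrichiaFixture())
#' @export
cochranQ <- function(ratios, b_ivw = NULL) {
  ratios <- .checkRatios(ratios, 2L)
  w <- 1 / ratios$se^2
  if (is.null(b_ivw)) b_ivw <- sum(w * ratios$b) / sum(w)
  Q <- sum(w * (ratios$b - b_ivw)^2)
  df <- nrow(ratios) - 1L
  data.frame(method = "IVW", Q = Q, df = df,
             p = stats::pchisq(Q, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the fixed-effect IVW estimate omitting each instrument in turn,
#' flagging estimates driven by a single SNP. Fixed-effect weighting is used
#' for every subset regardless of the headline IVW mode, keeping the rows
#' comparable.
#'
#' @param ratios data.frame of Wald ratios; at least 3.
#' @return data.frame with one row per omitted SNP, in input order: columns
#'   \code{omitted_snp}, \code{nsnp}, \code{b}, \code{se}, \code{p}.
#' @export
leaveOneOut <- function(ratios) {
  ratios <- .checkRatios(ratios, 3L)
  rows <- lapply(seq_len(nrow(ratios)), function(i) {
    r <- mrIVW(ratios[-i, , drop = FALSE], mode = "fixed")
    data.frame(omitted_snp = ratios$snp_id[i], nsnp = nsnp(r),
               b = estimate(r), se = stdError(r), p = pvalue(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-SNP results table
#'
#' Emits the per-SNP Wald ratios in the reporting schema (one row per
#' instrument with its own b, se, p); their inverse-variance combination
#' equals the full fixed-effect IVW estimate.
#'
#' @param ratios data.frame of Wald ratios (may be empty).
#' @return data.frame with columns \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{b}, \code{se}, \code{p}.
#' @export
singleSnp <- function(ratios) {
  cols <- c("snp_id", "chrom", "pos", "effect_allele", "b", "se", "p")
  missing_cols <- setdiff(cols, names(ratios))
  for (col in missing_cols) ratios[[col]] <- NA
  out <- ratios[, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Funnel-plot data
#'
#' Per-SNP estimate versus precision pairs for funnel-plot asymmetry
#' inspection, together with the reference (combined) estimate. Under balanced
#' pleiotropy the points scatter symmetrically around the reference line.
#'
#' @param ratios data.frame of Wald ratios.
#' @param b_ivw reference estimate; fixed-effect IVW of \code{ratios} when
#'   omitted.
#' @return list with \code{data} (data.frame: \code{snp_id}, \code{b},
#'   \code{precision} = 1/se) and \code{b_ivw}.
#' @export
funnelData <- function(ratios, b_ivw = NULL) {
  if (nrow(ratios) && is.null(b_ivw)) {
    w <- 1 / ratios$se^2
    b_ivw <- sum(w * ratios$b) / sum(w)
  }
  list(data = data.frame(snp_id = ratios$snp_id, b = ratios$b,
                         precision = 1 / ratios$se,
                         stringsAsFactors = FALSE),
       b_ivw = if (is.null(b_ivw)) NA_real_ else b_ivw)
}
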