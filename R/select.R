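#' Filter variants by association p-value
#'
#' Retains exactly the records with \code{pval} strictly below the threshold,
#' preserving input order. The conventional instrument-selection cutoff for
#' microbiome GWAS, where few variants reach 5e-8, is 1e-5.
#'
#' @param x a \linkS4class{SummaryStats}.
#' @param threshold significance cutoff in (0, 1); default \code{1e-5}.
#' @return A \linkS4class{SummaryStats} with the passing subset.
#' @export
filterByPvalue <- function(x, threshold = 1e-5) {
  stopifnot(is(x, "SummaryStats"), threshold > 0, threshold < 1)
  x[which(x@stats$pval < threshold)]
}

# Deterministic processing order: ascending p, ties by chromosome (numeric
# where possible), position, then snp_id.
.clumpOrder <- function(df) {
  chrom_num <- suppressWarnings(as.numeric(df$chrom))
  chrom_key <- ifelse(is.na(chrom_num), Inf, chrom_num)
  order(df$pval, chrom_key, df$chrom, df$pos, df$snp_id)
}

#' Greedy LD clumping of candidate instruments
#'
#' Thins correlated variants so that retained instruments are approximately
#' independent: repeatedly take the unprocessed variant with the smallest
#' p-value as an index SNP, retain it, and remove every unprocessed variant on
#' the same chromosome within \code{clump_kb} kilobases whose r-squared with
#' the index is at least \code{clump_r2}. Ties on p-value break by smaller
#' chromosome, then position, then identifier, making the result invariant to
#' input row order.
#'
#' @param x a \linkS4class{SummaryStats}; every variant must be present in
#'   \code{ld}.
#' @param ld an \linkS4class{LDMatrix} covering the variants of \code{x}.
#' @param clump_r2 r-squared removal cutoff (default 0.001).
#' @param clump_kb window half-width in kilobases (default 10000);
#'   variants with \code{|pos_i - pos_j| <= clump_kb * 1000} on the same
#'   chromosome are in the window.
#' @return A \linkS4class{SummaryStats} of retained variants, sorted by
#'   chromosome then position.
#' @export
clumpVariants <- function(x, ld, clump_r2 = 0.001, clump_kb = 10000) {
  stopifnot(is(x, "SummaryStats"), is(ld, "LDMatrix"),
            clump_r2 >= 0, clump_r2 <= 1, clump_kb > 0)
  df <- x@stats
  if (nrow(df) == 0L) return(x)
  missing_ld <- setdiff(df$snp_id, snpIds(ld))
  if (length(missing_ld))
    stop("variant(s) absent from LD matrix: ",
         paste(missing_ld, collapse = ", "))
  r2 <- ld@r2[df$snp_id, df$snp_id, drop = FALSE]
  ord <- .clumpOrder(df)
  alive <- rep(TRUE, nrow(df))
  keep <- logical(nrow(df))
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    in_window <- alive & df$chrom == df$chrom[i] &
      abs(df$pos - df$pos[i]) <= clump_kb * 1000
    alive[in_window & r2[i, ] >= clump_r2] <- FALSE
  }
  kept <- df[keep, , drop = FALSE]
  chrom_num <- suppressWarnings(as.numeric(kept$chrom))
  chrom_key <- ifelse(is.na(chrom_num), Inf, chrom_num)
  kept <- kept[order(chrom_key, kept$chrom, kept$pos), , drop = FALSE]
  x[match(kept$snp_id, df$snp_id)]
}

#' Select instruments: p-value filter then LD clumping
#'
#' Convenience wrapper applying [filterByPvalue()] followed by
#' [clumpVariants()], with the conventional defaults (p < 1e-5, r-squared <
#' 0.001 within a 10,000 kb window).
#'
#' @inheritParams clumpVariants
#' @inheritParams filterByPvalue
#' @return A \linkS4class{SummaryStats} of selected instruments.
#' @export
selectInstruments <- function(x, ld, threshold = 1e-5, clump_r2 = 0.001,
                              clump_kb = 10000) {
  clumpVariants(filterByPvalue(x, threshold), ld,
                clump_r2 = clump_r2, clump_kb = clump_kb)
}
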