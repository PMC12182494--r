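#' @import methods
NULL

.SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")

#' GWAS summary statistics for one sample
#'
#' An S4 container for per-variant association statistics from a single GWAS
#' (either the exposure or the outcome sample). The \code{stats} slot holds one
#' row per variant with columns \code{snp_id}, \code{chrom}, \code{pos}
#' (1-based), \code{effect_allele}, \code{other_allele}, \code{eaf}
#' (effect-allele frequency, may be \code{NA}), \code{beta} (per-allele effect,
#' log-odds for binary traits), \code{se}, \code{pval} and \code{n} (may be
#' \code{NA}). The \code{rejected} slot carries the per-row validation report
#' produced when the object was read from a file (columns \code{row},
#' \code{snp_id}, \code{reason}); it is empty for programmatically built
#' objects.
#'
#' Validity requires: alleles in \{A,C,G,T\} with \code{effect_allele !=
#' other_allele}, \code{se > 0}, \code{pval} in (0, 1], \code{eaf} in [0, 1]
#' when present, positive integer positions, and unique \code{snp_id}.
#'
#' @slot stats data.frame of validated records.
#' @slot rejected data.frame describing rows rejected during parsing.
#' @seealso [readSumstats()], [SummaryStats()]
#' @export
setClass("SummaryStats",
  representation(stats = "data.frame", rejected = "data.frame"),
  prototype(
    stats = data.frame(
      snp_id = character(), chrom = character(), pos = integer(),
      effect_allele = character(), other_allele = character(),
      eaf = numeric(), beta = numeric(), se = numeric(), pval = numeric(),
      n = numeric(), stringsAsFactors = FALSE),
    rejected = data.frame(row = integer(), snp_id = character(),
                          reason = character(), stringsAsFactors = FALSE))
)

setValidity("SummaryStats", function(object) {
  df <- object@stats
  missing_cols <- setdiff(.SUMSTATS_COLS, names(df))
  if (length(missing_cols))
    return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  msgs <- .recordProblems(df)
  if (any(nzchar(msgs)))
    return(paste0("invalid record(s): ",
                  paste(utils::head(msgs[nzchar(msgs)], 3), collapse = "; ")))
  if (anyDuplicated(df$snp_id))
    return("duplicate snp_id within table")
  TRUE
})

# One message per row; "" when the row satisfies every invariant.
.recordProblems <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    probs <- character()
    if (is.na(r$snp_id) || !nzchar(r$snp_id)) probs <- c(probs, "empty snp_id")
    ok_allele <- function(a) !is.na(a) && a %in% c("A", "C", "G", "T")
    if (!ok_allele(r$effect_allele) || !ok_allele(r$other_allele))
      probs <- c(probs, "allele not in {A,C,G,T}")
    else if (r$effect_allele == r$other_allele)
      probs <- c(probs, "effect_allele == other_allele")
    if (is.na(r$pos) || r$pos < 1) probs <- c(probs, "non-positive pos")
    if (is.na(r$beta)) probs <- c(probs, "non-numeric beta")
    if (is.na(r$se) || r$se <= 0) probs <- c(probs, "se must be > 0")
    if (is.na(r$pval) || r$pval <= 0 || r$pval > 1)
      probs <- c(probs, "pval outside (0,1]")
    if (!is.na(r$eaf) && (r$eaf < 0 || r$eaf > 1))
      probs <- c(probs, "eaf outside [0,1]")
    if (!is.na(r$n) && r$n <= 0) probs <- c(probs, "non-positive n")
    paste(probs, collapse = ", ")
  }, character(1))
}

#' Construct a SummaryStats object from a data.frame
#'
#' @param stats data.frame with the columns described in
#'   \linkS4class{SummaryStats}; \code{eaf} and \code{n} may be absent and are
#'   filled with \code{NA}. Allele strings are upper-cased.
#' @param rejected optional validation report to attach.
#' @return A validated \linkS4class{SummaryStats} object.
#' @export
SummaryStats <- function(stats, rejected = NULL) {
  stats <- as.data.frame(stats, stringsAsFactors = FALSE)
  for (col in c("eaf", "n")) if (is.null(stats[[col]])) stats[[col]] <- NA_real_
  stats$snp_id <- as.character(stats$snp_id)
  stats$chrom <- as.character(stats$chrom)
  stats$pos <- as.integer(stats$pos)
  stats$effect_allele <- toupper(as.character(stats$effect_allele))
  stats$other_allele <- toupper(as.character(stats$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n"))
    stats[[col]] <- as.numeric(stats[[col]])
  stats <- stats[, .SUMSTATS_COLS, drop = FALSE]
  rownames(stats) <- NULL
  if (is.null(rejected))
    rejected <- data.frame(row = integer(), snp_id = character(),
                           reason = character(), stringsAsFactors = FALSE)
  new("SummaryStats", stats = stats, rejected = rejected)
}

#' Linkage-disequilibrium matrix
#'
#' Squared-correlation (r-squared) matrix between variants. Validity requires a
#' square symmetric matrix with unit diagonal, values in [0, 1] and matching
#' row/column variant labels. The constructor clamps values to [0, 1] and
#' symmetrizes discrepancies up to \code{tol}; larger asymmetries are an
#' error.
#'
#' @slot r2 numeric matrix with dimnames set to the variant identifiers.
#' @seealso [readLDMatrix()], [LDMatrix()]
#' @export
setClass("LDMatrix", representation(r2 = "matrix"))

setValidity("LDMatrix", function(object) {
  m <- object@r2
  if (nrow(m) != ncol(m)) return("matrix not square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("variant labels absent")
  if (!identical(rownames(m), colnames(m)))
    return("row/column label mismatch")
  if (nrow(m) > 0) {
    if (any(abs(m - t(m)) > 1e-8)) return("matrix not symmetric")
    if (any(abs(diag(m) - 1) > 1e-8)) return("diagonal not 1")
    if (any(m < 0 | m > 1)) return("values outside [0,1]")
  }
  TRUE
})

#' @rdname LDMatrix-class
#' @param r2 square numeric matrix of squared correlations.
#' @param snp_ids variant identifiers; defaults to existing dimnames.
#' @param tol maximum tolerated asymmetry / out-of-range excursion.
#' @return A validated \linkS4class{LDMatrix}.
#' @export
LDMatrix <- function(r2, snp_ids = rownames(r2), tol = 1e-8) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("LD matrix must be square")
  if (is.null(snp_ids)) stop("LD matrix requires variant labels")
  if (any(abs(r2 - t(r2)) > tol))
    stop("LD matrix asymmetric beyond tolerance ", tol)
  r2 <- (r2 + t(r2)) / 2
  r2[r2 < 0] <- 0
  r2[r2 > 1] <- 1
  diag(r2) <- 1
  dimnames(r2) <- list(snp_ids, snp_ids)
  new("LDMatrix", r2 = r2)
}

#' Harmonized exposure/outcome variant pairs
#'
#' Result of aligning outcome-sample effects to the exposure sample's effect
#' allele. One row per exposure variant with columns \code{snp_id},
#' \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#' \code{beta_exp}, \code{se_exp}, \code{eaf_exp}, \code{beta_out},
#' \code{se_out}, \code{eaf_out}, \code{status} (one of \code{aligned},
#' \code{swapped}, \code{strand_flipped}, \code{palindromic_kept},
#' \code{dropped}) and \code{reason}. Dropped pairs are excluded from
#' estimation; use [retained()] to obtain the estimable subset.
#'
#' @slot pairs data.frame as described above.
#' @seealso [harmonize()], [retained()]
#' @export
setClass("HarmonizedPairs", representation(pairs = "data.frame"))

.HARMONIZED_STATUSES <- c("aligned", "swapped", "strand_flipped",
                          "palindromic_kept", "dropped")

setValidity("HarmonizedPairs", function(object) {
  df <- object@pairs
  need <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out",
            "status", "reason")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    return(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  if (!all(df$status %in% .HARMONIZED_STATUSES))
    return("unknown harmonization status")
  kept <- df$status != "dropped"
  if (any(kept & (is.na(df$se_exp) | df$se_exp <= 0)) ||
      any(kept & (is.na(df$se_out) | df$se_out <= 0)))
    return("retained pair with non-positive se")
  TRUE
})

#' One MR estimator's causal estimate
#'
#' Output of a single Mendelian-randomization estimator, mirroring the usual
#' reporting columns: method, number of instruments, causal log-odds estimate
#' \code{b} with standard error and two-sided p-value, and the derived odds
#' ratio with 95\% confidence bounds (\code{or = exp(b)},
#' \code{or_lci95 = exp(b - 1.959964 se)},
#' \code{or_uci95 = exp(b + 1.959964 se)}). MR-Egger results additionally carry
#' the pleiotropy intercept, its SE and p-value; these are \code{NA} for the
#' other methods.
#'
#' @slot exposure character label for the exposure trait.
#' @slot method one of \code{"IVW"}, \code{"MR-Egger"},
#'   \code{"weighted-median"}, \code{"weighted-mode"}.
#' @slot nsnp integer number of instruments used.
#' @slot b,se,p numeric estimate, standard error and two-sided p-value.
#' @slot or_,or_lci95,or_uci95 numeric odds-ratio scale summaries.
#' @slot egger_intercept,egger_intercept_se,egger_intercept_p numeric, only
#'   populated for MR-Egger.
#' @export
setClass("MRResult",
  representation(exposure = "character", method = "character",
                 nsnp = "integer", b = "numeric", se = "numeric",
                 p = "numeric", or_ = "numeric", or_lci95 = "numeric",
                 or_uci95 = "numeric", egger_intercept = "numeric",
                 egger_intercept_se = "numeric", egger_intercept_p = "numeric"),
  prototype(exposure = "exposure", egger_intercept = NA_real_,
            egger_intercept_se = NA_real_, egger_intercept_p = NA_real_))

setValidity("MRResult", function(object) {
  if (!object@method %in% c("IVW", "MR-Egger", "weighted-median",
                            "weighted-mode"))
    return("unknown method")
  if (object@nsnp < 1L) return("nsnp must be >= 1")
  if (!is.na(object@se) && object@se <= 0) return("se must be > 0")
  if (abs(object@or_ - exp(object@b)) > 1e-12 * max(1, object@or_))
    return("or_ must equal exp(b)")
  if (!is.na(object@se) &&
      !(object@or_lci95 < object@or_ && object@or_ < object@or_uci95))
    return("CI bounds must bracket the odds ratio")
  TRUE
})

# 97.5% normal quantile to the precision used for the printed CI bounds.
.Z975 <- 1.959964

#' @rdname MRResult-class
#' @param method,nsnp,b,se,p core estimator outputs.
#' @param exposure exposure label.
#' @param egger_intercept,egger_intercept_se,egger_intercept_p MR-Egger
#'   intercept summaries.
#' @return A validated \linkS4class{MRResult}; odds-ratio fields are computed
#'   from \code{b} and \code{se}.
#' @export
MRResult <- function(method, nsnp, b, se, p, exposure = "exposure",
                     egger_intercept = NA_real_,
                     egger_intercept_se = NA_real_,
                     egger_intercept_p = NA_real_) {
  new("MRResult", exposure = exposure, method = method,
      nsnp = as.integer(nsnp), b = b, se = se, p = p,
      or_ = exp(b), or_lci95 = exp(b - .Z975 * se),
      or_uci95 = exp(b + .Z975 * se),
      egger_intercept = egger_intercept,
      egger_intercept_se = egger_intercept_se,
      egger_intercept_p = egger_intercept_p)
}
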