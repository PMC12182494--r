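#' Variant identifiers of an object
#' @param x a \linkS4class{SummaryStats} or \linkS4class{LDMatrix}.
#' @return character vector of SNP identifiers.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname snpIds
#' @export
setMethod("snpIds", "SummaryStats", function(x) x@stats$snp_id)

#' @rdname snpIds
#' @export
setMethod("snpIds", "LDMatrix", function(x) rownames(x@r2))

#' Rejected-row validation report of a SummaryStats object
#' @param x a \linkS4class{SummaryStats}.
#' @return data.frame with columns \code{row}, \code{snp_id}, \code{reason}.
#' @export
setGeneric("rejected", function(x) standardGeneric("rejected"))

#' @rdname rejected
#' @export
setMethod("rejected", "SummaryStats", function(x) x@rejected)

#' Estimable subset of harmonized pairs
#' @param x a \linkS4class{HarmonizedPairs}.
#' @return data.frame of pairs whose status is not \code{dropped}.
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))

#' @rdname retained
#' @export
setMethod("retained", "HarmonizedPairs", function(x) {
  df <- x@pairs[x@pairs$status != "dropped", , drop = FALSE]
  rownames(df) <- NULL
  df
})

#' Accessors for MRResult
#'
#' \code{estimate}, \code{stdError}, \code{pvalue}, \code{oddsRatio},
#' \code{orCI}, \code{nsnp}, \code{mrMethod} and \code{eggerIntercept} extract
#' the corresponding summaries from an \linkS4class{MRResult}.
#'
#' @param x an \linkS4class{MRResult}.
#' @return numeric scalar (or a named length-2 vector for \code{orCI}; a named
#'   length-3 vector for \code{eggerIntercept}).
#' @name MRResult-accessors
NULL

#' @rdname MRResult-accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))
#' @rdname MRResult-accessors
#' @export
setMethod("estimate", "MRResult", function(x) x@b)

#' @rdname MRResult-accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))
#' @rdname MRResult-accessors
#' @export
setMethod("stdError", "MRResult", function(x) x@se)

#' @rdname MRResult-accessors
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))
#' @rdname MRResult-accessors
#' @export
setMethod("pvalue", "MRResult", function(x) x@p)

#' @rdname MRResult-accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))
#' @rdname MRResult-accessors
#' @export
setMethod("oddsRatio", "MRResult", function(x) x@or_)

#' @rdname MRResult-accessors
#' @export
setGeneric("orCI", function(x) standardGeneric("orCI"))
#' @rdname MRResult-accessors
#' @export
setMethod("orCI", "MRResult",
          function(x) c(lci95 = x@or_lci95, uci95 = x@or_uci95))

#' @rdname MRResult-accessors
#' @export
setGeneric("nsnp", function(x) standardGeneric("nsnp"))
#' @rdname MRResult-accessors
#' @export
setMethod("nsnp", "MRResult", function(x) x@nsnp)

#' @rdname MRResult-accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))
#' @rdname MRResult-accessors
#' @export
setMethod("mrMethod", "MRResult", function(x) x@method)

#' @rdname MRResult-accessors
#' @export
setGeneric("eggerIntercept", function(x) standardGeneric("eggerIntercept"))
#' @rdname MRResult-accessors
#' @export
setMethod("eggerIntercept", "MRResult", function(x)
  c(intercept = x@egger_intercept, se = x@egger_intercept_se,
    p = x@egger_intercept_p))

#' @describeIn SummaryStats-class number of variants.
#' @param x a SummaryStats object.
#' @export
setMethod("length", "SummaryStats", function(x) nrow(x@stats))

#' @describeIn HarmonizedPairs-class number of pairs (including dropped).
#' @param x a HarmonizedPairs object.
#' @export
setMethod("length", "HarmonizedPairs", function(x) nrow(x@pairs))

#' Coerce package objects to data.frame
#' @param x object to coerce.
#' @param row.names,optional,... ignored; present for generic compatibility.
#' @return data.frame view of the object's tabular content.
#' @export
as.data.frame.SummaryStats <- function(x, row.names = NULL,
                                       optional = FALSE, ...) x@stats

#' @rdname as.data.frame.SummaryStats
#' @export
as.data.frame.HarmonizedPairs <- function(x, row.names = NULL,
                                          optional = FALSE, ...) x@pairs

#' @rdname as.data.frame.SummaryStats
#' @export
as.data.frame.MRResult <- function(x, row.names = NULL,
                                   optional = FALSE, ...) {
  data.frame(exposure = x@exposure, method = x@method, nsnp = x@nsnp,
             b = x@b, se = x@se, p = x@p, OR = x@or_,
             OR_lci95 = x@or_lci95, OR_uci95 = x@or_uci95,
             egger_intercept = x@egger_intercept,
             egger_intercept_se = x@egger_intercept_se,
             egger_intercept_p = x@egger_intercept_p,
             stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "SummaryStats",
          function(x, ...) as.data.frame.SummaryStats(x, ...))
setMethod("as.data.frame", "HarmonizedPairs",
          function(x, ...) as.data.frame.HarmonizedPairs(x, ...))
setMethod("as.data.frame", "MRResult",
          function(x, ...) as.data.frame.MRResult(x, ...))

#' Subset a SummaryStats by row
#' @param x a \linkS4class{SummaryStats}.
#' @param i row index (integer, logical, or snp_id character vector).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "SummaryStats", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@stats$snp_id)
  df <- x@stats[i, , drop = FALSE]
  rownames(df) <- NULL
  initialize(x, stats = df,
             rejected = x@rejected[0, , drop = FALSE])
})

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats with", nrow(object@stats), "variants\n")
  if (nrow(object@rejected))
    cat(" ", nrow(object@rejected), "rows rejected at parse time\n")
  if (nrow(object@stats))
    print(utils::head(object@stats, 5))
  if (nrow(object@stats) > 5) cat("  ...\n")
})

setMethod("show", "LDMatrix", function(object) {
  cat("LDMatrix (r-squared) for", nrow(object@r2), "variants\n")
  if (nrow(object@r2))
    print(object@r2[seq_len(min(5, nrow(object@r2))),
                    seq_len(min(5, ncol(object@r2))), drop = FALSE])
})

setMethod("show", "HarmonizedPairs", function(object) {
  tab <- table(factor(object@pairs$status, levels = .HARMONIZED_STATUSES))
  cat("HarmonizedPairs with", nrow(object@pairs), "pairs\n")
  for (s in names(tab)) if (tab[[s]]) cat(" ", s, ":", tab[[s]], "\n")
})

setMethod("show", "MRResult", function(object) {
  cat(sprintf("MRResult [%s] %s\n", object@method, object@exposure))
  cat(sprintf("  nsnp = %d, b = %.6g (se %.6g), p = %.6g\n",
              object@nsnp, object@b, object@se, object@p))
  cat(sprintf("  OR = %.6g (95%% CI %.6g - %.6g)\n",
              object@or_, object@or_lci95, object@or_uci95))
  if (!is.na(object@egger_intercept))
    cat(sprintf("  Egger intercept = %.6g (se %.6g), p = %.6g\n",
                object@egger_intercept, object@egger_intercept_se,
                object@egger_intercept_p))
})
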