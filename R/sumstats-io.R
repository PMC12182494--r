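#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table with a header row into a
#' \linkS4class{SummaryStats} object. The default column names follow a
#' GWAS-SSF-like dialect (\code{snp_id}, \code{chrom}, \code{pos},
#' \code{effect_allele}, \code{other_allele}, \code{eaf}, \code{beta},
#' \code{se}, \code{pval}, \code{n}); \code{column_map} adapts other dialects
#' by mapping internal names to the names found in the file, e.g.
#' \code{c(snp_id = "SNP", pval = "P")}. \code{eaf} and \code{n} are optional.
#'
#' Validation is total: rows violating a record invariant (non-positive SE,
#' p-value outside (0,1], identical alleles, ...) are rejected with a per-row
#' report retrievable via [rejected()], never silently dropped. Allele strings
#' are upper-cased.
#'
#' @param path path to a tab-separated file with a header row.
#' @param column_map optional named character vector mapping internal column
#'   names to file column names.
#' @return A \linkS4class{SummaryStats}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(paste(
#'   c("snp_id\tchrom\tpos\teffect_allele\tother_allele\tbeta\tse\tpval",
#'     "rs1\t1\t1000\tA\tG\t0.1\t0.02\t1e-6"), collapse = "\n"), tsv)
#' ss <- readSumstats(tsv)
#' length(ss)
#' @export
readSumstats <- function(path, column_map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (!is.null(column_map)) {
    for (internal in names(column_map)) {
      ext <- column_map[[internal]]
      if (!ext %in% names(df))
        stop("mapped column '", ext, "' not found in ", path)
      names(df)[names(df) == ext] <- internal
    }
  }
  required <- setdiff(.SUMSTATS_COLS, c("eaf", "n"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in c("eaf", "n"))
    if (is.null(df[[col]])) df[[col]] <- rep(NA, nrow(df))
  parsed <- data.frame(
    snp_id = as.character(df$snp_id),
    chrom = as.character(df$chrom),
    pos = suppressWarnings(as.integer(df$pos)),
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele = toupper(as.character(df$other_allele)),
    eaf = suppressWarnings(as.numeric(df$eaf)),
    beta = suppressWarnings(as.numeric(df$beta)),
    se = suppressWarnings(as.numeric(df$se)),
    pval = suppressWarnings(as.numeric(df$pval)),
    n = suppressWarnings(as.numeric(df$n)),
    stringsAsFactors = FALSE)
  msgs <- if (nrow(parsed)) .recordProblems(parsed) else character()
  dup <- duplicated(parsed$snp_id) | duplicated(parsed$snp_id, fromLast = TRUE)
  first_of_dup <- !duplicated(parsed$snp_id)
  msgs[dup & !first_of_dup & !nzchar(msgs)] <- "duplicate snp_id"
  bad <- nzchar(msgs)
  report <- data.frame(row = which(bad), snp_id = parsed$snp_id[bad],
                       reason = msgs[bad], stringsAsFactors = FALSE)
  SummaryStats(parsed[!bad, , drop = FALSE], rejected = report)
}

#' Write a SummaryStats table
#'
#' Writes the tab-separated dialect read back by [readSumstats()]; numeric
#' fields round-trip to at least 6 significant digits.
#'
#' @param x a \linkS4class{SummaryStats}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSumstats <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an LD matrix
#'
#' Reads a tab-separated square matrix of squared correlations whose header
#' row and first column carry matching variant labels. Entries marginally
#' outside [0, 1] (within 1e-8) are clamped; asymmetries beyond 1e-8 are an
#' error.
#'
#' @param path path to the tab-separated matrix file.
#' @return An \linkS4class{LDMatrix}.
#' @export
readLDMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, quote = "", comment.char = "")
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("LD matrix in ", path, " is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("LD matrix row/column labels differ in ", path)
  LDMatrix(m)
}

#' Write an LD matrix
#' @param ld an \linkS4class{LDMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeLDMatrix <- function(ld, path) {
  df <- as.data.frame(ld@r2)
  utils::write.table(cbind(snp_id = rownames(ld@r2), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED-like file
#'
#' Accepts a tab-separated file with columns chrom, start, end, gene (no
#' header). BED's 0-based half-open coordinates are converted to the internal
#' 1-based inclusive convention (\code{start + 1}, \code{end}).
#'
#' @param path path to the BED-like file.
#' @return data.frame with columns \code{gene}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive).
#' @export
readGeneIntervals <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "gene"),
                          colClasses = c("character", "integer", "integer",
                                         "character"),
                          quote = "", comment.char = "#")
  out <- data.frame(gene = df$gene, chrom = df$chrom,
                    start = df$start + 1L, end = df$end,
                    stringsAsFactors = FALSE)
  bad <- out$start > out$end
  if (any(bad))
    stop("gene interval with start > end: ",
         paste(out$gene[bad], collapse = ", "))
  out
}

#' Write MR results and per-SNP tables
#'
#' Writes the combined estimator results with columns \code{exposure},
#' \code{method}, \code{nsnp}, \code{b}, \code{se}, \code{p}, \code{OR},
#' \code{OR_lci95}, \code{OR_uci95} (one row per \linkS4class{MRResult}) and,
#' when supplied, a per-SNP table with columns \code{SNP}, \code{chr},
#' \code{pos}, \code{effect_allele}, \code{b}, \code{se}, \code{p}. Numeric
#' values round-trip to at least 6 significant digits.
#'
#' @param results list of \linkS4class{MRResult} objects (may be empty).
#' @param per_snp optional data.frame of per-SNP estimates (Wald ratios,
#'   single-SNP or leave-one-out rows) with columns \code{snp_id},
#'   \code{chrom}, \code{pos}, \code{effect_allele}, \code{b}, \code{se},
#'   \code{p}.
#' @param dir output directory, created if needed.
#' @return named character vector of the files written, invisibly.
#' @export
writeResults <- function(results, per_snp = NULL, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  res_df <- if (length(results)) {
    do.call(rbind, lapply(results, function(r)
      as.data.frame(r)[, c("exposure", "method", "nsnp", "b", "se", "p",
                           "OR", "OR_lci95", "OR_uci95")]))
  } else {
    data.frame(exposure = character(), method = character(), nsnp = integer(),
               b = numeric(), se = numeric(), p = numeric(), OR = numeric(),
               OR_lci95 = numeric(), OR_uci95 = numeric())
  }
  files <- c(results = file.path(dir, "mr_results.tsv"))
  utils::write.table(res_df, files[["results"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(per_snp)) {
    snp_df <- data.frame(SNP = per_snp$snp_id, chr = per_snp$chrom,
                         pos = per_snp$pos,
                         effect_allele = per_snp$effect_allele,
                         b = per_snp$b, se = per_snp$se, p = per_snp$p,
                         stringsAsFactors = FALSE)
    files <- c(files, per_snp = file.path(dir, "mr_per_snp.tsv"))
    utils::write.table(snp_df, files[["per_snp"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(files)
}
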