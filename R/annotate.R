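#' Annotate SNPs with their nearest gene
#'
#' Maps each variant to the nearest gene interval on its chromosome within a
#' window, formatted as \code{"GENE(d)"} where \code{d} is the distance in
#' whole kilobases (floor; 0 when the variant lies inside the gene). Distance
#' is measured to the nearer interval endpoint. Ties break by smaller
#' distance, then alphabetical gene symbol; variants with no gene within the
#' window get an empty annotation. The result does not depend on the order of
#' the gene list.
#'
#' @param snps a \linkS4class{SummaryStats} or data.frame with columns
#'   \code{snp_id}, \code{chrom}, \code{pos} and optionally \code{pval}.
#' @param genes data.frame of gene intervals with columns \code{gene},
#'   \code{chrom}, \code{start}, \code{end} (1-based inclusive), e.g. from
#'   [readGeneIntervals()].
#' @param window_kb maximum annotation distance in kilobases (default 10).
#' @return data.frame with columns \code{snp_id}, \code{chrom}, \code{pos},
#'   \code{pval}, \code{annot}.
#' @export
annotateSnps <- function(snps, genes, window_kb = 10) {
  stopifnot(window_kb >= 0)
  df <- if (is(snps, "SummaryStats")) as.data.frame(snps) else
    as.data.frame(snps)
  if (is.null(df$pval)) df$pval <- NA_real_
  if (nrow(genes) && any(genes$start > genes$end))
    stop("gene interval with start > end")
  annot <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    g <- genes[genes$chrom == df$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    dist <- pmax(0, pmax(g$start - df$pos[i], df$pos[i] - g$end))
    ok <- dist <= window_kb * 1000
    if (!any(ok)) next
    g <- g[ok, , drop = FALSE]; dist <- dist[ok]
    pick <- order(dist, g$gene)[1]
    annot[i] <- sprintf("%s(%d)", g$gene[pick], floor(dist[pick] / 1000))
  }
  data.frame(snp_id = df$snp_id, chrom = df$chrom, pos = df$pos,
             pval = df$pval, annot = annot, stringsAsFactors = FALSE)
}
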