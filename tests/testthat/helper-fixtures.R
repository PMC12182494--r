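# Shared fixture builders; everything is generated in code.

makeSumstatsDF <- function(k = 5, seed = 1, chrom = NULL, pos = NULL,
                           pval = NULL) {
  set.seed(seed)
  data.frame(
    snp_id = sprintf("rs%04d", seq_len(k)),
    chrom = if (is.null(chrom)) as.character(rep_len(1:3, k)) else chrom,
    pos = if (is.null(pos)) seq_len(k) * 100000L else pos,
    effect_allele = rep_len(c("A", "C", "G", "T"), k),
    other_allele = rep_len(c("G", "T", "A", "C"), k),
    eaf = round(runif(k, 0.1, 0.45), 4),
    beta = round(rnorm(k, 0, 0.1), 6),
    se = round(runif(k, 0.01, 0.05), 6),
    pval = if (is.null(pval)) round(runif(k, 1e-8, 0.9), 10) else pval,
    n = 10000,
    stringsAsFactors = FALSE)
}

writeTempSumstats <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Wald-ratio table with given estimates/SEs.
ratioTable <- function(b, se, snp_id = sprintf("rs%03d", seq_along(b))) {
  data.frame(snp_id = snp_id, chrom = "1", pos = seq_along(b) * 1000L,
             effect_allele = "A", b = b, se = se,
             p = 2 * pnorm(-abs(b / se)), stringsAsFactors = FALSE)
}

# Exhaustive clumping oracle: enumerate every subset of the (<= 12) variants
# and keep those that are a fixed point of the greedy-by-p definition --
# a variant is retained iff no retained variant earlier in the (p, chrom,
# pos, id) order conflicts with it (same chromosome, within the window,
# r-squared at or above the cutoff). Returns the sorted ids of the unique
# fixed point.
oracleClump <- function(df, r2, clump_r2, clump_kb) {
  k <- nrow(df)
  stopifnot(k <= 12)
  chrom_num <- suppressWarnings(as.numeric(df$chrom))
  ord <- order(df$pval, ifelse(is.na(chrom_num), Inf, chrom_num),
               df$pos, df$snp_id)
  rank <- integer(k); rank[ord] <- seq_len(k)
  conflict <- outer(seq_len(k), seq_len(k), function(i, j)
    df$chrom[i] == df$chrom[j] &
      abs(df$pos[i] - df$pos[j]) <= clump_kb * 1000 &
      r2[cbind(i, j)] >= clump_r2)
  diag(conflict) <- FALSE
  solutions <- list()
  for (code in 0:(2^k - 1)) {
    inset <- as.logical(bitwAnd(bitwShiftR(code, 0:(k - 1)), 1L))
    ok <- TRUE
    for (s in seq_len(k)) {
      blocked <- any(inset & conflict[, s] & rank < rank[s])
      if (inset[s] == blocked) { ok <- FALSE; break }
    }
    if (ok) solutions[[length(solutions) + 1]] <- sort(df$snp_id[inset])
  }
  stopifnot(length(solutions) == 1)
  solutions[[1]]
}
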