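#' Run the full two-sample MR pipeline
#'
#' Orchestrates the analysis end to end: instrument selection (p-value filter
#' and LD clumping), harmonization, the requested MR estimators, Cochran's Q,
#' leave-one-out and single-SNP sensitivity tables, funnel-plot data, and
#' optional SNP-to-gene annotation. Per-stage counts are logged and every
#' table can be written to an output directory.
#'
#' All randomness (bootstrap SEs) flows from the single \code{seed} via
#' per-method derived streams, so runs are reproducible and adding a method
#' does not perturb another's draws.
#'
#' @param exposure,outcome \linkS4class{SummaryStats} objects or paths to
#'   tab-separated tables readable by [readSumstats()].
#' @param ld an \linkS4class{LDMatrix} or path readable by [readLDMatrix()].
#' @param genes optional gene-interval data.frame or BED-like path
#'   ([readGeneIntervals()]); when supplied, selected instruments are
#'   annotated.
#' @param p_threshold,clump_r2,clump_kb instrument-selection settings
#'   (defaults 1e-5, 0.001, 10000).
#' @param palindromic_eaf_window ambiguity window for palindromic variants
#'   (default 0.08).
#' @param methods estimators to run, subset of \code{c("ivw", "egger",
#'   "wmedian", "wmode")}.
#' @param ivw_mode \code{"random"} or \code{"fixed"}.
#' @param n_boot,seed bootstrap settings; \code{seed} is required when a
#'   bootstrap method is requested.
#' @param annotation_window_kb window for gene annotation (default 10).
#' @param exposure_name label used in result rows.
#' @param out_dir optional directory; when given, all tables plus a JSON run
#'   summary are written there.
#' @return list with elements \code{results} (list of
#'   \linkS4class{MRResult}), \code{ratios}, \code{loo},
#'   \code{heterogeneity}, \code{single_snp}, \code{funnel},
#'   \code{harmonized}, \code{annotation} (or \code{NULL}) and \code{counts}.
#' @export
runPipeline <- function(exposure, outcome, ld, genes = NULL,
                        p_threshold = 1e-5, clump_r2 = 0.001,
                        clump_kb = 10000, palindromic_eaf_window = 0.08,
                        methods = c("ivw", "egger", "wmedian", "wmode"),
                        ivw_mode = "random", n_boot = 5000, seed = NULL,
                        annotation_window_kb = 10,
                        exposure_name = "exposure", out_dir = NULL) {
  if (is.character(exposure)) exposure <- readSumstats(exposure)
  if (is.character(outcome)) outcome <- readSumstats(outcome)
  if (is.character(ld)) ld <- readLDMatrix(ld)
  if (is.character(genes)) genes <- readGeneIntervals(genes)
  if (any(c("wmedian", "wmode") %in% methods) && is.null(seed))
    stop("a seed is required when bootstrap methods are requested",
         call. = FALSE)

  counts <- list(exposure_in = length(exposure))
  filtered <- filterByPvalue(exposure, p_threshold)
  counts$after_p_filter <- length(filtered)
  clumped <- clumpVariants(filtered, ld, clump_r2 = clump_r2,
                           clump_kb = clump_kb)
  counts$after_clumping <- length(clumped)
  if (length(clumped) == 0L) {
    cond <- simpleError(sprintf(
      "no instruments: 0 of %d exposure variants survive p < %g and clumping",
      length(exposure), p_threshold))
    class(cond) <- c("mr_no_instruments", class(cond))
    stop(cond)
  }

  harmonized <- harmonize(clumped, outcome,
                          palindromic_eaf_window = palindromic_eaf_window)
  kept <- retained(harmonized)
  counts$harmonized <- nrow(kept)
  counts$dropped_in_harmonization <- length(harmonized) - nrow(kept)
  if (nrow(kept) == 0L) {
    cond <- simpleError("no instruments: all pairs dropped in harmonization")
    class(cond) <- c("mr_no_instruments", class(cond))
    stop(cond)
  }

  ratios <- waldRatios(harmonized)
  results <- tryCatch(
    mrEstimate(harmonized, methods = methods, ivw_mode = ivw_mode,
               n_boot = n_boot,
               seed = if (is.null(seed)) 0L else as.integer(seed),
               exposure = exposure_name),
    error = function(e) {
      cond <- simpleError(paste0("estimation failed: ", conditionMessage(e)))
      class(cond) <- c("mr_estimation_error", class(cond))
      stop(cond)
    })

  ivw_fixed <- mrIVW(ratios, mode = "fixed", exposure = exposure_name)
  het <- if (nrow(ratios) >= 2) cochranQ(ratios, estimate(ivw_fixed)) else NULL
  loo <- if (nrow(ratios) >= 3) leaveOneOut(ratios) else NULL
  funnel <- funnelData(ratios, estimate(ivw_fixed))
  annotation <- if (!is.null(genes))
    annotateSnps(clumped, genes, window_kb = annotation_window_kb) else NULL

  out <- list(results = results, ratios = ratios, loo = loo,
              heterogeneity = het, single_snp = singleSnp(ratios),
              funnel = funnel, harmonized = harmonized,
              annotation = annotation, counts = counts)

  if (!is.null(out_dir)) {
    writeResults(results, per_snp = singleSnp(ratios), dir = out_dir)
    tsv <- function(df, name) if (!is.null(df))
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    tsv(loo, "leave_one_out.tsv")
    tsv(het, "heterogeneity.tsv")
    tsv(funnel$data, "funnel.tsv")
    tsv(annotation, "annotation.tsv")
    dropped <- as.data.frame(harmonized)
    tsv(dropped[dropped$status == "dropped",
                c("snp_id", "status", "reason"), drop = FALSE],
        "harmonization_dropped.tsv")
    summary <- list(
      counts = counts,
      results = lapply(results, function(r)
        as.list(as.data.frame(r))))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
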