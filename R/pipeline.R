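## End-to-end classification: ChIP-positive selection, regulation evidence
## search, RCS gating, per-TF functional-fraction filter, result emission.

#' Pipeline configuration
#'
#' Bundles and validates the tunable thresholds of the classification
#' pipeline. Defaults are the published operating point: binding p <= 0.01
#' defines a ChIP positive, RCS > 1000 (against R = 10000 random networks)
#' defines confident regulation, and a TF is retained only if at least 25%
#' of its ChIP positives are classified functional.
#'
#' @param chipAlpha ChIP binding p-value threshold (inclusive), in (0, 1].
#' @param rcsThreshold RCS gate for confident regulation.
#' @param nRandomNetworks number of degree-preserving random networks R.
#' @param minFunctionalFraction per-TF retention threshold (inclusive).
#' @param unreachableCap cap value coding unreachable pairs in the null;
#'   `NULL` = node count of the TFKO network.
#' @param seed integer master seed.
#' @return a validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(chipAlpha = 0.01, rcsThreshold = 1000,
                           nRandomNetworks = 10000L,
                           minFunctionalFraction = 0.25,
                           unreachableCap = NULL, seed = 1L) {
  stopifnot(chipAlpha > 0, chipAlpha <= 1,
            minFunctionalFraction >= 0, minFunctionalFraction <= 1,
            nRandomNetworks >= 2L)
  structure(list(chipAlpha = chipAlpha, rcsThreshold = rcsThreshold,
                 nRandomNetworks = as.integer(nRandomNetworks),
                 minFunctionalFraction = minFunctionalFraction,
                 unreachableCap = unreachableCap, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Select start-up ChIP positives
#'
#' Keeps binding records with `p_binding <= chipAlpha` (boundary inclusive),
#' preserving input order.
#'
#' @param bindings data.frame from [readBindingTable()].
#' @param chipAlpha binding p-value threshold (default 0.01).
#' @return the filtered data.frame.
#' @export
selectChipPositives <- function(bindings, chipAlpha = 0.01) {
  bindings[bindings$p_binding <= chipAlpha, , drop = FALSE]
}

#' Per-TF functional-fraction filter
#'
#' Computes, per TF, the fraction of its scored ChIP positives classified
#' functional; TFs at or above `minFunctionalFraction` are retained. Low
#' fractions typically flag TFs whose TFKO coverage is too sparse for the
#' method rather than genuinely non-functional binding.
#'
#' @param results data.frame from [scorePairs()].
#' @param minFunctionalFraction retention threshold (inclusive, default
#'   0.25).
#' @return list with `tfSummary` (data.frame: `tf`, `n_binding`,
#'   `n_functional`, `fraction`, `retained`) and `results` (the functional
#'   pairs of retained TFs only).
#' @export
tfLevelFilter <- function(results, minFunctionalFraction = 0.25) {
  tfs <- unique(results$tf)
  nb <- vapply(tfs, function(x) sum(results$tf == x), integer(1))
  nf <- vapply(tfs, function(x) sum(results$tf == x & results$functional),
               integer(1))
  frac <- ifelse(nb > 0L, nf / nb, 0)
  summ <- data.frame(tf = tfs, n_binding = nb, n_functional = nf,
                     fraction = frac,
                     retained = frac >= minFunctionalFraction,
                     row.names = NULL)
  keep <- results$functional &
    results$tf %in% summ$tf[summ$retained]
  list(tfSummary = summ, results = results[keep, , drop = FALSE])
}

#' Run the full functional-binding classification pipeline
#'
#' Composition of [selectChipPositives()] -> [buildNetwork()] ->
#' [scorePairs()] -> [tfLevelFilter()], with a run report counting pairs at
#' every stage.
#'
#' @param bindingPath path to the ChIP binding TSV ([readBindingTable()]).
#' @param tfkoPath path to the TFKO regulation edge TSV ([readEdgeList()]).
#' @param config a [pipelineConfig()].
#' @param outDir optional directory; when given, `functional_pairs.tsv`
#'   (functional pairs of retained TFs), `all_scored_pairs.tsv`,
#'   `tf_summary.tsv` and `report.json`-style `report.txt` are written.
#' @return list with `results` (all scored ChIP positives), `functional`
#'   (functional pairs of retained TFs), `tfSummary`, and `report` (stage
#'   counts, TFs without TFKO data, config echo).
#' @export
runPipeline <- function(bindingPath, tfkoPath, config = pipelineConfig(),
                        outDir = NULL) {
  bindings <- readBindingTable(bindingPath)
  tfko <- readEdgeList(tfkoPath)
  positives <- selectChipPositives(bindings, config$chipAlpha)
  net <- buildNetwork(tfko)
  tfsNoTfko <- setdiff(unique(positives$tf), net@nodes)
  scored <- scorePairs(net, positives, R = config$nRandomNetworks,
                       seed = config$seed,
                       rcsThreshold = config$rcsThreshold,
                       cap = config$unreachableCap)
  filt <- tfLevelFilter(scored, config$minFunctionalFraction)
  report <- list(
    n_binding_records = nrow(bindings),
    n_chip_positives = nrow(positives),
    n_tfko_edges = nrow(tfko),
    n_case_direct = sum(scored$evidence_case == "direct"),
    n_case_hypostatic = sum(scored$evidence_case == "hypostatic"),
    n_no_evidence = sum(scored$evidence_case == "none"),
    n_rcs_passing = sum(scored$functional),
    n_tfs = length(unique(positives$tf)),
    n_tfs_no_tfko_data = length(tfsNoTfko),
    tfs_no_tfko_data = tfsNoTfko,
    n_tfs_retained = sum(filt$tfSummary$retained),
    n_functional_retained = nrow(filt$results),
    config = unclass(config))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeFunctionalPairs(filt$results,
                         file.path(outDir, "functional_pairs.tsv"))
    writeFunctionalPairs(scored, file.path(outDir, "all_scored_pairs.tsv"))
    .writeTsv(filt$tfSummary, file.path(outDir, "tf_summary.tsv"))
    scal <- unlist(report[setdiff(names(report),
                                  c("tfs_no_tfko_data", "config"))])
    writeLines(paste(names(scal), scal, sep = "\t"),
               file.path(outDir, "report.txt"))
  }
  list(results = scored, functional = filt$results,
       tfSummary = filt$tfSummary, report = report)
}
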