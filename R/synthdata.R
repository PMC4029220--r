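## Synthetic scenario generator: binding tables, TFKO networks with planted
## cascades and dropout, complex-structured PPI, module-correlated
## expression, annotations, and ground-truth labels.

#' Parameters of a synthetic scenario
#'
#' Defaults describe a strong-signal regulatory system at desk scale: 50
#' TFs binding 20 of 500 genes each, 60% of binding truly functional, half
#' of the true regulation edges missing from the TFKO table (emulating the
#' low ChIP/TFKO overlap) but compensated by a planted epistatic cascade of
#' 2-5 steps, 5% decoy TFKO edges on non-functional positives, and 20
#' regulation-without-binding background targets per TF (TFKO tables are
#' substantially larger than the ChIP positives they overlap). Expression
#' comes as 40 conditions of 8 timepoints with within-module correlation
#' 0.7 among each TF's functional targets; PPI places each TF's functional
#' targets into complexes (cliques) of 6.
#'
#' @param n_tfs,n_genes,targets_per_tf scenario sizes.
#' @param functional_fraction fraction of each TF's binding targets that
#'   are truly functional (exact count, rounded).
#' @param tfko_dropout probability that a functional pair's direct TFKO
#'   edge is missing and replaced by a planted cascade (drives Case II).
#' @param cascade_length_range integer range of planted cascade lengths.
#' @param spurious_edge_rate probability that a non-functional binding pair
#'   receives a decoy direct TFKO edge.
#' @param background_targets_per_tf TFKO-only regulation targets per TF.
#' @param chip_alpha ChIP positive threshold the binding p-values are
#'   generated around: functional pairs draw p from a low-concentrated
#'   distribution on [0, chip_alpha], non-functional pairs from U(0, 1).
#' @param n_conditions,timepoints expression panel dimensions.
#' @param module_correlation within-module expression correlation (rho).
#' @param ppi_complex_size clique size for planted complexes.
#' @param ppi_background_edges random background PPI edges.
#' @param background_terms random annotation terms per namespace.
#' @param seed integer master seed; all randomness derives from it.
#' @return a validated list of class `ScenarioParams`.
#' @export
scenarioParams <- function(n_tfs = 50L, n_genes = 500L,
                           targets_per_tf = 20L,
                           functional_fraction = 0.6, tfko_dropout = 0.5,
                           cascade_length_range = c(2L, 5L),
                           spurious_edge_rate = 0.05,
                           background_targets_per_tf = 20L,
                           chip_alpha = 0.01, n_conditions = 40L,
                           timepoints = 8L, module_correlation = 0.7,
                           ppi_complex_size = 6L,
                           ppi_background_edges = n_genes,
                           background_terms = 10L, seed = 42L) {
  p <- list(n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
            targets_per_tf = as.integer(targets_per_tf),
            functional_fraction = functional_fraction,
            tfko_dropout = tfko_dropout,
            cascade_length_range = as.integer(cascade_length_range),
            spurious_edge_rate = spurious_edge_rate,
            background_targets_per_tf = as.integer(background_targets_per_tf),
            chip_alpha = chip_alpha, n_conditions = as.integer(n_conditions),
            timepoints = as.integer(timepoints),
            module_correlation = module_correlation,
            ppi_complex_size = as.integer(ppi_complex_size),
            ppi_background_edges = as.integer(ppi_background_edges),
            background_terms = as.integer(background_terms),
            seed = as.integer(seed))
  probs <- c(p$functional_fraction, p$tfko_dropout, p$spurious_edge_rate,
             p$chip_alpha, p$module_correlation)
  stopifnot(all(probs >= 0 & probs <= 1), p$n_tfs >= 1, p$n_genes >= 1,
            p$targets_per_tf >= 1, p$timepoints >= 3,
            length(p$cascade_length_range) == 2L,
            p$cascade_length_range[1L] >= 2L,
            diff(p$cascade_length_range) >= 0L)
  if (p$targets_per_tf > p$n_genes)
    stop("targets_per_tf cannot exceed n_genes", call. = FALSE)
  structure(p, class = "ScenarioParams")
}

#' Named scenario presets
#'
#' `"strong"` is [scenarioParams()] as documented. `"overlap-only"` plants
#' no cascades and no decoys (dropout 0, spurious rate 0), so the
#' recoverable functional set is exactly the intersection of ChIP positives
#' and TFKO edges. `"weak"` halves the functional fraction and raises the
#' decoy rate, a harder regime for power checks.
#'
#' @param preset one of `"strong"`, `"overlap-only"`, `"weak"`.
#' @param seed integer master seed.
#' @return a `ScenarioParams` list.
#' @export
scenarioPreset <- function(preset = c("strong", "overlap-only", "weak"),
                           seed = 42L) {
  preset <- match.arg(preset)
  switch(preset,
    "strong" = scenarioParams(seed = seed),
    "overlap-only" = scenarioParams(tfko_dropout = 0,
                                    spurious_edge_rate = 0, seed = seed),
    "weak" = scenarioParams(functional_fraction = 0.3,
                            spurious_edge_rate = 0.15, seed = seed))
}

#' Generate a complete synthetic scenario on disk
#'
#' Emits `binding.tsv`, `tfko.tsv`, `ppi.tsv`, `annotations.tsv`,
#' `truth.tsv` and `expr/cond_XX.tsv` under `dir`, all parseable by the
#' package readers, plus the planted ground truth. Functional pairs either
#' keep their direct TFKO edge or (with probability `tfko_dropout`) have it
#' replaced by a planted epistatic cascade through fresh intermediate TFs,
#' every edge of which is present in the emitted TFKO table. Non-functional
#' ChIP positives have neither, except a `spurious_edge_rate` of decoy
#' direct edges. Each TF's functional targets form an expression module and
#' PPI cliques; one planted annotation term per TF covers its functional
#' targets.
#'
#' @param params a [scenarioParams()] list.
#' @param dir output directory (created if needed).
#' @return a [ScenarioTruth-class] object.
#' @export
generateScenario <- function(params = scenarioParams(), dir = tempfile()) {
  stopifnot(inherits(params, "ScenarioParams"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "expr"), showWarnings = FALSE)
  set.seed(params$seed)

  tfs <- sprintf("TF%03d", seq_len(params$n_tfs))
  genes <- sprintf("G%04d", seq_len(params$n_genes))
  nFun <- round(params$functional_fraction * params$targets_per_tf)

  truth <- list(); tfkoFrom <- character(0); tfkoTo <- character(0)
  cascadeOf <- character(0)
  moduleOf <- rep(NA_character_, params$n_genes)  # first-come module owner
  names(moduleOf) <- genes

  for (tf in tfs) {
    targets <- sample(genes, params$targets_per_tf)
    functional <- c(rep(TRUE, nFun),
                    rep(FALSE, params$targets_per_tf - nFun))
    pBind <- ifelse(functional,
                    params$chip_alpha * stats::runif(length(targets))^2,
                    stats::runif(length(targets)))
    evid <- rep("none", length(targets))
    casc <- rep(NA_character_, length(targets))
    for (i in seq_along(targets)) {
      g <- targets[i]
      if (functional[i]) {
        if (is.na(moduleOf[g])) moduleOf[g] <- tf
        if (stats::runif(1) < params$tfko_dropout) {
          len <- sample(seq(params$cascade_length_range[1L],
                            params$cascade_length_range[2L]), 1L)
          mids <- sprintf("X%s_%s_%d", tf, g, seq_len(len - 1L))
          chain <- c(tf, mids, g)
          tfkoFrom <- c(tfkoFrom, chain[-length(chain)])
          tfkoTo <- c(tfkoTo, chain[-1L])
          evid[i] <- "cascade"
          casc[i] <- paste(chain, collapse = "->")
        } else {
          tfkoFrom <- c(tfkoFrom, tf); tfkoTo <- c(tfkoTo, g)
          evid[i] <- "direct"
          casc[i] <- paste(tf, g, sep = "->")
        }
      } else if (stats::runif(1) < params$spurious_edge_rate) {
        tfkoFrom <- c(tfkoFrom, tf); tfkoTo <- c(tfkoTo, g)
        evid[i] <- "decoy"
      }
    }
    ## regulation-without-binding background edges
    nbg <- min(params$background_targets_per_tf,
               params$n_genes - params$targets_per_tf)
    if (nbg > 0L) {
      bg <- sample(setdiff(genes, targets), nbg)
      tfkoFrom <- c(tfkoFrom, rep(tf, nbg)); tfkoTo <- c(tfkoTo, bg)
    }
    truth[[tf]] <- data.frame(tf = tf, gene = targets, p_binding = pBind,
                              functional = functional, evidence = evid,
                              cascade = casc)
  }
  truth <- do.call(rbind, c(truth, make.row.names = FALSE))

  ## expression: module-structured; module profile shared by the functional
  ## targets of a gene's first TF, plus independent noise
  rho <- params$module_correlation
  condNames <- sprintf("cond_%02d", seq_len(params$n_conditions))
  for (cn in condNames) {
    moduleProfile <- matrix(stats::rnorm(params$n_tfs * params$timepoints),
                            nrow = params$n_tfs,
                            dimnames = list(tfs, NULL))
    noise <- matrix(stats::rnorm(params$n_genes * params$timepoints),
                    nrow = params$n_genes, dimnames = list(genes, NULL))
    expr <- noise
    inMod <- !is.na(moduleOf)
    expr[inMod, ] <- sqrt(rho) * moduleProfile[moduleOf[inMod], ,
                                               drop = FALSE] +
      sqrt(1 - rho) * noise[inMod, , drop = FALSE]
    colnames(expr) <- sprintf("t%d", seq_len(params$timepoints))
    writeExpressionMatrix(expr, file.path(dir, "expr",
                                          paste0(cn, ".tsv")))
  }

  ## PPI: cliques over each TF's functional targets + random background
  ppiA <- character(0); ppiB <- character(0)
  for (tf in tfs) {
    ft <- truth$gene[truth$tf == tf & truth$functional]
    if (length(ft) < 2L) next
    groups <- split(ft, ceiling(seq_along(ft) / params$ppi_complex_size))
    for (grp in groups) {
      if (length(grp) < 2L) next
      cmb <- utils::combn(grp, 2L)
      ppiA <- c(ppiA, cmb[1L, ]); ppiB <- c(ppiB, cmb[2L, ])
    }
  }
  if (params$ppi_background_edges > 0L) {
    ppiA <- c(ppiA, sample(genes, params$ppi_background_edges,
                           replace = TRUE))
    ppiB <- c(ppiB, sample(genes, params$ppi_background_edges,
                           replace = TRUE))
  }
  keep <- ppiA != ppiB
  ppi <- data.frame(from = ppiA[keep], to = ppiB[keep])
  ppi <- ppi[!duplicated(paste(pmin(ppi$from, ppi$to),
                               pmax(ppi$from, ppi$to))), ]

  ## annotations: one planted term per TF over its functional targets,
  ## plus random background terms in every namespace
  annGene <- character(0); annTerm <- character(0); annNs <- character(0)
  for (tf in tfs) {
    ft <- truth$gene[truth$tf == tf & truth$functional]
    if (length(ft) == 0L) next
    annGene <- c(annGene, ft)
    annTerm <- c(annTerm, rep(paste0("TERM_", tf), length(ft)))
    annNs <- c(annNs, rep("process", length(ft)))
  }
  for (ns in c("process", "function", "component")) {
    for (b in seq_len(params$background_terms)) {
      sz <- sample(5:30, 1L)
      annGene <- c(annGene, sample(genes, sz))
      annTerm <- c(annTerm, rep(sprintf("BG_%s_%02d", ns, b), sz))
      annNs <- c(annNs, rep(ns, sz))
    }
  }
  ann <- data.frame(gene = annGene, term = annTerm, namespace = annNs)
  ann <- ann[!duplicated(ann), ]

  files <- c(binding = file.path(dir, "binding.tsv"),
             tfko = file.path(dir, "tfko.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeBindingTable(truth, files["binding"])
  tfko <- data.frame(from = tfkoFrom, to = tfkoTo)
  writeEdgeList(tfko[!duplicated(tfko), ], files["tfko"])
  writeEdgeList(ppi, files["ppi"])
  writeAnnotationTable(ann, files["annotations"])
  .writeTsv(truth, files["truth"])
  files <- c(files, stats::setNames(
    file.path(dir, "expr", paste0(condNames, ".tsv")), condNames))

  new("ScenarioTruth", truth = truth, params = unclass(params),
      files = files)
}

#' @rdname ScenarioTruth-class
#' @export
setMethod("truthTable", "ScenarioTruth", function(object) object@truth)

#' @rdname ScenarioTruth-class
#' @export
setMethod("scenarioFiles", "ScenarioTruth", function(object) object@files)

setMethod("show", "ScenarioTruth", function(object) {
  cat("ScenarioTruth:", nrow(object@truth), "binding records,",
      sum(object@truth$functional), "functional;",
      sum(object@truth$evidence == "cascade"), "planted cascade(s)\n")
  invisible(NULL)
})

#' Generate a negative control set of TF-gene pairs
#'
#' Uniformly samples `n` TF-gene pairs that belong neither to the positive
#' control set nor to the evidence list (pairs with any curated regulation
#' evidence are excluded to keep the negatives stringent). No duplicates.
#'
#' @param positives data.frame `tf`, `gene`: the positive control pairs.
#' @param evidence data.frame `from`, `to`: pairs with regulation evidence.
#' @param n number of negative pairs to draw.
#' @param seed integer seed.
#' @param tfs,genes the pair universe; defaults to the TFs and genes
#'   occurring in `positives` and `evidence`.
#' @return data.frame `tf`, `gene` of `n` sampled pairs.
#' @export
generateNegativeControls <- function(positives, evidence, n, seed = 1L,
                                     tfs = NULL, genes = NULL) {
  if (is.null(tfs))
    tfs <- sort(unique(c(positives$tf, evidence$from)))
  if (is.null(genes))
    genes <- sort(unique(c(positives$gene, evidence$to)))
  excl <- unique(c(paste(positives$tf, positives$gene, sep = "\r"),
                   paste(evidence$from, evidence$to, sep = "\r")))
  all <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  all <- all[all$tf != all$gene, , drop = FALSE]
  avail <- all[!(paste(all$tf, all$gene, sep = "\r") %in% excl), ,
               drop = FALSE]
  if (n > nrow(avail))
    stop("requested ", n, " negatives but only ", nrow(avail),
         " non-excluded pairs exist", call. = FALSE)
  set.seed(seed)
  out <- avail[sample.int(nrow(avail), n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
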