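## Validation battery: ROC/AUC on a labelled control set, Fisher-based
## functional enrichment, protein-protein interaction prevalence,
## expression coherence, and the random-assignment benchmark.

#' ROC curve and AUC over RCS thresholds
#'
#' Sweeps the score threshold over all distinct values and records
#' (false positive rate, sensitivity) points from (0,0) to (1,1). The AUC
#' equals the Mann-Whitney concordance probability, with ties credited 1/2.
#'
#' @param scores numeric scores (higher = more confidently functional).
#' @param labels logical (or 0/1) truth labels; both classes must occur.
#' @return list of class `rocCurve` with `points` (data.frame `fpr`, `tpr`)
#'   and `auc`.
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, TRUE, FALSE, TRUE))$auc  # 2/3
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes required to build a ROC curve", call. = FALSE)
  # Mann-Whitney AUC via midranks (ties get half credit)
  r <- rank(scores)
  auc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o]); fp <- cumsum(!labels[o])
  # one point per distinct threshold (last index of each tied block)
  keep <- c(diff(scores[o]) != 0, TRUE)
  pts <- data.frame(fpr = c(0, fp[keep] / nNeg), tpr = c(0, tp[keep] / nPos))
  structure(list(points = pts, auc = auc), class = "rocCurve")
}

#' @export
print.rocCurve <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "points, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

# log10 one-tailed hypergeometric over-representation p-value:
# P(X >= k) with K annotated among N, drawing n.
.log10PHyperUpper <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Functional (GO-style) enrichment of a target gene set
#'
#' One-tailed over-representation test of the target set against every
#' annotated term in every namespace, Benjamini-Hochberg corrected across
#' all terms tested for this set. A TF's functional target set is called
#' functionally enriched if at least one term in any namespace is
#' significant at `alpha`.
#'
#' @param targetGenes character vector of target gene ids (must be a subset
#'   of `background`).
#' @param annotations data.frame `gene`, `term`, `namespace` from
#'   [readAnnotationTable()].
#' @param background character vector: the gene universe.
#' @param alpha FDR threshold (default 0.05).
#' @return list with `terms` (data.frame: `term`, `namespace`, `k`, `n`,
#'   `K`, `N`, `log10_p`, `log10_q`, `significant`) and `enriched`
#'   (logical scalar).
#' @export
fisherEnrichment <- function(targetGenes, annotations, background,
                             alpha = 0.05) {
  targetGenes <- unique(targetGenes)
  background <- unique(background)
  if (!all(targetGenes %in% background))
    stop("target genes must be a subset of the background", call. = FALSE)
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  N <- length(background); n <- length(targetGenes)
  key <- paste(ann$term, ann$namespace, sep = "\r")
  terms <- !duplicated(key)
  termId <- ann$term[terms]; termNs <- ann$namespace[terms]
  K <- as.integer(table(factor(key, levels = key[terms])))
  inTarget <- ann$gene %in% targetGenes
  k <- as.integer(table(factor(key[inTarget], levels = key[terms])))
  lp <- .log10PHyperUpper(k, K, N, n)
  lq <- fdrCorrectLog10(lp)
  sig <- lq <= log10(alpha)
  res <- data.frame(term = termId, namespace = termNs, k = k, n = n, K = K,
                    N = N, log10_p = lp, log10_q = lq, significant = sig)
  list(terms = res, enriched = any(sig))
}

#' Prevalence of protein-protein interaction among target genes
#'
#' For each target set: core genes are targets with at least one physical
#' interaction to another target; neighbour genes are genome genes
#' interacting with a core gene; the protein complex is their union. The
#' one-tailed Fisher test asks whether the proportion of core genes in the
#' target set exceeds the proportion of the complex in the whole genome
#' (2x2 table: rows target set / rest of genome, columns in complex / not).
#' BH-FDR is applied across the supplied sets.
#'
#' @param targetSets named list of character vectors (one per TF), or a
#'   single character vector.
#' @param ppiEdges data.frame `from`, `to` of undirected physical
#'   interactions.
#' @param genome character vector: all genes (target sets must be subsets).
#' @param alpha FDR threshold (default 0.05).
#' @return list with `summary` (data.frame: `tf`, `n_target`, `n_core`,
#'   `n_neighbour`, `n_complex`, `log10_p`, `log10_q`, `prevalent`) and
#'   `complexes` (named list with `core`, `neighbours` per set).
#' @export
ppiPrevalence <- function(targetSets, ppiEdges, genome, alpha = 0.05) {
  if (!is.list(targetSets)) targetSets <- list(set = targetSets)
  if (is.null(names(targetSets)))
    names(targetSets) <- paste0("set", seq_along(targetSets))
  genome <- unique(genome)
  a <- as.character(ppiEdges$from); b <- as.character(ppiEdges$to)
  N <- length(genome)
  complexes <- list()
  rows <- lapply(names(targetSets), function(tfId) {
    tg <- unique(targetSets[[tfId]])
    if (!all(tg %in% genome))
      stop("target set '", tfId, "' not a subset of the genome",
           call. = FALSE)
    within <- (a %in% tg) & (b %in% tg) & (a != b)
    core <- unique(c(a[within], b[within]))
    touch <- (a %in% core) | (b %in% core)
    nb <- setdiff(intersect(unique(c(a[touch], b[touch])), genome), core)
    complexes[[tfId]] <<- list(core = core, neighbours = nb)
    cmplx <- union(core, nb)
    lp <- if (length(core) == 0L) 0
          else .log10PHyperUpper(length(core), length(cmplx), N, length(tg))
    data.frame(tf = tfId, n_target = length(tg), n_core = length(core),
               n_neighbour = length(nb), n_complex = length(cmplx),
               log10_p = lp)
  })
  summ <- do.call(rbind, rows)
  summ$log10_q <- fdrCorrectLog10(summ$log10_p)
  summ$prevalent <- summ$log10_q <= log10(alpha) & summ$n_core > 0L
  list(summary = summ, complexes = complexes)
}

# Squared Pearson correlations over all unordered gene pairs within a set,
# restricted to genes present in the expression matrix; zero-variance
# vectors are dropped (r undefined). Returns NULL if < 2 usable genes.
.pairwiseR2 <- function(genes, mat) {
  g <- intersect(unique(genes), rownames(mat))
  if (length(g) < 2L) return(NULL)
  x <- mat[g, , drop = FALSE]
  v <- apply(x, 1L, stats::var)
  x <- x[v > 0, , drop = FALSE]
  if (nrow(x) < 2L) return(NULL)
  cm <- stats::cor(t(x))
  cm[upper.tri(cm)]^2
}

#' Expression coherence comparison between two methods' target sets
#'
#' For every condition and every TF common to both methods, the squared
#' Pearson correlations over all within-set gene pairs are compared by
#' one-tailed rank-sum tests under both hypotheses (A more coherent than B,
#' and B more coherent than A), BH-corrected across TFs within each
#' condition and hypothesis. A condition is "won" by the side with strictly
#' more winning TFs; ties give winner `"none"` (wins need not sum to the TF
#' count: many TFs are statistically invariant).
#'
#' @param targetsA,targetsB named lists (per TF) of target gene vectors.
#' @param conditions named list of expression matrices
#'   ([readExpressionMatrix()]).
#' @param alpha FDR threshold (default 0.05).
#' @return list with `summary` (per condition: `condition`, `n_tfs`,
#'   `wins_A`, `wins_B`, `winner`) and `detail` (per condition x TF:
#'   rank-sum log10 q-values and win flags). TFs with fewer than 2 usable
#'   genes in a condition are skipped (reported in `detail` as `NA`).
#' @export
expressionCoherenceCompare <- function(targetsA, targetsB, conditions,
                                       alpha = 0.05) {
  common <- intersect(names(targetsA), names(targetsB))
  if (is.null(names(conditions)))
    names(conditions) <- paste0("cond", seq_along(conditions))
  detail <- list(); summary <- list()
  for (cid in names(conditions)) {
    mat <- conditions[[cid]]
    pa <- rep(NA_real_, length(common)); pb <- rep(NA_real_, length(common))
    for (i in seq_along(common)) {
      r2a <- .pairwiseR2(targetsA[[common[i]]], mat)
      r2b <- .pairwiseR2(targetsB[[common[i]]], mat)
      if (is.null(r2a) || is.null(r2b)) next
      pa[i] <- suppressWarnings(stats::wilcox.test(
        r2a, r2b, alternative = "greater")$p.value)
      pb[i] <- suppressWarnings(stats::wilcox.test(
        r2a, r2b, alternative = "less")$p.value)
    }
    ok <- !is.na(pa)
    qa <- rep(NA_real_, length(common)); qb <- qa
    if (any(ok)) {
      qa[ok] <- fdrCorrectLog10(log10(pa[ok]))
      qb[ok] <- fdrCorrectLog10(log10(pb[ok]))
    }
    winA <- !is.na(qa) & qa <= log10(alpha)
    winB <- !is.na(qb) & qb <= log10(alpha)
    detail[[cid]] <- data.frame(condition = cid, tf = common,
                                log10_q_A_higher = qa,
                                log10_q_B_higher = qb,
                                win_A = winA, win_B = winB)
    summary[[cid]] <- data.frame(
      condition = cid, n_tfs = sum(ok),
      wins_A = sum(winA), wins_B = sum(winB),
      winner = if (sum(winA) > sum(winB)) "A"
               else if (sum(winB) > sum(winA)) "B" else "none")
  }
  list(summary = do.call(rbind, c(summary, make.row.names = FALSE)),
       detail = do.call(rbind, c(detail, make.row.names = FALSE)))
}

# Random functional assignment: per TF remove floor(removalFraction * n)
# binding targets uniformly at random; TFs where the floor is 0 are left
# untouched.
.randomAssignment <- function(bindingSets, removalFraction) {
  lapply(bindingSets, function(tg) {
    nRemove <- floor(removalFraction * length(tg))
    if (nRemove < 1L) return(tg)
    tg[-sample.int(length(tg), nRemove)]
  })
}

#' Benchmark observed validation results against random assignments
#'
#' Builds `reps` random functional-assignment lists by removing
#' `removalFraction` of each TF's original binding targets uniformly at
#' random, scores the chosen validation metric on each, and tests whether
#' the observed result beats the random ensemble. For the count metrics
#' (`enrichment`: number of TFs with a functionally enriched target set;
#' `ppi`: number of TFs with PPI prevalence) a left-tailed one-sample t-test
#' of the random sample against the observed count is reported,
#' `t = (mean_random - observed) / (sd_random / sqrt(reps))`. For
#' `coherence`, each condition contributes `reps` paired win-counts
#' (observed-vs-random rank-sum wins per side) and a right-tailed paired
#' t-test; a condition with p < `alpha` is counted as better-than-random.
#'
#' @param functionalSets named list (per TF) of the observed functional
#'   target genes.
#' @param bindingSets named list (per TF) of all original binding targets.
#' @param metric one of `"enrichment"`, `"ppi"`, `"coherence"`.
#' @param annotations,background for `metric = "enrichment"`.
#' @param ppiEdges,genome for `metric = "ppi"`.
#' @param conditions for `metric = "coherence"`.
#' @param removalFraction fraction of binding targets removed per TF in
#'   each random list (default 0.18, the published non-functional rate).
#' @param reps number of random lists (default 50).
#' @param seed integer seed.
#' @param alpha significance threshold (default 0.05).
#' @return for count metrics: list with `metric`, `observed`, `randomMean`,
#'   `randomSd`, `reps`, `t`, `log10_p`, `significant`, `randomCounts`.
#'   For coherence: list with `metric`, `perCondition` (data.frame:
#'   `condition`, `mean_wins_observed`, `mean_wins_random`, `t`, `log10_p`,
#'   `better_than_random`), and `n_better`.
#' @export
randomAssignmentBenchmark <- function(functionalSets, bindingSets,
                                      metric = c("enrichment", "ppi",
                                                 "coherence"),
                                      annotations = NULL, background = NULL,
                                      ppiEdges = NULL, genome = NULL,
                                      conditions = NULL,
                                      removalFraction = 0.18, reps = 50L,
                                      seed = 1L, alpha = 0.05) {
  metric <- match.arg(metric)
  if (reps < 2L) stop("reps must be >= 2", call. = FALSE)
  set.seed(seed)
  randomLists <- lapply(seq_len(reps), function(r)
    .randomAssignment(bindingSets, removalFraction))
  countMetric <- switch(metric,
    enrichment = function(sets) sum(vapply(sets, function(tg)
      fisherEnrichment(intersect(tg, background), annotations,
                       background, alpha)$enriched, logical(1))),
    ppi = function(sets)
      sum(ppiPrevalence(sets, ppiEdges, genome, alpha)$summary$prevalent),
    NULL)
  if (metric %in% c("enrichment", "ppi")) {
    observed <- countMetric(functionalSets)
    randomCounts <- vapply(randomLists, countMetric, numeric(1))
    m <- mean(randomCounts); s <- stats::sd(randomCounts)
    t <- tStatistic(observed, m, s, reps)
    lp <- stats::pt(t, df = reps - 1L, lower.tail = TRUE, log.p = TRUE) /
      log(10)
    return(list(metric = metric, observed = observed, randomMean = m,
                randomSd = s, reps = reps, t = t, log10_p = lp,
                significant = lp <= log10(alpha),
                randomCounts = randomCounts))
  }
  ## coherence: per condition, paired wins over the random lists
  perCond <- lapply(names(conditions), function(cid) {
    winsObs <- numeric(reps); winsRnd <- numeric(reps)
    for (r in seq_len(reps)) {
      cmp <- expressionCoherenceCompare(functionalSets, randomLists[[r]],
                                        conditions[cid], alpha)
      winsObs[r] <- cmp$summary$wins_A
      winsRnd[r] <- cmp$summary$wins_B
    }
    d <- winsObs - winsRnd
    if (stats::sd(d) == 0) {
      t <- if (mean(d) > 0) Inf else if (mean(d) < 0) -Inf else 0
      lp <- if (mean(d) > 0) -Inf else if (mean(d) < 0) 0 else log10(0.5)
    } else {
      tt <- stats::t.test(winsObs, winsRnd, paired = TRUE,
                          alternative = "greater")
      t <- unname(tt$statistic)
      lp <- stats::pt(t, df = reps - 1L, lower.tail = FALSE, log.p = TRUE) /
        log(10)
    }
    data.frame(condition = cid, mean_wins_observed = mean(winsObs),
               mean_wins_random = mean(winsRnd), t = t, log10_p = lp,
               better_than_random = lp < log10(alpha))
  })
  perCond <- do.call(rbind, perCond)
  list(metric = "coherence", perCondition = perCond,
       n_better = sum(perCond$better_than_random))
}
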