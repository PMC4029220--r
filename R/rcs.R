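## Regulatory confidence scores: one-sample t-test of the observed shortest
## regulation path length against the random-network null, one-tailed
## (shorter than random), FDR-corrected in log space, RCS = -log10(p).

#' One-sample t-statistic of an observed value against a null sample
#'
#' `t = (nullMean - observed) / (nullSd / sqrt(n))`, oriented so that an
#' observed path length shorter than the random-network average gives a
#' positive t. The same statistic (with sides swapped by its sign) is the
#' core of the random-assignment benchmark, where `observed` is the real
#' validation count and the null sample is the 50 random-assignment runs.
#'
#' @param observed observed value (path length, or validation count).
#' @param nullMean,nullSd,n mean, sample standard deviation and size of the
#'   null sample.
#' @return the t statistic (vectorized); `Inf`/`-Inf`/`NaN` when
#'   `nullSd == 0` (callers handle the degenerate cases explicitly).
#' @examples
#' tStatistic(2, mean(c(4, 4, 5, 3, 4)), sd(c(4, 4, 5, 3, 4)), 5) # 6.3246
#' tStatistic(62, 44.8, 3.53, 50)  # -34.45, a benchmark-style use
#' @export
tStatistic <- function(observed, nullMean, nullSd, n) {
  (nullMean - observed) / (nullSd / sqrt(n))
}

#' Log10 upper-tail probability of Student's t
#'
#' Returns `log10 P(T_df >= t)`, computed in log space so that deep tails
#' (|t| up to 1e4) give finite values instead of underflowing to -Inf.
#'
#' @param t t statistic(s).
#' @param df degrees of freedom (>= 1).
#' @return log10 of the one-tailed p-value (<= 0), vectorized.
#' @examples
#' log10POneTailed(0, 10)        # log10(0.5)
#' log10POneTailed(800, 9999)    # about -9066, finite
#' @export
log10POneTailed <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  stats::pt(t, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Benjamini-Hochberg adjustment of log10 p-values, in log space
#'
#' Step-up FDR adjustment computed entirely on log10 p-values, so that
#' p-values far below double-precision underflow (log10 p < -300) are
#' corrected without loss. Output order matches input order; each adjusted
#' value is >= its input and <= 0.
#'
#' @param log10p numeric vector of log10 p-values (all <= 0).
#' @return numeric vector of log10 BH-adjusted p-values.
#' @export
fdrCorrectLog10 <- function(log10p) {
  if (any(log10p > 0)) stop("log10 p-values must be <= 0", call. = FALSE)
  m <- length(log10p)
  if (m <= 1L) return(log10p)
  o <- order(log10p)
  scaled <- log10p[o] + log10(m / seq_len(m))
  adj <- rev(cummin(rev(scaled)))   # step-up: min over larger ranks
  adj <- pmin(adj, 0)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Degenerate-sd handling (sd == 0 in the null sample): the path is either
# always shorter than the constant null (certainty, capped), exactly equal
# (p = 0.5, as for t = 0), or longer (p = 1).
.DEGENERATE_LOG10P_CAP <- -4000

.log10PFromNull <- function(observed, nullMean, nullSd, R) {
  t <- tStatistic(observed, nullMean, nullSd, R)
  lp <- numeric(length(t))
  degen <- nullSd == 0
  lp[!degen] <- log10POneTailed(t[!degen], df = R - 1L)
  if (any(degen)) {
    lp[degen & nullMean > observed] <- .DEGENERATE_LOG10P_CAP
    lp[degen & nullMean == observed] <- log10(0.5)
    lp[degen & nullMean < observed] <- 0
  }
  list(t = t, log10p = lp)
}

#' Score candidate TF-gene pairs for confident regulation evidence
#'
#' For each candidate pair the regulation evidence is resolved: `direct` if
#' the curated TFKO edge tf -> gene exists (Case I), else `hypostatic` if
#' the modified BFS finds a regulation cascade (Case II), else `none`. For
#' every evidence-bearing pair, the observed shortest path length is tested
#' against its null distribution over `R` degree-preserving random networks
#' (one-sample t, one-tailed for shorter-than-random; direct pairs are
#' scored exactly like cascades with observed length 1). Benjamini-Hochberg
#' correction is applied jointly across all evidence-bearing pairs of the
#' call, and RCS = -log10(corrected p). A pair is functional iff it has
#' evidence and RCS exceeds `rcsThreshold`.
#'
#' The default threshold 1000 is calibrated to the default R = 10000
#' (corrected p below 1e-1000: the observed cascade is essentially always
#' shorter than random); for smaller R the attainable RCS scales roughly
#' linearly with R - 1, see the package vignette.
#'
#' @param net a [RegulatoryNetwork-class] built from the TFKO data.
#' @param candidates data.frame with columns `tf`, `gene`, `p_binding`
#'   (typically ChIP positives from [selectChipPositives()]).
#' @param R number of degree-preserving random networks (default 10000).
#' @param seed integer master seed for the random networks.
#' @param rcsThreshold RCS gate for the functional verdict (default 1000).
#' @param cap unreachable-path coding value; `NULL` for `numNodes(net)`.
#' @param maxDepth passed to [shortestRegulationPath()].
#' @return data.frame with one row per candidate: `tf`, `gene`,
#'   `p_binding`, `evidence_case` (`direct`/`hypostatic`/`none`),
#'   `observed_length`, `cascade` (nodes joined by `"->"`), `t_stat`,
#'   `log10_p_raw`, `log10_p_corrected`, `rcs`, `functional`. Pairs without
#'   evidence carry `NA` statistics and `rcs = 0`.
#' @export
scorePairs <- function(net, candidates, R = 10000L, seed = 1L,
                       rcsThreshold = 1000, cap = NULL, maxDepth = Inf) {
  tf <- as.character(candidates$tf)
  gene <- as.character(candidates$gene)
  pb <- if ("p_binding" %in% names(candidates)) candidates$p_binding
        else rep(NA_real_, length(tf))
  nc <- length(tf)
  evid <- rep("none", nc)
  obsLen <- rep(NA_integer_, nc)
  cascade <- rep(NA_character_, nc)
  for (i in seq_len(nc)) {
    if (tf[i] == gene[i]) next  # self-pairs carry no cascade evidence
    if (hasDirectRegulation(net, tf[i], gene[i])) {
      evid[i] <- "direct"
      obsLen[i] <- 1L
      cascade[i] <- paste(c(tf[i], gene[i]), collapse = "->")
    } else {
      p <- shortestRegulationPath(net, tf[i], gene[i], maxDepth = maxDepth)
      if (!is.null(p)) {
        evid[i] <- "hypostatic"
        obsLen[i] <- length(p) - 1L
        cascade[i] <- paste(p, collapse = "->")
      }
    }
  }
  tStat <- rep(NA_real_, nc)
  lpRaw <- rep(NA_real_, nc)
  lpCor <- rep(NA_real_, nc)
  rcs <- rep(0, nc)
  scored <- which(evid != "none")
  if (length(scored)) {
    nulls <- nullPathLengths(net, data.frame(tf = tf[scored],
                                             gene = gene[scored]),
                             R = R, seed = seed, cap = cap)
    nm <- nullMean(nulls); ns <- nullSD(nulls)
    st <- .log10PFromNull(obsLen[scored], nm, ns, R)
    tStat[scored] <- st$t
    lpRaw[scored] <- st$log10p
    lpCor[scored] <- fdrCorrectLog10(st$log10p)
    rcs[scored] <- -lpCor[scored]
  }
  data.frame(tf = tf, gene = gene, p_binding = pb, evidence_case = evid,
             observed_length = obsLen, cascade = cascade, t_stat = tStat,
             log10_p_raw = lpRaw, log10_p_corrected = lpCor, rcs = rcs,
             functional = evid != "none" & rcs > rcsThreshold)
}
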