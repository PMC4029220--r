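---
title: "Classifying functional TF-gene binding with TFKO regulation networks"
author: "funcbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying functional TF-gene binding with TFKO regulation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcbind)
```

## The model

A ChIP experiment yields TF-gene *binding* candidates with a binding
p-value; a TF-knockout (TFKO) compendium yields TF-gene *regulation* edges.
`funcbind` calls a ChIP positive (binding p at or below `chipAlpha`)
**functional** when confident regulation evidence exists for it in the TFKO
regulatory relation network. Two kinds of evidence are accepted:

* **Case I (direct)** — the curated edge TF → gene is present.
* **Case II (hypostatic)** — no direct edge, but a shortest regulation path
  TF → X₁ → … → gene of length two or more exists. The interpretation is
  knockout epistasis: an intermediate TF on the cascade compensates the
  knockout of the upstream TF, masking its (real) regulation of the gene in
  the TFKO readout. The path is found by a modified breadth-first search
  (mBFS) that keeps visited and discovered node sets and expands discovered
  nodes first-in-first-out, tracing parents back for the cascade.

Both evidence kinds can arise by chance in a noisy edge set, so both are
scored identically. For a pair with observed shortest-path length
$\ell$ (direct pairs have $\ell = 1$), the same pair's shortest-path length
is measured in $R$ degree-preserving random networks, giving a null sample
with mean $\bar{x}$ and standard deviation $s$. The one-sample t statistic

$$ t = \frac{\bar{x} - \ell}{s / \sqrt{R}} $$

is converted to a one-tailed p-value $P(T_{R-1} \ge t)$ (significance means
*shorter than random*: only shorter-than-chance cascades evidence
regulation; observed paths longer than the null mean get $p > 0.5$ and can
never pass). Benjamini–Hochberg FDR correction is applied jointly across all
pairs scored in one run, and the regulatory confidence score is

$$ \mathrm{RCS} = -\log_{10}(p_{\text{corrected}}). $$

A pair is functional iff it has evidence and RCS exceeds `rcsThreshold`.
Finally, a per-TF filter retains only TFs whose functional fraction among
their ChIP positives reaches `minFunctionalFraction`; in practice a very low
fraction flags insufficient TFKO coverage of that TF rather than genuinely
non-functional binding.

### Degree-preserving randomization

The null networks preserve every node's in- and out-degree exactly: the
degree sequences are expanded into node *frequency* sequences (a node with
in-degree 3 appears three times in the in-sequence), both sequences are
independently shuffled with a seeded generator, and edges are formed by
pairing the shuffled sequences position-wise. Stub pairing can create
self-loops and parallel edges; they are retained, because rejecting them
would bias the degree distribution while they cannot shorten any inter-node
shortest path. Network $r$ of a run uses seed `seed + r`, so any subset of
networks can be regenerated independently of evaluation order.

Pairs unreachable in a given random network are coded with a **cap** equal
to the node count of the original network (configurable via
`unreachableCap`). This keeps the null sample size fixed at $R$ and
penalizes pairs that are reachable only by chance: a pair that random
networks rarely connect has a null mean near the cap, making any observed
short cascade strongly significant.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `chipAlpha` | 0.01 | binding p-value (probability) at or below which a pair is a ChIP positive; 0.01 keeps pairs that are often already functional while 0.001 would trade false negatives for false positives |
| `nRandomNetworks` (R) | 10000 | null sample size; 10000 bounds the sampling error of the null mean at about 1% with 95% confidence |
| `rcsThreshold` | 1000 | functional gate on RCS = −log₁₀(corrected p); at R = 10000 it demands corrected p < 10⁻¹⁰⁰⁰, i.e. cascades essentially always shorter than random |
| `minFunctionalFraction` | 0.25 | per-TF retention threshold (inclusive), motivated by a jump in the observed per-TF fraction distribution |
| `unreachableCap` | node count | cap coding unreachable pairs in the null |
| `seed` | — | master seed; all randomization derives from it |

**The threshold scales with R.** For a fixed standardized shift
$\delta = (\bar{x}-\ell)/s$, $t = \delta\sqrt{R}$ and the log tail of the t
distribution behaves as
$\log_{10} p \approx -\frac{R-1}{2}\log_{10}(1 + t^2/(R-1))$, which grows
roughly linearly in $R - 1$ once $\delta$ is fixed. RCS > 1000 at R = 10000
corresponds to $\delta \gtrsim 0.77$; the matched gate at the same $\delta$
is RCS > 100 for R = 1000 and RCS > 50 for R = 500. The desk-scale presets
therefore pair R = 1000 with threshold 100. Comparing an RCS against a
threshold calibrated for a different R is a configuration error, not a
stricter test.

## Numerical choices

* **Log space throughout.** The t tail is evaluated with
  `pt(..., log.p = TRUE)`; a tail of $10^{-9000}$ is representable as
  $\log_{10} p = -9000$. The implementation matches a 60-digit
  arbitrary-precision incomplete-beta oracle to six significant digits over
  $t \in [0.1, 800]$, $\mathrm{df} \in \{4, 49, 9999\}$ (frozen in the test
  suite). BH correction is likewise performed on log₁₀ p-values
  ($q_{(i)} = \min_{j \ge i}(\log_{10} p_{(j)} + \log_{10}(m/j))$, capped at
  0), since `p.adjust` would round such tails to zero.
* **Degrees of freedom** are R − 1 (one-sample t convention).
* **One-tailed direction**: shorter-than-random only.
* **Degenerate null (s = 0)**: if the constant null exceeds the observed
  length, $\log_{10} p$ is set to −4000 (certainty sentinel, beyond any
  attainable smooth value); equality gives p = 0.5 (as for t = 0); a
  constant null below the observed length gives p = 1.
* **Tie-breaking in mBFS**: among equal-length shortest paths the
  lexicographically smallest node sequence is returned (neighbours expanded
  in sorted order, first discovery wins), making the reported cascade
  deterministic.
* **FDR family**: all pairs scored in one `scorePairs()` call. Enrichment
  q-values are corrected per target set (per TF), PPI prevalence across the
  supplied TFs, coherence across TFs within each condition and hypothesis.
* **PPI 2×2 table**: rows {target set, rest of genome}, columns {in protein
  complex, not}, one-tailed over-representation, where the complex is the
  union of core genes (targets interacting with another target) and their
  interaction neighbours. The underlying proportion comparison could be
  formalized several ways; this concrete table reports the core-gene count
  alongside so the inputs remain auditable.
* **Query nodes absent from the TFKO network** are isolated, not errors
  (binding tables routinely contain genes never assayed by knockout); such
  TFs are counted separately in the run report so that data unavailability
  is not conflated with the 25% filter.
* **Boundary conventions**: ChIP selection is `p <= chipAlpha`; the per-TF
  filter is `fraction >= minFunctionalFraction` (the inclusive, weaker
  reading); the RCS gate is strict (`rcs > rcsThreshold`).

## The synthetic scenario generator

`generateScenario()` emits a complete, parseable scenario — binding table,
TFKO edges, PPI, per-condition expression, annotations, truth labels — whose
statistical structure matches what the method assumes:

* each TF binds `targets_per_tf` genes; a fixed fraction
  (`functional_fraction`) is truly functional, with binding p-values drawn
  low-concentrated on [0, `chipAlpha`] (functional pairs are always ChIP
  positives), non-functional p-values uniform on [0, 1];
* each functional pair keeps its direct TFKO edge, or, with probability
  `tfko_dropout`, loses it and gains a planted epistatic cascade of
  `cascade_length_range` steps through fresh intermediate TFs (fresh chains
  keep the truth bookkeeping exact, at the cost of not reusing regulators);
* non-functional ChIP positives carry no evidence except a
  `spurious_edge_rate` of decoy direct edges (TFKO noise);
* `background_targets_per_tf` regulation-without-binding edges per TF
  emulate the large excess of TFKO pairs over ChIP positives seen in real
  compendia and give the degree distribution realistic mass;
* each TF's functional targets share an expression module
  (gene = √ρ·module + √(1−ρ)·noise, ρ = `module_correlation`, so the
  within-module pairwise correlation is ρ) across `n_conditions` conditions
  (default 40, the size of a typical curated condition panel), form PPI
  cliques of `ppi_complex_size`, and share one planted annotation term.

Defaults (50 TFs, 500 genes, 20 targets/TF, functional fraction 0.6,
dropout 0.5, spurious rate 0.05, 20 background targets/TF) define the
strong-signal preset; `overlap-only` sets dropout and spurious rate to 0, so
the recoverable functional set is exactly the ChIP ∩ TFKO intersection.

What the generator does **not** emulate: real yeast degree distributions
(power-law hubs), autoregulation and TF-TF cross-regulation outside planted
cascades, condition-dependent regulation, correlated ChIP/TFKO noise, or
sequence-level signal. Passing tests on these scenarios therefore
demonstrate correctness of the machinery and recoverability under the
stated generative assumptions — not performance on real compendia, where
denser TF-TF connectivity will produce more incidental Case II paths and a
correspondingly larger role for the RCS gate.

## Problem sizes

The test suite and the acceptance script run the strong-signal preset at 50
TFs × 500 genes with R = 1000 (threshold 100, the R-scaled gate), the
overlap-only preset at the same size, oracle equivalences on 200 seeded
digraphs up to 50 nodes, 1000 random BH lists, and 100 degree-conservation
resamples of a 30-node/120-edge digraph; a full suite run and the
acceptance script each complete in well under a minute on one CPU. The
published operating point (R = 10000, thousands of candidate pairs) runs in
minutes and scales linearly in R.

## Known limitations

* mBFS is exact but single-pair; very large candidate sets dominate runtime
  through the null-distribution stage (all pairs share the same R random
  networks, so the cost is R × (one BFS per distinct source TF)).
* The cap rule for unreachable null pairs is a documented choice; an
  alternative (dropping unreachable samples) would shrink the effective R
  per pair and bias the null toward reachable (shorter) lengths.
* The RCS gate is meaningful only together with its R (see above).
* Expression coherence uses squared Pearson correlation over within-set gene
  pairs; zero-variance profiles are dropped, and sets with fewer than two
  usable genes in a condition are skipped and logged in the detail table.
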