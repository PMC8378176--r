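---
title: "Ranking essential proteins by NMTF-denoised score propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking essential proteins by NMTF-denoised score propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntmep)
```

## The model

PPI networks are small-world, scale-free graphs assembled from noisy
screens: they contain spurious edges and miss real ones. The pipeline in
this package treats essentiality prediction as score propagation on a
*denoised* version of the network, seeded with per-protein biological
priors.

**Stage 1 — CoN weighting.** The binary adjacency is replaced by the
co-neighbor statistic: for proteins $i,j$ with neighbor sets $N(i),N(j)$,

$$P_{CoN}(i,j) = \frac{|N(i)\cap N(j)|^2}{(|N(i)|-1)(|N(j)|-1)}
\quad\text{if } |N(i)|>1 \text{ and } |N(j)|>1,\qquad 0 \text{ otherwise.}$$

Two proteins sharing many neighbors relative to their degrees are strongly
associated even if the screen missed their direct interaction. We evaluate
the statistic for *every* pair with a common neighbor, not only for raw
edges: sharing a neighbor is itself evidence of association, and letting
CoN create edges is what gives the downstream factorization something to
complete. `conMatrix(net, domain = "edges-only")` restricts support to the
observed edge set for users who prefer a pure reweighting. For adjacent
pairs the statistic lies in $[0,1]$ (the common neighborhood excludes the
pair itself, so $|N(i)\cap N(j)| \le |N(i)|-1$); non-adjacent pairs can
exceed 1 — opposite corners of a 4-cycle score $2^2/(1\cdot 1)=4$ — so
values are clamped at 1 to keep the matrix on one scale. The clamp is
reported when triggered.

**Stage 2 — NMTF.** The CoN matrix is approximated as $P_{CoN}\approx
FSG^T$ with $F\in\mathbb{R}^{n\times k}_{\ge 0}$,
$S\in\mathbb{R}^{k\times k}_{\ge 0}$, $G\in\mathbb{R}^{n\times k}_{\ge 0}$
by minimizing the squared Frobenius residual with multiplicative updates

$$F \leftarrow F\odot\frac{P_{CoN}GS^T}{FSG^TGS^T+\epsilon},\quad
  G \leftarrow G\odot\frac{P_{CoN}^TFS}{GS^TF^TFS+\epsilon},\quad
  S \leftarrow S\odot\frac{F^TP_{CoN}G}{F^TFSG^TG+\epsilon},$$

the forms dictated by the KKT stationarity conditions of the objective.
Each rule is applied in the fixed order F, G, S using the freshest factors;
the order is a reproducibility convention, since each rule is separately
non-increasing. The low-rank reconstruction $Y=FSG^T$ smooths noise and
fills in latent associations.

**Stage 3 — propagation.** $Y$ is converted to the operator
$P^*(i,j)=\max(Y_{ij},Y_{ji})/\sum_k Y_{ik}$ (zero rows stay zero), and the
final score solves $S_F=\alpha P^*S_F+(1-\alpha)S_I$ by the Jacobi
iteration $S_F^{(t)}=\alpha P^*S_F^{(t-1)}+(1-\alpha)S_I$ started at
$S_F^{(0)}=S_I$. The seed combines two priors: the conservation score
$S_H(p)=H(p)/\max_q H(q)$, where $H$ counts reference species with a direct
ortholog, and the localization score $S_L(p)=\max_{r\in C(p)} OF(r)$, where
$OF(r)$ is the max-normalized occupancy of compartment $r$. Essential
proteins tend to be both widely conserved and concentrated in heavily
populated compartments, so the product $S_I=S_H\cdot S_L$ demands both
signals.

## Parameters

* `alpha` (damping, default **0.2**, range $[0,1)$): weight of the
  neighbor-induction term against the prior. At 0 the ranking is the prior
  alone; as $\alpha\to 1$ the prior washes out. 0.2 is the operating point
  at which the combined signal performs well across top-$k$ cutoffs in our
  benchmarks; the extremes discard one of the two information sources and
  measurably degrade recovery.
* `k` (factorization rank, default **100**): the number of latent
  association patterns. There is no principled universal value; 100 is a
  sensible default for networks of a few thousand proteins, and ~10% of
  $n$ works well at benchmark scale (the package tests use `k = 50` on
  500-protein networks). It is deliberately configurable and recorded in
  every run manifest.
* `maxIter` / `relTol` (NMTF stopping, defaults **2000** / **1e-6**):
  iteration stops when the relative per-sweep objective decrease falls
  below `relTol`. Multiplicative updates make fast initial progress and
  then crawl, so `relTol` — not `maxIter` — is the usual stop at these
  defaults.
* `epsilon` (ranking stop, default **1e-6**) and the **L1** norm for the
  residual $\|S_F^{(t)}-S_F^{(t-1)}\|_1$; `maxIter = 10000` is a safety
  cap that is never reached for $\alpha<1$ with row-normalized $P^*$.
* `rowRenormalize` (default **TRUE**): the raw quotient form of $P^*$ has
  rows that sum to $\ge 1$ wherever max-symmetrization lifted an entry;
  rescaling every nonzero row to sum exactly 1 bounds the operator's
  spectral radius by 1, which makes the damped iteration a contraction for
  any $\alpha<1$ and the fixed point unique. The raw form remains
  available (`rowRenormalize = FALSE`) for studying the printed-form
  operator; convergence is then still observed in practice but is not
  guaranteed by the row-sum argument.

## Numerical choices

* **Initialization.** Factors start uniform on $(0,1]$: multiplicative
  updates cannot move an entry off an exact zero, so a zero-free start
  keeps the search space open. Runs are reproducible per seed.
* **Denominator guard.** A fixed $\epsilon=10^{-12}$ in every update
  denominator; standard non-negative-factorization practice for zero
  denominators, small enough not to perturb converged factors.
* **Convergence behavior.** The objective is provably non-increasing per
  sweep (asserted to $10^{-9}$ relative in the tests). Near an optimum the
  updates slow to a crawl, and the objective is non-convex, so exact-rank
  targets are recovered to $10^{-6}$ relative objective on *most* but not
  all random starts — the recovery test therefore asserts success on a
  majority of seeds (4 of 5), with a generous sweep budget on a small
  (n = 30, k = 2) instance.
* **Contraction.** With row sums $\le 1$, the per-step contraction of the
  iteration is exact in the max norm; the L1 residual used for stopping
  decays geometrically with ratio $\le\alpha$ in all tested instances,
  and the tests ignore residuals at machine-noise level where ratios are
  meaningless.
* **Ties.** `topProteins()` breaks score ties lexicographically (C
  locale), so ranked tables and overlap statistics are reproducible across
  platforms and input line orders.
* **Degenerate inputs.** Graphs where no pair passes the degree-$>1$
  filter yield an all-zero CoN matrix (warning); a zero target matrix
  collapses the factors to zero without error; all-zero priors trigger a
  warning since at $\alpha=0$ they make the ranking vacuous; empty gold
  sets are an error in evaluation but only a warning at the I/O layer.
* **Jackknife AUC normalization.** The cumulative-hit curve is summed to
  `kMax` and divided by `kMax * min(|gold|, kMax)`, mapping it to $[0,1]$
  with a perfect ranking short of 1 only by its initial ramp. PR AUC is
  the trapezoid over achieved (recall, precision) points with no
  interpolation to recall 0. Both conventions are stated because published
  curve summaries of this kind rarely define their normalization; values
  are comparable *within* this package across methods, not necessarily
  with externally computed AUCs.

## The synthetic benchmark

`generateSynthetic()` emulates the four inputs of a real study. A
preferential-attachment graph (n = 500, m = 3 by default) reproduces the
scale-free degree distribution of PPI networks with a single parameter.
Essentials (20% of proteins) are sampled with weight $\propto
\text{degree}^{2}$, reflecting the centrality–lethality observation;
ortholog counts are Binomial(99, 0.8) for essentials versus Binomial(99,
0.3) for background, mirroring an ortholog-count scale over 99 reference
species; and each protein carries 1–3 of 11 yeast-style compartments with
essentials annotated to the enriched compartment (Nucleus) with
probability 0.8. `hubBias = 0` is the built-in negative control: the
essential set becomes a uniform draw and topology carries no planted
signal.

What the generator does *not* emulate: false-positive/false-negative edge
noise with realistic screen-specific structure, correlated multi-protein
complexes, degree-dependent annotation completeness, or the identifier
harmonization problems of real databases. Passing the end-to-end test —
the pipeline's top-100 true-essential count matching or beating degree
centrality on at least 4 of 5 replicates, both far above the random
expectation of 20 — therefore shows the machinery integrates the three
planted signals correctly, not that it attains any particular accuracy on
real yeast data.

Test and acceptance problem sizes (500-protein benchmarks with `k = 50`,
300 sweeps; oracle comparisons at $n\le 200$; recovery at n = 30) were
chosen so the full suite exercises every guarantee in well under a minute
of numerics per component; all of them are package choices recorded here,
and every quantity reported by `scripts/acceptance.R` is recomputed from
scratch at run time.

## Design decisions that were genuinely open

* **CoN pair domain.** Whether the statistic applies to all pairs with a
  shared neighbor or only to existing edges is ambiguous in the method's
  usual description; we default to all pairs (the reading under which CoN
  performs completion) and expose `domain = "edges-only"`.
* **Transition-matrix symmetry.** The quotient form is called symmetric in
  informal descriptions but is not, in general, once rows are divided by
  their own sums. We keep the printed quotient (optionally renormalized)
  rather than forcing symmetry, and expose both behaviors.
* **Identifier handling.** Identifiers are compared case-sensitively after
  whitespace stripping; no accession cross-referencing is attempted. The
  network defines the protein universe; annotations and gold lists are
  projected onto it.
* **Isolated nodes** (mentioned only in dropped self-loops) are retained
  at degree 0: they keep indexing reproducible and still rank via their
  prior.

## Limitations

* The NMTF rank for genome-scale data is unreported in the literature this
  method descends from; results depend on it and it must be chosen (and is
  logged) per study.
* Dense $n\times n$ computation: fine to a few thousand proteins on a
  laptop, not for interactomes of $10^5$ nodes.
* The method presumes the three planted premises. On organisms where
  essentiality decouples from degree, conservation or localization, the
  seeded propagation has no signal to integrate — the `hubBias = 0`
  control quantifies exactly this failure mode for topology.
* Only DC, BC, CC and SC baselines are built in; other published
  essentiality scores can be compared by supplying their rankings to
  `evaluateRanking()` / `overlapDifferenceTable()`.
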