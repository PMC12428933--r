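---
title: "Boolean network analysis of CLL-to-Richter transformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean network analysis of CLL-to-Richter transformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cllrs)
```

# The model

Chronic lymphocytic leukemia (CLL) cells in peripheral blood are mostly
anergic: chronically stimulated through the B-cell receptor (BCR) yet
non-proliferating. In a minority of patients the disease transforms into
Richter syndrome (RS), an aggressive large-B-cell lymphoma. `cllrs`
provides the machinery to study this transition with synchronous Boolean
networks: each gene or protein is a binary variable $x_i \in \{0,1\}$, a
Boolean function $f_i$ over the states of its regulators updates every node
simultaneously at each discrete time step, and the deterministic dynamics
on the finite state space $\{0,1\}^n$ must eventually revisit a state,
producing recurring state sequences — attractors (fixed points when the
cycle has length one). The set of states flowing into an attractor is its
basin of attraction; basin sizes serve as a proxy for how much of the
state space, and hence how much of a heterogeneous cell population, a
phenotype captures.

Phenotypes are read out through indicator nodes:

* **anergy** — NFAT active while NF-κB, AKT and S phase are inactive;
* **proliferation** — the S-phase node, requiring E2F and cyclin E
  (CCNE1) jointly;
* **apoptosis** — BIM active with AKT inactive;
* **cell-cycle alert** — cyclin D (CCND1) and CCNE1 active without
  S-phase entry;
* **quiescence (G0)** — none of the above.

For cyclic attractors every cycle state is labelled with the precedence
apoptosis > proliferation > cell-cycle alert > anergy > G0; a homogeneous
cycle carries that label, a heterogeneous one is reported as `mixed`
together with its precedence-dominant label and per-indicator activity
fractions, so stricter callers can be layered on top. Screening uses the
dominant label. This reconciles two needs: faithful reporting of unstable
attractors that oscillate between, say, cell-cycle alert and
proliferation, and a deterministic single label for automated filtering.

Knockouts and knockins clamp a node to 0 or 1 throughout the simulation;
the clamped node ignores its function. Interventions never modify the
input network object.

# Attractor search: exhaustive oracle plus sampling

For networks up to 20 nodes (about $10^6$ states) `exhaustive_attractors()`
enumerates the full state space, assigning every state to exactly one
attractor, so basin counts are exact and sum to $2^n$. Beyond that scale
an exact enumeration of basins is hopeless ($2^{49} \approx 5.6\times
10^{14}$ states for a 49-node model), so `sampled_attractors()` discovers
attractors by following the dynamics from uniformly random start states
and estimates each basin as the fraction of starts converging to it.
Transient states are memoised, so repeated walks short-circuit quickly.
The design trades the original SAT-based exhaustive attractor enumeration
for a single sampling pass that yields both the attractor set and the
basins; attractors with very small basins can be missed, which is why the
landscape records `n_samples` and the package tests sampling against the
exhaustive oracle (20 random 10-node N-K networks, $10^5$ samples,
basin ratios within ±0.02).

States are encoded as integers with node 1 (declaration order) as the
least-significant bit; cycles are canonicalized by rotating the smallest
encoding first, so the same cycle entered anywhere yields one key.

# The reconstructed CLL/RS network

`reconstructed_cll_network()` ships a 39-node reconstruction covering the
BCR signalosome (LYN, SYK, ZAP70, BTK, PLCG2, SHP1), calcium/NFAT anergy
signaling (STIM1, PKCB, GSK3B, NFAT, CD5, PTEN), the PI3K/AKT axis with
its PP2A/SET brake, the TP53–MDM2–S100A4 module, MYC with its targets
CITED2 and BMI1, the cell-cycle inhibitors CDKN1A/2A/2B/1B, the cyclin
D/E–E2F axis, NF-κB/BCL2/BIM survival control, the TME costimulation
input, and the three indicator nodes. Every rule carries a provenance
note (`$provenance`); where the describing literature is silent, minimal
pass-through logic is used and flagged as such. **This is a best-effort
reconstruction, not the authoritative published rule table of the original
49-node model**: only qualitative attractor behavior is asserted, never
basin percentages. The rule-file parser accepts the authoritative table
verbatim should a user obtain it.

The scenarios in `cll_scenarios()` fix the biological context: CLL
conditions keep `BCR = 1` (the disease model is defined under chronic BCR
stimulation) and `TME = 0` unless the scenario says otherwise. The
reconstruction reproduces, by simulation:

* an anergic unperturbed CLL landscape (NFAT, CD5, SHP1, ERK, PTEN,
  CDKN1A, CDKN2B on; AKT, SYK, MYC, S phase off) reached from the
  all-zero-except-BCR start;
* fully apoptotic landscapes after IgM/BCR withdrawal, rescued into
  quiescence by a BCL2 knockin;
* fully proliferative landscapes under CDKN2A/B+TP53 loss (BCR-dependent:
  adding a BCR knockout reverts to apoptosis), AKT knockin (with NFAT
  loss and S100A4 gain), NOTCH1 knockin, and NFAT knockout (with AKT
  activation and CDKN2A/CD5 loss);
* coexistence of anergic and proliferative attractors under TME
  costimulation;
* the two-hit driver requirement: BMI1 knockin plus TP53 knockout yields
  full S-phase activity while either single lesion does not.

# Robustness and topology

`bitflip_response()` draws random states, flips one random bit, advances
both the original and the perturbed state one synchronous step and
records the normalized Hamming distance $HD(x,y) = \frac{1}{n}\sum_i x_i
\oplus y_i$ between the successors. `robustness_test()` compares the mean
response of the reference network against random N-K networks matched in
node count and per-node in-degrees (regulators drawn uniformly, truth
tables fair coin flips). The empirical p-value uses the add-one
correction $(1 + \#\{\text{null} \le \text{obs}\})/(N+1)$ — the
uncorrected counting fraction is also reported — and the 5% quantile of
the null distribution is returned for the conventional comparison. The
per-network summary is the mean distance; the full distributions are kept
so other summaries can be formed.

`powerlaw_plausibility()` fits a discrete power law $P(k) \propto
k^{-\alpha}$ to the positive degrees: $\alpha$ by maximum likelihood (a
closed-form estimate refined by a short exact-likelihood optimization with
a truncated Hurwitz-zeta normalizer), $x_{\min}$ by minimizing the
Kolmogorov–Smirnov distance over candidate values, and a semi-parametric
bootstrap for goodness of fit: each replicate resamples the body
empirically and the tail from the fitted law, is refitted from scratch,
and contributes its KS distance to the null. Plausibility is declared at
$p > 0.1$. A caveat this package states openly: with a freely chosen
$x_{\min}$ the test has limited power against short, light tails —
Poisson-like degree data can retain a steep but formally plausible
power-law tail once the fit is free to discard the distribution's body.
The fitted $x_{\min}$/$\alpha$ values agree with igraph's independent
`plfit` implementation (cross-checked in the test suite), so this is a
property of the method, not of this implementation.

# Graded input–output analysis

Boolean inputs are softened into duty cycles: an input at $p\%$ activity
is overridden with a realized ON/OFF sequence containing exactly
$\mathrm{round}(pT/100)$ ON steps among $T$, placed by a seeded uniform
shuffle. A fresh realization is drawn per starting state, avoiding the
phase-locking artifacts a deterministic block schedule would cause in
oscillating attractors. Output activity is the mean ON ratio over the
last `window` steps, averaged over random starts; defaults follow the
study conditions (250 starts, $T = 500$, window 100). At 100% the
schedule degenerates into a knockin, and the package tests that the
graded outputs then match the knockin landscape's fused activities within
±0.05. `io_grid()` derives one sub-seed per grid cell from the master
seed and the cell coordinates, so cells are independent of evaluation
order; the default axis resolution is 5% (the full 1–100% sweep is
available by passing `percents = 1:100`).

# Trajectories and flip attribution

Under synchronous updating a start state fixes the entire path, so
mechanism tracing is exact. `trajectory()` records every state from the
start through one full traversal of the terminal attractor (the default
CLL start is all nodes zero except BCR) and classifies the terminal
attractor's phenotype. `attribute_flips()` explains each node flip: among
the regulators that themselves changed in the preceding step, each is
toggled back one at a time; those whose toggle reverts the node's new
value are reported as responsible, and flips of clamped nodes are tagged
`intervention`. This single-regulator reversion is deliberately minimal —
exhaustive cause analysis over regulator subsets is exponential — and
matches how mechanism arrows are drawn in pathway narratives.

# Expression binarization and concordance

`basca_binarize()` sorts the values ascending and computes, by dynamic
programming, the least-squares optimal step function for every number of
discontinuities $d$. Each optimal step function contributes its strongest
discontinuity; strength combines the jump height between adjacent step
means with the approximation error of thresholding the whole series at
that position, so a jump must both be large and separate the data well —
a plain largest-jump rule degenerates into single-spacing selection at
high $d$ and, on zero-inflated matrices, locks onto the dropout block.
Candidate break locations are aggregated by their median across $d$, and
the threshold is the midpoint of the two flanking data values. For
matrices, `binarize_matrix()` caps the discontinuity ladder at 30 by
default (a computational choice; on well-separated data the aggregated
median break is insensitive to the cap) and fits on the $\log(1+x)$ scale
— the conventional scale for normalized expression; the transform is
monotone, so calls are unchanged and the threshold is mapped back.

Significance is a resampling test of break strength against a no-jump
null: the statistic is the widest value interval spanned by 5% of
consecutive sorted observations (the empirical density valley a true
discontinuity carves out), normalized by the range, and the null
distribution comes from sorted uniform samples of the same size. This
statistic was chosen after calibration simulations in which raw-spacing
and variance-explained statistics could not separate 4σ log-normal
mixtures from the uniform null at a few hundred cells, while the valley
width separated the two classes cleanly (the package's recovery tests
exercise exactly this setting); a strictly linear ramp — the most
regular no-jump input —
is the statistic's minimizer and is therefore essentially never called
significant. Genes with no expression anywhere are excluded as
`all_zero`; genes failing the test (including constants) as
`not_significant`.

Downstream, `select_proliferative_cells()` labels a cell RS-like when at
least one cyclin D/E signature gene (CCNE1, CCNE2, CCND1, CCND2, CCND3)
is 1, and `concordance()` compares per-node activation fractions between
the binarized data (OR-aggregated over each node's isoform group, an
overridable mapping) and the model's fused activities, both thresholded
at 30% — the Hans-score convention for calling a marker positive. The
model side should be restricted to fully proliferative attractors
(`fuse_landscape_subset()` with `is_fully_proliferative`), mirroring the
cyclin-based cell selection on the data side. `roc_binarize()` covers the
scored-marker case: a threshold sweep maximizing Youden's J, ties broken
toward the smallest candidate.

# Synthetic data: what it emulates and what it does not

`synth_expression()` emulates the sparsity structure that makes single-
cell validation hard: per gene, cells fall into a low or high log-normal
expression mode (separation $(\mu_{hi}-\mu_{lo})/\sigma = 4$ by default),
observed values are zeroed with probability 0.3 (dropout), a set of
all-zero genes exercises the exclusion path, and the cyclin signature
genes are planted with known mixing fractions so cell selection has a
known outcome. Ground truth is the mode membership; dropout cells retain
their mode label and the dropout mask is returned, so recovery accuracy
is judged on observed (non-dropped) entries — a zeroed cell is
uncallable by any method. Defaults (200 genes × 500 cells) are desk-scale
stand-ins for pooled patient populations. The end-to-end concordance
check plants the node-map marker genes at known mixing fractions without
dropout, isolating the pipeline's threshold logic (when a gene's high
mode is rare, a dropout block makes the expressed/unexpressed gap the
dominant discontinuity — correct binarization behavior, but a different
question than the one that check asks); dropout robustness is exercised
separately by the recovery test. What the generator does *not*
emulate: counts and library-size effects, gene–gene correlation, batch
structure, and continuous (non-bimodal) expression gradients. Passing the
recovery tests therefore demonstrates correctness of the binarization
machinery on well-posed inputs, not performance on arbitrary real data.

# Numerical choices and problem sizes

* Sampling-based landscapes in the test-suite use $10^5$ starts (the
  package's chosen desk-scale default for the 39-node reconstruction);
  basin ratios are then stable to well under a percentage point for the
  dominant attractors.
* The robustness calibration study runs 200 repetitions against 200 null
  networks with 100 bit-flip states each; the power-law study uses 50
  runs with 100 bootstrap replicates; both are the package's chosen
  simulation sizes for routine verification, with the larger published
  conventions (1000 networks, 1000 replicates) available through the
  function arguments.
* Iteration caps on attractor walks default to $\max(2^{\min(n,20)},
  10^4)$; synchronous dynamics must cycle, so hitting the cap signals an
  implementation bug rather than a data condition.
* Seeds: every stochastic entry point takes an explicit `seed`;
  compound procedures derive per-unit sub-seeds (per screen candidate,
  per grid cell, per gene) so results are independent of evaluation
  order.

# Known limitations

* The packaged CLL/RS network is a reconstruction; quantitative basin
  percentages of the original model are out of reach and deliberately
  unasserted.
* Asynchronous and probabilistic update schemes are out of scope.
* Sampled screening treats a phenotype as eliminated when its estimated
  basin fraction is exactly zero among the samples; tiny surviving basins
  below the sampling resolution can escape, so screening reports the
  sample count used.
* The power-law plausibility test inherits the limited power of
  free-$x_{\min}$ goodness-of-fit testing against short tails (see
  above).
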