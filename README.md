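# cllrs — Boolean network modeling of CLL transformation to Richter syndrome

Chronic lymphocytic leukemia (CLL) cells circulate in an anergic,
non-proliferating state despite chronic B-cell-receptor (BCR)
stimulation; in a fraction of patients the disease transforms into
Richter syndrome (RS), an aggressive large-B-cell lymphoma with dismal
prognosis and almost no tractable preclinical models. `cllrs` implements
the in-silico route to studying this transformation: a synchronous
Boolean network model of the CLL signaling landscape together with the
full analysis toolbox such a model needs. It is aimed at systems
biologists and computational oncologists who want to simulate perturbed
disease conditions, screen interventions, and confront logical-model
predictions with binarized expression data.

## What is inside

A synchronous Boolean network is a set of binary variables
`x_1..x_n` updated simultaneously by Boolean functions `f_i` built from
AND/OR/NOT. Dynamics on the finite state space `{0,1}^n` converge to
attractors (fixed points or cycles); the states flowing into an attractor
form its basin. The package provides:

* **Network core** — BoolNet-style `targets, factors` rule-file parsing
  and serialization, interventions (knockout/knockin = clamping a node to
  0/1), and a compiled synchronous step.
* **Attractor landscapes** — exhaustive enumeration (exact basins, small
  networks) and sampling-based estimation from random start states, with
  phenotype classification through indicator nodes (anergy,
  proliferation via the S-phase node `E2F & CCNE1`, apoptosis via
  `BIM & !AKT`, cell-cycle alert, quiescence), basin-weighted "fused"
  activity profiles and phenotype pie fractions.
* **Perturbation screening** — exhaustive single/double-hit intervention
  enumeration (`sum_i C(c,i)·2^i` candidates; 4802 for a 49-node model,
  `m = 2`) filtered by attractor criteria, covering the tumor-driver
  screen (eliminate anergy, force full S phase) and the drug-target
  screen (delete proliferation or induce apoptosis).
* **Robustness & topology** — one-step bit-flip response measured by the
  normalized Hamming distance `HD(x,y) = H(x,y)/n`, compared against
  random N-K networks matched in size and in-degrees; discrete power-law
  fitting (`P(k) ∝ k^-α`) with a semi-parametric bootstrap
  goodness-of-fit test.
* **Graded input–output analysis** — duty-cycle softening of Boolean
  inputs (an input at p% activity is ON in exactly `round(pT/100)` of `T`
  steps), two-input activity grids for heatmaps.
* **Trajectory tracing** — deterministic paths from defined start states
  (default: all zero except BCR) with per-step attribution of node flips
  to responsible regulators.
* **Binarization & concordance** — BASC-A-style step-function
  binarization of expression values with a significance filter,
  cyclin-signature selection of proliferative cells, node↔gene (isoform
  group) mapping, and model/data concordance at the 30% activation
  threshold (Hans-score convention); ROC/Youden binarization for scored
  markers.
* **Synthetic data** — toy networks with exact ground-truth landscapes,
  random N-K generators, sparse bimodal expression matrices with known
  truth, and a 39-node literature-motivated **reconstruction** of the
  CLL/RS network with named scenarios (unperturbed CLL, IgM withdrawal,
  CDKN2A/B+TP53 loss, AKT or NOTCH1 knockin, NFAT knockout, TME
  costimulation, high-risk CLL, BMI1/TP53 driver pairs). The
  reconstruction asserts qualitative behavior only — it is not the
  authoritative published rule table.

## Worked example

```r
library(cllrs)

card <- reconstructed_cll_network()
net  <- apply_interventions(card$network, cll_scenarios()$cll)  # BCR on, TME off

ls <- sampled_attractors(net, 1e5, seed = 1)
ls
#> Attractor landscape: 2 attractor(s), basins estimated from 1e+05 random starts
#>   #1 length 1 basin 0.0872
#>   #2 length 1 basin 0.9127

round(phenotype_fractions(ls, use_dominant = TRUE), 3)
#>        anergy proliferation
#>         0.913         0.087

trajectory(net, bcr_start_state(net))
#> Trajectory: 17 recorded states, attractor entered at step 16 (cycle length 1)
#> Terminal phenotype: anergy

round(fuse_landscape(ls)[c("NFAT", "CD5", "AKT", "MYC", "TP53", "SPhase")], 3)
#>   NFAT    CD5    AKT    MYC   TP53 SPhase
#>  0.913  0.913  0.087  0.087  0.913  0.087
```

The unperturbed CLL landscape is dominated (91%) by an anergic fixed
point — NFAT and CD5 on, AKT/MYC off, TP53 stabilized, no S phase —
reached deterministically from the BCR-stimulated start state; a small
proliferative basin coexists. Simulating the RS condition flips the
picture:

```r
rs <- sampled_attractors(
  apply_interventions(card$network, cll_scenarios()$rs_cdkn2ab_tp53_ko),
  1e5, seed = 1)
round(phenotype_fractions(rs, use_dominant = TRUE), 3)
#> proliferation
#>             1
```

Loss of CDKN2A/B together with TP53 produces a fully proliferative
landscape (S phase active in every attractor state), which reverts to
apoptosis when BCR stimulation is additionally withdrawn — the
BCR-dependence of the transformed clone.

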