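---
title: "Stiffness network analysis of two-cohort microbiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stiffness network analysis of two-cohort microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiffnet)
```

## The model

stiffnet treats a microbial co-occurrence network as an elastic structure.
In structural engineering the stiffness matrix $K$ links the forces $f$
applied to the joints of a framework to the displacements $d$ they produce,
$f = K d$. Carried over to a weighted network, the connectivity (weight)
matrix $W$ plays the role of $K$: edge weights express how strongly a
perturbation at one node propagates to another. For a two-cohort microbiome
study the node attribute is the per-taxon mean relative abundance, measured
once in the reference cohort ($x_a$, e.g. healthy controls) and once in the
condition cohort ($x_b$). The observed attribute change
$d_{\mathrm{obs}} = x_b - x_a$ is read as a displacement, and the method
asks what forces, scalings and perturbation responses are consistent with
it under the network's stiffness.

Five per-taxon parameters are computed by `compute_profile()`:

* **Force** $f = W\,d_{\mathrm{obs}}$ — the load pattern that produces the
  observed abundance shift through the network.
* **Displacement** $d = W^{-1} f$ — the node response to that force. On a
  well-conditioned $W$ this recovers $d_{\mathrm{obs}}$; it is reported from
  the solve, not copied, so regularised solves are visible in the output.
* **Stiffness scale** $s_i = x_i \big/ \sum_j w_{ij} y_j$ — the diagonal
  scaling with $\operatorname{diag}(s)\,W\,y = x$, mapping the reference
  state $y = x_a$ onto the condition state $x = x_b$ through the network.
  The defining identity is enforced to $10^{-10}$ on defined entries and is
  part of the test suite.
* **Impact** $I_i = \sum_j A_{ij} G_{ji}$ — the summed response of node
  $i$'s first-order neighbours to a perturbation of $i$, where
  $G_{ij} = \left| (\Delta x_i / x_i) / (\Delta x_j / x_j) \right|$ is the
  relative-change ratio matrix and $A$ the 0/1 adjacency.
* **Stability** $S_i = 1 \big/ \sum_j A_{ij} G_{ij}$ — the inverse response
  of node $i$ to perturbations of its neighbours. Values near 1 mark taxa
  whose neighbourhood barely moves them; values near 0 mark susceptible
  taxa. Stability is reported raw: values above 1 occur and are noted, not
  clipped, since the nominal $[0, 1]$ range is an empirical observation,
  not a mathematical bound.

Symmetry of the two directions is assumed: the attribute change from A to B
is taken equal in magnitude to the change from B to A, so profiles are
computed once, A to B.

## Network construction

Each cohort's network is built from its samples alone
(`estimate_correlations()` then `build_network()`). Three estimators are
available: Spearman (default), Pearson, and a compositional
log-ratio-variance estimator of the SparCC family, written in-package
because no installed dependency provides it. The SparCC implementation is a
deterministic point estimate: zeros are replaced by a pseudocount, basis
variances are solved from the log-ratio variance row sums under the
sparsity assumption, and the most strongly correlated pairs are excluded
from the row sums over a fixed number of re-solve rounds. Dirichlet
resampling of the fractions is deliberately omitted; the estimate is the
one the rest of the pipeline can reproduce bit-for-bit under a seed.

Spearman with an absolute-correlation edge threshold of 0.3 is the default
for the main analysis: rank correlation is robust to the skewed,
compositional scale of relative abundances, and the threshold is exposed in
`network_config()` because network topology is known to be sensitive to the
cutoff. The compositional estimator is the default for first-order
neighbour graphs in the pipeline configuration. Edge weights store
correlation *magnitudes* with a unit diagonal, so $W$ is usable as a
stiffness matrix (the unit diagonal keeps it away from trivial
singularity); signs are kept in a separate matrix for the
positive/negative-edge analyses. Per-edge significance filtering is not
performed — thresholding is by magnitude only.

Taxa are prevalence-filtered before any network is built
(`filter_taxa()`); the filter counts nonzero samples across the pooled
study, so it commutes with cohort relabeling and can sit outside the
permutation loop.

## Permutation inference

`sna_permtest()` implements the pooled-label permutation test. The $m + n$
samples are pooled; in each of `n_perm` rounds a uniform permutation
assigns the first $m$ to the reference cohort and the rest to the
condition cohort, and the *entire* per-cohort pipeline — cohort-A network
re-estimation plus both attribute vectors — is re-run to produce null
values of stiffness scale, impact and stability. Force and displacement are
computed for the profile but not permutation-tested. For each taxon and
parameter the pseudo-P pair is

$$P_1 = \#\{R_i < R\}/N, \qquad P_2 = \#\{R_i \ge R\}/N,$$

with ties counting towards $P_2$ and undefined permutation values dropped
from $N$. $P_1 + P_2 = 1$ holds exactly; a configuration flag switches to
the $(N+1)/(B+1)$ convention when exact zeros are undesirable. Small $P_2$
marks a real value unusually *high* under the null and yields the label
`sig_increased` after Benjamini–Hochberg adjustment across taxa; small
$P_1$ yields `sig_decreased`. The two directions are adjusted as separate
families within each parameter; a global correction across parameters was
considered and rejected because the three parameters answer distinct
questions and are reported separately. One known ambiguity in the
literature this method follows: the summary-table header convention
associates "significantly increased" with the column labelled $R_i < R$;
read the labels through the definition above ($R$ real, $R_i$ null), which
is the reading implemented here.

All permutation indices are drawn up front under a single seed, so runs are
bit-reproducible and results do not depend on execution order. Undefined
values (isolated nodes, zero relative changes, zero denominators) propagate
as missing values with counts in the run manifest — never as silent zeros.

## Neighbourhood analyses

Taxa classified as significantly increased or decreased are *biomarkers*.
`extract_fon()` builds the first-order-neighbour graph: the induced
subgraph on biomarkers and their direct neighbours, with roles
`biomarker_inc` / `biomarker_dec` (cluster I / II), `nn_inc` / `nn_dec`
(single-class neighbours) and `shared_nn` (neighbours of both classes;
only non-biomarker nodes can be shared — a biomarker adjacent to the other
class keeps its biomarker role). `fon_pn_table()` reports the
positive/negative edge-count ratio between cluster I or II and its own or
the shared neighbours, counting between-cluster edges only; a cell with
positive edges and no negative ones is rendered "–" and an empty cell
"NA". `mine_subgroups()` finds "allies" sub-communities as connected
components of the positive-edge subgraph induced on the biomarkers — the
simplest module definition consistent with an all-positive biomarker
clique, and pluggable should a denser definition be wanted.

## The synthetic generator

`generate_study()` draws both cohorts from a logistic-normal model: a
multivariate normal on the log scale with a block-structured correlation
backbone, exponentiated and renormalised to per-sample proportions.
Logistic-normal rather than Dirichlet because arbitrary signed correlation
backbones are expressible. Both cohorts share one log-mean vector, so any
cohort difference is purely a *relationship alteration*: cohort B's
correlations among a planted taxon subset are rewired (`sign_flip`,
`decorrelate`, or `strengthen`). Zeros are injected post-hoc by an
independent Bernoulli mask and are a phenomenological stand-in for
under-sampling, not a mechanistic model; a sample is never fully zeroed.

Defaults are the study conditions used throughout the calibration and
recovery tests: 40 taxa in 30 + 30 samples; four five-taxon blocks with
within-block correlations 0.7, 0.6, 0.5 and 0.4 on an independent
background (a modest, realistic amount of structure for a 16S genus-level
table); a log-abundance gradient from $e^{2}$ to $e^{-2}$; 10% extra
zeros; and a sign-flip of the first (0.7) block. Sign-flipping an
equicorrelated block of five cannot remain a valid correlation matrix (the
most negative feasible equicorrelation is $-1/4$), so the rewired matrix is
repaired to the nearest positive semi-definite correlation matrix with a
warning; realised cohort-B block correlations land near $-0.25$ and remain
negative, which the generator tests verify against sampled data.

What the generator does *not* emulate: taxonomic correlation structure
beyond blocks, mechanistic zero generation, sequencing depth variation,
overdispersion families other than log-normal, and any particular real
data set. Passing calibration on it shows the inference machinery is
correct under exchangeability and compositionality; it does not certify
power or error rates on real 16S data.

## Numerical choices

* Singular or ill-conditioned stiffness systems (condition number above
  `cond_cap = 1e12`) are solved by minimum-norm least squares
  (Moore–Penrose) and flagged `regularized`; real correlation networks do
  violate invertibility and the flag is surfaced in the profile and the
  manifest.
* Denominators in the relative-change matrix use the baseline (reference
  cohort) attribute with a `1e-6` pseudocount floor; ratios with
  $|r_j| < 10^{-12}$, stiffness-scale denominators below $10^{-12}$, and
  nodes with no defined neighbour term are undefined (`NA`), never zero.
* Pseudo-P of exactly 0 is kept (matching the $N_1/N$ definition); the
  add-one convention is opt-in.
* Zero-variance taxa get zero correlations plus a flag rather than `NA`,
  so one degenerate taxon cannot poison a whole matrix.

## Problem sizes and known limitations

The test suite exercises closed-form identities on 8-node instances,
brute-force oracle equivalence on at least 100 random instances of up to 15
nodes, null calibration at the default study conditions (40 taxa, 30 + 30
samples, 500 permutations, 20 replicates), and planted-signal recovery over
5 replicates at the same size; an end-to-end pipeline determinism check
runs at 15 taxa. These sizes were chosen so the whole suite completes in a
few minutes while keeping the calibration claims at the stated study
conditions.

Two limitations deserve emphasis. First, per-taxon power for *pure*
relationship alterations is low: when marginal means are held equal, the
relative changes $r_i$ entering $G$ are sampling noise, and the null spread
of $\log I_i$ (driven by $\log |r_i|$, standard deviation above one log
unit) dominates the degree contrast that the rewiring induces (about
$\log 2$). In our recovery experiments the planted taxa show consistently
shifted pseudo-P values in the expected direction, but rarely reach
FDR-corrected significance at these sample sizes — detecting
mean-preserving rewiring reliably needs either larger cohorts or a
statistic less exposed to the $1/|r_i|$ factor. On real data, where
abundance shifts accompany rewiring, the parameters are far more
responsive. Second, stability above 1 and heavy-tailed impact values are
intrinsic to ratio-based perturbation matrices; summaries should prefer
medians or the permutation framework over raw means when distributions are
extreme.
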