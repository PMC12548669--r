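---
title: "Stable metabolic brain networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable metabolic brain networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabmbn)
```

## The problem

Metabolic brain networks (MBNs) describe the coupling between brain regions
as a weighted graph: nodes are predefined volumes of interest (VOIs), and an
edge weight is the Pearson correlation, *across subjects of a group*, between
the standardized uptake value ratios (SUVR) of two VOIs measured with
FDG-PET. Because each group yields a single correlation matrix, the
conventional construction — one correlation pass over the full group table,
followed by a multiple-comparison correction — is at the mercy of every
subject in the table. A handful of atypical subjects (mislabelled diagnoses,
scanner artefacts, borderline cases) can visibly rewire the group network,
and group comparisons inherit that fragility.

`stabmbn` implements a multiple-sampling (MS) construction designed to
produce group networks that are insensitive to small contaminations of the
subject table, together with the machinery needed to *measure* that
insensitivity.

## The multiple-sampling construction

Given a group table \(X \in \mathbb{R}^{N \times d}\) (N subjects, d VOIs),
the MS scheme:

1. draws \(n\) random samples \(Y^1, \dots, Y^n\) of the subjects —
   bootstrap (N rows with replacement) or subsampling (a fraction of rows
   without replacement);
2. computes for each sample the Pearson adjacency matrix
   \(M^k = (r^k_{pq})\), with two-sided p-values from the exact
   t-transform \(t = r\sqrt{(N-2)/(1-r^2)}\) on \(N-2\) degrees of freedom,
   and applies Benjamini–Hochberg FDR at level \(\alpha\) to the
   \(d(d-1)/2\) edge p-values, zeroing non-surviving weights;
3. selects one member of the ensemble \(\Phi = \{M^1,\dots,M^n\}\) as the
   group representative:
   \[ M = \arg\min_{1\le k\le n} \lVert M^k - \bar M \rVert_F \]
   under the **mean** criterion (\(\bar M\) the elementwise mean matrix),
   with the elementwise median matrix for the **median** criterion, or the
   maximum-density member for the **mode** criterion;
4. optionally applies a second, occurrence-based threshold: the probability
   map \(\dot P_{pq}\) is the fraction of ensemble members in which edge
   (p,q) survives FDR, and edges of the representative with
   \(\dot P_{pq} \le \theta\) are removed (strict inequality retains), with
   \(\theta = 1 - \alpha\) by default. This "FDR + Pmap" correction is
   provably never less conservative than FDR alone, since it can only remove
   further edges from the FDR-corrected representative.

The representative is always an actual ensemble member, never a synthetic
average — an average matrix is not a network that any sample produced, and
its graph-theoretic properties can be unrepresentative (e.g. averaged weak
edges that no sample retains).

All of this is wrapped by the `mbn()` fitting function; the individual
stages (`build_ensemble()`, `select_representative()`, `compute_pmap()`,
`apply_pmap_threshold()`, `conventional_mbn()`) are exported for users who
need the pieces.

### The mode criterion

The mode ("maximum density") criterion requires a density estimate in the
space of \(d \times d\) matrices. We use a k-nearest-neighbour surrogate:
each member's density score is the negative mean Frobenius distance to its
\(\lceil\sqrt n\rceil\) nearest ensemble neighbours, and the member with the
highest score (smallest mean neighbour distance) is selected. A kernel or
Bayesian density model over matrices would require choices (bandwidth,
prior) that the data at typical ensemble sizes cannot support; the k-NN
surrogate is assumption-free, deterministic given the ensemble, and — as the
criteria-equivalence experiment shows — selects representatives whose
stability behaviour is indistinguishable from the mean and median criteria.
Ties in every argmin are broken by the lowest ensemble index, so selection
is fully deterministic.

## Measuring stability: the outlier attack

Stability is quantified by perturb-and-compare. An *outlier attack* appends
\(L = \mathrm{round}(P_o/100 \cdot N)\) rows (at least 1 when \(P_o > 0\);
the percentage-to-count map is a package choice) drawn from the two other
diagnostic groups — half from each, an odd row assigned by a seeded coin
flip — to the group's data. Cross-group rows are a realistic contamination:
metabolic patterns differ only subtly between adjacent diagnostic groups, so
such rows would not be flagged by univariate outlier screens.

The perturbed network is then rebuilt and compared with the original using
four distances:

* **dF** — Frobenius norm of the matrix difference;
* **dH** — Hausdorff distance between the two sets of matrix row vectors,
  \(d_H = \max\{h(M,\tilde M), h(\tilde M, M)\}\) with
  \(h(M,\tilde M) = \max_i \min_j \lVert m_i - \tilde m_j\rVert_2\).
  Rows rather than columns are used; by symmetry of the adjacency matrices
  the choice is immaterial;
* **dE**, **dC** — Euclidean and Canberra distances between the
  six-component graph-feature vectors \(f = [ge, ac, ad, as, d, acc]\)
  (global efficiency, degree assortativity, average degree, average
  strength, density, average clustering). Canberra terms with both
  components zero contribute 0 (standard convention).

Lower values mean higher stability. For the MS methods the unperturbed
reference is the group network as the scheme defines it: the FDR+Pmap
representative. Each attack appends the outlier rows to the
representative's *own source sample* \(Y^q\) (recovered from the ensemble's
recorded sample indices), reruns Pearson + FDR at the same \(\alpha\), and
masks the result with the *same* threshold matrix \(\dot T\) that defines
the reference — no new ensemble is built. Freezing \(\dot T\) is the point:
the question the attack answers is how much the group network, as
delivered, moves when its data are contaminated, and the occurrence
threshold is part of the network's definition, exactly as FDR is part of
the conventional network's definition (the conventional side appends the
same rows to the full table \(X\) and reruns Pearson + FDR). A zero-outlier
attack reproduces the reference exactly for both methods (all four
distances identically 0), which the tests assert. An alternative protocol —
comparing FDR-only networks on both sides — measures the stability of the
*uncorrected* representative instead; it discards the occurrence threshold
that the scheme introduces, and with it most of the scheme's resistance to
contamination.

### Graph measures: variant choices

The feature measures follow the standard complex-network definitions with
these conventions, all of which matter only at the margins:

* shortest-path lengths for global efficiency use \(1/|w|\) as edge length,
  so strong correlations (of either sign) are short edges; disconnected
  pairs contribute 0;
* degree, clustering and assortativity are computed on the binarized
  surviving-edge graph; average strength uses absolute weights;
* an empty graph has \(ge = ad = as = d = acc = 0\); assortativity is
  undefined on graphs with zero degree variance and is reported as 0 with a
  warning and a flag attribute.

Shortest paths, local clustering and assortativity are delegated to
`igraph`; the test suite verifies all six measures against an independent
brute-force implementation (Floyd–Warshall, direct triangle counting,
endpoint-degree correlation).

## Imbalance handling

Diagnostic groups are rarely equal-sized. Two balancing strategies are
provided ahead of network construction:

* `undersample_groups()` removes random rows from the larger groups until
  all match the smallest (no synthetic data, loses subjects);
* `adasyn_oversample()` grows minority groups to the majority size with
  ADASYN: each minority point receives a synthetic-generation budget
  proportional to the fraction of other-group points among its k nearest
  neighbours (k = 5 by default), and each synthetic subject is
  \(x_i + \lambda(x_z - x_i)\), \(\lambda \sim U(0,1)\), with \(x_z\) a
  random same-group point among \(x_i\)'s k nearest minority neighbours.
  Every synthetic row therefore lies on a segment between two original
  same-group rows (a property the tests check geometrically), and synthetic
  rows are flagged. Budgets are apportioned by largest fractional part so
  the balanced size is met exactly.

## Choosing the ensemble size

`tune_n()` selects \(n\) by convergence of the representative's degree
distribution: for each candidate \(k\) it builds independent representatives
at \(n = k\) and \(n = k + 100\) (fresh derived seeds) and computes the
Bhattacharyya distance \(d_B = -\ln\sum_i \sqrt{p_i q_i}\) between their
degree histograms; the selected \(n\) minimizes \(d_B\), and the full trace
is returned for plotting. Degree histograms always share the integer bins
\(0 \dots d-1\), and weight histograms use 100 equal bins on \([-1, 1]\), so
distances are well defined across runs. Disjoint-support histogram pairs
(Bhattacharyya coefficient 0) are reported as the finite sentinel 700,
keeping traces plottable. The default grid \(k \in \{100, \dots, 9900\}\)
covers the full operating range; the trace decays roughly monotonically, so
a shortened grid (e.g. up to 1000) locates the convergence regime at a
fraction of the cost. The comparison uses the representative network's
degree distribution — one network per \(n\) — rather than pooling
distributions across ensemble members; pooling would mix sampling
variability into the criterion that representative selection is designed to
remove.

## The synthetic cohort generator

`generate_cohort()` exists so the full pipeline is testable without clinical
data. It draws each group from a multivariate normal whose correlation
matrix is block-constant: VOIs are partitioned into `n_blocks` modules with
correlation `rho_in` inside a module and `rho_out` between modules
(`0 <= rho_out <= rho_in < 1` guarantees positive semi-definiteness by
construction, since the matrix decomposes into nonnegative combinations of
block one-matrices and the identity). Group contrasts are mean SUVR offsets
per block; values sit on a positive baseline rather than being truncated,
because truncation would distort the very correlations the package
estimates.

Defaults, fixed once: `d = 72` VOIs in 6 modules; `rho_in = 0.6`,
`rho_out = 0.2` (interregional FDG-PET SUVR correlations are moderate to
strong within functional systems and weak-to-moderate between them);
`noise_sd = 0.1` around a baseline of 1.2, a plausible pons-referenced SUVR
scale; group sizes 352/641/234 mirroring the imbalance typical of
Alzheimer's-continuum cohorts; and graded hypometabolism offsets (0, −0.04,
−0.08) on the first half of the blocks for the successive groups, echoing
the reduced cortical uptake seen along the disease continuum.

What the generator does *not* emulate: PET image noise and partial-volume
effects, scanner/site harmonization, non-Gaussian tails, covariate-driven
structure (age/sex covariates can be attached but do not influence the SUVR
draw), and realistic outlier geometry — attacks transplant real cross-group
rows instead of modelling outlier shape, exactly as the stability protocol
defines them. Passing tests therefore demonstrate correctness of the
machinery and the directional behaviour of the method under a known
generative model, not clinical performance on real cohorts.

## Numerical choices and degenerate inputs

* Pearson p-values use the exact t-transform; \(r^2\) is clamped below 1 so
  perfectly collinear columns give \(p \to 0\) rather than NaN.
* Zero-variance VOI columns make the correlation undefined; they are
  rejected with the VOI named. Bootstrap draws that produce a zero-variance
  column (possible only at tiny N) are redrawn up to 100 times — preserving
  the ensemble size without biasing typical draws — then error.
* Missing SUVR values are rejected at validation with the offending cells
  named; imputation is upstream of this package's contract.
* The Hausdorff cross-distance matrix is computed by explicit row
  differencing rather than the usual Gram-matrix expansion: the latter loses
  ~8 digits on identical rows, and the zero-outlier no-op property is worth
  the marginal cost.
* All randomness flows through explicit integer seeds; multi-stage
  procedures derive per-stage seeds from one master seed with a fixed
  integer hash (modulo \(2^{31}-1\)), recorded in run manifests, so one
  number reproduces an entire experiment bit for bit.

## Problem sizes used in the validation suite

The package's own experiments (test suite and the acceptance script) run the
protocol at desk scale, chosen so the full suite completes in minutes while
preserving every qualitative contrast: 3-group cohorts of 150 subjects per
group (100/200/70 for the imbalance scenarios) with d = 30 VOIs in 6 blocks;
ensembles of n = 500 (300 for the size sweep); 64 attacks per condition (32
in the size sweep); size grid ns ∈ {10, 15, …, 100}; tuning grid
k ∈ {100, …, 1000}. The attack experiments run at α = 0.01: at d = 30 and
N ≤ 150 the stricter levels used on full-size cohorts leave the FDR
networks degenerate (exact disjoint cliques, or empty at small N), a floor
that hides the stability contrasts the experiments exist to measure; the
tuning experiment has no such degeneracy and runs at α = 10⁻⁴. The
operating defaults of the exported functions (n = 9300, 256 attacks, ns up
to 200, k up to 9900) reflect the scale at which the method is used on real
cohorts.

## Known limitations

* Pearson correlation only; partial/Spearman correlation or mutual
  information would slot into the same scheme but are not implemented.
* At very small subject counts the probability-map mask empties out — no
  edge can recur in >99% of resampled networks that barely clear FDR — so
  the MS network below roughly 30–60 subjects (at desk-scale d and the
  generator's correlation strengths) is empty and its stability is vacuous.
  The size-sweep behaviour seen on real cohorts, where even 10-subject
  networks are dense and unstable, requires correlation strengths the
  block-constant generator deliberately keeps moderate; the validation
  suite records this as an expected failure of the size-convergence
  experiment rather than hiding the regime.
* The mode criterion is a k-NN density surrogate, not a posterior mode.
* The attack model is row transplantation between groups; node- or
  edge-deletion attacks are out of scope.
* ANOVA-style significance summaries over attack distributions are left to
  general statistics tooling; `write_stability_report()` emits tidy
  per-attack tables for exactly that purpose.
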