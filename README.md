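# stabmbn — stable metabolic brain networks via multiple sampling

`stabmbn` builds group-level **metabolic brain networks (MBNs)** from PET
SUVR tables and makes them *stable*: insensitive to the handful of atypical
subjects that can rewire a conventionally constructed network.

An MBN is a weighted undirected graph whose nodes are brain volumes of
interest (VOIs) and whose edge weights are intersubject Pearson correlations
of SUVR values within a diagnostic group. The conventional construction —
one correlation pass over the group table \(X \in \mathbb{R}^{N \times d}\),
then FDR correction — hands every subject a vote in every edge. This package
implements a **multiple-sampling (MS) scheme** instead:

1. draw *n* bootstrap (or subsample) datasets \(Y^1,\dots,Y^n\) from \(X\);
2. build a Pearson correlation network \(M^k\) per sample, with edge
   p-values from the exact t-transform \(t = r\sqrt{(N-2)/(1-r^2)}\) and
   Benjamini–Hochberg FDR at level \(\alpha\);
3. select the representative \(M = \arg\min_k \lVert M^k - \bar M\rVert_F\)
   (mean criterion; median and maximum-density "mode" criteria available);
4. threshold the representative by the edge **probability map**
   \(\dot P_{pq}\) (the fraction of ensemble networks in which the edge
   survives FDR), retaining edges with \(\dot P_{pq} > \theta = 1 - \alpha\).

Around this core the package provides the full experimental apparatus:
**outlier attacks** (appending cross-group subject rows, half from each
comparison group) with four stability distances (Frobenius and Hausdorff
over matrices; Euclidean and Canberra over the graph-feature vector
\(f = [ge, ac, ad, as, d, acc]\)); group-size balancing by **random
undersampling** and **ADASYN** oversampling; ensemble-size tuning by
**Bhattacharyya-distance** convergence of degree distributions; a synthetic
block-correlated SUVR cohort generator; and a YAML-driven pipeline runner
with reproducible seed manifests.

Intended users: neuroimaging groups deriving group connectivity from FDG-PET
(or any radiotracer) SUVR tables, and methodologists studying the robustness
of intersubject correlation networks.

## Worked example

```r
library(stabmbn)

# a synthetic 3-group cohort: 150 subjects/group, 30 VOIs in 6 blocks
spec <- cohort_spec(n_subjects = c(CU = 150, MCI = 150, AD = 150),
                    d = 30, n_blocks = 6)
cohort <- generate_cohort(spec, seed = 3)

# fit the group network with the MS bootstrap scheme
fit <- mbn(cohort$CU, method = "bootstrap", n = 500, alpha = 0.01, seed = 5)
summary(fit)
#> Metabolic brain network fit
#>   method: bootstrap (n = 500, criterion = mean), alpha = 0.01, theta = 0.99
#>   MBN: 30 VOIs, 61 edges (density 0.140), correction: fdr+pmap (alpha = 0.01)
#>   graph features:
#>     ge  = 0.0926
#>     ac  = 0.1286
#>     ad  = 4.0667
#>     as  = 2.3823
#>     d   = 0.1402
#>     acc = 0.9733
```

The fit retains 61 of 435 possible edges: the probability-map stage keeps
only edges that survive FDR in more than 99% of the 500 resampled networks,
so what remains is essentially the reproducible within-module correlation
structure (density 0.140 against a generative within-block density of
0.138 — 6 blocks of 5 VOIs). The near-unity clustering (`acc` 0.97)
reflects the resulting modular, clique-like topology.

How much more stable is this network than the conventional one under
contamination? Attack both with 2% cross-group outliers, 64 times:

```r
ms <- run_attack_experiment(cohort$CU, cohort$MCI, cohort$AD,
                            method = "ms_bootstrap", p_o = 2, q_attacks = 64,
                            n = 500, alpha = 0.01, seed = 9)
conv <- run_attack_experiment(cohort$CU, cohort$MCI, cohort$AD,
                              method = "conventional", p_o = 2,
                              q_attacks = 64, alpha = 0.01, seed = 9)
ms
#> Stability report: ms_bootstrap, P_o = 2% (L = 3 of N = 150), 64 attacks
#>  metric     mean       sd
#>      dF 0.085880 0.026970
#>      dH 0.032860 0.012830
#>      dE 0.012110 0.008702
#>      dC 0.004885 0.003497
conv
#> Stability report: conventional, P_o = 2% (L = 3 of N = 150), 64 attacks
#>  metric   mean      sd
#>      dF 1.4170 0.32800
#>      dH 0.4764 0.09203
#>      dE 0.8311 0.72680
#>      dC 0.3316 0.20840
```

Each row summarizes a distance between the unperturbed network and its
64 attacked recomputations; lower is more stable. The MS network moves an
order of magnitude less than the conventional one on every measure.

Choosing the ensemble size, and balancing groups before construction:

```r
tuned <- tune_n(cohort$CU, k_grid = seq(100, 1000, by = 100),
                alpha = 1e-4, seed = 4)
plot(tuned)                       # Bhattacharyya decay trace
balanced <- undersample_groups(cohort, seed = 2)        # or
oversampled <- adasyn_oversample(cohort, seed = 2)
```

A command-line front end over the same functions lives at
`inst/cli/mbn.R` (subcommands `pipeline`, `build`, `attack`, `tune`), and
`run_pipeline("experiment.yaml")` executes multi-stage experiments with a
JSON manifest of seeds and output checksums.

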