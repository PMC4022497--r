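# ecrflip

Energy centrality classification of protein–protein interfaces.

## The problem

Most protein–protein interfaces deposited in the PDB come from X-ray
crystallography, and a crystal lattice creates many chain–chain contacts that
never exist in solution. Telling a **FLIP** (functionally linked interface of
proteins — one whose mutation or modification is known to alter biological
function) apart from a **FunC** (functionally uncorrelated contact, typically
a crystal-packing artefact) from coordinates alone is a long-standing
annotation problem for structural biologists, docking practitioners and
anyone curating quaternary-structure assignments.

`ecrflip` implements the *energy centrality relationship* (ECR) approach:
functional interfaces tend to concentrate their energetically important
residues near the interface centre, while crystal contacts do not. The
package takes per-residue computational alanine-scanning energies (ΔΔG, in
kcal/mol, produced by an external scan — the package does not compute them)
together with the structure, and turns each interface into a small feature
vector that an unsupervised two-round clustering separates into FLIP-like
and FunC-like groups.

## The method

For an interface between two chains (residues in contact through any heavy
atom pair within a cutoff, default 4.0 Å):

- the **centre of interface** (CoI) is the mean of the interfacial Cα
  positions, and each residue's displacement is
  `Δr = ‖x_Cα − CoI‖`;
- an ordinary least-squares fit of `ΔΔG = slope·Δr + intercept` summarises
  the radial organisation of the energetics (FLIPs: positive intercept,
  negative slope);
- eight features describe the interface: `slope_ddg`, `intcpt_ddg`,
  `r2_ddg`, `sum_ddg`, `avg_ddg`, `n_total`, `n_hot` (residues with
  ΔΔG > +1 kcal/mol) and `frac_hot = n_hot / n_total`.

Classification drops `r2_ddg`, z-scores the remaining seven features,
performs a correlation-matrix PCA, and runs k-means (k = 2) on the
(PC1, PC2) scores. The cluster whose centroid maps back to high
`sum_ddg + n_hot + avg_ddg` is designated FLIP and removed; a second PCA +
k-means round on the remainder recovers the weaker FLIPs. Performance is
reported as accuracy `(TP+TN)/N` and the Matthews correlation coefficient

```
MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))
```

New interfaces are projected through the trained components (training means,
standard deviations, eigenvectors and centroids) without refitting.

## Worked example

Everything below is runnable without external data: the synthetic generator
emits FLIP-like interfaces (disc-shaped residue patches whose ΔΔG decays
linearly with distance from the centre) and FunC-like ones (no radial trend,
lower overall ΔΔG).

```r
library(ecrflip)

ds  <- generate_dataset(n_flip = 100, n_func = 60, seed = 1)
fit <- ecr_fit(ds$features, seed = 1)
summary(fit)
#>                    TP   FP   FN   TN   Accuracy    MCC
#> 1st clustering     51    0   49   60      69.4%   0.53
#> 2nd clustering     38    3   11   57      87.2%   0.75
#> Total              89    3   11   57      91.3%   0.82
```

Round 1 isolates a high-confidence FLIP cluster (51 interfaces, no false
positives here); round 2 re-clusters the remaining 109 and recovers most of
the weaker FLIPs, for an overall training accuracy of 91.3% and MCC 0.82
against the generator's true labels. Projection of a fresh dataset through
the trained model:

```r
holdout <- generate_dataset(100, 60, seed = 2)
mean(predict(fit, holdout$features) == holdout$features$category)
#> [1] 0.85
```

Feature computation for a single synthetic interface:

```r
s <- generate_flip(ecr_sim_params(n_residues = 20), seed = 5)
round(compute_features(s$interface)[, 4:11], 3)
#>   slope_ddg intcpt_ddg r2_ddg sum_ddg avg_ddg n_total n_hot frac_hot
#> 1    -0.169      2.266  0.304  22.668   1.133      20    12      0.6
```

The negative slope and positive intercept are the ECR signature: the centre
of this interface is hot and the rim is not. Confusion-count metrics can
also be used stand-alone:

```r
print(confusion_counts(tp = 49, fp = 1, fn = 51, tn = 59))
#> TP 49  FP 1  FN 51  TN 59  |  accuracy 67.5%, MCC 0.49
```

With real data the workflow is `read_structure()` → `find_interface()` →
`apply_exclusion_filters()` → `read_ddg_table()` + `attach_ddg()` →
`compute_features()`, or the equivalent shell interface
(`inst/scripts/ecr.R` with subcommands `features`, `train`, `predict`,
`evaluate`, `simulate`, `subsample`).

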