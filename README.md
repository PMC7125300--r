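# attractorscape

Attractor-landscape analysis of rapid transcriptome-wide state
transitions from time-course RNA-seq.

## What it is for

When a cell population switches physiological state — the motivating
system is *E. coli* transitioning from anaerobic to aerobic growth within
the first ten minutes of aeration, sampled at 0, 0.5, 1, 2, 5 and 10
minutes with three replicates — thousands of transcripts move at once.
Instead of selecting genes above an arbitrary fold cut-off, this package
asks the dynamical-systems question: which fraction of the transcriptome
moves *coherently*, as a trajectory converging into the basin of the new
stable state (the attractor), and which fraction merely drifts?

It is aimed at computational biologists analysing dense early time
courses of bulk RNA-seq (counts in, gene sets out), and at methodologists
who want a fully seeded, testable implementation of deviation-correlation
attractor analysis with a synthetic benchmark generator.

## The method in brief

Counts are TPM-normalised and filtered (genes above 5 TPM; lognormality
of the abundance distribution is checked by maximum-likelihood fits of
lognormal, Pareto, Burr XII, log-logistic, Weibull and gamma, ranked by
AIC; the top-2 extreme expressors are removed). For each replicate the
deviation vector at time *t* is

> v_j(t_i) = x_j(t_i) − x̄_j

and two statistics compare it with the initial state:

* **R_v** = V(t_i)·V(t_0) / (|V(t_i)||V(t_0)|) — the cosine of the
  deviation vectors;
* **MI_v** = MI(V(t_i), V(t_0)) / MI(V(t_0), V(t_0)) — histogram mutual
  information on K = 10 rank bins, bias-corrected by subtracting the
  minimum MI over 100 permutations, normalised to 1 at t_0.

Random 100-gene ensembles traced through (R_v, MI_v) space define a
superimposed kernel-density landscape; the attractor basin is the closed
iso-contour at the mean inflection level around the major density peak.
Genes ranked by temporal variability are cut into 100-gene transcriptomic
elements; elements whose trajectories end in or above the basin — plus
"pseudo-attractor" elements that individually fall below but collectively
re-enter the basin — make up the attractor gene set. The set is validated
by PCA sample trajectories and decomposed into temporal groups by Ward
clustering with correlation-threshold (r ≥ 0.7) refinement, then compared
with the conventional 2-fold-change selection.

Transcriptome-wide temporal correlations (Pearson, Spearman, biweight
midcorrelation, and MI_c = √(1 − e^(−2·MI))) are available alongside.

A seeded synthetic generator (`generate_timecourse()`) produces count
matrices with lognormal baselines, six planted temporal pattern families,
a configurable coherently-changing fraction, flat no-response genes, two
extreme-expression outlier genes, and ground-truth labels — so the whole
pipeline is covered by recovery tests.

## Worked example

```r
library(attractorscape)

cfg  <- synthetic_config(n_genes = 2000, seed = 1)
pcfg <- pipeline_config(synthetic = cfg, ensemble_repeats = 60,
                        ranking = "fold_change", seed = 1)
res  <- run_pipeline(pcfg)
print(res)
#> PipelineResult
#>   genes: 2000 input -> 1978 above threshold -> 1976 analysed
#>   elements: 20 (6 above / 5 in / 9 below basin)
#>   attractor 1100 (core 1100 + pseudo 0), non-attractor 876,
#>   no-response 7, collective non-attractor 869 (56% attractor)
```

2000 synthetic genes were generated with half of them planted as
coherent responders; 22 fell below the 5 TPM filter and the two planted
outlier genes were removed. Of the 20 ranked elements, 11 end in or above
the attractor basin, yielding 1100 attractor genes (56% of the analysed
transcriptome). Comparing with the ground truth:

```r
truth    <- res$truth
true_att <- intersect(truth$gene_id[truth$is_attractor], res$expr$gene_ids)
rec      <- res$gene_sets$attractor
length(intersect(rec, true_att)) / length(union(rec, true_att))
#> [1] 0.905
```

— the recovered set overlaps the planted coherent set at Jaccard 0.91.
A single gene set's deviation trajectory shows the convergence the basin
captures (start at (1, 1), rapid decay, then little late movement):

```r
correlation_trajectory(res$expr, res$expr$gene_ids[1:100], seed = 1)
#>   time_min     rv   miv
#>        0.0  1.000 1.000
#>        0.5 -0.227 0.277
#>        1.0 -0.808 0.248
#>        2.0 -0.861 0.228
#>        5.0 -0.852 0.310
#>       10.0 -0.743 0.324
```

Stage outputs (gene sets, element labels and distances, boundary
polyline, correlation series, JSON summary) are written by
`run_pipeline(pcfg, output_dir = "out/")`.

See `vignettes/attractor-landscape-methods.Rmd` for the model, every
tunable threshold, the synthetic-data design and known limitations.

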