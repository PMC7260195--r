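# cytoHybrid

Template-driven automated gating and hybrid immunophenotyping validation
for flow cytometry, in R.

## The problem

Immunophenotyping of large population studies means gating the same ~dozens
of cell populations in thousands of FCS files. Purely manual gating is slow
and analyst-dependent; purely automated gating fails quietly on rare
subsets. cytoHybrid implements the *hybrid* middle ground for analysts and
pipeline engineers running such studies:

1. **Automated hierarchical gating** from a plain-CSV template. Each row
   fits one gate on its parent population: 1D density-valley cuts
   (Gaussian KDE; with peaks at heights ≥ `min_peak_height`·max, the cut is
   the density minimum between the two tallest peaks), quadrants that
   partition the parent exactly, fixed rectangles, FSC-A/FSC-H singlet
   bands (`h ≈ βa`, `β = median(h/a)`, keep |residual| ≤ 4·MAD), and
   boolean combinations. Gate failures tag the subtree
   (`needs_manual_refinement`, `low_cell_count`) instead of aborting.
2. **A three-marker k-means T-cell subset caller**: z-score (CCR7, CD45RA,
   CD28) over the pooled CD4⁺/CD8⁺ T cells, Lloyd's k-means with k = 4
   (k-means++, 10 seeded restarts), label clusters ± per marker by the two
   highest cluster medians, map (CCR7, CD45RA) signs to
   naive / central memory / effector memory / effector, split by parent
   into eight populations — and **flag the sample for manual gating** when
   clusters cannot be mapped onto the targeted phenotypes.
3. **Batch review**: pre-generated per-gate PNGs, a latest-wins annotation
   store (good / bad / needs_manual_refinement / low_cell_count), and the
   derived hand-off list of (sample, gate) pairs routed to manual work.
4. **Validation statistics** against a manual gold standard, per
   population: Pearson r with Fisher-z 95% CI; percent bias
   `100·(mean(hybrid) − mean(manual))/mean(manual)` with bootstrap CI;
   mean (absolute) difference; event-level F-measure
   `F = 2TP/(2TP + FP + FN)`; >3 SD outlier sensitivity; the strict
   r > 0.75 roll-out gate; and inter/intra-technician intraclass
   correlation `ICC = σ²_inter/(σ²_inter + σ²_intra)` from a REML mixed
   model of repeated controls (controls fixed, technician random).
5. **A synthetic-data generator** (hierarchical Gaussian mixtures with
   ground truth, doublets, dead cells, paired method noise, technician
   variance designs) so the whole pipeline is testable end to end.

See `vignettes/hybrid-gating-methods.Rmd` for the full model description,
parameter meanings and known limitations.

## Worked example

Simulate one 20,000-event sample, gate it with the shipped template (a
synthetic reconstruction of a standard immunophenotyping hierarchy), and
print the population table:

```r
library(cytoHybrid)
sim <- generateSample(defaultPanelSpec(), seed = 7)
tpl <- parseGatingTemplate(system.file("extdata", "hip_template_synthetic.csv",
                                       package = "cytoHybrid"))
applyTemplate(sim$events, tpl, wbc = sim$wbc)
```

```
GatingResult 'sim007': 20000 events, 20 populations (0 errored)
  singlets                 parent=root         count=19400 pct_of_parent=97.00
  live                     parent=singlets     count=18400 pct_of_parent=94.85
  lymphocytes              parent=live         count=11002 pct_of_parent=59.79
  Tcells                   parent=lymphocytes  count=6054 pct_of_parent=55.03
  Bcells                   parent=lymphocytes  count=1655 pct_of_parent=15.04
  NK                       parent=lymphocytes  count=1618 pct_of_parent=14.71
  monocytes                parent=live         count=4043 pct_of_parent=21.97
  ...
  CD4_naive                parent=CD4          count=1422 pct_of_parent=39.15
  CD4_central_memory       parent=CD4          count=914 pct_of_parent=25.17
```

Reading the output: 97% of events survive doublet exclusion and 94.85% of
those are viable; T cells are 55.03% of lymphocytes (the generator's truth
is 55%); the k-means caller recovers the CD4 memory subsets near their
true 40/25/25/10% composition. `pct_of_parent` is each population as a
percentage of its immediate ancestor; with a white-blood-cell count the
result also carries absolute counts (fraction of total × WBC, 10⁹
cells/L).

The statistics battery recovers a known −15% hybrid bias from simulated
paired counts:

```r
p <- generatePairedCounts(true = c(Tcells = 1.2), bias = 0.85,
                          nSamples = 200, seed = 1)
round(percentBias(p), 2)
#>   bias     lo     hi
#> -14.75 -15.67 -13.83
round(pearsonCI(p), 3)
#>     r    lo    hi
#> 0.964 0.953 0.973
```

A thin command-line wrapper ships in `inst/scripts/hybridcyto`
(subcommands `gate`, `subsets`, `validate`, `simulate`) over the same
functions (`cmdGate()`, `cmdSubsets()`, `cmdValidate()`, `cmdSimulate()`).

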