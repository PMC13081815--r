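# adaptscales

Cells integrate many environmental cues at once, and their transcriptomes
encode those cues at different statistical scales: a dominant, shared
stress-response program rides the leading principal components, while
individual cues — carbon source, media composition, osmolarity, temperature,
oxidative stress — surface in progressively deeper components. `adaptscales`
is an R toolkit for quantifying that organization from single-cell RNA-seq
ensembles and for the companion measurements that connect it to physiology.
It is written for computational biologists analyzing multi-condition
single-cell experiments and for quantitative labs measuring stress
prioritization in microbes.

## What it computes

**Spectral mutual-information profiling (SCALES).** Given the SVD/PCA of the
log-normalized expression matrix `X` (cells × genes, gene-centered), with
cell scores `U diag(s)` and variance fractions `f_k = s_k² / ‖X‖²_F`, the
procedure slides a window `w` of 3 consecutive components across the
spectrum and computes, for a shared sample of cell pairs `(i, j)`, the
spectral correlation

```
c_w(i, j) = ⟨ proj_w(i), proj_w(j) ⟩ ,   proj_w(i) = U[i, w] · diag(s[w])
```

and the plug-in mutual information (bits, 16 equal-frequency bins)

```
MI_w(v) = Σ_{b,y} p(b, y) log₂ [ p(b, y) / ( p(b) p(y) ) ]
```

between the binned correlations `b` and the indicator `y` of whether cells
`i` and `j` share the same value of environmental variable `v`. The running
sum of `MI_w` is the cue's MI(CDF) curve; the window where its normalized
version reaches 0.5 is the cue's **spectral depth**, and variables ordered
by depth form the adaptation **hierarchy**. Significance is judged against a
per-condition permutation null that reassigns labels across sample blocks.

**Dual-stress epistasis.** From bulk counts over a 2×2 heat/salt design
(log2 CPM, pseudocount 1, replicate-averaged), the deviation of each gene's
dual-stress response from log-additive independence:

```
deviation = lfc_dual − (lfc_heat + lfc_osmo)
```

summarized by gene-set medians, plus condition correlations and
between-strain concordance (Pearson R²).

**Physiology.** Polysome-to-monosome ratios from integrated A260 trace
regions; maximum specific growth rates as the largest OLS slope of ln(OD)
over sliding windows; competitive-fitness selection coefficients as the OLS
slope of ln(test/reference) counts per day.

**Synthetic data with ground truth.** Generators for multi-condition
ensembles with cues planted at chosen spectral depths, bulk designs with
controlled interaction terms, absorbance traces with known peak areas,
growth curves and competition series — every analysis stage is testable
against planted truth.

## Worked example

Simulate a three-cue ensemble with signals planted at components 2, 6 and
10, run the pipeline, and recover the planted hierarchy:

```r
library(adaptscales)

sim <- simulate_scrna(synthetic_spec(
  seed = 42, n_genes = 400, cells_per_condition = 40,
  cues = list(
    list(name = "carbon",      levels = 2, depth = 2,  effect = 1.0),
    list(name = "osmolarity",  levels = 3, depth = 6,  effect = 0.6),
    list(name = "temperature", levels = 2, depth = 10, effect = 0.45)),
  n_components = 12))

cm <- qc_filter(sim$counts)
#> count_matrix: 480 cells x 397 genes
#>   nonzero entries: 135349
#>   samples: 12

d <- decompose(normalize_log(cm), K = 12)
#> spectral_decomposition: K = 12 components, 480 cells x 397 genes (gene-centered)
#>   variance explained by retained components: 22.52%

res <- scales_analysis(d, c("carbon", "osmolarity", "temperature"),
                       max_pc = 12, n_perm = 50, seed = 42)
res$hierarchy
#> hierarchy_ranking (depth threshold 0.5 ):
#>     variable depth   total_mi rank undefined_depth
#>       carbon     1 0.52103476    1           FALSE
#>   osmolarity     7 0.03636793    2           FALSE
#>  temperature     8 0.02570388    3           FALSE
```

The carbon signal, planted shallowest with the largest effect, reaches half
of its cumulative MI within the first window; osmolarity and temperature
rise in deeper windows, in the planted order. Each profile in
`res$profiles` carries per-window MI in bits, the cumulative curve, and the
permutation-null mean and 95th-percentile envelope.

The same stages run from a single configuration file:

```r
run_pipeline("run.yaml")   # preprocess -> svd -> scales (+ epistasis, physiology)
```

writing per-variable MI tables, a hierarchy JSON, a filter report and a
reproducibility manifest; `inst/cli/adapt.R` wraps this and the physiology
readers for shell use.

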