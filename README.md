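# tradistat

Downstream analysis of **saturated transposon insertion libraries**
(TraDIS / Tn-seq) in R, for microbiologists who have mapped their
transposon–genome junctions and want per-gene essentiality calls plus the
comparative analyses that usually follow them: cross-species essentiality,
taxonomic conservation, paralog families, and phyletic profiles.

## The statistic at the core

For each annotated feature the **insertion index** is

```
x_g = (unique insertion sites within the gene) / (gene length in bp)
```

In a saturated library its genome-wide distribution is bimodal: a spike
at/near zero (essential genes) and a broad mode around the library's
dispensable-sequence density (~1 unique site per 11 bp). `tradistat` fits
an exponential distribution to the low section of the axis (below 0.013,
closed-form MLE λ̂ = n/Σx) and a gamma distribution to the non-essential
section ([0.022, 0.25], numerical MLE), then scores every gene by

```
s(x) = log2( f_exp(x; λ̂) / f_gamma(x; k̂, θ̂) )
```

calling it **essential** if `s > log2(12)`, **non-essential** if
`s < −log2(12)`, and **unclear** otherwise. A sliding 300 bp window
(step 150 bp) then rescues genes in which only a protein domain is
intolerant of insertions: unclear/non-essential genes containing an
insertion-free window are relabelled **domain_essential**.

Around that core the package provides BLAST-tabular filtering
(E ≤ 1e-5, coverage ≥ 70%), bidirectional-best-hit orthology with a
runner-up paralogy margin, cross-species essentiality agreement tables,
nested taxonomic conservation summaries, paralog clustering via
second-order similarity neighbours (60% length rule; 0.1/0.2 self-score
bit-score rule depending on COG sharing; 20% membership rule), phyletic
presence/absence matrices with complete-linkage/Euclidean ordering — and
a seeded synthetic-library simulator with known ground truth that the
entire test suite is built on.

Everything takes a data frame first and returns tibbles, so stages chain
with the pipe; fitted objects have `tidy()`/`glance()`/`autoplot()`
methods.

## Worked example

```r
library(tradistat)
library(dplyr)

lib <- simulate_library(sim_config(seed = 42))   # 2000 genes, 15% essential
res <- run_essentiality_pipeline(
  lib$annotation, lib$insertions,
  replicon_lengths = setNames(lib$genome_length, "sim_chr"))

res$fit
#> Insertion-index mixture fit
#>   exponential rate: 20486.1  (n = 302, index < 0.013)
#>   gamma shape 52.39, scale 0.001727 (mean 0.0905)  (n = 1698, [0.022, 0.25])
#>   excluded: 0 transition, 0 above high cutoff

count(res$calls, label)
#> # A tibble: 3 × 2
#>   label                n
#>   <chr>            <int>
#> 1 domain_essential    20
#> 2 essential          300
#> 3 non_essential     1680
```

The fitted gamma mean (0.0905) is the library's dispensable insertion
density — one unique site per ~11 bp — and the exponential component
absorbs the near-zero indices of essential genes. Against the simulator's
planted truth, every label is recovered:

```r
left_join(res$calls, lib$truth, by = "feature_id") |>
  count(truth_label, label)
#> # A tibble: 3 × 3
#>   truth_label      label                n
#>   <chr>            <chr>            <int>
#> 1 domain_essential domain_essential    20
#> 2 essential        essential          300
#> 3 non_essential    non_essential     1680
```

With real data the entry points are `read_annotation()` (GFF3 or feature
TSV), `read_insertions()` (per-position "plot" files, BED, or TSV) and
`read_blast_tabular()` (outfmt 6, ideally with `qlen`/`slen` appended);
`write_calls()` emits the per-gene result table. The methods vignette
(`vignettes/tradis-essentiality.Rmd`) documents the model, every tunable
parameter, and the design decisions.

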