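# hmcblocks

Consensus 5-hydroxymethylcytosine (5hmC) block analysis for two-cohort
(developmental) hydroxymethylome studies.

## What problem this solves, and for whom

5hmC enrichment sequencing yields per-sample peak calls that vary strongly
between individuals. For anyone analysing such cohorts (e.g. fetal versus
adult liver), the reproducible unit is the **5hmC block**: a maximal genomic
interval where at least *m* samples of a cohort show peak occupancy
(default *m* = 2). hmcblocks builds these blocks from per-sample BED files
and carries the downstream analysis chain:

* per-base support profiles, block calling and occupancy metrics
  (positive samples, summed peak bp, summed reads);
* peak-sharing classification across samples;
* cohort-only (fetal-only / adult-only) block derivation and cross-tissue
  bp overlaps;
* feature enrichment against a random-placement null, with fold
  enrichment

  fold = (observed overlap / block bp) / (feature bp / genome bp),

  analytically and by seeded permutation (empirical p = (r+1)/(n+1),
  two-sided);
* expression-level tertiles and developmental expression groups I–V
  (fetal-specific, ≥2-fold fetal, non-developmental, ≥2-fold adult,
  adult-specific);
* GREAT-style regulatory domains (basal 5 kb up / 1 kb down of the TSS,
  extended up to 1 Mb to the nearest basal domain) with the region-based
  binomial test P(X ≥ k), X ~ Bin(n, p₀ = domain bp / genome bp), the
  gene-based hypergeometric test, and Benjamini–Hochberg FDR;
* single-base TAB-Seq arithmetic: 5hmC = oxidized C/(C+T), 5mC =
  max(0, bisulfite ratio − oxidized ratio), interval means and
  NGS-vs-TAB-Seq concordance;
* a fully seeded synthetic-study generator with known ground truth, and a
  one-call pipeline (`run_pipeline()`) producing a machine-readable run
  report.

Everything is tibble-in / tibble-out (intervals as `chrom`/`start`/`end`,
0-based half-open) and composes with dplyr; result objects have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(hmcblocks)
library(dplyr)

st <- simulate_study(simulate_config(seed = 1))
fetal <- call_blocks(filter(st$peaks, cohort == "fetal"),
                     min_support = 2, genome = st$genome)
nrow(fetal)
#> [1] 148
sum(fetal$end - fetal$start)
#> [1] 279771

adult <- call_blocks(filter(st$peaks, cohort == "adult"),
                     min_support = 2, genome = st$genome)
sp <- cohort_specific_blocks(fetal, adult, genome = st$genome)
nrow(sp$a_only)   # fetal-only blocks
#> [1] 78

tidy(analytic_enrichment(fetal, st$features["cgi"], st$genome))
#> # A tibble: 1 × 5
#>   feature observed_bp expected_bp feature_fraction  fold
#>   <chr>         <dbl>       <dbl>            <dbl> <dbl>
#> 1 cgi           16949       4889.           0.0175  3.47

gr <- great_enrichment(sp$a_only, st$genes, st$terms, st$genome)
glance(gr)$top_term
#> [1] "T01"
```

The fetal cohort's 148 called blocks recover the 120 planted fetal blocks
(the extras are fragments and rare noise-supported runs); fold 3.47 says
CpG islands hold about three and a half times the block bases expected
under random placement (the generator plants that bias); and the
top-ranked term `T01` is the gene set whose members carry the planted
fetal-only blocks.

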