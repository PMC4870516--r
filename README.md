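# isocoex

Analysis of alternative 3′-terminal exon usage and isoform co-expression
during neuronal differentiation, from splice-junction count data.

Many genes choose between an upstream alternative 3′-terminal exon (UA3E) —
a last exon buried inside an intron of a longer isoform — and the
alternative isoform with downstream exon(s) (AIDE). The choice sets both the
protein C terminus and the 3′ UTR, and in developing neurons it is under
strong regulation, notably by the polypyrimidine tract-binding proteins
Ptbp1/Ptbp2. `isocoex` provides the computational side of that analysis for
anyone working from gene models and junction counts:

* **Event cataloging** — find UA3E/AIDE pairs in a GTF annotation, with
  filters that remove cassette exons (the candidate acceptor must never be
  used internally) and tandem alternative polyadenylation (the two 3′ splice
  sites must differ).
* **ψ quantification** — percent-spliced-in from the two donor-anchored
  junction counts, `ψ = 100·inclusion/(inclusion+exclusion)`, with
  detectability flags and exact-test calls of developmental or
  knockdown-dependent regulation (with a design-effect correction for
  replicate overdispersion).
* **Isoform co-expression index** — `ν = exp(H)`, where
  `H = −Σ pᵢ ln pᵢ` is the Shannon entropy of the isoform mixture; ν is the
  effective number of co-expressed isoforms (the Hill number of order 1).
  For two isoforms, ν ranges from 1 (one isoform only) to 2 (ψ = 50%).
* **Trend statistics** — Kendall τ-b between ν and developmental stage per
  event (exact permutation p at small n, tie-corrected normal approximation
  otherwise), Benjamini–Hochberg adjustment, and classification of
  significantly increasing/decreasing co-expression (defaults τ > 0.4,
  BH-adjusted p < 0.005).
* **Bimodality testing** — an exact Hartigan dip statistic (greatest convex
  minorant / least concave majorant sweep, ties handled) with a seeded
  Monte-Carlo uniform null, for the characteristic two-peaked τ
  distribution of regulated events.
* **Motif enrichment** — overlapping k-mer scans of the 250-nt window
  around UA3E 3′ splice sites (intronic R4 + exonic R5 halves) and
  one-sided Fisher tests of pyrimidine-rich (Ptbp-type) hexamer
  over-representation in regulated versus non-regulated windows.
* **Single-cell classification** — marker gating (Gapdh/NeuN/Gfap) into
  neurons, astrocytes and other cells, per-cell ψ, group medians, and Welch
  t comparisons.
* **Synthetic data with ground truth** — generators for gene models (with
  decoys), an 8-stage differentiation time course with beta-binomial
  replicate noise, motif-planted windows, and single-cell profiles, so the
  entire pipeline is testable end to end without external downloads.

All user-facing functions take data frames first and return tibbles, so
steps chain with the pipe; fitted results have `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` views.

## Worked example

```r
library(isocoex)

# 8-stage time course (DIV -8 ... DIV 28), 3 replicates, 200 events of
# which 50 have a planted logistic psi trajectory 5% -> 45%
sim    <- simulate_timecourse_counts(n_events = 200, n_increasing = 50, seed = 1)
psi    <- psi_table(sim$counts)
trends <- compute_trends(psi, sim$samples)
glance(trends)
#>   n_events n_tested increasing decreasing  none tau_threshold alpha
#> 1      200      200         50          0   150           0.4 0.005

dip_test(trends$tau[!is.na(trends$tau)], n_boot = 2000, seed = 1)
#> Hartigan dip test of unimodality (Monte-Carlo uniform null)
#>   dip = 0.0705, n = 200, p-value = 0.0004998 (2000 null samples, seed 1)
```

All 50 planted events — and no flat event — cross the τ > 0.4 &
BH-adjusted p < 0.005 gate, and the presence of a second τ mode makes the
dip test reject unimodality.

```r
cells <- simulate_single_cells(seed = 1)   # 72 neurons / 18 astrocytes / 33 other
cls   <- classify_cells(cells$profiles)
summarize_composition(cls)
#>   class         n fraction percent
#> 1 neuron       72    0.585   58.54
#> 2 astrocyte    18    0.146   14.63
#> 3 other        33    0.268   26.83

s <- summarize_psi_by_class(cls)
s[, c("class", "n", "psi_median")]
#>   class         n psi_median
#> 1 neuron       72      44.8
#> 2 astrocyte    18       2.86
#> 3 other        33      19.0

compare_psi_groups(s$psi_values[[1]], s$psi_values[[2]])
#>       t df   p_value mean_a mean_b median_a median_b
#> 1 38.58 88 6.273e-57  43.81  3.505    44.81    2.865
```

Simulated neurons co-express both isoforms (median ψ near 43%) while
astrocytes use almost exclusively the downstream isoform (median near 4%),
and the Welch test separates the groups decisively.

The whole chain — catalog → quantify → regulation → trends → bimodality →
motifs — runs as one call:

```r
report <- run_pipeline(pipeline_config(seed = 1))
glance(report)
```

A thin command-line wrapper around these functions is installed at
`inst/scripts/isocoex.R` (`run` and `simulate` subcommands).

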