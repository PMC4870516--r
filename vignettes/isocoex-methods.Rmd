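---
title: "Methods: quantifying alternative 3'-terminal exon co-expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying alternative 3'-terminal exon co-expression}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models, parameter choices and
numerical conventions behind `isocoex`. It is the reference for *why* the
package computes what it computes; the README shows *how* to run it.

## The event model

A UA3E/AIDE event is a pair of splicing outcomes anchored at one donor
site: either the transcript terminates at an upstream alternative
3'-terminal exon (UA3E) lying wholly inside an intron of the longer
isoform, or it splices past it to downstream exon(s) (AIDE). The catalog is
built from exon features of a GTF annotation, using three structural
requirements and two exclusion filters:

* the UA3E must be the *last* exon of its transcript, strictly inside the
  intron that the long isoform splices over (at least 1 nt of intron
  between the shared donor and the UA3E acceptor);
* the donor must be the *identical genomic position* in both transcripts —
  alternative 5' donors disqualify a pair, because they would confound the
  3'-terminal choice with donor choice;
* the AIDE is represented by the acceptor of the first exon downstream of
  the shared donor; further downstream structure is irrelevant to the two
  discriminating junctions and is ignored for quantification;
* *cassette filter*: the UA3E acceptor must not be used as an
  internal-exon acceptor by any transcript of the gene, which removes
  cassette exons masquerading as terminal exons;
* *tandem-APA filter*: the UA3E and AIDE acceptors must differ; terminal
  exons sharing one acceptor differ only in cleavage/polyadenylation, not
  splicing.

Transcripts with identical exon chains (a common redundancy in UCSC-style
annotation) are collapsed before cataloging, and duplicate events (same
donor and acceptor pair seen through several transcript pairs) are emitted
once. Coordinates are 0-based half-open internally, 1-based inclusive in
GTF, 0-based half-open in the BED-like event table — stated explicitly
because every off-by-one in this domain is an acceptor in the wrong exon.

Because annotation pipelines differ in additional, unpublished filtering
steps, a catalog built from a full genome annotation with these two filters
alone should be expected to be a superset of more aggressively filtered
catalogs.

## ψ and regulation calls

Both isoforms share all sequence upstream of the donor, so the two
donor-anchored junction counts are the discriminating observations:
`psi = 100·inclusion/(inclusion+exclusion)`, undefined when both counts are
zero. No exon-body reads enter the estimate, which keeps the pipeline
alignment-free (it consumes junction count tables, not BAM files).

**Detectability.** An event is detectable when at least `min_stages`
(default 1) stages have every replicate's junction total at or above
`min_total_per_sample` (default 20 reads; a replicate-mean rule is
available). The threshold is a reporting convention, not a fitted quantity;
it is echoed into the run report so downstream counts are interpretable.

**Developmental regulation.** Replicates are pooled within stage and every
consecutive-stage pair is tested with a two-sided Fisher exact test on the
pooled 2×2 (inclusion, exclusion) table; the per-event p-value is the
minimum pair p Bonferroni-scaled by the number of tested pairs, then
BH-adjusted across events; a call additionally requires a maximum absolute
pooled-ψ change of at least `min_delta_psi` (default 10 percentage points).
This transparent construction stands in for unpublished pipeline detail and
is fully configurable.

**Overdispersion correction.** Pooling biological replicates and applying
an exact test assumes binomial sampling, but replicate splicing ratios are
overdispersed; uncorrected, the pooled exact test badly exceeds its nominal
level on beta-binomial data (in our null simulations at ρ = 0.02, roughly a
third of flat events were called "regulated"). `isocoex` therefore applies
a Rao–Scott-style design-effect correction by default: the replicate-level
Pearson dispersion of inclusion counts, pooled over all events and groups
and clamped at ≥ 1, divides the pooled counts before testing ("effective
counts"). Effect sizes (Δψ) are always computed from the raw pooled counts.
With exactly binomial replicates the factor is 1 and the test is the plain
pooled Fisher test; `overdispersion = "none"` disables the correction.

**Knockdown dependence** follows the same machinery with three condition
groups: an event is dependent when both contrasts (single and double
knockdown versus control) pass the significance and |Δψ| gates *with the
same sign* — consistency across the two knockdowns being the criterion of
interest.

**Overlap enrichment** between two event sets over a universe uses the
two-sided Fisher exact test (probability-mass rule: the p-value sums
hypergeometric probabilities of all fixed-margin tables no more probable
than the observed one). The reported odds ratio is the sample
(cross-product) ratio, with `Inf` by convention when a denominator cell is
zero; the conditional-MLE estimate is deliberately not used so the number
is directly recomputable from the four cells.

## The co-expression index ν and its trends

For isoform proportions `p`, `ν = exp(H)` with `H = −Σ pᵢ ln pᵢ` (natural
logarithm; `0·ln 0 := 0`). ν is the Hill number of order 1 — the effective
number of co-expressed isoforms: 1 when a single isoform carries all
splicing, `k` for `k` uniformly expressed isoforms, and for the two-isoform
case `ν(ψ) = ν(100 − ψ)` with a maximum of 2 at ψ = 50%. The natural
logarithm is forced by the `exp(H)` definition together with the maximum
of 2 at a balanced mixture.

Trends are tested per event with the Kendall rank correlation between
developmental time and ν:

* time is coded as *stage rank* (1…8), not days-in-vitro values — Kendall
  depends only on ranks, so the coding matters only through ties;
* by default each replicate contributes its own (stage rank, ν) point,
  giving the test its sample size (24 points for 8 stages × 3 replicates);
  stage-mean ν is available via `per_replicate = FALSE`. Samples with
  undefined ψ are dropped from that event's trajectory and the remaining
  point count is reported;
* τ-b (tie-corrected) is computed from concordant/discordant pair counts;
  the two-sided p-value is exact — from the full permutation distribution,
  computed by the inversion-count (Mahonian) recursion — when n ≤ 8 with no
  ties, and otherwise uses the normal approximation with the tie-corrected
  variance of the S statistic. A constant input vector returns τ = 0,
  p = 1, flagged as degenerate;
* p-values are BH-adjusted across events, and classes assigned by
  τ > 0.4 & adjusted p < 0.005 (increasing; decreasing symmetric). Both
  thresholds are arguments.

## Bimodality: the dip statistic

The two-peaked structure of the τ distribution is tested with Hartigan's
dip: the smallest sup-norm distance between the empirical CDF and any
unimodal CDF (convex up to the mode, concave after it, an atom allowed at
the mode). The implementation is an exact greatest-convex-minorant /
least-concave-majorant sweep:

* the sample is collapsed to unique points with the ECDF value just below
  (`lo`) and at (`hi`) each atom;
* a candidate modal window is iteratively narrowed toward the largest gap
  between the two hulls, while misfits of the one-sided convex/concave
  tail fits outside the window accumulate;
* within the window, the misfit is minimised over the crossover position
  where the fit passes from the convex to the concave branch — the ECDF
  atom at the crossover is absorbable by the unimodal CDF's jump, which is
  what makes tied data (e.g. discrete τ values) behave correctly;
* the dip is half the final max of tail and window misfits, clamped to the
  discrete lower bound `1/(2n)`. An all-equal sample returns `1/(2n)` by
  convention (maximal unimodality; the Monte-Carlo p-value is then ≈ 1).

The test suite validates this implementation, case by case, against an
independent oracle that solves the underlying optimisation directly:
binary search on the tolerance `d`, with feasibility of a unimodal CDF
within the ECDF ± d bands checked via convex/concave band hulls for every
candidate mode position, coupled through the modal jump. The two
agree to ~1e-12 across randomized batteries including heavily tied samples.

`dip_test()` compares the observed dip against `n_boot` (default 2000)
uniform(0,1) samples of the same size — the least-favourable unimodal
null — with add-one smoothing `(b+1)/(n_boot+1)`. The seed is a required
argument and the caller's RNG state is never disturbed.

## Motif enrichment

Windows of `width` nt (default 250) are centered on the UA3E 3' splice
site. The split is exactly half intronic (R4) / half exonic (R5); the
symmetric split is a package convention (configurable via
`intronic_width`), since "centered" does not dictate an asymmetry.
Sequences are strand-corrected and reported as RNA; windows running off a
contig are truncated with the realized widths recorded.

Enrichment uses *presence/absence* of each k-mer per window (robust to
window length and composition; occurrence counts are available from
`scan_motif()`, which counts overlapping matches and never matches `N`),
a one-sided (enrichment) Fisher exact test per k-mer, and BH adjustment
across the k-mers tested; regions R4, R5 and their union are tested
separately. The built-in `default_ptbp_motifs()` set — all hexamers over
{C, U} containing `UCUU` or `CUCU` — is a deterministic, documented proxy
for polypyrimidine-tract-binding protein consensus motifs; it is *not* a
published motif database, and users with a curated list should supply it.

## Single cells

Gel-based marker detection is modelled as a count threshold (default ≥ 1):
cells below threshold on the housekeeping marker are excluded from all
denominators; NeuN⁺/Gfap⁻ cells are neurons, Gfap⁺/NeuN⁻ astrocytes, and
anything else (double-positive or double-negative) "other" — only
unambiguous classes are analysed. Per-cell ψ is the E6 (UA3E isoform)
fraction of the two isoform counts, undefined at zero total (the cell is
dropped from summaries, with a message). Group summaries use the median,
which is robust to the strongly skewed per-cell ψ near the 0% and 100%
boundaries; group comparisons use the two-tailed Welch t test
(unequal variances, Welch–Satterthwaite degrees of freedom).

## What the synthetic data do and do not emulate

The generators reproduce the statistical structure the analysis assumes,
with ground-truth tables covering every record:

* *gene models*: one locus per contig, jittered exon boundaries, random
  strand; cassette and tandem-APA decoy genes exercise both filters;
* *time course*: the eight stages DIV −8, −4, 0, 1, 7, 16, 21, 28 with 3
  replicates; per sample the junction total is Poisson(`depth_mean`,
  default 100) and inclusion is beta-binomial with ρ = 0.02 by default —
  biological replicates of splicing ratios are overdispersed, and a
  binomial generator would make every pooled test look better than it is.
  Planted trajectories are logistic in ψ (slope 1.5 per stage, switch at
  the stage midpoint, defaults 5% → 45% — the halfway-switch regime where
  ν rises over most of its range); a large slope turns the plant into an
  adjacent-stage step. Flat events draw a constant ψ uniform on 10–90%;
* *windows*: i.i.d. uniform {A,C,G,U} background with one hexamer planted
  at a random position in R4 or R5 at class-specific rates; one motif per
  fixture keeps enrichment tests unambiguous;
* *single cells*: class counts default to 72 neurons / 18 astrocytes / 33
  other; expressed markers are `rpois(8)+1` (strictly positive, so
  zero-dropout classification is exact by construction) with optional
  dropout; per-cell ψ is logit-normal around class means 42.8% (neuron),
  4.5% (astrocyte), 20% (other) with logit-scale SD 0.35, realized as
  binomial counts at Poisson(200) depth.

What they deliberately do not model: read-level artefacts (mappability,
positional bias, junction-spanning alignment errors), correlated events
within a gene, stage-dependent sequencing depth, marker cross-contamination,
and any real motif grammar beyond a single planted k-mer. Passing tests
therefore demonstrate correctness of the statistics under the assumed noise
model, not robustness to alignment or annotation artefacts.

## Problem sizes and determinism

The test suite runs everything at desk scale, chosen so the full suite
completes in a few minutes: trend recovery at 200 events (50 planted) ×
8 stages × 3 replicates at depth 100, ρ = 0.02; bimodality with 2000-sample
Monte-Carlo nulls at n ≈ 200; motif recovery over 20 seeds at 100 + 100
windows; catalog exactness over 5 seeds at 50 true events + 50 decoys;
dip/Kendall/Fisher oracle batteries at n ≤ 8, n ≤ 30 and table totals ≤ 40
respectively. Every stochastic routine takes an explicit seed, restores the
caller's RNG state, and is byte-reproducible given (configuration, seed);
the pipeline threads one base seed through its stages with fixed offsets.

## Known limitations

* The regulated/dependent calls test *consecutive-stage* contrasts only; a
  slow monotone drift that never moves 10 ψ points between adjacent stages
  is the trend module's job, not the regulation caller's.
* The design-effect correction assumes a shared overdispersion scale across
  events; strongly heterogeneous per-event dispersion would call for a full
  beta-binomial likelihood model, which is out of scope here.
* The exact Kendall branch applies only to untied inputs at n ≤ 8; the
  replicate-level trend test virtually always has stage ties and so uses
  the tie-corrected normal approximation, which is an approximation at the
  n ≈ 24 typical of an 8 × 3 design.
* Event cataloging trusts the annotation: unannotated terminal exons are
  invisible, and annotation redundancy is handled only through exact
  exon-chain duplication.
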