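---
title: "Consensus voting pathway enrichment for DNA methylation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus voting pathway enrichment for DNA methylation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Interpreting an epigenome-wide association study (EWAS) usually ends in
pathway over-representation analysis, and that analysis usually begins with
two fragile choices: a single cutoff deciding which CpGs "count", and a
single rule mapping each CpG to one gene (typically its nearest gene by
genomic position). Both choices are arbitrary, and the nearest-gene rule is
biologically wrong often enough to matter: methylation regulates
transcription through promoters, but also through chromatin loops and
enhancer–promoter contacts, so one CpG can regulate several genes and one
gene can be regulated by CpGs hosted far away. Expression quantitative trait
methylation (eQTM) resources measure these many-to-many CpG–gene links
empirically — effect size (e.g. correlation), CpG-to-TSS distance, and a
pair-level p-value — and this package uses them as the mapping layer.

Rather than committing to one cutoff, the pipeline evaluates a whole grid of
filtering choices, scores and prunes the resulting gene lists, and asks which
pathways are enriched *consistently* across the surviving lists.

## The pipeline

**Parameter grid.** Three axes: the number `k` of top-ranked CpGs, a minimum
absolute eQTM effect size `e`, and a maximum CpG–TSS distance `d`. When the
EWAS metric is a p-value, `k` values are log-spaced between 25% and 100% of
the number of CpGs with Benjamini–Hochberg FDR < 0.05 (denser at small `k`);
for statistic or importance metrics the user supplies `k_values` explicitly.
Effect and distance thresholds are evenly spaced between the 5th and 95th
percentiles of their observed distributions (computed once on the full eQTM
table, before any top-`k` filtering). Each grid cell `(k, e, d)` yields a
candidate gene list: the union of eQTM target genes over links whose CpG is
in the top `k`, with `|effect| >= e` and `distance <= d`. Grid densities
default to 5 per axis; pruning makes the result insensitive to this choice,
and 4 per axis is used in the simulation benchmark. A single-point threshold
grid takes the lenient end of its band (the 5th percentile for effect, the
95th for distance) so that a degenerate grid still reaches most of the
resource.

**Entropy-based pruning.** Candidates are scored within each `k`-pool (never
across `k`, so longer lists from larger `k` cannot dominate). With `N_k`
distinct candidates at a given `k` and `n_k(g)` the number of them containing
gene `g`:

- information score `I(G) = mean over g in G of -ln((n_k(g) + 1)/(N_k + 2))`
  (Laplace smoothing, alpha = 1) — favors lists enriched for genes that are
  rare across candidates;
- discordance `D(G) = mean over other candidates G' of (1 - J(G, G'))` with
  `J` the Jaccard similarity — penalizes idiosyncratic lists (defined as 0
  when `N_k = 1`);
- over-representation penalty: the expected recurrence of `g` is modelled by
  a quasi-Poisson GLM with log link, `ln E[n_k(g)] = b0 + b1 ln(1 + c(g))`,
  where `c(g)` is the gene's unique-CpG count in the eQTM resource; then
  `R(G) = sum over g of ln(1 + max(0, n_k(g) - nhat_k(g)))`. Only *excess*
  recurrence beyond what CpG mapping density predicts is penalized, and the
  log keeps extreme residuals bounded. The GLM is fitted once per pool on the
  distinct genes appearing in at least one candidate (that is the domain on
  which `n_k` is defined); fewer than two covariate levels degrade gracefully
  to an intercept-only fit.

The composite score is `S = zI - zD - zR` with z-scores taken within the
pool using the population (divide-by-N) standard deviation — pools can be as
small as two candidates, where the N-1 convention would inflate wildly; a
zero-variance component contributes zero. Candidates are then selected
greedily: take the highest-scoring remaining list (ties: larger list, then
grid enumeration order), discard every remaining list with Jaccard
similarity *strictly above* 0.7 to it, repeat. Exact duplicates within a
pool are collapsed before scoring (keeping the least stringent cell) so that
`N_k` counts distinct lists.

**Enrichment and voting.** Every surviving list is tested against every
pathway by the exact hypergeometric upper tail, with the universe defined as
the genes present in *both* the eQTM resource and the pathway database —
the genes the pipeline can actually reach; anything else would manufacture
enrichment out of unreachable genes. A pathway "appears" in a run when it is
part of that run's standard enrichment output, i.e. its within-run
BH-adjusted p-value is below 0.05 (the convention of standard enrichment
tools; `run_p_cutoff = 1` disables the gate). Pathways are retained when
they appear with at least `min_count = 2` overlap genes in at least
`min_votes = 2` distinct runs — the count filter first, the stricter order.
Retained pathways get the harmonic mean of their raw member p-values (equal
weights; no weighting scheme is forced on the user's runs), calibrated into
an asymptotically exact combined p-value that stays valid under the positive
dependence the nested grid induces: under the null the reciprocal of the
harmonic mean of `L` p-values follows a Landau distribution (the
alpha = 1, beta = 1 stable law) with location `ln L + 0.8744` and scale
`pi/2`. `L` is the pathway's own vote count — those are the tests actually
combined. Finally the calibrated p-values are BH-adjusted across the
retained pathways.

**Numerical notes.** The Landau upper tail is computed from Nolan's
non-oscillatory integral representation of the stable(1, 1) CDF; the
integrand is bounded in [0, 1] and evaluated with `expm1` so small tails
lose no precision. The calibration was validated against a 10^6-draw
Monte-Carlo null at L in {2, 5, 10} (it matches within Monte-Carlo error in
the rejection region; in the body of the distribution the asymptotic
calibration is mildly conservative at small L, a property of the published
calibration itself). Because the approximation can undershoot the identity
near hmp = 1, the calibrated value is floored at the harmonic mean — a
combined p-value is never smaller than the quantity it calibrates. The
quasi-Poisson point estimates coincide with Poisson maximum likelihood
(dispersion never enters the fitted means, which are all the penalty uses);
fitted means were verified to 1e-8 against an independent
iteratively-reweighted-least-squares implementation. All result orderings
carry total tie-breaks (q, then hmp, then pathway id) so identical inputs
give byte-identical outputs.

## The classical baseline

The comparator is the conventional pipeline: take the top-k ranked CpGs, map
each to its single annotated gene, run one hypergeometric pass (universe:
annotated genes present in the database), BH-adjust. It shares the ranking
rules, the hypergeometric implementation, and the BH step with the consensus
pipeline, so differences in results come from the mapping and the ensemble,
not from implementation details. Its default `k` is the FDR-significant CpG
count; the simulation passes the same anchor both pipelines use, keeping the
comparison symmetric.

## The simulation benchmark

`simulation_config()` encodes the study conditions: 7 signal pathways drawn
per replicate from 14 top-level pathways (each at least 200 genes, pairwise
Jaccard below 0.2), 25 signal genes per pathway, up to 3 signal CpGs per
gene chosen among its strong eQTM links (pair p < 1e-7), signal CpG effect
scores Normal(3, 0.5), noise CpG scores Normal(0, 1), 100,000 noise CpGs and
1000 replicates at full scale. Detection of a planted top-level pathway or
any of its direct descendants at q < 0.05 counts as recovery; a non-signal
family is a false positive under the same rule (the specificity denominator
is the non-signal top-level families, symmetric to the sensitivity rule).
Signal-gene coverage is the fraction of planted genes contained in the union
of detected pathways' gene sets. Effect scores are converted to one-sided
upper-tail normal p-values (`1 - Phi(score)`), preserving the
stronger-is-better ranking.

**The synthetic universe.** The real eQTM resource the benchmark emulates is
access-restricted, so the generator reproduces its structure: a 6000-gene
pool; 14 top-level pathways of 200–350 genes redrawn until the redundancy
constraint holds; 2–5 direct descendants per parent, proper subsets at
20–50% of its size (mirroring hierarchy containment); 60 background pathways
of 20–200 genes. Per-gene CpG link counts are right-skewed
(1 + Poisson with a log-normal(0.55, 0.9) rate, capped at 30). Each CpG is
*hosted* near one gene; regulation mode is a gene-level property: half the
genes are promoter-driven (85% of their links proximal, correlation
magnitudes 0.9 x Beta(2.5, 4) proximal and 0.9 x Beta(2, 6) distal) and half
enhancer-driven (15% proximal at 0.9 x Beta(1.5, 8), 85% distal at
0.9 x Beta(2.5, 5) attached to CpGs hosted by other genes). Pair p-values
follow from the correlation magnitude at a nominal sample size of 1000, so
strong links (p < 1e-7) arise on both routes; distances are |N(0, 20 kb)|
proximal versus Uniform(5 kb, 1 Mb) distal, capped at 1 Mb. The baseline's
annotation maps each CpG to its single strongest-effect gene. The gene-level
regulation mode is what gives the annotation its realistic partial
discordance with the regulatory truth: enhancer-driven genes are reached
mostly through CpGs that the annotation assigns to their host genes. What
the generator does **not** emulate: real pathway redundancy and size
heterogeneity, array design, genomic clustering of CpGs, and the full extent
of real annotation error — so passing benchmarks here demonstrate correct
mechanics and directional behavior, not field performance.

**Anchoring k in the benchmark.** The planted scores put the converted
p-values exactly at the Benjamini–Hochberg detection boundary: with ~500
signal CpGs at Normal(3, 0.5) against 20,000 uniform nulls, the expected
BH < 0.05 count oscillates between ~0 and a few dozen, and at the full
100,000-noise scale it is essentially zero — the FDR count is not a usable
grid anchor under these conditions. The benchmark therefore anchors `k` (for
both pipelines, symmetrically) with `estimate_signal_count()`: a
Meinshausen–Rice-type lower bound on the number of non-null tests,
`max_t floor(#{p <= t} - n t - z_0.999 sqrt(n t (1 - t)))`. Under a pure
null this is almost always zero — a signal-free study still constructs no
grid, failing loudly rather than silently — and under the study conditions
it sits stably near 85% of the true signal count. Outside the benchmark,
p-value-based workflows default to the FDR count.

**Problem sizes.** The shipped benchmark profile (used by the acceptance
script and tests) is 100 replicates, 20,000 noise CpGs and a 4x4x4 grid —
about half a minute on one core; the full-scale profile (1000 replicates,
100,000 noise CpGs) remains available through `simulation_config()` and the
`simulate` subcommand. Replicate seeds derive from the master seed, so any
profile regenerates byte-identically.

## Known limitations

- Gene identifiers are harmonized by trimming and upper-casing only; they
  are otherwise opaque strings that must match between the eQTM resource and
  the GMT file. Cross-namespace mapping (symbol vs Ensembl) is out of scope.
- The greedy Jaccard selection guarantees low overlap between each survivor
  and the candidate that was on top when it was picked — not a pairwise
  bound across all survivors.
- The Landau calibration is asymptotic in the number of combined tests; at
  very small vote counts it is mildly conservative away from the tail.
- In the benchmark's clean universe both pipelines operate near their
  performance ceiling, so *fold* contrasts between them are small even where
  their directions are stable; magnitudes of that kind are properties of
  messy real resources that the generator deliberately does not fake.
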