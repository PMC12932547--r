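---
title: "Internal-reference ratio normalization for differential microbiome screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Internal-reference ratio normalization for differential microbiome screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irmdma)
```

## The problem: compositional closure

Amplicon sequencing reports *relative* abundances: every sample's genus
fractions sum to 100%. The community behind the sample, however, has a free
total microbial load, and that load varies between environments. When one
taxon's absolute abundance surges in a group — a "bloomer" — every other
taxon's relative abundance in that group is mechanically depressed even
though nothing happened to those taxa. Rank tests applied directly to
relative abundances (here called **PA-DMA**, primary-abundance differential
microorganism analysis) therefore flag spurious group differences whose
direction and size are artifacts of closure.

## The method: anchor the table to a host-specific reference taxon

The workflow implemented by this package replaces the fixed 100% anchor
with a biological one:

1. **IRM screen.** A candidate *internal reference microorganism* (IRM) is
   a genus that is present in the target plant's rhizosphere at *every*
   sampled site, absent from the rhizosphere of every co-located companion
   plant (a neighboring plant sharing soil, water and air but not roots —
   the host-specificity background), and has a group-mean relative
   abundance of at least a threshold (default 0.005%) in *every*
   target-host group. Presence defaults to detection (> 0) in at least one
   sample of a group; a prevalence-based rule is available because
   "present" is genuinely ambiguous at n = 6 — the default is the more
   permissive reading, and both are exposed (`presence_profile(rule =)`).

2. **RCQ normalization.** Every genus *g* in sample *s* is re-expressed as
   the *relative community quantity*

   RCQ(g, s) = relative abundance of g in s / relative abundance of the IRM in s.

   Because both numerator and denominator are divided by the same sample
   total, the total cancels: if the IRM's absolute abundance is stable
   across groups, RCQ is proportional to the genus's absolute abundance, a
   semiquantitative, closure-free scale. RCQ columns are deliberately *not*
   re-closed — their free column sums are the point.

   Zeros are handled asymmetrically, following the asymmetry of their
   roles: a zero *denominator* (IRM undetected) is replaced by a
   pseudo-count of half the detection limit (detection limit 0.002% of
   relative abundance in a typical amplicon dataset, hence pseudo-count
   0.001%); a zero *numerator* stays zero — an undetected genus should not
   acquire abundance from the reference.

3. **Differential screening (IRMRA-DMA).** The same rank tests used on the
   relative-abundance scale are re-run on RCQ: two-sided Wilcoxon rank-sum
   for two groups, Kruskal-Wallis (tie-corrected, chi-square reference) for
   three or more, at raw p < 0.05 with a relative-abundance filter
   (> 0.005% group mean in at least one group). The *wild-enriched* set is
   the subset of k-group-significant genera whose reference-group center
   strictly exceeds every comparison group's center.

4. **Method comparison.** The PA-DMA and IRMRA-DMA wild-enriched sets are
   partitioned into common, PA-only ("suppressed" false positives the
   ratio scale discards) and IRM-only ("rescued" genera) — the package's
   `compare_sets()`.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `detection_limit` | 0.002 (%) | smallest reliably observed relative abundance; anchors the pseudo-count (always half of it) |
| `irm_threshold` | 0.005 (%) | minimum group-mean abundance an IRM must reach in every host group; inclusive (≥) |
| `abundance_filter` | 0.005 (%) | screen eligibility: group mean must *exceed* this in ≥ 1 group, evaluated on the relative-abundance scale for both methods so they screen the same genus universe |
| `alpha` | 0.05 | raw-p significance level; BH adjustment available (`mtc = "BH"`) but off by default since the screen is defined on raw p |
| `mode` | `per_sample` | RCQ denominator: the sample's own IRM abundance. `group_mean` divides by the group-mean IRM abundance instead; then the column sums obey Σ RCQ = 100 / (group-mean IRM %) exactly |

Design choices that were genuinely open, and how they were resolved:

* **Per-sample vs. group-mean denominator.** Rank tests need per-sample
  variation, and a group-constant denominator makes RCQ a monotone
  transformation of relative abundance within each group (identical ranks,
  different means). `per_sample` is therefore the default; `group_mean` is
  kept because the pseudo-count rule is phrased per group, and the mode is
  recorded in every output.
* **Filter scale for IRMRA-DMA.** The 0.005% filter is evaluated on the
  relative-abundance scale for both methods, keeping the two genus
  universes identical and the Venn comparison meaningful.
* **Inclusive threshold, exact-tie direction.** Threshold comparisons are
  ≥; exactly tied group means give direction `none`, never an arbitrary
  sign.
* **Multiple candidates.** When several genera pass the IRM screen, all are
  reported ranked by their minimum across-group mean (descending, ties
  alphabetical); automatic selection takes the top-ranked one, and the
  choice is recorded in the run manifest.
* **Degenerate tests.** All-identical observations give Wilcoxon p = 1 and
  Kruskal-Wallis H = 0, p = 1 rather than a 0/0 tie correction. This is
  what makes the IRM itself (RCQ ≡ 1) structurally non-significant.
* **Exact vs. approximate p.** Wilcoxon uses the exact rank-sum
  distribution when both groups have ≤ 8 observations and the pooled data
  are tie-free, otherwise the tie-corrected normal approximation with
  continuity correction. Spearman correlations use full permutation
  enumeration up to n = 9 and the t approximation beyond.
* **Model-object shape.** `irmdma()` returns a classed object with
  `print`/`summary`/`plot` methods; `predict`/`residuals` analogues are
  not provided because a screening result has no prediction semantics.

## What the simulator emulates — and what it does not

`simulate_community()` generates communities on the *absolute* scale and
lets relative abundances arise only through closure and multinomial
sequencing at a fixed depth:

* per-taxon baselines are log-normal across taxa (log-sd 1), a standard
  heavy-tailed community model;
* each sample multiplies its group's expected abundance by independent
  log-normal noise (log-sd 0.3);
* group structure enters as fold changes on the absolute scale: planted
  differential taxa, an optional bloomer (default baseline 5% of the
  community, so a ×20 surge roughly doubles total load), and an IRM held
  at a stable level (default 0.5% of the community) in host groups and at
  zero in companion groups;
* counts are multinomial at depth 5 × 10⁴, so one read corresponds to
  0.002% — the detection limit the pseudo-count is anchored to.

Ground truth is a pure function of the configuration (the fold matrix), so
false- and true-positive rates are well defined per group contrast.

Two built-in scenarios ship. `null_load_shift` (200 taxa, 3 host groups ×
6 samples, bloomer ×20 in the two cultivated-analog groups) isolates the
closure artifact: apart from the bloomer, no taxon differs in absolute
abundance, so every other significant call is a compositional false
positive. `planted_signal` (100 taxa, 3 sites with host + companion groups,
10 taxa ×4 in the wild-analog group) exercises the full pipeline including
the automatic IRM screen. Its community size was fixed from a design
calculation rather than convention: with a raw-p screen at α = 0.05 and the
reference-highest direction rule, roughly α/3 of the null taxa land in the
wild-enriched set, so the expected false-discovery fraction of a 10-taxon
truth set is ≈ (α/3 · n_null)/(α/3 · n_null + 10) — about 13% at 100 taxa,
but above 20% at 200 taxa for *any* seed. At 200 taxa a ≤ 20% contamination
target would be unattainable in expectation without multiplicity
correction, which the screen deliberately does not apply.

What the simulator does **not** emulate: taxonomic misassignment,
sequencing error and chimeras, overdispersion beyond the log-normal ×
multinomial hierarchy, spatial or temporal autocorrelation between
replicates, and any fidelity to a particular real dataset. Passing the
benchmark therefore demonstrates that the method removes *closure-induced*
false positives under a known mechanism — not that it is robust to every
distortion of real amplicon data, and dataset-level genus counts from real
studies are not reproduction targets here.

The benchmark (`run_benchmark()`, 100 replicates, master seed 42,
per-replicate seed = master + replicate index) runs the WFt-analog vs. one
cultivated-analog Wilcoxon contrast with both methods. Typical behaviour:
PA-DMA's per-taxon false-positive rate is an order of magnitude above the
nominal 5% while IRMRA-DMA stays near nominal, and PA-DMA is worse in
essentially every replicate. These sizes (200 taxa × 18 samples × 100
replicates) keep the full benchmark under a minute on a single core; they
are the package's chosen study conditions, not a limit of the method.

## Numerical conventions and degenerate inputs

* Percent closure is validated to a relative 10⁻⁶ (fraction tables to
  10⁻⁹); total-sum scaling is idempotent to 10⁻¹².
* RCQ is invariant to the input unit (counts, fraction, percent) to
  10⁻¹², because the per-sample normalizer cancels in the ratio.
* All-zero sample columns are a hard error (a sample with no reads cannot
  be scaled), as are duplicate taxon or sample identifiers — never merged
  silently.
* Reported percentages (up-fractions) use half-up rounding to two
  decimals; raw values are retained in the returned objects.
* Group RCQ column sums (`rcq_group_sums()`) are a diagnostic of how far
  the normalization moves group totals apart; they are reported, never
  validated against external values, because their value depends on the
  normalization mode and genus universe in ways no single formula pins
  down.

## Worked example

```{r example, eval = FALSE}
library(irmdma)

com <- simulate_community(scenario_planted_signal(), seed = 43)
fit <- irmdma(com$percent, com$design, irm = "auto")
fit
summary(fit)

bench <- run_benchmark(scenario_null_load_shift(), contrast = c("WFt", "HFt"),
                       n_reps = 100, alpha = 0.05, master_seed = 42)
bench
```

## Known limitations

* The method stands or falls with the IRM's stability assumption: if the
  reference taxon's absolute abundance itself differs between groups, every
  RCQ inherits that difference with opposite sign. The screen can only
  verify host-specificity and abundance, not stability, which is why the
  candidate table reports all passers and their per-group means for
  inspection (`irmdma` warns when the IRM mean is within 2× of the
  detection limit, where the ratio becomes noise-dominated).
* RCQ is semiquantitative: proportional to absolute abundance only up to
  the unknown IRM level; it supports rank tests and correlations, not
  absolute cell counts.
* With the default raw-p screening, the wild-enriched set carries the
  nominal α contamination quantified above; users wanting FDR control
  should switch `mtc = "BH"`.
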