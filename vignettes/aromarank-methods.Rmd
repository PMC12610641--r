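---
title: "Methods: ROAV-based aroma prioritization and sensory–chemical co-localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROAV-based aroma prioritization and sensory–chemical co-localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromarank)
```

## The problem

A GC-MS headspace profile of a fruit typically identifies dozens of
volatile organic compounds (VOCs), quantified as percent of total
chromatographic peak area. Abundance alone is a poor guide to sensory
relevance: a sesquiterpene at 34 % of the chromatogram can matter less
to the nose than a lactone at 0.24 %, because detection thresholds
span five orders of magnitude. `aromarank` implements the standard
flavoromics answer — odor-activity weighting — together with the
descriptive-panel statistics and ordination geometry needed to connect
chemistry to perception across cultivars.

## The ROAV model

For compound $i$ in one sample, with relative abundance $C_i$ (percent
of total peak area) and odor threshold $T_i$, the Relative Odor
Activity Value is

$$\mathrm{ROAV}_i \;=\; \frac{C_i / T_i}{C_{\mathrm{ref}} / T_{\mathrm{ref}}} \times 100,$$

where the reference compound maximizes $C/T$ among detected,
thresholded compounds of that sample. By construction the reference
scores exactly 100 and every ROAV lies in $[0, 100]$; the statistic is
invariant to rescaling all abundances. Compounds with
$\mathrm{ROAV} \ge 1$ are *key* odorants, $0.1 \le \mathrm{ROAV} < 1$
*modifiers*, positive values below 0.1 *negligible*, and exactly 0
*absent* (both boundary values are inclusive at the lower tier edge).

Two design points deserve justification:

* **Reference rule.** A common textbook phrasing picks the compound of
  highest *concentration* as the reference. On the bundled cultivar
  tables that reading fails to reproduce the published per-cultivar
  100s, while the argmax-$C/T$ reading reproduces every printed value;
  argmax $C/T$ is therefore the default, with `reference_rule =
  "conc-max"` available for comparison. Exact ties are broken by byte
  order of the compound id so output is deterministic.
* **Threshold resolution.** Threshold databases mix media and report
  several values per compound. `resolve_threshold()` prioritizes air
  thresholds (mg/m³), falls back to water (mg/kg), and takes the
  arithmetic mean within the selected medium. Magnitudes are used in
  source units and never converted between media: the ROAV is a ratio
  of ratios within one sample, so a consistent convention — not a unit
  conversion — is what reproducibility requires. The medium filter is
  applied *before* averaging.

Compounds absent from the threshold table are excluded and listed,
never silently dropped: on the bundled 49-compound table, 24 compounds
carry thresholds and 25 are reported as excluded. ROAV is computed on
replicate means, matching the single printed value per cultivar.

## Detection and composition accounting

`detection_sets()` partitions each sample's detected compounds into
the set shared by all samples, sets shared by some, and
sample-unique sets, with a terpenoid-only view (mono-/sesquiterpene
hydrocarbons plus their oxygenated forms) used for chemotype
statements. A cell is "detected" iff its stored abundance is positive;
a literal `0` in an input file is treated as not-detected by default
(`zero_as_nd`), because relative-area quantitation reports no true
zeros and an undetected compound must carry zero odor activity.
`class_composition()` and `named_sum()` provide per-class and named
sums of mean abundances.

When class labels are absent, `classify_formula()` assigns them from
the molecular formula (C10/C15 hydrocarbons and their mono-oxygenated
forms, ester/lactone/alcohol/aldehyde aliphatics by degree of
saturation). The bundled table carries explicit labels; note that the
oxygenated-sesquiterpene class is required to reproduce published
unique-terpenoid counts (one cultivar's four specific terpenoids
include a C15H26O alcohol).

## Sensory panel statistics

Panels are stored long-format (assessor, session, sample, attribute,
score on a 0–10 intensity scale) and validated for bounds, duplicate
observations, and lexicon membership. Sessions are pooled as
independent replicate observations — the model is a fixed-effects
one-way ANOVA per attribute (no assessor random effect; a mixed model
is out of scope). Post hoc options:

* **Tukey HSD** (default) via `stats::TukeyHSD`;
* **Duncan's multiple range test**, implemented as the classical
  step-down procedure: ordered means, span-dependent protection level
  $\alpha_p = 1-(1-\alpha)^{p-1}$, studentized-range critical values,
  and the containment rule (pairs inside a non-significant range are
  never declared significant). Harmonic means handle unequal group
  sizes.

All pairwise decisions are condensed by the insert-and-absorb
compact-letter-display algorithm: sharing a letter is exactly
equivalent to "not significantly different", and the letter `a`
always attaches to the highest mean. When every group has zero
internal variance but means differ, the ANOVA p-value is reported as
the 0 limit and flagged `degenerate` rather than left `NaN`.
`alpha` defaults to 0.05.

## Multivariate stage

* **Z-score heatmap.** `zscore_rows()` standardizes each compound
  across samples (denominator $n-1$); constant rows become zeros and
  are flagged. `cluster_heatmap()` clusters rows and columns with
  Euclidean distance and average linkage by default (the published
  analysis names neither; both are configurable), via
  `stats::hclust`.
* **PCA.** `run_pca()` eigendecomposes the explicit covariance or
  correlation matrix — exact for the tiny matrices of cultivar
  studies, with no iterative-SVD convergence nondeterminism. Sign
  convention: the largest-magnitude element of each loading column is
  positive. Components are ordered by decreasing variance; explained
  variance ratios sum to 1 when all components are kept.
* **Joint PCA and co-localization.** `joint_pca()` concatenates the
  sample × attribute panel means with sample × compound abundances and
  z-scores every variable so the blocks are commensurable.
  `colocalize()` reports, per (compound, attribute) pair, the angle
  θ between loading vectors restricted to the first two components
  (matching 2-D loading plots) and the Pearson correlation r of raw
  values across samples; a pair is co-localized when θ < 10° and
  r > 0.9 (both thresholds configurable). With three cultivars, r has
  essentially no degrees of freedom; every result carries a `small_n`
  flag below five samples, and θ/r should be read as descriptive
  geometry, not inference. Only key odorants (tier `key` in at least
  one sample) enter the heatmap and joint PCA in the `run_all()`
  pipeline.

## The synthetic-data generator

`simulate_dataset()` exists so every pipeline stage can be tested
against known ground truth. Its defaults are fixed study conditions,
not tuning knobs:

* 3 cultivars × 49 compounds; 19 shared by all, 1/7/4
  cultivar-unique, the remainder on two-cultivar overlaps — the
  detection structure of a real three-cultivar comparison;
* log-normal abundances (meanlog 0, sdlog 1.5), renormalized to
  percent, spanning roughly 0.04–34 % like a real normalized
  chromatogram; triplicates with fractional replicate SD 0.15, each
  replicate renormalized to 100 % (so mean columns sum to 100
  exactly);
* log-uniform thresholds over ~0.005–40 with an 80/20 air/water mix,
  20 % chance of a second database entry, and 80 % database coverage
  (uncovered compounds exercise the exclusion path);
* one planted marker: a cultivar-unique compound whose threshold is
  set so its *analytic* (noise-free) ROAV lands in the requested tier
  with at least a two-fold margin from the tier boundaries
  (infeasible requests error before sampling);
* a 12-assessor × 3-session × 7-attribute panel with additive
  per-assessor bias (SD 0.3), Gaussian residual (SD 0.7, matching
  published score SDs of 0.7–0.9), truncation to the 0–10 scale, and
  planted cultivar-attribute means contrasting a woody-pungent, a
  sweet-aromatic, and a fresh-herbaceous profile;
* a planted sensory–chemical link: by default the marker compound's
  abundance follows the coconut-like attribute's cultivar means,
  mirroring a unique lactone aligned with a creamy attribute.

Ground truth records the generating reference compounds, analytic
tiers, expected letter patterns, and the analytic co-localization of
the linked compounds against *every* attribute, computed from the
noise-free configuration. Two subtleties:

* **Letter-pattern truth** groups cultivars whose planted means differ
  by at most `letter_equiv_tol` (default 0.25): the default design
  deliberately plants a 0.1-point gap that a finite panel cannot and
  should not resolve. Noise-free recovery tests set the band to 0.
* **Co-localization truth** labels each assessed pair (positive or
  negative) from the noise-free geometry. With three samples, chance
  alignments between arbitrary compound and attribute patterns are
  common, so recovery is meaningful as *noise robustness over the
  assessed pairs*, not as discovery over all pairs.

What the generator does not emulate: chromatographic peak shapes,
retention-time drift, censoring at a detection limit (structural
absence is the default ND mechanism; a censoring stress mode can be
emulated by lowering abundances), assessor×attribute interactions,
and session order effects. Passing recovery tests therefore
demonstrates correctness of the computations under the stated
generative model, not robustness to every artefact of real panels or
instruments.

## Numerical choices and degenerate inputs

* Writers emit fixed column order and 6-significant-digit floats;
  write∘read round-trips are exact for masks and metadata and exact to
  the written precision for values.
* Compound matching between composition and threshold tables is exact
  (UTF-8, trimmed, case-sensitive); no fuzzy matching, because a
  silent mismatch corrupts every downstream ROAV.
* Reference ties break lexicographically (byte order); hclust leaf
  order is the deterministic order of `stats::hclust`.
* A sample whose compounds all lack thresholds, an all-zero sample in
  peak-area normalization, empty threshold entry lists, and scores
  outside $[0,10]$ are errors, not warnings.
* Problem sizes used in the shipped tests: 1000 random profiles for
  the ROAV oracle suite, 8 items for the exhaustive clustering oracle,
  200 seeded panels for the letter-pattern study, and 100 seeded
  datasets for co-localization recovery — sizes at which the
  brute-force oracles are exact and the whole suite stays fast.

## Known limitations

* ROAV inherits the usual caveats of relative quantitation: percent
  composition is closed (sums to ~100), so ROAVs are not comparable
  across samples with very different identified totals.
* Mixed threshold media are a convention, not a physical model;
  air-vs-water priority changes individual ROAVs (it is applied
  uniformly and reported per compound).
* The sensory model pools sessions; panels with strong
  assessor-by-sample interaction need a mixed model outside this
  package's scope.
* With three samples the co-localization correlation is descriptive;
  the `small_n` flag is attached for exactly this reason.
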