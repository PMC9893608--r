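---
title: "flexitau: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flexitau: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexitau)
```

## Scope

`flexitau` implements the quantitative calculus used in FLEX-tagged
full-length-standard (FLEXITau-style) SRM studies of Tau aggregation: from
transition-level peak areas to absolute insoluble/soluble Tau abundance and
per-peptide modification extent; from multi-engine PTM site tables to
canonical-numbered consensus matrices; and the downstream progression
statistics. Everything upstream of these inputs — peak picking, search-engine
scoring, FDR control — is out of scope and assumed done by the acquisition
software.

## Sequence model

Canonical numbering follows the 441-residue human 2N4R isoform (UniProt
P10636-8); the two N-terminal inserts occupy canonical 45–73 and 74–102, so
the 0N4R isoform (P10636-6, 383 aa) maps as local `1–44 → 1–44` and
`45–383 → 103–441`. Coordinate maps are precomputed from this insert
annotation (shipped as `inst/extdata/isoform_structure.tsv`), not from
on-the-fly alignment, and every site or peptide label is reported in 2N4R
numbering (`pT212`, `cR155`, interval `195-209`).

Tryptic digestion cleaves C-terminal of K/R and is suppressed before
proline. The KP/RP rule is required for the assay's own peptides: the
mutation-bearing peptide `HVPGGGSVQIVYKPVDLSK` (canonical 299–317) is fully
tryptic only because K311 is followed by P312, and its mutant forms
(`HVSGGG…`/`HVLGGG…` for P301S/P301L) are the spiked heavy peptides of the
assay.

**The mouse sequence is a synthetic surrogate.** The true mouse Tau sequence
(UniProt P10637) cannot be redistributed from this build environment, so the
fixture `mouse` entry (marked `TAU_MOUSE_SYNTHETIC`) is constructed from the
human sequence: eight substitutions and an 11-residue deletion in the
N-terminal projection domain, identical to human from canonical 151 onward.
This reproduces the *structure* that matters to the pipeline — N-terminal
peptides are human-specific, PRD/MTBD/C-terminal peptides are shared — but
peptide-level specificity calls against real mouse data must not rely on it.

The default quantification panel is the set of fully tryptic 2N4R peptides
of length 6–32 plus the FLEX reporter and, for mutated transgenes, the
mutant spiked peptide. The published assay quantified 18 peptides without
listing them; the default panel is deliberately broader and user-overridable
rather than a guess at the exact membership.

## Quantification calculus

* **L/H aggregation** is ratio-of-sums (`sum(light areas)/sum(heavy
  areas)`), not mean-of-ratios: it is robust to low-intensity transitions
  and matches summed-area export practice.
* **Reference selection is per sample**: each sample's own class maximum
  normalizes that sample. Mutant-specific peptides normalize within the
  human-specific class, after rescaling their L/H by
  `spike_conc / standard_conc` — their heavy signal comes from a synthetic
  spiked peptide (default 50 fmol/µl), not from the 2N4R standard, and the
  rescaling puts them on the standard scale. The source assay does not state
  how this was handled; this is the package's own convention.
* **Clipping**: fractions above 1 (noise inverting the class maximum) are
  clipped to 1 with a logged count; extents stay in [0, 1].
* **Undefined ratios** (zero heavy signal) propagate as `NA`, never 0.
* **Singly phosphorylated peptides** are quantified as light-phospho over
  heavy-*unmodified*-counterpart area ratio: the standard is
  dephosphorylated, so no heavy phospho form exists. This is an interpretive
  choice, documented rather than claimed from the source.
* Volume/mass bookkeeping defaults: 10 mg tissue, 50 µl processed volume
  (5 µl per mg homogenization), 500 fmol heavy standard per sample
  (fixed fmol per sample, not per mg — the alternative reading of "equal
  amounts"), 15 fmol/µl light FLEX spike.

A known estimator property worth stating: normalizing to the *maximum* L/H
of a class is upward-biased in the reference when many truly unmodified
peptides compete (a max over noisy replicates). With a single designated
reference peptide the estimator is effectively unbiased (empirical bias
< 0.01 at 10 % CV); parameter-recovery tests therefore give every
non-reference peptide a nonzero true extent, which is also the regime the
assay is designed for.

## PTM consensus

"Cumulative" combination across engines is implemented as
union-at-replicate-level: a site counts in a biological replicate if *any*
engine reports it there. The replicate frequency of a site in a condition
(model × region × time) uses the metadata's replicate count as denominator,
and the binary matrix applies an inclusive `>= 50 %` threshold. Engine
confidence filtering is assumed already applied upstream; readers validate
residue/modification compatibility (phospho on S/T/Y, GlyGly/acetyl on K,
methyl on K/R, citrullination on R, oxidation on M) and reject ambiguous
localizations (position ranges) with a count rather than guessing.

Engine tables arrive in search-database coordinates (0N4R local for the
mouse-model datasets) and are mapped through the isoform coordinate map;
residues are checked against the genotype, so `pS301` can only arise from a
P301S database.

## Progression statistics

* **Clustering** is complete-linkage on euclidean distances, authored
  in-package so tie-breaking is documented and outputs bit-stable: equally
  distant pairs merge lowest-original-row-first; leaf order visits the
  smaller subtree first (ties: the subtree holding the lower row index).
  Rows with missing values are dropped (complete-case default). Tests check
  merge heights against both `stats::hclust` and a naive O(n³)
  membership-list agglomerator.
* **t-test**: Welch (unequal variances), two-sided, uncorrected — variances
  across ages are visibly unequal in this kind of data; the source says only
  "t-test". Zero variance in both groups is an error; identical groups with
  variance give t = 0, p = 1.
* **Correlation**: Pearson r of a peptide's unmodified fraction (or a
  phosphopeptide's relative amount) against `log10` burden; base 10 because
  abundances span orders of magnitude ("logarithmic amount" is otherwise
  unspecified). `n >= 3` required; constant vectors give `NA`.
* **Ranking** of correlating peptides sorts by mean |r| across conditions,
  ties broken by canonical start position.
* Rows are not standardized before clustering (inputs are already fractions
  or binary); row clustering with time-ordered columns is the default
  (whether the source bi-clustered is not stated).

## The synthetic world

The generator's defaults state the study design they emulate:

* Grid: P301S at 2/3/4/5 months (cortex, brainstem, subcortical), P301L at
  1.5/2.5/4/6/8 months (cortex, hippocampus, subcortical), 6 biological
  replicates (the study used 5–7).
* Burden trajectories are logistic in age,
  `B(t) = plateau / (1 + exp(-k (t - onset)))`, with onset 4 months (tangle
  formation) and steepness solved in closed form from the printed cortical
  fold changes at onset: `k = log(2·fold − 1)/(onset − t_first)` with
  fold 5.1 (P301S, plateau 250 fmol/mg) and 11.2 (P301L, plateau
  1000 fmol/mg). Non-cortical regions use plausible values (brainstem
  faster/higher in P301S; subcortical delayed, onset 6 months, in P301L)
  chosen once. Inter-animal variation is mean-1 lognormal with CV 0.25
  (P301S) / 0.5 (P301L — this model is visibly more variable).
* Modification extent couples to burden through a sigmoid in log10 burden
  for the driver peptides 195–209, 212–221, 386–395, 396–406 (max extents
  0.85–0.92, half-point 100 fmol/mg, slope 2 per decade) and 407–438
  (half-point 300 fmol/mg — it becomes a driver only in the high-burden
  P301L regime). All other modified peptides are constitutive (constant low
  extent, uncoupled): only the PRD/C-terminus tracks pathology, and Pearson
  r is scale-invariant, so amplitude alone cannot separate drivers — the
  uncoupling is what makes the "top correlating peptides" structure
  meaningful. Peptides 275–280 (shared) and 25–44 (human-specific) stay
  unmodified so each normalization class has a true reference; without an
  exact zero-extent reference the class-max normalization could not recover
  truth exactly.
* PTM site detection probability is logistic in the local stoichiometry of a
  linked quantified peptide (slope 60). Half-points are placed against the
  default trajectory means with ≥ ~0.05 margins so the planted temporal
  categories are crisp: negative half-points give sites present at all time
  points; PRD half-points stage the pre-onset → concomitant → post-onset
  sequence; ubiquitin sites (canonical K254/K267, named in R1) track the
  late 407–438 ramp so they appear only in the P301L regime; `ubK290`
  (half 0.9) is a planted never-detected negative control; `pS301` exists
  only in the P301S genotype. Engines draw independently, exercising the
  union rule; site tables are emitted in 0N4R local coordinates on purpose,
  forcing the consensus module's mapping path.
* Areas: heavy ∝ standard concentration × per-peptide response factor ×
  transition weight; light additionally carries the true unmodified fraction
  and the endogenous/standard ratio; all areas receive mean-1 multiplicative
  lognormal noise (CV 0.1 default; CV 0 reproduces truth to machine
  precision because every quantity is a ratio of like-noised sums). Peak
  areas are positive and CV-stable, hence lognormal rather than additive
  Gaussian. An optional per-sample mouse-endogenous term inflates shared
  peptides only, to exercise the reference-class logic.

What a green test does **not** establish: the generator has no
interference, no missing transitions, no retention-time drift, no
engine-specific localization errors, and its coupling law is smooth — real
data are messier in all four ways. Green means the calculus and plumbing are
correct, not that the biological parameter values are validated.

## Numerical and degenerate-input choices

Inclusive threshold boundary (`>= 0.5`); fold change baseline is the
earliest time point with data, zero baseline flags folds undefined rather
than erroring; `annotate_temporal` excludes sites absent everywhere;
clustering requires ≥ 2 complete rows; CLI exit codes are 0 (success),
2 (partial, per-sample failures collected in `failures.tsv`), 1 (fatal).
Configs are JSON (no YAML parser in the supported stack). All randomness is
seeded and emission is byte-reproducible under a fixed seed.

## Known limitations

* The mouse sequence is a labelled surrogate (above).
* The exact 18-peptide SRM panel of the source assay is unknown; results on
  the default panel are not peptide-for-peptide comparable.
* Class-max normalization inherits a small upward reference bias when many
  unmodified peptides compete (quantified above).
* Temporal categories depend on the configured onset time point; the
  package takes it as input (default 4 months) rather than estimating it.
* No multiple-testing correction is applied; p-values are labelled
  uncorrected.
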