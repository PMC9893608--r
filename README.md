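# flexitau

Quantitative analysis of Tau aggregation and its post-translational
modification (PTM) landscape from targeted proteomics data.

## The scientific problem

In tauopathies (Alzheimer's disease, frontotemporal dementias) the
microtubule-associated protein Tau accumulates as detergent-insoluble
aggregates whose formation is driven by an ordered accumulation of PTMs —
chiefly phosphorylation of the proline-rich domain (PRD) and the C-terminus
adjacent to the microtubule-binding domain. Transgenic P301S and P301L mouse
models are the standard preclinical systems for this process. Tracking *how
much* insoluble Tau accumulates, and *which fraction of each Tau peptide is
modified* as disease progresses, requires:

1. **Absolute quantification** against a heavy-isotope-labeled, unmodified
   full-length Tau standard carrying a FLEX reporter peptide
   (`SENLYFQGDISR`). A known light synthetic FLEX spike calibrates the
   standard; selected-reaction-monitoring (SRM) light/heavy (L/H) peak-area
   ratios of 3–5 transitions per tryptic peptide then yield fmol Tau per mg
   tissue:

   `standard (fmol/µl) = FLEX spike / (L/H)_FLEX`

   `Tau (fmol/mg) = max(L/H over reference class) × standard × volume / mass`

   where the reference class is the peptide shared between mouse and the
   human transgene (mouse samples) or human-specific (human samples).

2. **Modification extent** per peptide, the fraction of molecules carrying
   any mass-shifting modification:

   `extent_i = 1 − (L/H)_i / max(L/H over the peptide's specificity class)`

3. **PTM site consensus** across search engines (Mascot, MaxQuant,
   ProteinPilot, FragPipe dialects), mapped from the search database's 0N4R
   coordinates to canonical 2N4R numbering (site names `pT212`, `cR155`,
   `ubK254`, ...), retained when seen in ≥ 50 % of biological replicates.

4. **Progression statistics**: complete-linkage/euclidean hierarchical
   clustering, temporal PTM categories relative to the tangle-onset time
   point (present at all time points / before / concomitant / after onset),
   fold changes versus the first time point, Welch t-tests, and Pearson
   correlations of each peptide's unmodified fraction with the log10 amount
   of insoluble Tau.

The raw mass-spectrometry data behind such studies are not desk-scale
reproducible, so the package ships a first-class **synthetic-data module**
that emulates the full measurement structure (logistic insoluble-Tau
trajectories, stoichiometry–burden coupling, heavy-standard spiking,
3–5 transitions per precursor with multiplicative lognormal noise,
stoichiometry-gated PTM detection across replicates and engines) with a
ground-truth sidecar, so every stage is testable end to end.

## Worked example

```r
library(flexitau)

cfg <- scenario_config(replicates = 3)     # P301S + P301L study design
sc  <- simulate_scenario(cfg, seed = 1)
dir <- tempfile()
emit_transition_report(sc, dir, noise_model(area_cv = 0.1), seed = 2)

# quantify one late-stage cortical sample
rep <- read_transition_report(file.path(dir, "transitions",
                                        "P301S_cortex_5m_r1.csv"))
q <- quantify_sample(rep, sc$panels$P301S,
                     tissue_mass = 10, processed_volume = 50)
```

This prints (seed 1):

```
insoluble Tau: 195.9 fmol/mg (reference peptide 275-280, standard 10.24 fmol/ul)
round(sort(q$extent, decreasing = TRUE)[1:5], 3)
212-221 195-209 386-395 396-406 407-438
  0.665   0.579   0.560   0.540   0.292
```

— a late P301S cortex carries ~200 fmol insoluble Tau per mg tissue, and the
most heavily modified peptides are exactly the PRD (195–209, 212–221) and
C-terminal (386–395, 396–406) intervals. Fold change of the same region's
abundance over age reproduces the characteristic surge at tangle formation
(4 months):

```
fold_change_vs_baseline(abundance, time)
  time n      mean     fold flag
1    2 3  24.13559 1.000000   ok
2    3 3  75.52249 3.129092   ok
3    4 3 155.66165 6.449465   ok
4    5 3 235.47119 9.756180   ok
```

The command-line interface runs the same pipeline from files:

```sh
flexitau simulate  --out sim --seed 1 --cv 0.1
flexitau report    --in sim --out report --threshold 0.5 --onset 4
```

`report/` then holds abundance, unmodified-fraction/extent matrices,
consensus PTM frequency and binary matrices, fold changes, t-tests,
correlations, cluster orders and temporal categories, each as TSV, with the
serialized run configuration for provenance.

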