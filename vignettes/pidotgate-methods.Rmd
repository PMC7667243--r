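---
title: "Methods: simulated comparison of manual and automated gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated comparison of manual and automated gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pidotgate` reconstructs, as tested and reusable code, the comparison of
two analysis strategies for blood samples stained with a PID-orientation
style 14-parameter panel: expert-like hierarchical Boolean **manual
gating (MG)** and database-driven **automated gating and identification
(AG&I)**. Real clinical FCS files and the commercial automated module are
proprietary and unavailable, so the package supplies the missing pieces
explicitly: a synthetic-data generator with per-event ground truth, a
transparent automated-gating surrogate with auditable mathematics, and
the statistics layer used for paired method comparison. Everything
downstream of the generator treats samples exactly as it would treat real
event data read from FCS files.

# Data model

A sample is an `event_matrix`: N events by 14 channels (FSC-A, FSC-H,
SSC-A and 11 markers, with CD16&CD56 a single combined channel, as in the
physical tube). Raw intensities live on the instrument scale
`[0, 262144]` (18-bit digitizer convention). Gating operates on a
standardized display scale obtained by `asinh(x / cofactor)` applied to
fluorescence channels only; scatter is never transformed. The cofactor
(default 150) sets the width of the quasi-linear region around zero; it
is a display convention, not a fitted parameter, and the transform is
exactly invertible, which the suite checks to 1e-9. Median fluorescence
intensities (`delta_mfi()`) are always reported in raw channel units, the
scale on which such diagnostics are conventionally quoted; the
transformed scale is treated as display-only.

# The synthetic cohort generator

## Band model

Marker expression is generated from four qualitative bands — neg, lo,
pos, hi — realized as Gaussians on the transformed scale with means
0 / 1.5 / 3.0 / 4.5 and common sd 0.35. Adjacent bands are therefore
separated by more than 4 sd, which makes ground truth recoverable by a
competent gating strategy; weak-separation regimes are produced by
raising `sd`, never by new code paths. Transformed draws are clamped to
the representable raw range before inversion, so a neg-band marker has an
atom of probability at zero intensity, as compensated cytometry data
clipped at the axis does.

## Populations and frequencies

The shipped registry (`inst/extdata/population_registry.yaml`) defines
the full lymphoid hierarchy — four B-cell maturation stages, the
TCRγδ⁺ / CD4⁺ / CD8⁺ / double-negative / double-positive T-cell split
with CD27×CD45RA memory subsets, and NK cells — plus debris and a single
`other_leukocyte` background class. Each terminal population carries a
`fraction_range`, an order-of-magnitude plausible adult healthy-donor
frequency window expressed as a fraction of all white blood cells (for
example, CD4⁺ naive 6–9 %, unswitched memory B cells 0.4–0.8 %, CD8⁺
effector CD27⁺ cells 0.1–0.4 %, double-positive T cells 0.05–0.15 %).
These are generator inputs, not biological claims; per sample, one value
is drawn uniformly in each window, the remaining white-cell mass becomes
the background class, and event counts are a single multinomial draw.
Minor effector subsets deliberately sit below 1 % of WBC, the regime
where the hardest disagreements between strategies occur.

Scatter is Gaussian per template (lymphocytes centered at FSC-A 55,000 /
SSC-A 12,000, inside the recommended QC intervals; debris low; background
high). Doublets receive doubled area signals at singlet height —
FSC-H/FSC-A ≈ 0.49 against ≈ 0.98 for singlets — and inherit the marker
profile (and any aberration) of a randomly drawn lymphoid component.
Default nuisance rates are 2 % doublets and 3 % debris.

## Aberrations and observers

An `aberration_spec` shifts one marker in one population by a constant on
the transformed scale and may widen its sd. Two presets reproduce
described clinical failure modes: `aberration_dim_cd4()` (a technical
staining issue driving CD4⁺ subsets onto the CD4⁻CD8⁻TCRγδ⁻ phenotype)
and `aberration_igd_dim()` (dim IgD on IgM⁻ memory B cells). An expanded
TCRγδ⁺ compartment is produced with `fraction_overrides`.

Observer-to-observer variability in manual gating is modeled exclusively
as threshold jitter: one `N(0, sd²)` draw per marker added to all three
of that marker's cut points. A common shift per marker (rather than
independent shifts per cut) is deliberate: the cuts of one marker sit
0.2 apart in places, and independent jitter at sd 0.1 would regularly
invert them, producing an invalid threshold set rather than a plausible
observer. `jitter_sd = 0` reproduces the canonical thresholds exactly.

## What the generator does not emulate

No fluorescence spillover or compensation error, no acquisition-time
drift, no heavy-tailed or log-normal population shapes, no maturation
continua (CD27 heterogeneity can be approximated by widening its sd via
an aberration's `sd_scale`), and only a single aggregate non-lymphoid
class. Consequently, passing tests demonstrate the correctness and
calibration of the *pipelines* under controlled, well-separated
conditions — not the clinical accuracy of any strategy on real stained
blood, where populations are less Gaussian and less separated.

# Manual gating engine

Published gating tables write phenotypes with superscripts; the engine
fixes their mapping onto band sets: `-` = neg, `lo` = lo, `+` = pos or
hi, `hi` = hi, `- to lo` = neg∪lo, `lo to +` = lo∪pos∪hi,
`- to +` = neg∪lo∪pos. The gate tree mirrors the published strategy:
doublets → debris/lymphocyte gate (scatter rectangle + CD45 hi) → B/T/NK
lineages → TCRγδ⁺ removal before the CD4/CD8 partition → CD27×CD45RA
memory subsets. Sibling predicates are validated to be mutually
exclusive before any event is touched; events matching no sibling fall
into an explicit `unclassified_<parent>` bucket — the engine refuses to
silently imitate the human call that real manual gating would make.
Switched memory B cells follow the printed `CD27^- to +^` band and thus
include truly CD27-negative switched cells; the CD4⁺CD8⁺ double-positive
population is gated but excluded from method comparison by default.

## Threshold placement

The canonical cut points (`inst/extdata/thresholds_pidot_v1.yaml`) are
*not* band-midpoints. An expert places a gate in the low-density valley
between the populations actually present on that marker, and the engine
does the same: on markers whose lo band is unoccupied in normal blood the
neg|lo and lo|pos cuts bracket the center of the wide empty valley
(1.40 / 1.60), making tail losses negligible; CD45's pos|hi cut sits at
3.20, well below the lymphocyte hi band. CD27 is the one marker whose lo
band is genuinely occupied (CD8⁺ effector CD27⁺ cells), so its cuts are
0.75 / 2.00 — the lo|pos cut pushed toward the sparse lo band because
CD27⁺ naive/memory subsets outnumber the CD27-lo effector subset roughly
tenfold, and a mid-valley cut would leak more naive events into the small
subset than that subset contains. A simple error budget drives this
policy: each band constraint whose cut sits k·sd from the population's
band mean loses a `pnorm(-k)` tail to the unclassified bucket or a
neighbor, and the placement keeps the total per-population bias within a
few percent even for rare subsets.

Counts follow the dual-platform convention,
`absolute count/µL = %WBC × WBC/µL / 100`, with all non-doublet,
non-debris events as the WBC-representing denominator (the published
formula leaves the post-cleanup denominator undefined; fixing it
identically in both engines makes their counts directly comparable).

# Automated gating surrogate

The commercial module's internals are undisclosed, so the package fixes a
transparent surrogate that reproduces every *described* behavior —
cluster step, database classification, checks with candidate
populations, numerical remarks — with auditable mathematics. No claim is
made that it numerically matches the commercial implementation on real
files.

* **Database.** Labeled training samples (simulated here; expert-annotated
  in a real deployment) are pooled per population into a mean vector and
  covariance matrix over the 13-dimensional analysis space (11
  transformed fluorescence channels + FSC-A + SSC-A; FSC-H is collinear
  with FSC-A for singlets and already consumed by cleanup). Covariances
  are shrunk toward their diagonal, `(1−λ)S + λ diag(S)` with λ = 0.1, so
  sparse populations stay well conditioned; λ = 1 gives exactly diagonal
  covariances. At least 10 samples and 50 pooled events per population
  are required. Double-positive T cells are excluded by default
  (`include_dp = TRUE` adds them), mirroring the observed behavior that
  the automated module does not report them — and the report accordingly
  omits populations the database cannot represent.
* **Clustering.** Seeded k-means in the per-channel standardized analysis
  space deliberately over-clusters: `k = max(50, ⌈√N⌉)`. For large
  samples, centers are fitted on a seeded subsample (default 50,000
  events) and all events are then assigned to their nearest center in
  fixed-size blocks — memory stays flat and the result is deterministic
  given the seed. Initialization is seeded k-means++ for k ≤ 200 (which
  reliably seeds sparse, well-separated populations) and a seeded simple
  random sample of events above that. With over-clustering, cluster-level
  classification agrees with per-event nearest-population classification
  for >99 % of events on well-separated samples; at k close to the number
  of populations, vanilla k-means regularly lands in local optima that
  split abundant populations and merge adjacent rare ones, which is why
  over-clustering is the default and not a tuning afterthought.
* **Classification.** Each cluster centroid is compared with every
  database population by squared Mahalanobis distance and assigned to the
  nearest population iff that distance does not exceed the χ² quantile
  (df = 13) at `cutoff_quantile` (default 0.999). Distances equal within
  1e-12 are ties, broken toward the larger training population, then
  lexicographically. Unassignable clusters become *checks* carrying the
  up-to-three nearest candidates; an expert resolution map can assign or
  discard them, with auto-assigned clusters immutable unless an explicit
  override mirrors an extended expert revision. Lowering the cutoff can
  only grow the checks load, and the checks fraction is reported under
  both denominator conventions (lymphoid events, and all clustered
  events) since the convention is otherwise ambiguous.
* **Report.** Counts use the same cleanup and denominator as MG; each
  population (terminals plus ancestors) is compared with its age-matched
  p5–p95 interval and flagged with a remark when outside. Fixed database,
  seed and cutoff give a bit-identical report on reruns — the property
  behind the automated module's reproducibility advantage.

# Reference ranges

`derive_reference_ranges()` emulates the construction of age-matched
reference intervals from a healthy cohort: empirical 5th/95th percentiles
(linear interpolation between order statistics, `quantile` type 7) of
ground-truth absolute counts per population per age bin. Default bin
edges (0, 2, 5, 10, 18, 65, 120 years) are a documented convention —
published sources do not state theirs — and every bin must hold at least
20 samples; adult-only studies pass `c(18, 65)` explicitly. Degenerate
intervals (p5 = p95, e.g. from constant counts) are an error, not a
silent zero-width range. With 250 training donors, roughly 10 % of
held-out healthy counts fall outside the derived interval per population,
which the suite checks as a calibration property (jointly across 20
populations, individual rates are judged against familywise binomial
bands; a per-population 90 % band applied 20 times simultaneously would
be expected to fail by chance alone).

# Comparison statistics: conventions

* Percent difference is signed and MG-referenced:
  `(MG − AG&I)/MG × 100`; both counts zero → 0; MG zero with AG&I
  positive → undefined, treated as non-equivalent. Equivalence is strict:
  `|diff| < 20`.
* Range statuses use the inclusive interval `[p5, p95]`; clinical
  relevance is any status mismatch (including below-p5 vs above-p95). In
  the study harness it is tabulated only for observations that already
  failed the 20 % criterion, matching how such comparisons are reported.
* CVs use the sample SD (n − 1); a zero mean leaves the CV undefined and
  excluded from medians. Both choices are the package's documented
  defaults where the source conventions are unstated.
* The Yates-corrected χ² implements `Σ(|O−E|−0.5)²/E` exactly, without
  capping the correction at `|O−E|` — the divergence from
  `stats::chisq.test` appears only at the O = E boundary, and the two
  agree elsewhere (cross-checked in the suite).
* Bonferroni rejection uses the strict inequality `p < α/m`; adjusted
  p-values are `min(1, m·p)`.

# The study harness

`run_study()` analyzes every cohort sample with both engines against a
database trained on a *disjoint* cohort (overlapping sample ids are a
hard error), produces per-population comparison records, and tabulates
discrepancy and clinical-relevance rates per population and group plus
Spearman correlations. Per-sample automated-gating seeds are derived from
sample ids rather than list positions, so the study is invariant under
reordering of the cohort.

The reproducibility harness re-analyzes a seeded subset (default 12
samples) five times per condition. Manual intra-observer replicates are
independent small-jitter re-gatings (sd 0.05 by default); inter-observer
replicates are five observers with independent jitter at sd 0.1.
Automated intra-observer replicates rerun the pipeline with a fixed
clustering seed — the runs are provably bit-identical, so identical
invocations are computed once and reused, and the intra-observer CV is
exactly 0; inter-observer replicates use observer-specific clustering
seeds and produce small but nonzero CVs. This reproduces the qualitative
contrast reported for such modules: manual inter-observer CV medians
exceed the automated ones by an order of magnitude in the shipped study.

# Numerical choices and degenerate inputs

Raw intensities are clamped to `[0, 262144]`; transformed draws are
clamped to the corresponding asinh range before inversion. Events with
zero FSC-A cannot form a singlet ratio, are excluded by the doublet gate
and tallied separately. Scatter-QC bounds are strict inequalities, so a
median exactly on a bound fails. Empty clusters (possible when k
approaches N) are skipped during classification. All randomness flows
from explicit integer seeds through isolated RNG scopes; no function
perturbs the caller's RNG state.

# Problem sizes

The shipped tests and the acceptance script run at sizes chosen to make
the statistical properties measurable while keeping a full run on one
CPU comfortable: 10 training donors at 5×10⁴ events for the database, 250
simulated donors at 2×10⁴ events for reference ranges, 26-donor
evaluation cohorts at 10⁵ events, a 10⁶-event sample for the
ground-truth-recovery check, and 12 samples × 5 observers/replicates for
the reproducibility harness. All sizes are arguments, not constants.

# Known limitations

The automated surrogate shares only its observable behavior with the
commercial module, not its algorithms; agreement with that module on real
files is unknowable from here and not claimed. The generator's Gaussian
bands understate real biological overlap (notably continuous CD27
maturation), so absolute discrepancy rates in the simulated study are
lower than published real-data rates — the package mirrors directions
and mechanisms (which populations disagree, why, and how alarms fire),
not their field magnitudes. Reference ranges are derived from simulated
cohorts and have no clinical meaning.
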