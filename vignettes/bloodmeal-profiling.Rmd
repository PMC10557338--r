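---
title: "Methods: combined human-mosquito STR profiling of blood meals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combined human-mosquito STR profiling of blood meals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodmealSTR)
```

## The problem

A blood-fed *Aedes albopictus* female carries two genomes of interest: her
own and her host's. Genotyping both on one platform — 19 mosquito STRs for
vector population structure and 16 human STRs (13 CODIS loci, two further
fingerprinting loci, and Amelogenin for sex) for host identification —
makes it possible to reconstruct *who bit whom*: a bipartite biting network
linking individual mosquitoes to individual people. The biological
obstacles are that host DNA in a blood meal degrades with digestion time,
that storage chemistry changes signal strength, and that a mosquito may
feed on several people in one gonotrophic cycle, superimposing two or three
genotypes in a single electropherogram.

This vignette documents the models and procedures the package implements,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the problem left the design open.

## From peaks to profiles

**Binning.** A peak is a `(multiplex, dye, size_bp, height)` record. It is
assigned to the unique panel locus sharing its channel whose size range,
widened by `tol_bp` (default **0.5 bp**, the conventional capillary
electrophoresis resolution; no binning window is prescribed by the
chemistry itself), contains the fragment. Peaks matching no locus are
rejected with a reason; peaks falling inside a same-channel overlap of two
loci are rejected as *ambiguous* rather than guessed. The packaged marker
table itself contains two such overlaps (Alb-tri-21/Aealbmic7 at 194–206 bp
in multiplex 1/ATTO565 and Alb-tri-6/D21S11 at 203–219 bp in multiplex
3/6-FAM); `validate_panel()` reports them, and fragments landing there are
surfaced instead of silently mis-scored.

**Allele labels** are integer repeat offsets from the range start,
`round((size - size_min) / repeat_unit_len)`, not nomenclature allele
numbers: the panel table publishes only bp ranges, and offsets are
sufficient for identity, kinship and mixture work. Amelogenin is labelled
by nearest amplicon, X at 106 bp and Y at 112 bp (the X/Y indel); one peak
means X,X, two mean X,Y.

**Homozygote convention.** A homozygote presents a single peak of roughly
twice a heterozygote's per-allele height. `per_allele_heights()` therefore
splits a single-peak locus into two half-height allele copies. Mean peak
height (`mean_ph()`) deliberately does *not* split: it is defined as the
sum of detected-allele peak heights over the number of alleles detected,
matching how electropherograms are read.

**Standardization.** Peak heights are only comparable within a run, so
batch statistics are range-standardized (Sneath–Sokal "ranging"):
`x' = (x - min) / (max - min)` over the batch being compared. Whether the
published analyses ranged per locus or per sample mean is not stated; the
package standardizes the *per-sample mean* across the experiment batch by
default (that is the scale on which the preservation and digestion
comparisons are plotted), and the function is scope-agnostic — callers can
pass per-locus batches instead. A constant batch maps to zeros with a
warning.

**Completeness.** Against the post-exclusion 13-locus human panel, a
profile is `complete` when all loci are typed, `nearly_complete` at ≥ 11
(the field rule), `incomplete` otherwise.

## Nei's D_A on individuals

For profiles `x`, `y` with within-individual allele frequencies (1 for a
homozygous allele, 0.5/0.5 for a heterozygote),

$$D_A = 1 - \frac{1}{L}\sum_{l=1}^{L}\sum_{a}\sqrt{x_{la}\,y_{la}}.$$

Two choices matter:

* **Missing loci.** Default is pairwise deletion: `L` counts loci typed in
  *both* profiles. Blood-meal profiles are routinely partial, and the
  published matching explicitly tolerated amplification failures, so
  partial-vs-full comparisons must not be penalised for missingness. A
  complete-union policy (`policy = "all"`, missing side scored as zero
  similarity) is available; how the original matrix software treated
  missing loci is unknowable from the text, so both are exposed.
* **Amelogenin** participates as an ordinary two-allele locus by default
  (it is one of the 16 profiling loci); `exclude = "Amelogenin"` gives
  autosomal-only distances.

Matching applies the strict rule **D_A < 0.15** against every reference,
with `min_shared = 6` jointly typed loci as a comparability floor (no floor
is published; six loci keep sparse partial profiles from producing
spurious certainty — they come back `incomparable`, not `unmatched`).
Multiple sub-threshold references are reported `ambiguous`, never resolved
to the smallest distance: no such case occurred in the original data, so
the artifact surfaces rather than invents a tie-break.

PCoA of a D_A matrix is classical Gower double-centering of −D²/2 with
eigendecomposition, delegated to `ape::pcoa()` behind `run_pcoa()` (the
same route the original analysis used). Axes with eigenvalue below 1e-10 of
the largest are dropped — a numerical floor, nothing more; negative
eigenvalues are reported, never embedded.

## Mixtures

The minimum contributor count is `ceil(max per-locus distinct alleles / 2)`
with Amelogenin capped at two alleles. Deconvolution peels contributors
from the height ranking at each locus: a lone top allele at least
`major_ratio` times the runner-up is a homozygous major genotype; a top
pair jointly clearing the third allele by the same margin is a
heterozygous one; anything flatter is a *masked* locus (the masking effect
of taller alleles in the same position) and stays unassigned. Defaults:

* `major_ratio = 2.0` — no numeric rule is published; 2× mirrors the
  homozygote-doubling logic and is configurable.
* `consistency = 0.75` — if the major genotype resolves at fewer than 75%
  of typed loci the report is flagged `unresolved_major` (the near-equal
  proportions case).

Minor contributors are reported as *partial profiles only*; when the
remainder at a locus cannot be split further it is pooled into the current
minor rank. No cross-locus phasing of minors is attempted — with the
height signal alone that would be invention, and the original work likewise
recovered only partial minor profiles.

## Digestion decay

Detectability and standardized PH versus post-feeding time follow a
descending sigmoid. The package fits the three-parameter descending
logistic `v(t) = A / (1 + exp(k (t - t50)))` with floor 0 by
Levenberg-Marquardt least squares (`minpack.lm`), initialised at
`A = max(v)`, `t50` at the time nearest `A/2`, `k = 0.1`/h, bounded
`A > 0, k ≥ 0`. Constant input or non-convergence is flagged, never
silently defaulted. `invert_time()` is the exact inverse
`t = t50 + log(A/v - 1)/k`, making PH usable as a proxy for post-feeding
time. Fits default to per-sample values; per-time means can be fitted by
passing the summary table instead (which of the two the original curve
used is not stated).

## What the generator emulates

`generator_config()` fixes the simulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_alleles` | 6 / locus | flat-Dirichlet frequencies, labels legal for each range |
| `base_height` | 300 RFU | heterozygote per-allele peak at t = 0, ethanol |
| `preservation_multipliers` | ethanol 1, lysis buffer 2.2 | the observed ~120% buffer advantage, as a calibration *input* |
| `digestion` | A = 1, t50 = 55 h, k = 0.15/h | decay factor on expected heights |
| `height_sigma` | 0.3 | lognormal multiplicative noise |
| `detection_threshold` | 50 RFU | peaks below are dropped and ledgered |
| `base_dropout`, `length_dropout_slope` | 0.002 at 100 bp, +0.01 logit/bp | amplicon-length-dependent allelic dropout |

Expected peak height is the closed-form product *base × proportion ×
preservation × sigmoid(t) × (2 if homozygous)*; shared alleles sum across
contributors; each sample draws from its own RNG stream derived from the
master seed, so any subset regenerates identically. The digestion
calibration was chosen so that detection is near-complete through 48 h
(~31.5 of 32 alleles), under 20% at 72 h and essentially zero at 96 h,
with the longest amplicons (PentaD 376–449 bp, PentaE, FGA) dropping out
preferentially — a calibration, not an estimate: no quantitative
dropout-versus-length curve is published, so the logit-linear slope is a
free, documented parameter. Double-meal simulations draw the dominant
proportion in [0.70, 0.80], representing consecutive partial feeds with
unequal remaining template; near-equal mixtures (the regime where
deconvolution must defer) are exercised separately in the tests.

Not modelled: stutter peaks, pull-up between dyes, within-locus
degradation slopes, PCR competition between contributors, and size-standard
miscalibration. Passing tests therefore show that the *inference logic* is
correct under clean mixture/decay/dropout kinetics — not that real
electropherogram artifacts are handled; real data still needs expert
review of flagged ambiguous and masked calls.

## Numerical choices and degenerate inputs

* Size intervals are closed integer bp intervals; overlap means non-empty
  intersection.
* The D_A threshold comparison is strict (`<`), exactly as specified; the
  boundary behaviour is tested by setting the threshold equal to a
  computed distance.
* Percentages in the field summary round half away from zero to integer
  percent (62%, 89%, 11%, 55% presentation).
* Empty inputs are legal throughout: empty panels, empty peak tables and
  empty networks flow through and yield empty-but-valid results; zero
  detected alleles make `mean_ph()` an error (undefined), while the
  detectability table scores such samples as zero signal.
* Field exclusions are configuration, not computed: as printed, the vWA
  and D5S818 ranges intersect no same-multiplex same-dye partner, so their
  exclusion (reported as overlap under field scoring) is applied by name.

## Shape of the repository

The package is organised as an analysis workflow: all computation lives in
the package (`R/`), and the numbered scripts under `analysis/` are thin
narrative drivers reproducing the study's experiments on synthetic data —
panel audit and family discrimination, preservation comparison, digestion
curve, multiple feedings, and the field trial — writing their tables under
`results/`. `run_pipeline()` plus these drivers are the intended
entry points; there is no separate shell CLI.

Problem sizes used by the test suite and the drivers mirror the study
design where one exists (5 + 5 preservation samples; 21 digestion
mosquitoes at 0/12/24/48/72/96 h; 7 multiple-feeding mosquitoes; 61
mosquitoes / 40 references / 38 positive / 4 doubles in the field layout)
and otherwise stay small (500 matching-calibration trials, 100 simulated
families) so a full run completes in a few minutes.

## Known limitations

* Allele labels are panel-relative repeat offsets; exporting to forensic
  nomenclature would need a ladder calibration table.
* Deconvolution is deterministic and height-threshold based, not a
  probabilistic genotyping model; three-contributor meals with heavy
  allele sharing will return pooled, partially masked minors.
* The completeness mix of simulated field profiles is more optimistic than
  degraded field material (the generator lacks stutter and extraction
  losses); percentages that depend on it, other than the worked-example
  arithmetic, should be read as generator properties.
* `nei_da()` on candidate mixtures (>2 alleles per locus) uses
  proportional counts; deconvolve first for meaningful host comparisons.
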