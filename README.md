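# bloodmealSTR

Who did that mosquito bite? `bloodmealSTR` is an R toolkit for identifying
the human hosts in *Aedes albopictus* blood meals with a combined
human–mosquito short tandem repeat (STR) panel: 35 loci (16 human, including
13 CODIS markers and the sex locus Amelogenin, plus 19 *Ae. albopictus*
loci) co-amplified in three multiplexes and scored on a capillary
sequencer. The package is aimed at vector ecologists and genetic
epidemiologists who want to turn sized electropherogram peaks into
human–mosquito biting networks.

It implements the complete analysis chain:

* **Panel model** — machine-readable marker table (motif, repeat unit,
  allele size range in bp, multiplex, dye), conflict auditing
  (same-multiplex same-dye size overlaps), and named locus exclusions for
  field work (`PentaD`, `vWA`, `D5S818`, leaving 13 human loci).
* **Peak calling** — binning of sized fragments (default tolerance 0.5 bp)
  into allele calls labelled by repeat offset (Amelogenin X = 106 bp,
  Y = 112 bp), per-sample multilocus profiles, the homozygote
  peak-doubling convention, mean peak height (PH), Sneath–Sokal range
  standardization, and completeness classes (complete / nearly complete,
  i.e. ≥ 11 loci / incomplete).
* **Population genetics** — Nei's D_A distance between individual
  profiles,

  D_A = 1 − (1/L) Σ_loci Σ_alleles √(x_a · y_a),

  with pairwise deletion over jointly typed loci; distance matrices; PCoA
  (Gower double-centering, via `ape`); one-way ANOVA with Tukey HSD.
* **Matching** — blood-meal profiles vs a saliva reference database under
  the strict rule D_A < 0.15, with explicit `unmatched`, `ambiguous` and
  `incomparable` outcomes.
* **Mixtures** — minimum contributor count `ceil(max alleles per locus / 2)`
  and deconvolution of multiple feedings by relative peak heights (major
  profile, minor partial profiles, masked loci).
* **Digestion** — descending sigmoid `v(t) = A / (1 + exp(k (t − t50)))`
  fitted to detectability or standardized PH versus post-feeding time, with
  exact inversion to estimate time since feeding.
* **Networks** — bipartite mosquito ↔ human-profile graphs with match
  annotations and the field summary counts.
* **Synthetic data** — a fully seeded generator (HWE populations, Mendelian
  families, mixed meals, preservation multiplier, digestion decay,
  amplicon-length-dependent dropout) with ground-truth ledgers, used by the
  analysis scripts and the test suite.

## Worked example

Simulate a field campaign in the published design — 61 trapped mosquitoes,
38 carrying human DNA (4 of them double meals), 40 swabbed volunteers — and
push it through the whole pipeline:

```r
library(bloodmealSTR)

cfg <- generator_config(seed = 1)
fs  <- gen_field_study(cfg)          # 61 mosquitoes, 40 references
res <- run_pipeline(fs$peaks, fs$references, fs$panel,
                    n_collected = 61, sessions = fs$sessions)
res$summary
#> Field summary: 38/61 mosquitoes with human DNA (62%); 34 single / 4 double / 0 triple meals;
#> 42 profiles, 38 complete or nearly (90%); 38 matched to 25 individual(s)
```

62% of collected mosquitoes yield a human signal, the four double meals are
recognised from loci showing three or four alleles, and every single-meal
major profile is matched to its true reference (the generator's ledger in
`fs$truth` confirms it). Distances behave like textbook Nei's D_A:

```r
a <- str_profile("hom", list(TH01 = c("6", "6")))
b <- str_profile("het", list(TH01 = c("6", "9")))
nei_da(a, b)
#> [1] 0.2928932          # = 1 - sqrt(1 * 0.5), one shared allele
```

The `analysis/` directory holds the five numbered study drivers
(`01_panel_and_families.R` … `05_field_study.R`: panel audit and family
PCoA, preservation comparison, digestion curve, multiple feedings, field
trial). Each is run as `Rscript analysis/01_panel_and_families.R [seed]`
and writes its tables under `results/`.

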