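---
title: "Methods: cross-species oligo painting, panel design and karyotyping"
author: "oligofish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species oligo painting, panel design and karyotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligofish)
```

## The problem

Chromosome painting probes are pooled libraries of short synthetic
oligonucleotides (here ~45 nt) tiling an entire chromosome of a source
genome. Because they are designed from single-copy sequence, they stay
usable across species that diverged many million years ago: hybridized to
metaphase spreads of a related species, each pool lights the chromosomes
that retain enough homologous sequence. `oligofish` models the full dry-lab
side of such an experiment: screening a painting library against a target
genome, predicting which chromosome/probe combinations will produce visible
FISH signals, planning sequential hybridization rounds that uniquely
identify every chromosome of a complement, and condensing metaphase arm
measurements into a karyotype table and idiogram. A seeded simulator
generates every input with a complete truth log so each stage can be
validated end to end.

## Homology screen and the retention rule

Each oligo is aligned to the target genome on both strands without gaps.
A placement is *retained* when its matched bases reach both

* an absolute floor, `min_match_bp` (default **32 bp**), and
* a fraction of the oligo length, `min_homology_frac` (default **0.70**).

For 45-nt oligos the two coincide (`ceil(0.70 * 45) = 32`), which is also
why 45 nt is the simulator's default oligo length: it is the length at
which a 32-bp absolute cutoff equals 70% homology. Ambiguous bases (N)
count as mismatches. A hit is one (chromosome, strand, diagonal) placement;
overlapping seeds on the same diagonal are merged; per oligo at most
`max_hits_per_oligo` (default 50) best hits are kept, ties broken by
chromosome name then start so output is reproducible byte for byte.
Placements must lie fully inside a chromosome: end-clipped partial
placements are not scored, which keeps the hit algebra (span, identity,
mirror symmetry under reverse complement) exact.

Two search modes are provided because no seeded heuristic can be complete
at this threshold:

* **`"seed"`** (default): classic seed-and-extend over an exact k-mer index
  (`seed_k`, default 16). Fast at genome scale, but a qualifying placement
  with up to 13 scattered mismatches need not contain any exact 16-mer, so
  hits near the 32/45 threshold can be missed — exactly as with any
  heuristic mapper.
* **`"exhaustive"`**: scores every full-length diagonal with early abort.
  Complete with respect to the retention rule; the right tool for small
  genomes and for calibration against closed-form expectations. The test
  suite proves it equal to an independent brute-force oracle.

Interpretation note: "70% homology" is implemented as
`matched >= ceil(frac * length)` jointly with the absolute floor, and
retention counts are *distinct oligos per chromosome* (an oligo hitting one
chromosome five times counts once there, but an oligo hitting three
chromosomes counts on each). Row sums can therefore exceed the probe-set
size on polyploid targets, which is intended.

## Signal calls: two tiers, not one

A probe set with more than ~1000 retained oligos on a chromosome is a
*candidate* for a visible signal (`candidate_min`, default 1000). Published
microscopy, however, shows counts in the low thousands both producing and
failing to produce observed signals, so a single cutoff cannot reproduce
what is seen at the microscope. We therefore add a second, configurable
tier `confident_min` (default 3000): counts in `[candidate_min,
confident_min)` are *uncertain*, counts above are *present*. Planning
functions can barcode chromosomes at either level (`min_level`): candidate
level reflects everything that might hybridize; present level reflects what
an observer can rely on, and is the level at which the published
seven-probe, three-round panel's identification-by-exclusion structure is
reproduced.

Density profiles bin retained hits into fixed windows (default 500 kb) by
their start coordinate — half-open, last window short, every window of
every chromosome emitted so BED output tiles each chromosome completely.
Window counts are per retained locus (no per-oligo deduplication), so
window sums are >= the count-matrix cell. Patterns (window vectors
normalized to sum 1) are attached only to cells at candidate level or
above; below that they are noise.

## Panel planning

A chromosome is *identified* by a panel when its binary barcode over the
panel's probes is unique and non-zero. Two refinements mirror microscope
practice:

* **Pattern disambiguation.** Chromosomes sharing a barcode can still be
  told apart when a shared probe paints them in visibly different
  along-chromosome patterns (whole-arm versus distal block, say). Patterns
  are rescaled to a common 20-bin relative-position grid and compared by
  total-variation distance; a pair is separable above `tv_threshold`
  (default 0.2, our quantification of "visually distinct" — the literature
  offers none). The 0.2 default separates a uniform whole-chromosome paint
  from any pattern concentrating >= 20% of its signal elsewhere, while
  tolerating binning noise.
* **Exclusion.** A chromosome with no reliable signal at all cannot be
  positively named, even if it is the only dark one — but after every other
  chromosome is identified, the single leftover is named by exclusion. At
  most one chromosome may be identified this way, and an all-zero barcode
  is never treated as a positive identification.

Rounds carry `fluorophores_per_round` painting probes (default 2:
digoxigenin/red and biotin/green); single-locus extra probes such as 5S and
35S rDNA ride along sharing a channel, as in practice, and do not consume
capacity. Probes are never reused across rounds because re-probing strips
the prior signal.

`plan_rounds()` is greedy: it repeatedly adds the probe that newly resolves
the most chromosomes (ties: fewer lit chromosomes, then label order) and —
deliberately — keeps adding probes through zero-gain picks while budget and
unresolved chromosomes remain, because two probes can jointly split a group
that neither splits alone. Since adding a probe only refines barcodes
(resolution is monotone), greedy provably succeeds whenever the *full* pool
resolves and the budget covers it. With a tight budget greedy is an
approximation and can fail where a cleverer subset exists;
`enumerate_optimal()` is the exhaustive oracle (all minimum-size resolving
subsets, guarded to <= 12 probes and chromosomes) used to check it.

## Karyotype summaries

Arm measurements arrive one row per measured homolog copy. Homolog copies
are averaged *within* each cell first, so cells missing a copy remain
comparable; statistics are then across cells. The per-cell total is
long + short and the per-cell arm ratio is long/short of the cell-averaged
arms; reported values are means of per-cell values. The distinction
matters: published tables are only consistent with the *mean of per-cell
ratios*, not the ratio of mean arms (mean arms 2.02/1.56 give 1.29 where
1.30 is printed). Records with short > long are swapped with a warning, a
zero or negative arm is an error. Reported tables round half-up to two
decimals, matching how such tables are conventionally printed.

Centromere classes use the conventional arm-ratio boundaries — m <= 1.7 <
sm <= 3.0 < st <= 7.0 < t, boundaries inclusive on the left class and
configurable — applied to the mean ratio.

Reference numbering transfers by exact binary barcode identity between
target and reference signal calls; all-zero, unmatched, or multiply
matching targets are flagged, never silently assigned. Many targets mapping
to one reference is reported but is the expected outcome for homoeologous
groups of a polyploid.

Idiograms draw bars proportional to total length (short arm up, centromere
at the arm boundary) with annotation tracks on four regions (`whole`,
`distal-short`, `distal-long`, `pericentromeric`); SVG and JSON exports are
deterministic, so identical inputs give byte-identical files.

## The simulator and what it does (not) emulate

Every generator is a pure function of its configuration and seed.

* **Reference genome**: i.i.d. uniform A/C/G/T. Base composition is
  deliberately unrealistic — none of the screened properties depend on GC
  content — and chromosomes default to a 2.0 -> 0.8 Mb ramp (desk scale).
* **Library**: oligos at evenly spaced starts to a density of 0.25 per kb
  (the published library's density), one probe set per source chromosome,
  with a single-copy filter (a retained oligo occurs exactly once in the
  genome over both strands; failures are locally re-sampled, and the
  generator errors if filtering destroys more than 20% of the target
  density).
* **Divergence**: per-site independent substitution, always to a different
  base, no indels — consistent with the ungapped aligner and a declared
  limitation. Common random numbers across rates make substitution sites
  nested at a fixed seed, so library retention is non-increasing in the
  rate *by construction*, and retention has the closed form
  `P(Binom(45, 1 - s) >= 32)`. At rate 0.10 that probability is 0.99992:
  with a few hundred oligos the observed retention typically ties the
  rate-0 value at exactly 1, so only the distant-scenario comparison is
  strict. Scenario labels in million years map to rates only through a
  user-chosen clock.
* **Rearrangements**: translocations move tagged segments (and any rDNA
  analog inside them) between chromosomes, recorded in the truth log. rDNA
  analogs are tagged intervals, not repeat arrays.
* **Polyploid complement**: `ploidy_level` copies per basic chromosome with
  independent low-rate jitter, default 2n = 60, x = 10 (hexaploid).
* **Measurements**: per cell and copy, arms are truth plus Gaussian noise
  (SD 0.15 um, truncated positive), copies dropped at a missing-copy rate,
  and long/short relabeled after noise as a microscopist would. That
  relabeling is an order statistic: for chromosomes whose arms differ by
  less than ~2 noise SDs it biases the long arm up and the ratio away
  from 1. The default truth karyotype therefore uses well-separated arms
  (ratios 1.45-2.2, arm differences >= 0.5 um); recovery tests on
  near-metacentric truths would measure that bias, not an implementation
  error. This is a known limitation of enforced arm ordering, not of the
  estimator.

Passing tests on these synthetics show the machinery is correct and
calibrated under the stated model; they do not show that real hybridization
intensity, repeat landscapes, or condensation-dependent arm measurements
behave this way.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere, matching BED output.
* Probe sets are encoded as the FASTA identifier prefix before `_`
  (configurable) — the published libraries ship as per-chromosome pools
  with no dedicated format.
* Thousands separators are accepted when reading count matrices (printed
  tables use them) and never written.
* `ceil(frac * length)` is computed with a 1e-9 guard against binary
  representation artifacts.
* Hit ordering, window ordering, and SVG text formatting are fully
  deterministic; reports contain no timestamps, so identical runs are
  byte-identical.
* Desk-scale problem sizes used by the tests and the acceptance script —
  genomes of 4-200 kb, libraries of 10-260 oligos, 100 oracle-equality
  instances, a 200-oligo divergence grid — were chosen so the whole suite
  validates the method in about a minute while keeping every statistical
  check adequately powered.

## Worked example

```{r demo, eval = FALSE}
cfg <- demo_config(seed = 1)
report <- run_pipeline(cfg)
vapply(report$stages, `[[`, character(1), "summary")
```

The demo preset (60-150 kb chromosomes, 263 oligos, divergence 0.10,
12-mer seeds) screens, profiles, plans and karyotypes in a few seconds;
the plan resolves all ten homoeologous groups with the two rDNA probes
riding on the final round.

## Known limitations

* Ungapped alignment only; real divergence includes indels that a
  matched-length rule would treat harshly.
* Seed mode is incomplete near the retention threshold (use exhaustive
  mode when completeness matters).
* Hybridization efficiency decay over sequential rounds, fluorophore
  spectral overlap, and probe cost are not modeled.
* The uncertain band exposes, but does not explain, why some
  low-thousands counts produce signals and others do not.
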