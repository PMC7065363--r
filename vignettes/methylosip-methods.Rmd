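---
title: "Methods and design of the methylosip pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the methylosip pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylosip)
```

## The problem

DNA stable-isotope probing (SIP) identifies which members of a microbial
community assimilate a particular carbon substrate. Microbes that grow on a
^13^C-labelled substrate (here: methanol, or CO~2~ fixed by plants and
released as root exudate) synthesize DNA that is denser than normal, and
this "heavy" DNA can be separated from unlabelled "light" DNA on a CsCl
density gradient. Sequencing the heavy and light fractions of both a ^13^C
incubation and a parallel ^12^C control yields, for each taxon, four
relative abundances:

* ^13^C~H~ — abundance in the heavy fraction of the ^13^C incubation,
* ^13^C~L~ — abundance in the light fraction of the ^13^C incubation,
* ^12^C~H~, ^12^C~L~ — the same two quantities in the ^12^C control.

methylosip implements the decision rule that turns these four numbers into
a labelled / not-labelled verdict, the gradient-fraction bookkeeping that
precedes it, the degenerate-primer design used to assay the divergent
methanol dehydrogenase gene *mdh2*, and the quantification of methanol
dehydrogenase gene clades (*mxaF*, *xoxF1*–*xoxF5*, *mdh2*) from metagenome
screens and qPCR.

## The labelling decision rule

A taxon is called ^13^C labelled when all of the following hold on its
replicate-averaged profile:

1. **Abundance floor.** ^13^C~H~ > 0.1% (0.001). Taxa below this are too
   rare in the heavy fraction for the comparisons to be meaningful; they are
   reported as `below_floor`, not as negatives.
2. **Criterion 1.** ^13^C~H~ > ^12^C~H~: more abundant in the ^13^C heavy
   fraction than in the ^12^C heavy fraction, which controls for DNA that
   bands heavy for reasons unrelated to labelling (GC content).
3. **Criterion 2.** ^13^C~H~ > *k* · ^13^C~L~ **and** ^12^C~H~ ≤ ^12^C~L~:
   genuinely shifted into the heavy fraction under ^13^C, and *not* shifted
   under ^12^C.

The factor *k* is the tunable stringency. For substrate-based labelling
with methanol, secondary consumption of labelled metabolites
(cross-feeding) is the dominant false-positive source and *k* = 10 is
appropriate; for the more transient ^13^CO~2~ root-exudate labelling,
*k* = 2. `call_params()` holds both knobs.

Numerical conventions, chosen once and applied literally:

* All `>` comparisons are strict; the ^12^C~H~ ≤ ^12^C~L~ comparison is
  non-strict. A taxon with ^13^C~H~ exactly 0.001 is `below_floor`.
* ^13^C~L~ = 0 with ^13^C~H~ > 0 passes the *k* test for every *k*
  (0 · *k* = 0). This is documented behaviour, not special-cased.
* Taxa absent from a fraction sample have abundance 0, never `NA`.
* Abundances are taken as given per fraction sample (they are already
  compositional); nothing is re-closed after filtering.
* Replicates are combined by the arithmetic mean of each of the four
  abundances *before* the criteria are applied. A per-replicate voting
  mode (`mode = "vote"`, majority wins) exists but is off by default.
* The floor is evaluated on the replicate mean by default. Whether it
  should instead be required of every replicate individually is a
  legitimately open choice; `floor_per_replicate = TRUE` provides the
  stricter reading.
* The rule is deterministic, not a hypothesis test, so no multiple-testing
  correction applies.

**Control exclusion.** Autotrophs fix ^13^CO~2~ whether or not a plant is
present, so in the CO~2~ experiment an unplanted control incubated under
the same atmosphere is analysed with the same parameters, and any taxon
labelled in *both* the rhizosphere and the unplanted control has its
verdict replaced by `excluded_control`. Exclusion only ever downgrades
`labelled` rows: the final labelled set is exactly (test labelled) minus
(control labelled).

## Gradient fractionation

Twelve fractions are typically collected per gradient and their CsCl
density estimated from refractometer readings through an affine
calibration, `density = slope · nD + intercept`. The defaults
(slope 10.9276, intercept −13.593 g ml^−1^) are the standard CsCl
linearization used in SIP protocols; they are configuration values, since
every refractometer/medium combination has its own calibration. Readings
outside 1.3–1.5 nD trigger a warning (transcription-error guard), never an
error.

Fractions are then designated `heavy`, `light` or `discard` by two
non-overlapping density windows, inclusive at both ends, defaulting to
1.725–1.735 and 1.705–1.720 g ml^−1^ — typical band positions of
^13^C-labelled and unlabelled DNA. Which collected fractions count as
heavy or light is ultimately a per-study pooling decision, so the windows
are exposed as configuration rather than fixed.

## The synthetic experiment generator

`simulate_experiment()` generates the full factorial of treatment
(rhizosphere / unplanted) × isotope (^13^C / ^12^C) × fraction class
(heavy / light) × replicate, with a truth table. It is the package's test
bed: every downstream stage is validated against data whose labelled,
cross-feeding and autotrophic taxa are known.

The generative model, per treatment:

* **Baseline composition** — one draw from a symmetric Dirichlet with
  concentration `base_abundance_concentration` (default 1, an
  exponential-like rank-abundance profile typical of genus-aggregated soil
  communities; lower values give more uneven communities).
* **Enrichment** — in a ^13^C incubation, an isotope-assimilating taxon's
  heavy-fraction weight is `baseline × e`, with `e` log-normal
  (median `enrichment_mean` = 50 for primary consumers and autotrophs,
  `crossfeed_enrichment_mean` = 5 for cross-feeders, log-sd
  `enrichment_sd` = 0.25). Its light-fraction weight is depleted to
  `baseline / e`: DNA that banded heavy has left the light fraction. The
  median 50 reflects the strong enrichment expected after days of growth
  on the labelled substrate; the cross-feeder median 5 sits deliberately
  between the k = 2 and k = 10 stringencies so that the two regimes
  separate primary from secondary consumers.
* **Leakage** — every non-enriched taxon contributes `λ · baseline` to
  heavy fractions. λ is `background_leakage` (default 0.1) for most taxa,
  but a random 5% "high-GC" minority leaks at `min(1, 20 ×
  background_leakage)`. This minority is what makes the otherwise DNA-poor
  ^12^C-heavy fraction compositionally dominated by a few taxa — the
  realistic structure under which the ^12^C~H~ ≤ ^12^C~L~ comparison is
  informative for everyone else. With uniform leakage that comparison
  would be an uninformative coin flip, because heavy and light
  compositions would be identical in expectation.
* **Autotrophs** are enriched in the ^13^C heavy fractions of *both*
  treatments — precisely the confounder that control exclusion removes.
  Primary consumers and cross-feeders are enriched in the rhizosphere
  treatment only.
* **Sampling** — weights are closed to compositions and counts drawn
  multinomially at `read_depth` (default 20 000, an ordinary amplicon
  library) per fraction sample, then re-closed. Replicates (default 3,
  matching a triplicate incubation design) share the baseline, truth and
  leakage assignment but redraw the enrichment factors and the counts.
* A single integer seed governs every draw; identical configurations are
  bit-for-bit reproducible.

What the generator does **not** emulate: growth dynamics during the
incubation (the baseline is the community at sampling), partial labelling
and gradual density shifts (heavy/light is a dichotomy here, so
quantitative-SIP methods cannot be tested against it), chimeras, OTU
clustering artefacts, or compositional correlations between taxa beyond
those induced by closure. Passing tests therefore demonstrate that the
decision rule recovers planted signal under realistic sampling noise and
leakage — not that it is robust to clustering artefacts or to partial
labelling, which real studies must assess separately.

Under the default design (200 taxa, 20 labelled, 5 cross-feeders, 5
autotrophs), sensitivity at *k* = 10 is limited mainly by taxa whose
heavy-fraction abundance sits near the 0.1% floor, where multinomial noise
on a handful of reads can flip the ^12^C comparison; this mirrors the
detection limit any real fraction-resolved analysis faces.

## Degenerate primer design

The *mdh2* assay is designed by scanning a DNA alignment of reference
sequences for windows of 18–20 columns containing at most 3 non-conserved
columns. Conventions:

* A column is conserved only if every sequence carries the same single
  base from A/C/G/T; a gap or N anywhere makes it non-conserved, and any
  window containing such a column is excluded outright — primers cannot
  span indels.
* "Non-conserved base" is read as non-conserved alignment *column*. The
  alternative reading (fully conserved window, ≤3 degenerate positions in
  the synthesized oligo) is expressible with the same machinery by setting
  `max_nonconserved` accordingly.
* Coordinates are 0-based, half-open. All overlapping windows are
  reported; `rank_windows()` sorts by (non-conserved count, degeneracy,
  −length) as a convenience, with no greedy merging.
* The consensus encodes each column as the minimal IUPAC code covering the
  observed bases; degeneracy is the product of column base-set sizes.

In-silico specificity screening (`predict_amplicons()`) scans the forward
primer along each template and the reverse primer along the reverse
complement with IUPAC-aware matching, and reports every site pair whose
product length falls in the configured range (the *mdh2* assay expects
~500 bp) and whose combined mismatches do not exceed the allowance
(default 0). In all modes the 3′-terminal 3 positions must match exactly,
because polymerase extension tolerates no terminal mismatch. A template
with any prediction is a positive-control verdict; none, a negative.

## Gene quantification

**Metagenome hit tables.** Hit counts are normalized to gene length
(hits kb^−1^) for assembled data, and to gene length and library size
(hits kb^−1^ Mread^−1^, the RPKM-like convention made dimensionally
explicit) for unassembled reads. Reference lengths are a required input —
the screen uses representative sequences per clade, so their lengths are
known, and defaulting to nucleotide bp is the package's choice where
amino-acid lengths would also have been defensible. The fraction of
bacteria carrying a methanol dehydrogenase is the summed MDH-clade
abundance divided by that of the single-copy housekeeping gene *recA*,
times 100; values above 100% are flagged (`multi_copy`) rather than
rejected, since multiple *xoxF5* copies per genome are common.

**E-value stringency.** The BLAST cutoff for a clade screen is calibrated
as the e-value of the strongest hit belonging to any other clade; hits
pass strictly below it. This makes the passing set provably free of
incorrect-clade sequences and maximal among thresholds with that property.
If the strongest hit overall is from the wrong clade the calibration
degenerates to an empty passing set, with a warning.

**qPCR.** Standard curves regress Cq on log~10~ copies over a dilution
series (10^8^ down to 10^1^ copies µl^−1^ in the assay this reproduces;
at least 3 distinct levels are required). Efficiency is
`10^(−1/slope) − 1`, reported as a percentage: slope −3.3219 is a perfect
doubling, 100%. A non-negative slope is rejected as an invalid assay.
Copy numbers are recovered by inverting the line, normalized to a
reference gene (16S rRNA), and all pairwise gene ratios are emitted —
xoxF5:mxaF being the comparison of interest. Group-level significance
testing (e.g. two-way ANOVA across soils) is left to standard tools; the
output table is tidy for that purpose.

## Problem sizes and verification

The test suite validates the caller against an independently restated
brute-force rule on 10^4^ random profiles, the window scan against naive
enumeration on 100 random alignments (≤10 sequences × ≤200 columns), and
parameter recovery on the default 200-taxon design (seed 42: sensitivity
0.90, specificity ≥ 0.95 at *k* = 10), with cross-feeder suppression
checked across 20 simulated experiments. These sizes give stable
statistics while keeping the whole suite fast enough to run on every
change. `scripts/acceptance.R` recomputes the same headline quantities
end-to-end from a fresh seed.

## Known limitations

* The heavy/light dichotomy discards within-class density structure; the
  package cannot estimate atom-fraction excess or density shifts (no
  quantitative SIP).
* The caller consumes relative abundances as given; if upstream filtering
  removed taxa without re-closure, the floors and comparisons inherit that
  convention.
* The primer scanner scores conservation only; melting temperature,
  hairpins and primer-dimer checks are out of scope and should be applied
  to its candidates with standard oligo tools.
* The e-value calibration is only as good as the clade labels of the
  reference hits.
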