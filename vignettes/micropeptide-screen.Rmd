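---
title: "Screening tumor-specific lincRNAs for translated small ORFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening tumor-specific lincRNAs for translated small ORFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smorfscreen)
```

## The screen and its assumptions

`smorfscreen` implements a five-stage funnel for finding micropeptide
candidates among long intergenic noncoding RNAs (lincRNAs) in a tumor
cell-line vs. normal-tissue-panel design. The stages, and what each
assumes, are:

**1. Tissue-exclusive expression.** A transcript is tumor-exclusive when
its FPKM is at least `tau_on` in the tumor sample and at most `tau_off` in
every normal-tissue sample. FPKMs are consumed as given — normalization is
upstream and out of scope. The defaults are `tau_on = 1` (a conventional
floor for "expressed") and `tau_off = 0` (strictly silent). The strict zero
matches how such candidate tables are usually reported — retained
candidates show exactly 0 FPKM in the normal reference — and the gap
between the two thresholds creates an *ambiguous* band (0 < FPKM < 1) that
conservatively excludes a candidate when seen in any normal sample: a
borderline normal signal is treated as evidence against exclusivity, not
for it. There is no principled universal value for either cutoff, which is
why both are config-exposed; with other data sources a `tau_off` of, say,
0.1 may be more appropriate than exact zero.

**2. Replicate confirmation.** Exclusive transcripts must be on (at least
`tau_on`) in an independent tumor expression measurement. Transcripts
absent from the replicate annotation are dropped and reported rather than
silently kept.

**3. Small-ORF content.** The transcript must carry at least one
sense-strand ORF *strictly* longer than `min_len_aa = 50` amino acids. The
strict inequality follows the field's convention of "longer than 50 aa":
a 50-aa ORF fails, 52- and 68-aa ORFs pass. ORF enumeration scans the three
sense frames only (the transcript itself is the translated molecule;
antisense frames are irrelevant), defines an ORF as the span from the
5′-most ATG to its first in-frame stop, and counts one ORF per
(frame, stop) pair — a downstream in-frame ATG sharing the stop is not a
separate ORF. This keeps "number of ORFs" well defined; a per-ATG
convention would inflate counts with nested sub-ORFs. ORFs lacking an
in-frame stop before the transcript end are discarded (no read-through
assumption), and any codon containing N matches neither ATG nor a stop.

**4. Cytoplasmic export.** To be translated a transcript must leave the
nucleus. The cytoplasmic fraction is estimated as
`cyt / (cyt + nuc)` from compartment FPKMs and compared against
`export_threshold = 0.2`. The published screens this mirrors are
qualitative ("clearly detected in cytoplasmic RNA-seq"), so the default is
a low floor that separates a genuinely nuclear-retained transcript
(cytoplasmic fraction near 0) from everything else; it is config-exposed.
A transcript detected in neither compartment has no defined localization
and fails the stage as not expressed.

**5. Polysome association.** From a sucrose-gradient qPCR experiment,
template abundance in fraction *i* scales as `E^(-ct_i)` with amplification
efficiency `E` (default 2.0, perfect doubling; per-assay efficiencies are
an input, never estimated here). Normalizing gives the RNA distribution
`p_i = E^(-ct_i) / sum_j E^(-ct_j)`, which is invariant to any global CT
shift — so no spike-in normalization is required for the distribution
itself, and the positive-control row (e.g. Actin) is carried through but
not used for normalization by default. A missing CT means no amplification
and is treated as zero abundance rather than an imputed
limit-of-detection cycle — simpler, and conservative for a translation
call. The polysome score is the mass in the fractions designated
polysomal; which fractions those are is a property of the gradient and the
absorbance trace, so the set is declared in config, defaulting to the
bottom 40% of fractions (e.g. 7–10 of 10). A transcript is called
translated at `translation_cutoff = 0.5`: most of its RNA rides with
polysomes.

**Promoter chromatin is evidence, not a filter.** For every confirmed
candidate the package annotates a strand-aware promoter window (default
1000 bp upstream to 500 bp downstream of the TSS — a conventional
"proximal promoter"; the mirrored minus-strand window is
`[tss - downstream + 1, tss + upstream + 1)` in 0-based half-open
coordinates) with tumor and normal DNase peak counts, arbitrary feature
tracks (cCREs, histone marks, TF peaks — counted generically, with no
per-factor logic), and CAGE support within ±100 bp of the TSS (CAGE
clusters mark capped 5′ ends; the exact tolerance is not standardized, so
it is config-exposed). `differential_open` requires at least one tumor
peak and zero normal peaks in the window. Candidates with closed promoters
deliberately stay in the funnel: tumor-specific expression can arise
without a detectable accessibility change, and in the motivating screens
such candidates were carried forward too.

ΔCt normalization against a reference gene
(`relative_expression(ct_target, ct_ref, E) = E^(-(ct_target - ct_ref))`)
is provided for knockdown-style comparisons; it is not part of the funnel.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `tau_on` / `tau_off` | 1.0 / 0.0 | FPKM | expressed / silent cutoffs |
| `upstream` / `downstream` | 1000 / 500 | bp | promoter window around TSS |
| `cage_slack` | 100 | bp | CAGE-to-TSS tolerance |
| `min_len_aa` | 50 | aa | ORF length floor (exclusive) |
| `export_threshold` | 0.2 | fraction | minimum cytoplasmic share |
| `efficiency` | 2.0 | per cycle | qPCR amplification efficiency |
| polysomal set | bottom 40% | fractions | gradient fractions counted as polysomal |
| `translation_cutoff` | 0.5 | mass | polysomal mass for a translated call |

## Numerical and representational choices

Coordinates are 0-based half-open throughout, matching BED, the only
genomic interval format consumed; ORF coordinates within a transcript use
the same convention (`start_nt mod 3 = frame`). RNA FASTA is normalized to
DNA on read (`U -> T`). Interval overlap is "shares at least one base"
under half-open semantics, strand-blind (DNase is unstranded); a
chromosome mismatch contributes zero rather than erroring. The fraction
distribution shifts CTs by their minimum before exponentiating, for
numerical stability at large CT values. Peptide masses use Expasy
*average* residue masses plus one water (18.02 Da), reported to 0.01 Da —
average rather than monoisotopic, because the predictions are compared
with kDa-scale gel estimates. Kozak context is classed from the two
dominant positions only (−3 purine, +4 G); positions beyond the sequence
end count as failing, so a transcript-initial ATG can never be strong.
Output ordering is deterministic everywhere: exclusivity calls by
descending tumor FPKM with ties broken lexicographically by id, ORFs by
start offset.

## The synthetic-data generator

Real inputs for such a screen are consortium-scale (RNA-seq of a tumor
line, a normal-tissue panel, nuclear/cytoplasmic compartments; DNase, cCRE
and CAGE tracks; polysome qPCR). The generator emulates their
*statistical structure* so the pipeline is testable offline:

- **Expression**: planted exclusive transcripts draw tumor FPKM
  log-normally with median ~30 (matching the 13.7–104.9 FPKM range typical
  of retained candidates) and are exactly zero across a 17-tissue normal
  panel; background transcripts are expressed in at least one normal
  tissue. A `leakage` probability flips normal cells of exclusive
  transcripts to small positive values, degrading precision in a
  controlled way. A replicate matrix re-draws tumor values and zeroes the
  planted non-confirmed subset.
- **Sequences**: each requested ORF is embedded with its requested Kozak
  class in an AT-rich random background (A = T = 0.35), chosen so that
  random background is stop-dense and rarely contains spurious >50-aa
  ORFs; an in-frame terminator is placed just upstream of each planted ORF
  so no background ATG can extend it. Every product is *scanner-verified*:
  the generator runs `find_orfs` on its own output and resamples on any
  mismatch, with a bounded retry budget (default 100) and a hard error
  after that — explicit failure rather than silent bias.
- **Tracks**: open-promoter transcripts receive a tumor-only DNase peak
  inside the default window, a CAGE cluster at the TSS, an H3K4me3 mark,
  and (for five of seven) a cCRE; normal DNase peaks fall far from every
  candidate promoter.
- **CT tables**: constructed by *inverting* the fraction-distribution
  formula from a target mass vector — translated transcripts place 80% of
  their mass in the polysomal fractions, non-translated 10% — around a
  global offset cycle (default 20), then adding Gaussian CT noise of the
  requested standard deviation. The 80/10 planting satisfies the ≥70% /
  ≤30% separation the recovery guarantees assume, with margin on both
  sides of the 0.5 cutoff.

The default truth plants the funnel 12 exclusive / 9 confirmed / 6 with a
qualifying ORF / 5 exported / 3 translated among 500 transcripts, with 7
of 9 promoters differentially open — the shape of the motivating screen —
and one flagship transcript carrying a weak 52-aa and a strong 68-aa ORF.

What the generator does **not** emulate: read-level noise (FPKMs are drawn,
not estimated from reads), mapping artifacts, splice-isoform complexity,
realistic genome coordinates (transcripts sit on a toy chromosome),
correlated tissue expression, or absorbance-trace shapes. Passing tests on
synthetic data therefore demonstrate that the *logic* of every stage is
correct and that planted signals are recovered under stated noise; they do
not validate upstream quantification or peak calling on real data.

## Design choices where the design was open

- **Exclusivity under ambiguity**: a normal-panel value between the two
  thresholds excludes the candidate (conservative).
- **ORF counting**: one ORF per (frame, stop) with the 5′-most ATG. The
  alternative per-ATG convention can be evaluated against a published
  per-transcript ORF count once the real sequence is available; the
  package does not silently switch defaults.
- **Chromatin as annotation**: accessibility never filters, because
  screens of this design keep closed-promoter candidates downstream.
- **Transcripts missing from an assay**: absent from the replicate matrix
  → dropped and reported; absent from the CT table → not translated (the
  gradient never detected them); detected in neither compartment → not
  exported. Each of these is the conservative reading.
- **Stage order** is fixed (exclusivity → confirmation → ORF → export →
  translation); individual stages can be disabled in config, in which case
  they filter nothing and their record fields stay unevaluated.

## Problem sizes used in the tests

The shipped suite runs the exclusivity filter against an exhaustive
per-cell oracle on 200×17 and 300×12 random matrices, the ORF scanner
against an independent per-ATG oracle on 300 random 600-nt sequences, the
overlap counter against GenomicRanges and all-pairs brute force on 1000
random window/track cases, distribution normalization and shift-invariance
on 1000 random CT vectors, and planted-truth recovery end to end on
500-transcript cohorts, with translated-call recall measured over 20 seeds
at CT noise of 0.5 and 1.0 cycles. These sizes exercise every code path
while keeping the default suite fast; all generators scale if heavier
simulation is wanted.

## Known limitations

- Non-AUG starts, ribosome-profiling-based ORF calling and
  coding-potential classifiers are out of scope; the ORF filter is purely
  structural, so it cannot distinguish a translated smORF from a
  fortuitous one — that is exactly what the polysome stage is for.
- Peptide mass is a plain average-mass sum; dedicated predictors that
  model modifications may differ slightly.
- The export and translation calls each rest on a single measurement; no
  replicate-level variance model is fitted.
- BAM/bigWig ingestion, peak calling and FPKM computation are upstream of
  this package: it consumes called peaks and normalized tables.
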