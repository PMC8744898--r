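# smorfscreen

Screening cancer-specific lincRNAs for micropeptide-encoding small ORFs.

## The problem

A subset of long intergenic noncoding RNAs (lincRNAs) is expressed in tumor
cells but in no normal tissue, typically because chromatin at their promoter
is remodeled in the tumor. Some of these "noncoding" transcripts carry small
open reading frames (smORFs) that are exported to the cytoplasm, loaded onto
polysomes and translated into micropeptides — attractive tumor-specific
target molecules and biomarkers. Finding them requires stitching together
several routine but fiddly analyses: tissue-exclusivity filtering of FPKM
tables, promoter accessibility annotation against DNase/cCRE/CAGE interval
tracks, ORF scanning with Kozak-context scoring, nuclear/cytoplasmic export
classification, and quantification of sucrose-gradient qPCR data.

`smorfscreen` packages this screen as a tested, reusable pipeline for
computational biologists working with a tumor line vs. normal-tissue panel
design. Because the real inputs are large consortium datasets, the package
also ships a truth-labelled synthetic-data generator that emulates their
statistical structure, so every stage — and the pipeline end to end — is
testable without downloading anything.

## The screen

Stages are applied as a funnel, in fixed order:

1. **Exclusivity** — transcript t is called tumor-exclusive iff
   FPKM_tumor(t) ≥ τ_on and FPKM_s(t) ≤ τ_off for every normal sample s
   (defaults τ_on = 1, τ_off = 0; values in between are ambiguous and
   exclude the transcript).
2. **Replicate confirmation** — t must be on (≥ τ_on) in an independent
   tumor replicate.
3. **Small-ORF filter** — t must carry ≥ 1 sense-strand ORF strictly longer
   than 50 aa. An ORF runs from the 5′-most ATG to its first in-frame stop
   (one ORF per frame/stop pair); Kozak context is classed strong /
   adequate / weak from the −3 purine and +4 G positions, and peptide mass
   is the sum of average residue masses plus one water.
4. **Export** — cytoplasmic fraction cyt/(cyt + nuc) from compartment FPKMs
   must reach 0.2.
5. **Translation** — from per-fraction qPCR CT values, the RNA mass in
   fraction i is p_i = E^(−ct_i) / Σ_j E^(−ct_j) (E = amplification
   efficiency, default 2); the polysome score Σ_{i∈polysomal} p_i must
   reach 0.5, with the bottom 40% of the gradient polysomal by default.

Promoter chromatin evidence (tumor vs. normal DNase peaks in a strand-aware
−1000/+500 bp window, cCRE and histone-mark overlap, CAGE support within
±100 bp of the TSS) is annotated for every confirmed candidate but is
deliberately *not* a filter. ΔCt reference normalization
(E^(−(ct_target − ct_ref))) is included for knockdown-style comparisons.

## Worked example

```r
library(smorfscreen)

bundle <- generate_bundle(seed = 1)   # synthetic cohort, truth-labelled
res <- run_screen(bundle)
print(res)
#> screen_result funnel:
#>   exclusive  12
#>   confirmed  9
#>   has_orf    6
#>   exported   5
#>   translated 3
#> final candidates: 3
```

The funnel counts say: of 500 transcripts, 12 were tumor-exclusive, 9
reproduced in the replicate, 6 carry a >50-aa ORF, 5 are cytoplasmic, and 3
sediment with polysomes — the final micropeptide candidates:

```r
subset(res$records, final_candidate,
       c(transcript_id, tumor_fpkm, max_orf_aa, best_kozak,
         cytoplasmic_fraction, polysome_score))
#>   transcript_id tumor_fpkm max_orf_aa best_kozak cytoplasmic_fraction polysome_score
#> 1  SYNTX00471.1      129.8         56       weak                0.824            0.8
#> 4  SYNTX00418.1       35.2         69   adequate                0.747            0.8
#> 6  SYNTX00466.1       23.9         63   adequate                0.797            0.8
```

Single stages are exported too. The generator plants one flagship
transcript carrying a weak-context 52-aa and a strong-context 68-aa ORF:

```r
find_orfs(bundle$sequences[[flagship_id]], min_len_aa = 50)
#>   frame start_nt end_nt length_aa  kozak
#> 1     0     1020   1179        52   weak
#> 2     0     1239   1446        68 strong
peptide_mass(...)  # 7441.6 Da for the 68-aa peptide, i.e. ~7-8 kDa
```

A thin command-line wrapper (`inst/exec/smorfscreen`) exposes `simulate`,
`screen-expression`, `annotate-chromatin`, `scan-orfs`, `localize`,
`polysome`, `run-all` and `report` subcommands over bundle directories of
plain FASTA/BED/TSV/CSV files.

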