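# cwmyb

Identification, classification and expression screening of plant MYB
transcription-factor families from protein sequences.

## The problem

The MYB superfamily is one of the largest transcription-factor families in
plants. Its members are defined by a DNA-binding domain of one to four
imperfect ~52-residue repeats ("R"), each carrying three regularly spaced
anchor residues — canonically tryptophans:

```
R2:  -W-x19-W-x19-W-
R3:  -[F/I/L/M]-x18-W-x18-W-
```

Family surveys classify proteins by repeat count — R2R3-MYB (two tandem
repeats), 3R-MYB, 4R-MYB — and place single-/partial-repeat proteins in the
MYB-related subfamily, subdivided by signature motifs: CCA1-like
(`SHAQK[Y/F]F`), R-R type (two distant repeats, the first with its third
tryptophan replaced by tyrosine), TBP-like (`LKDKW[R/K][N/T]`), Myb-CC
(`SHLQ[K/M]xR` plus an `LHEQLE` coiled-coil region outside the repeats),
and GARP-like (`SHLQ[K/M]xR` alone). Around the classification sit the
standard survey steps: collapsing redundant sequences at ≥80% identity,
computing each member's length, average molecular weight and theoretical
isoelectric point (Bjellqvist pKa set, as in the standard pI/Mw web tool),
screening expression tables for differential expression
(TPM > 0, |log2FC| > 1, p < 0.05), and quantifying qPCR by the comparative
2^−ΔΔCt method against an internal control gene.

cwmyb implements that whole pipeline as a tidyverse-native R package —
degenerate repeat scanning, motif typing, naming, physicochemical
characterization, redundancy removal, DEG screening and ΔΔCt — plus a
synthetic-data module that plants repeats, motifs, fold changes and Ct
shifts with known truth labels, so every stage is testable end to end
without any downloads. It is aimed at anyone running a desk-scale TF
family survey on an assembled transcriptome or proteome, and at anyone who
wants those surveys' classification rules to be explicit, configurable and
reproducible.

## Worked example

Generate a small labeled family, classify it, and characterize it:

```r
library(cwmyb)

recs <- gen_family_set(synthetic_family_spec(
  counts = c(R2R3 = 3, R_R = 2, MYB_CC = 2, NOT_MYB = 1), seed = 42))
calls <- classify_proteins(recs)
tidy(calls)
#> # A tibble: 8 × 8
#>   seq_id        subfamily   related_type assigned_name chain_length n_repeats n_motifs n_ear
#> 1 syn_R2R3_1    R2R3        <NA>         CwMYB1                   2         2        0     0
#> 2 syn_R2R3_2    R2R3        <NA>         CwMYB2                   2         2        0     0
#> 3 syn_R2R3_3    R2R3        <NA>         CwMYB3                   2         2        0     0
#> 4 syn_R_R_1     MYB_RELATED R_R          CwMYBR1                  0         1        1     0
#> 5 syn_R_R_2     MYB_RELATED R_R          CwMYBR2                  0         1        1     0
#> 6 syn_MYB_CC_1  MYB_RELATED MYB_CC       CwMYBR3                  0         0        2     0
#> 7 syn_MYB_CC_2  MYB_RELATED MYB_CC       CwMYBR4                  0         0        2     0
#> 8 syn_NOT_MYB_1 NOT_MYB     <NA>         <NA>                     0         0        0     0
```

Each row is one protein: its subfamily call, MYB-related type (if any),
assigned family name (`CwMYB<n>` for R2R3 members, `CwMYBR<n>` for
MYB-related, `CwMYB3R`/`CwMYB4R` for 3R/4R), the longest tandem repeat
chain found, and the evidence counts. The nested `repeats`/`motifs`
columns of `calls` hold hit coordinates; `summarize_family(calls)` gives
the survey-style count table, and `glance(calls)` a one-row overview.

Physicochemical properties (length, average Mw, theoretical pI):

```r
protein_props(recs[1:3, ])
#> # A tibble: 3 × 5
#>   seq_id     length  mw_da mw_kda    pi
#> 1 syn_R2R3_1    310 33562.   33.6  6.73
#> 2 syn_R2R3_2    262 29537.   29.5  7.39
#> 3 syn_R2R3_3    282 31105.   31.1  6.89
```

qPCR relative quantification (here: target induced ~8-fold, three
replicates, 18S-style constant reference):

```r
trt <- list(ct_target = c(21.9, 22.1, 22.0), ct_reference = c(15, 15.1, 14.9))
ctl <- list(ct_target = c(25.0, 25.1, 24.9), ct_reference = c(15, 15, 15.1))
ddct(trt, ctl)
#> # A tibble: 1 × 6
#>   dct_treated dct_control  ddct  fold    pvalue signif
#> 1           7        9.97 -2.97  7.82 0.0000338 **
```

The fold change is 2^−ΔΔCt ≈ 7.8 with a `**` flag (p < 0.01 on the
per-replicate ΔCt values).

For whole files rather than in-memory tables, `run_identify()`,
`run_expression()` and `run_qpcr()` read FASTA/TSV inputs and write TSV/
JSON reports plus a reproducibility manifest; `inst/cli/cwmyb` exposes the
same as shell subcommands (`identify`, `expression`, `qpcr`, `simulate`).
`autoplot()` methods draw the family composition, a DEG volcano and qPCR
fold-change bars; `plot_domain_map()` draws repeat/motif tracks.

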