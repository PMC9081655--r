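---
title: "Methods: MYB family annotation and expression screening with cwmyb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MYB family annotation and expression screening with cwmyb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwmyb)
library(dplyr)
```

## The model

Plant MYB transcription factors are defined by a DNA-binding domain built
from one to four imperfect repeats ("R") of roughly 52 residues. Each
repeat folds into three alpha-helices and carries three regularly spaced
anchor residues — canonically tryptophans — that pack the hydrophobic
core. cwmyb models a repeat as exactly that: three anchors with
constrained spacers.

The consensus classes, in priority order:

| class | anchors | spacers |
|---|---|---|
| `R2_CONSENSUS` | W, W, W | 19, 19 |
| `R3_CONSENSUS` | F/I/L/M, W, W | 18, 18 |
| `RR_FIRST` | W, W, Y | 19, 19 |
| `GENERIC_R` | W/F/I/L/M, W, W/F/Y | 17–20 |

The first tryptophan of R3-type repeats is commonly replaced by F, I, L or
M; the N-terminal repeat of R-R type MYB-related proteins replaces the
*third* tryptophan with tyrosine (`RR_FIRST`). `GENERIC_R` is the union
catch-all for degraded repeats.

Exact consensus spacers are printed as 19/19 and 18/18, but the repeats
are only approximately 52 residues long in real families and the
profile-HMM searches that family surveys rely on tolerate small indels.
Each spacer therefore allows `slack` residues of play (default ±1,
`myb_scan_config(slack = )`). The effective tolerance used by any
particular survey is not knowable from its printed consensus, so it is a
configuration knob rather than a constant.

### Repeat span, overlap, and hit selection

A hit's `start` is its first anchor; the reported `end` extends `tail`
residues (default 12) past the third anchor, completing the ~52-residue
repeat (41-residue anchor span + helix-3 tail), clipped at the sequence
end. The tail affects only EAR exclusion and non-MYB region boundaries:
**overlap between candidate repeats is judged on the anchor span**
(first..third anchor). This matters for tandem repeats, where one
repeat's tail runs into the next repeat's first anchor; judging overlap
on anchor spans lets true tandem architectures be reported side by side.

`detect_repeats()` enumerates every anchor triple satisfying any class
(a triple satisfying several gets the highest-priority class), then
selects a maximum set of mutually non-overlapping hits. Ties between
equal-size solutions are broken by class priority first, then leftmost
start and anchors (lexicographically on the key
`(priority, start, anchor2, anchor3)`). Priority must outrank position:
a backbone I/L/M residue 17–21 positions before a genuine repeat's first
tryptophan forms a spurious generic/R3 triple that *starts earlier* but
borrows two of the real repeat's anchors; preferring the earlier start
would displace the biological repeat. The selection is fully
deterministic; the test suite checks it hit-for-hit against an
exhaustive enumerator over hundreds of random sequences.

Coordinates in the R API are 1-based inclusive, the Bioconductor
convention; exported TSV/JSON use the same convention.

## Subfamily classification

`classify_proteins()` applies a fixed decision procedure per protein:

1. **Repeat chains.** Full repeats (`R2_CONSENSUS`, `R3_CONSENSUS`,
   `GENERIC_R`) are chained when each next repeat starts at most
   `tandem_gap` residues (default 10) after the previous repeat's
   tail-inclusive end. A chain of ≥4 is `R4_MYB`, exactly 3 is `R3_MYB`,
   exactly 2 is `R2R3`. A chain of two is `R2R3` regardless of which
   consensus each member matched — the first repeat of 3R proteins also
   matches the W-pattern — with the per-repeat classes preserved in the
   evidence.
2. **MYB-related typing**, first rule that fires wins:
   `TBP_LIKE` (motif `LKDKW[RK][NT]`), `MYB_CC` (`SHLQ[KM]xR` plus an
   `LHEQLE` hit outside every repeat interval), `GARP_LIKE`
   (`SHLQ[KM]xR` alone), `R_R` (`SHAQK[YF]F` with an `RR_FIRST` repeat
   ending at least `rr_min_separation` residues — default 40 — before the
   motif), `CCA1_LIKE` (`SHAQK[YF]F` alone), else `UNCLASSIFIED` if any
   repeat or signature motif fired at all.
3. `NOT_MYB` with no evidence.

The precedence TBP > Myb-CC > GARP > R-R > CCA1 orders motifs from most
to least constrained (a 7-residue fixed motif with W beats a 6-residue
alternative set), which makes the procedure deterministic without any
scoring machinery. Neither the "far apart" separation of R-R repeats nor
tandem adjacency is quantified in the descriptive literature; the
defaults (40 and 10 residues) come from the ~52-residue repeat scale and
are both configurable (`myb_classify_config()`).

Notes on the signature motifs:

* `SHLQK/MxR` is parsed as `S-H-L-Q-[K/M]-x-R`; the alternative reading
  (alternatives `SHLQK`/`SHLQM` with a trailing `xR`) is the same
  pattern.
* The Myb-CC coiled-coil domain (pfam14379) is approximated by its
  namesake hexapeptide `LHEQLE` outside the repeat intervals. Full
  profile matching is out of scope for a desk-scale tool; this is a
  documented approximation, not an implementation of the Pfam model.
* The group some summaries label "TBR-like" is the same group labelled
  TBP-like elsewhere; cwmyb uses `TBP_LIKE` throughout.
* The SHAQK motif is not required to lie inside a detected repeat for a
  CCA1-like call — presence anywhere in the sequence suffices. Published
  classifications do not state the stricter requirement, and requiring
  it would silently drop proteins whose repeat decayed below the anchor
  consensus.
* EAR (`LxLxL`) is scanned outside the repeat intervals and reported as
  annotation (`scan_ear()`, the `n_ear` column), but never counts as
  classification evidence: leucine-rich stretches arise constantly by
  chance, and a repression motif says nothing about family membership.

Members are named in input order by subfamily counters
(`CwMYB1..n`, `CwMYBR1..m`, `CwMYB3R<k>`, `CwMYB4R<k>`;
`assign_names()`), so permuting the input permutes only names, never
calls.

## Physicochemical properties

`compute_mw()` sums average residue masses plus one water (18.01528 Da).
Sequences containing `X` are rejected rather than imputed — an averaged
stand-in mass would corrupt the extreme-value reporting that family
surveys print. `compute_pi()` bisects the Henderson–Hasselbalch net
charge over pH 0–14 to `|charge| < 1e-4` (the charge is strictly
decreasing in pH, so the zero is unique; 100 iterations bound the
bisection). The default pKa set is the Bjellqvist parameterization used
by the standard web calculator: residue-specific N-terminal pKa, C-term
3.55 (4.55/4.75 when the last residue is D/E), side chains D 4.05,
E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0. One consequence worth
knowing: because a C-terminal D raises the terminal carboxyl pKa,
appending D to a *strongly acidic* protein can nudge pI slightly up —
monotonicity intuitions hold only away from that regime. Reported
precision is two decimals for kDa and pI, matching survey convention;
different historical versions of the pKa tables can move pI by a few
hundredths.

## Redundancy removal

Family surveys collapse near-identical transcripts/isoforms before
analysis at an 80% identity cutoff. The sources rarely state the
alignment mode or the identity denominator, so cwmyb makes the common
greedy-clustering choice explicit and configurable: global
Needleman–Wunsch alignment (match +1, mismatch 0, gap open 10, extend 1,
via `Biostrings::pairwiseAlignment`) with the **shorter-sequence
denominator** (`pairwise_identity()`, flags `denominator` and `mode`).
`dedupe()` is greedy: records sorted by length descending (ties by id),
each kept iff below threshold to every already-kept record; the
representative is the longest member, retaining maximal domain content
for downstream scanning. The procedure is deterministic, idempotent, and
checked against an explicit O(n²) bookkeeping oracle in the tests. It
operates on proteins only; whether a given study clustered nucleotide or
protein sequences is usually unstated, and nucleotide-level clustering
can merge or split differently — a documented limitation.

## Expression screening

`log2_matrix()` is the heatmap transform `log2(TPM + 1)`.
`deg_screen()` implements the screen *expression > 0, |log2FC| > 1,
p < 0.05*:

* `log2fc = log2((meanA + c)/(meanB + c))` with `c = 0.01` on group-mean
  TPM, keeping on/off genes finite (configurable).
* "TPM > 0" is ambiguous about which samples; the default reads it as
  *mean TPM > 0 in at least one group*, which admits on/off genes (the
  biologically interesting tails of a tissue heatmap);
  `expressed_rule = "all_samples"` gives the strict reading.
* p-values are two-sided Welch t-tests on `log2(TPM + 1)` replicates.
  Deposited DE results computed by some other procedure can be screened
  verbatim via `pvalues =`. No multiple-testing correction is applied by
  default, mirroring the raw p < 0.05 convention; `fdr = TRUE` switches
  the pass rule to Benjamini–Hochberg.
* All-zero (or otherwise constant) replicate vectors make the t statistic
  degenerate; equal constant groups are reported as p = 1, unequal
  constant groups as p = NA (never a pass).

`ddct()` is the comparative 2^−ΔΔCt method: per-replicate
`ΔCt = Ct_target − Ct_reference` against the internal control gene,
`ΔΔCt = mean ΔCt(treated) − mean ΔCt(control)`, fold `2^−ΔΔCt`, with a
two-sided t-test on the per-replicate ΔCt values and star flags at
p < 0.05 (`*`) and p < 0.01 (`**`). `qpcr_screen()` applies it across a
long-format table per gene × condition × timepoint, matching control
rows by timepoint when available.

## What the synthetic data emulates — and what it does not

The generators exist so every stage is testable without downloads.

`gen_family_set()` plants class-defining cassettes (consensus repeat
blocks, signature motifs, the R-R long-separation layout) into random
backbones. The backbone alphabet excludes **every** anchor letter —
W, Y, F and the first-anchor substitutes I, L, M — because excluding
only W/Y/F still lets a backbone I/L/M form a spurious triple with two
planted tryptophans; the full exclusion gives the exact
zero-false-anchor guarantee that makes recovery tests sharp (100%
accuracy at zero noise is a *construction* property, not a statistical
one). `realistic_backbone = TRUE` re-admits all 20 letters for stress
testing. Structure-preserving mutation never touches planted positions
and substitutes from the backbone alphabet, so true labels are provably
invariant; corrupting mutation can destroy anchors and degrade accuracy.

What this does *not* emulate: real amino-acid composition and homology
(backbones are i.i.d. uniform), indels inside repeats, decayed anchors,
multi-domain architectures, or families where signature motifs co-occur
atypically. Passing the zero-noise recovery test therefore shows the
decision procedure implements its own rules exactly — not that the rules
reproduce any particular curated family from raw transcriptome data.

`gen_expression()` draws per-gene baseline log2-TPM from Normal(5, 2),
shifts DE genes by ±the planted log2FC in group A, adds Normal(0, sd)
replicate noise on the log2 scale and maps to TPM via `2^v − 1` floored
at 0 — the exact inverse of the screen's transform. It deliberately
models TPM on the log scale with Gaussian noise rather than
negative-binomial counts: the screened quantity is TPM, not counts.
Null calibration of the Welch test (fraction of p < 0.05 ≈ 5% at 1,000
genes) is checked under this model. `gen_qpcr()` fixes the reference
gene Ct (default 15) and offsets the treated target Ct by
−log2(fold), so the expected recovered fold is exact; metadata mimics a
stress time-course (NaCl/MeJA/cold, 0–24 h).

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data
at desk scale: 500 random sequences (length ≤ 200) for the
scanner-vs-oracle check, 45 proteins (5 per class × 9 classes) for
zero-noise recovery, 1,000 random pairs for mass additivity, 200
sequences for the pI zero-charge check, 30 records for redundancy, 100
genes (10 DE) plus a 1,000-gene null for the DEG screen, and 100
Monte-Carlo replicates for qPCR fold recovery. Every stochastic step is
seeded; `gen_family_set()` for a fixed spec is byte-identical across
runs, and pipeline reruns produce byte-identical outputs (the manifest
records config, seed and input checksums).

## Known limitations

* The scanner is rule-based by design: no profile scores, PSSMs or
  E-values, and no tolerance for indels *between* anchors beyond the
  spacer slack.
* Phylogeny-based subgrouping of R2R3 members (the 13-subgroup style of
  analysis), domain confirmation against external databases and
  subcellular-localization prediction are out of scope.
* Redundancy removal is protein-level only (see above).
* The DEG screen's replicate structure must be supplied by the user;
  the p-values are only as meaningful as the replication design behind
  the TPM table.
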