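---
title: "Sm-site discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sm-site discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smsites)
```

## The biological question

U snRNAs carry an Sm-site — a uridine-rich motif flanked by stem-loop
structure — on which the SMN complex deposits the heteroheptameric
Sm-protein ring in an ATP-dependent reaction. If messenger RNAs carry
sequence and structure elements that satisfy the same rules, Sm-rings may
assemble on them too. This package implements the computational side of
that question: find candidate Sm-sites transcriptome-wide, require the
flanking structure that the assembly reaction needs, and test whether
site-bearing transcripts are preferentially captured in anti-Sm RIP
experiments.

## The motif model

Five motif classes are scanned (`sm_motifs()`), written 5'→3' over the
IUPAC RNA alphabet:

| class | pattern | note |
|---|---|---|
| U1 | `AUUUGUG` | canonical |
| U2 | `AUUUUUG` | canonical |
| U5 | `AUUUUUUG` | canonical |
| U7 | `AUUUGUCUAG` | histone-processing variant |
| NC | `AUNUKUN` (K = G/U) | degenerate noncanonical |

Every canonical pattern's 7-mer prefix lies inside the NC expansion, so a
canonical site always co-reports an NC hit at the same start. Per-gene
"true noncanonical" counts therefore subtract the canonical total from the
raw NC count; this subtraction is asserted to be non-negative and is
guaranteed by the subsumption property checked in the test suite.
Overlapping occurrences are all counted (every matching start is
reported); the per-hit output retains start coordinates so either
counting convention can be reconstructed. Subject-sequence `N`s never
match — a conservative choice for assembled transcripts with ambiguous
bases. T and U are the same letter everywhere; all internal coordinates
are 0-based half-open, while GFF3/GTF and SAF files are read and written
1-based inclusive and BED 0-based half-open.

Around each match the scanner captures up to 200 nt of upstream and up to
50 nt of downstream sequence; hits with fewer than 16 nt available 3' of
the motif are discarded before structure evaluation. This reading of the
"16–50 nt" capture makes a short 3' tail disqualifying, which is
consistent with U4atac (8 nt of tail) never being called.

## The structure filter

The assembly model requires predicted secondary structure *on both sides*
of the site: within 20 nt upstream and 10 nt downstream. The two captured
windows are folded independently, excluding the motif itself, and a flank
passes when at least one base within its window is paired — the weakest
reading of "a structure is predicted within k nt", chosen so that parity
runs against an external folder can quantify the difference rather than
hide it.

The built-in folder (`fold_rna()`) maximizes summed base-pair weights
(GC = 3, AU = 2, GU = 1, `min_loop = 3`, `min_helix = 2`) over
non-crossing structures. Because the consumed decision is binary
(paired-within-window), a weighted base-pair-maximization model suffices
and can be tested *exactly*: the suite checks the returned score against
exhaustive enumeration of all valid structures for every sequence up to
length 8 and for random 10–14-mers. Two numerical choices matter:

* the minimum-helix constraint is enforced **inside** the dynamic
  program (transitions add whole stacked runs of at least `min_helix`
  pairs), not by post-hoc pruning — pruning an unconstrained optimum is
  not optimal under the constraint and would break the enumeration
  equivalence;
* the traceback is deterministic: the 5'-most base pairs with its
  smallest admissible partner, recursing left to right, so identical
  inputs give identical dot-brackets.

An external folder (e.g. RNAfold) can be substituted per window through a
two-column dot-bracket sidecar; decisions then depend only on the
dot-bracket strings.

## Regions, representatives, merging

Transcript models come from GFF3/GTF; CDS genomic intervals are projected
through the exon chain into transcript coordinates, and positions map to
5'UTR/CDS/3'UTR (half-open bounds) or `noncoding` for transcripts without
a CDS. A site straddling a boundary takes its start's region — the
simplest rule consistent with one region per site. One transcript
represents each gene, prioritized MANE tag > Ensembl-canonical tag >
longest > lexicographically smallest id (the last two are this package's
tie-breakers; annotation sources specify only the first two). Hits called
under two annotations merge by the key (transcript id, motif, downstream
sequence): shared hits appear once, annotation-specific hits are
appended, and the operation is symmetric and idempotent.

## Splice-site and branch-point mimics

The 5' splice-site consensus `MAGGURAGK` is scanned exactly, and with a
"bulge" mode reporting 9-mers matching at exactly 8 of 9 positions
(single mismatch) and 8-mers equal to the consensus with one position
deleted. A start position reports at most one kind, precedence
exact > mismatch > deletion. Branch points use the consensus `YUNAYYYY`
(the 8-mer definition; a 9-mer variant appears once elsewhere in the
source material and is not used) or the stringent `YMYUNACW`.

## Intron counting

Introns are built per gene as the gene span minus the union of all exons
across that gene's transcripts — the operational meaning of "assign
counts only to intronic regions"; a genome-wide complement would include
intergenic space. Intervals are emitted as SAF (1-based inclusive), and
read intervals (BED) are assigned to genes by overlap of at least
`min_overlap` bases (default 1; no minimum fraction is imposed). Reads
overlapping introns of several genes count for each, or fractionally
(1/k) when requested, mirroring the two multi-locus counting behaviours
used with featureCounts. Strand is ignored by default; a stranded mode
exists.

## The enrichment layer

The fidelity path consumes an externally computed per-gene table of
log2 fold-changes and adjusted p-values (e.g. DESeq2 Wald tests);
re-implementing dispersion shrinkage is out of scope. For
simulation-only work, `simple_lfc()` provides median-of-ratios
normalization and a pseudocount log-ratio (pseudocount 0.5), carrying no
test. Genes classify as enriched (lfc > 0.6 and padj < .05), depleted
(lfc < −0.6 and padj < .05) or neither — the >1.5-fold convention.
Stratified comparisons test, for each ordered pair of Sm-site classes,
whether the left stratum's fold-changes are shifted in the stated
direction, via a one-sided Wilcoxon rank-sum test with midranks,
tie-corrected variance and continuity correction; Benjamini–Hochberg
correction is applied across the pairs supplied in one call (the
correction family is per call, since the original figure-by-figure
families are not enumerable). Rank correlations with length use Kendall
tau-b. Site densities are pooled counts per pooled region length scaled
to sites per million bases. The candidate intersection keeps genes
enriched in *every* supplied comparison and absent from a genomically
ambiguous set, ordered by descending minimum fold-change.

## The synthetic-data generator

The generator exists so that every stage has a planted, provable ground
truth:

* **Background** is random sequence with every match of the degenerate
  NC pattern removed by mutating its first base to C. Excluding NC
  matches excludes all five motifs (each motif's 7-mer prefix is in the
  NC expansion), so the background is motif-free by construction and any
  scanner call off a planted site is a genuine false positive. A C patch
  can complete no motif (motifs start with A, and the degenerate N
  positions matched any base already), so patching converges; the
  draw-then-patch design replaced block-wise rejection sampling, which
  can livelock when an accepted block ends in an `AUNUKU`-matching
  6-mer whose continuation always completes a match.
* **Structured plantings** place the site inside controlled flank zones:
  poly-A except a designed hairpin (poly-G arm, 4-nt A loop, poly-C arm;
  stem 8 bp by default) ending 2 nt before the site and another starting
  1 nt after it. Inside an A-only zone the G and C arms are the only
  pairable letters, so *every* maximum-weight structure pairs them and
  retention is guaranteed, not merely likely.
* **Unstructured plantings** use {C,A}-only zones covering the full
  captured windows (200 nt up, 60 nt down). No AU/GC/GU pair can form,
  so rejection by the filter is likewise guaranteed. This strengthens a
  "no G within 60 nt" zone, under which an A in the downstream window
  could still stack with a distant upstream U.
* **Counts** are negative-binomial, mean = basemean ×
  2^(lfc·[ATP+]) × size factor, with lognormal base means (meanlog
  log 200, sdlog 1), dispersion 0.1, per-sample size factors log-uniform
  on [0.7, 1.4], and 3 samples per condition — the ATP+/ATP− RIP
  contrast in miniature. The default plants lfc = +1 on 150 canonical
  genes out of 1000.
* **Reads** fall entirely within introns or exons at a configured
  intronic fraction, so interval counting can be checked against an
  exact per-read truth.

One transcript per gene, split by a single intron; genes alternate
strands so minus-strand extraction is always exercised. What the
generator does *not* emulate: sequencing error, coverage biases,
alternative isoforms, genuine RNA structure context (flank zones are
deliberately artificial), or annotation disagreement beyond what the
merge rule needs. Passing tests on this material demonstrates
correctness of the algorithms under their stated assumptions, not
recovery of any particular biological census; the headline numbers of a
real transcriptome analysis depend on annotation releases and deposited
sequencing data and are outside what a self-contained package can
reproduce.

## Problem sizes used in the checks

The shipped verification runs use: 1000 random sequences (≤ 2 kb) for
the scanner-versus-oracle identity; all 4^k sequences for k ≤ 8 plus 200
random 10–14-mers for the folding oracle; 20 seeds × 200 genes for
structure-recovery; 500 random toy genes for the intron oracle; n ≤ 8
per group for the exhaustive-permutation Wilcoxon comparison; and 20
planted-effect plus 100 null count simulations (1000 genes, 3 vs 3) for
the enrichment layer. These sizes were chosen as the points where the
checked properties have stabilized well below the tolerances asserted.

## Known limitations

* The folder is a weighted pair-maximization model, not a free-energy
  model; it supports the binary flank decision, and the sidecar backend
  exists for thermodynamic parity runs.
* `simple_lfc` is a point estimate with no inference; classification
  requires an external padj column by design.
* The "Exon Mismatch" region category (sites in exonic sequence
  discordant with the reference genome) is not implemented; region
  assignment presumes transcript and genome agree.
* Genome-level (unspliced) scanning and PWM scoring are non-goals.
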