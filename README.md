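# smsites

Transcriptome-wide discovery of Sm-sites — the uridine-rich motifs with
flanking stem-loops on which the Sm-protein ring of U snRNPs is
assembled — and the statistics used to ask whether Sm-site-bearing
transcripts are preferentially captured in anti-Sm RIP-seq experiments.

**Who it is for:** RNA biologists and bioinformaticians studying snRNP
biology, SMN/Sm-ring assembly on mRNAs, or any analysis that needs a
degenerate RNA motif scan constrained by local secondary structure, with
a fully testable synthetic ground truth.

## What it computes

1. **Motif scan.** Transcript sequences are scanned for five motif
   classes: U1 `AUUUGUG`, U2 `AUUUUUG`, U5 `AUUUUUUG`, U7 `AUUUGUCUAG`
   and the degenerate noncanonical pattern `AUNUKUN` (K = G/U). Every
   match captures up to 200 nt of 5' and 16–50 nt of 3' flanking
   sequence; matches with under 16 nt of 3' tail are discarded.
2. **Structure filter.** Both flanks are folded (weighted base-pair
   maximization: GC = 3, AU = 2, GU = 1, minimum loop 3, minimum helix
   2); a site is retained only when a paired base is predicted within
   20 nt 5' **and** 10 nt 3' of it. External RNAfold dot-brackets can be
   substituted per window.
3. **Per-gene master table.** One representative transcript per gene
   (MANE > Ensembl-canonical > longest > smallest id), sites binned into
   5'UTR/CDS/3'UTR, canonical totals `n(U1)+n(U2)+n(U5)`, and true
   noncanonical counts `n(NC) − canonical` (each canonical site also
   matches the degenerate pattern).
4. **Mimic scans.** 5' splice-site consensus `MAGGURAGK` (exact, single
   mismatch, or single deletion) and branch points `YUNAYYYY` /
   `YMYUNACW`.
5. **Intron counting.** Per-gene introns = gene span minus exon union
   (SAF output); reads assigned by interval overlap, whole or 1/k
   fractional.
6. **Enrichment layer.** Genes classify as enriched when
   log2(fold-change) > 0.6 with adjusted p < .05 (depleted below −0.6).
   Sm-site-stratified CDF comparisons use one-sided Wilcoxon rank-sum
   tests (midranks, tie-corrected variance, continuity correction) with
   Benjamini–Hochberg correction; Kendall tau-b for length
   correlations; site density in sites per million bases; and the
   intersection of genes enriched in every comparison.
7. **Synthetic data.** `sm_simulate()` writes a genome, annotation,
   reads and an ATP+/ATP− count matrix with planted sites whose
   retention or rejection by the structure filter is guaranteed by
   construction, plus the full ground truth.

## Worked example

```r
library(smsites)

cfg <- sim_config(seed = 42, n_genes = 20,
  site_spec = data.frame(motif = c("U1", "U2", "U5", "NC", "U2"),
                         region = "utr3",
                         structured = c("hairpin", "hairpin", "hairpin",
                                        "hairpin", "none"),
                         n_genes = c(3, 3, 3, 3, 3)),
  utr5_meanlog = log(150), cds_meanlog = log(600), utr3_meanlog = log(900))
sim  <- sm_simulate(cfg, "sim_out")          # genome.fa, annotation.gff3, ...
scan <- run_sm_scan("sim_out/genome.fa", "sim_out/annotation.gff3",
                    out_dir = "scan_out")    # sites.tsv, master.tsv
print(scan)
#> <sm_scan> 20 genes scanned; 21 of 27 motif hits retained by the structure filter
#>   genes with canonical sites: 9
#>   genes with true-noncanonical sites: 3

site_density(scan$master, "canonical")
#>   region sites length_nt density_per_mb
#> 1   utr5     0      2911         0.0000
#> 2    cds     0     11906         0.0000
#> 3   utr3     9     19722       456.3432

cm  <- make_counts(make_truth(cfg), cfg)     # ATP+/ATP- NB counts, lfc +1 planted
lfc <- simple_lfc(cm$counts, cm$design$condition, c("ATPplus", "ATPminus"))
stratified_cdf_test(lfc, sm_site_classes(scan$master),
                    list(c("Canonical", "Absent")))
#> Stratified Wilcoxon rank-sum comparisons (BH-corrected):
#>       left  right n_left n_right  W alternative           p        padj
#>  Canonical Absent      9       8 68     greater 0.001218367 0.001218367
```

Reading the output: 9 of the 20 genes carry a planted canonical Sm-site
with hairpin flanks — all 9 structured canonical plantings are retained
by the filter (sensitivity 1), the 3 unstructured plantings are
rejected, and sites land exclusively in 3'UTRs, where the density is
456 sites/Mb against zero elsewhere. With a planted +1 log2 fold-change
on canonical-site genes, their fold-change distribution is shifted above
the Absent class (one-sided rank-sum p ≈ 0.0012 despite only 9 vs 8
genes).

A thin command-line wrapper over the same functions is installed at
`inst/cli/smsites.R` (subcommands `simulate`, `scan`, `mimics`,
`introns`, `enrich`).

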