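# moRseq

Quantification of miRNAs, isomiRs and miRNA-offset RNAs (moRNAs) from bulk
small RNA sequencing, with subgroup differential expression and constrained
moRNA target-site scanning.

## What it does, and for whom

Small RNA-seq of molecularly stratified cohorts (the motivating setting is
multiple myeloma with its translocation/CCND1 subgroups) carries signal
well beyond the annotated mature miRNAs: boundary/substitution variants
(**isomiRs**), the unannotated mature from the opposite hairpin arm
(**sister miRNAs**), and ~20-nt species from the hairpin region immediately
flanking a mature (**moRNAs**). moRseq is for analysts who want all of
these called, quantified and tested from raw FASTQ with one reproducible,
fully seeded pipeline — and for method developers who want every stage
testable against a planted ground truth, via the built-in synthetic-data
generator.

## The method in brief

Reads are adapter-trimmed (leftmost match, ≥3-nt end overlap, ≤10%
mismatches), kept when 15–30 nt with mean quality > Q30 and ≤2 bases < Q20,
collapsed per sample, and denoised (unique sequences with < 10 reads
dropped). Unique sequences are mapped ungapped (≤2 substitutions) to the
genome and to hairpins extended by ±30 nt; sequences hitting > 5 genomic
loci outside annotated hairpins are discarded. Each hairpin placement is
classified with the precedence

```
exact miRNA  >  isomiR  >  moRNA  >  unclassified
```

where an isomiR has 5'/3' shifts within ±3 nt (≤1 mismatch anywhere or 2 in
the 3' half) and a moRNA has its central nucleotide strictly upstream of
the 5p mature (5'-moRNA) or strictly downstream of the 3p mature
(3'-moRNA). For single-mature hairpins, a stacking-energy secondary
structure (nearest-neighbour stacks + helix-initiation penalty, exact DP
optimum) predicts the sister mature as the duplex partner with 2-nt 3'
overhangs. Counts are normalized by median-of-ratios size factors, each
subgroup is tested against the rest with an exact conditional
negative-binomial test (common method-of-moments dispersion, BH-adjusted),
moRNA–miRNA co-expression is measured by one-tailed Kendall tau, and moRNA
target sites are called on transcripts when a 7-nt fully paired seed (≤1
G:U), ≥14 total pairs and duplex energy ≤ −20 kcal/mol coincide.

## Worked example

Simulate a six-sample study over 12 hairpins and run the full pipeline:

```r
library(moRseq)
cfg <- run_config(n_hairpins = 12L, genome_length = 40000L,
                  n_samples = 6L, seed = 7L)
res <- run_pipeline(cfg, "readme_run")

res$report$preprocess$pct_reads_passing
#> [1] 92.2                      # % of raw reads surviving all filters

res$catalog
#> species_catalog: 23 species
#>     miRNA  moRNA_3p  moRNA_5p new_miRNA
#>        15         1         4         3
```

23 species are detected: 15 annotated miRNAs (each summing its exact and
isomiR members), 5 moRNAs flanking matures, and 3 sister miRNAs discovered
from hairpin structure on single-mature precursors. Expression is strongly
concentrated — the top 4 species carry ~73% of the normalized signal, and
the abundant planted moRNA sits in the upper quartile:

```r
head(res$cume[, c("species_id", "total", "cumulative_fraction")], 3)
#>   species_id    total cumulative_fraction
#> 1   miR-8-5p 24836.06           0.289
#> 2   moR-2-5p 15933.62           0.475
#> 3   miR-4-5p 14191.37           0.640
```

The subgroup test recovers the planted 4-fold moRNA change in the "MAF"
group (log2FC 2.12, q = 2.1e-08), and the moRNA tracks its cognate miRNA:

```r
subset(res$de, qvalue < 0.05 & upper_quartile)[, c("species_id",
       "contrast", "log2fc", "qvalue")]
#>   species_id contrast log2fc   qvalue
#>     moR-2-5p      MAF   2.12  2.1e-08
head(res$correlations, 2)
#>      morna    mirna  tau p_one_tailed
#> 1 moR-2-5p miR-2-5p 0.41         0.18
#> 2 moR-3-5p miR-3-5p 0.47         0.14
```

`run_pipeline` writes per-stage outputs (filter statistics, species catalog
as GFF3 + FASTA, count and isomiR-detail TSVs, DE tables, a JSON report)
into the run directory and refuses to overwrite a completed run. A thin
command-line wrapper with `simulate` and `run` subcommands is installed at
`inst/cli/morseq`; every stage is equally callable as an exported function
(`preprocess_fastq`, `map_sequence`, `call_expressed_species`, `de_test`,
`scan_transcript`, ...).

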