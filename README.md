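# ends3p

Quantification of polyadenylated (pA+) and non-polyadenylated (pA−) RNA
3′ ends from metabolic-labeling 3′-end sequencing.

## The problem

Oligo-dT-primed 3′-end sequencing maps each RNA's exact 3′ terminus: the
5′ end of an aligned read marks one RNA 3′ end at single-nucleotide
resolution. Sequencing each sample twice — once pA-selected (only tailed
3′ ends) and once after in vitro E-PAP tailing (tailed *and* untailed
ends, "pA+,−") — makes the non-polyadenylated signal computable by
subtraction. Combined with a short 4-thiouracil (4tU) pulse that labels
nascent RNA, one experiment yields three quantities per transcription
unit:

* **transcription** — pA− 3′-end *density* in gene bodies (TSS to
  TES − 200 bp), the positions of elongating polymerases;
* **RNA level** — pA+ signal in gene-end regions (TES ± 200 bp);
* **decay** — from first-order pulse-labeling kinetics,
  `DR = −(1/t)·ln(1 − RNA_4tU/RNA_total)` with `t = 2` min, or from the
  transcription-to-level ratio (arbitrary scale, meaningful ranks).

The package implements the full computational pipeline for researchers
working with such data: 3′-end extraction from alignments, masking of
oligo-dT internal-priming artifacts at genomic A stretches (> 4 A and no
C/T in 6 nt downstream, or > 12 A in 18 nt), spike-in median-of-ratios
size factors, mock-IP background subtraction with exact dropped-mass
accounting, pA− derivation, region quantification, EE/EI/IE
splice-junction classification, Spearman correlation/clustering,
metagene matrices — plus a fully seeded kinetic simulator that generates
genomes, annotations, expected signals, Poisson count tracks and
spliced/unspliced reads with ground-truth tables, so every stage is
testable without external data.

## Worked example

Simulate a small study, run the pipeline, and compare estimated decay
rates against the simulator's truth:

```r
library(ends3p)
library(dplyr)

cfg <- sim_config(n_genes = 20, seed = 42)
bg  <- build_genome(cfg)
counts <- draw_counts(expected_signals(cfg), depth = 1e5, seed = 43)
run <- run_pipeline(counts, bg$tus, bg$genome)
run
#> <ends3p_run> 6 samples; 2 pA- track(s); 18 finite labeling-ratio DR estimates

run$decay_labeling |> filter(finite) |> arrange(desc(rate)) |> head(5)
#> # A tibble: 5 × 7
#>   tu_id  tu_class method         labeled_end total_end  rate finite
#>   <chr>  <chr>    <chr>                <dbl>     <dbl> <dbl> <lgl>
#> 1 CUT018 CUT      labeling_ratio       1290.     1482. 1.02  TRUE
#> 2 CUT017 CUT      labeling_ratio       2186.     2547. 0.977 TRUE
#> 3 SUT014 SUT      labeling_ratio       1585.     2890. 0.398 TRUE
#> 4 SUT015 SUT      labeling_ratio       1916.     4803. 0.254 TRUE
#> 5 SUT016 SUT      labeling_ratio       2714.     7233. 0.235 TRUE

truth <- write_truth(cfg)$genes
d <- inner_join(run$decay_labeling, truth, by = c("tu_id", "tu_class"))
cor(d$rate, d$k, method = "spearman", use = "complete.obs")
#> [1] 0.997936
```

The `rate` column is per minute: `CUT018`'s 1.02 min⁻¹ is a ~40-second
half-life, typical of cryptic unstable transcripts, while stable mRNAs
sit near the bottom of the table; unstable classes rank highest, and
estimated rates rank-match the simulated truth (ρ ≈ 0.998). Two of the
20 genes exceed label saturation under counting noise and are flagged
non-finite rather than clamped. `run$pa_minus` holds the derived pA−
tracks, `run$quant_avg` the per-TU body/end quantifications, and
`run$size_factors` the spike-in size factors.

A thin command-line wrapper covers shell use:

```sh
Rscript inst/cli/ends3p.R simulate --out sim --genes 50 --seed 1
Rscript inst/cli/ends3p.R mask --fasta sim/genome.fa --out mask.bed
Rscript inst/cli/ends3p.R run --manifest sim/manifest.tsv \
    --fasta sim/genome.fa --annotation sim/annotation.bed --out results
```

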