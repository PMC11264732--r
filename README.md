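# cashcandi

Quantification of circulating tumor DNA (ctDNA) from cell-free DNA
(cfDNA) methylation profiles.

## The problem

Tumor cells shed DNA into the blood. That ctDNA is a small minority
(often far below 1%) of the total cfDNA, most of which comes from blood
cells, so detecting and tracking a tumor from plasma requires features
that separate tumor-derived fragments from the overwhelming background.
DNA methylation is such a feature: some genomic regions are heavily
methylated in tumor tissue (β ≈ 0.9) while being essentially
unmethylated (β < 0.05) both in matched normal tissue and in the cfDNA
of healthy people. A sequencing read that falls entirely inside such a
region and is itself densely methylated is very unlikely to come from
anything but tumor.

`cashcandi` implements this idea end to end for methylation sequencing
data (e.g. enzymatic methyl-seq of plasma cfDNA):

1. **Region discovery** — cancer-specific hypermethylated (CaSH)
   regions are called from per-CpG methylation count tables. A CpG is
   differential when mean(β<sub>tumor</sub>) − mean(β<sub>normal</sub>) > 0.3,
   the healthy-plasma mean β < 0.05, and the Benjamini–Hochberg q-value
   of a two-sided Wilcoxon rank-sum test (tumor vs normal β) is < 0.05.
   Surviving CpGs within 75 bp up/downstream of each other merge into
   fragments; fragments with fewer than ten CpGs are discarded; each
   remaining fragment becomes a region spanning its first to last CpG
   (1-based inclusive — chr6:391,824–393,789 has length 1966 bp).
   Hypomethylated discovery is the mirrored rule (Δβ reversed, plasma
   β > 0.95).
2. **Scoring (ctCandi)** — for a plasma sample, every read carries a
   read methylation density RMD = methylated CpG calls / total CpG
   calls. A read is a *candidate ctDNA read* for a region when it is
   completely contained in the region and RMD > 0.6 (strictly; < 0.3
   for hypomethylated regions). Per-region candidate counts are
   normalised to counts per million mapped reads (CPM) and averaged over
   all regions:
   ctCandi = mean over regions of (candidates × 10⁶ / total mapped reads).
3. **In-silico validation** — tumor-tissue reads replace healthy-plasma
   reads at known fractions (0.1%–5%, six replicates each) and the
   Spearman correlation of ctCandi against the mixing fraction measures
   the dose-response.
4. **Cohort evaluation** — unpenalized logistic regression on the
   per-region CPM vector under stratified threefold cross-validation
   (ROC/AUC, Youden operating point), plus longitudinal monitoring
   (post-operative score deltas and per-region paired signed-rank
   contributions).
5. **Synthetic data** — a deterministic generator builds toy genomes
   with planted marker regions, beta-binomial count tables, and
   read-level Bernoulli methylation calls with a conversion-error rate,
   so the whole pipeline is testable without sequencing data.

## Worked example

```r
library(cashcandi)

cfg    <- synth_config(seed = 1)          # 2 x 1 Mb genome, 50 planted regions
genome <- make_genome(cfg)
tissue <- make_tissue_counts(genome, n_per_group = 5)
regions <- discover_regions(tissue$tumor, tissue$normal, tissue$plasma,
                            direction = "hyper")$hyper
#> discovery: 2784 CpGs, 2784 after missingness filter
#> discovery [hyper]: 842 differential CpGs -> 50 fragments -> 50 with >= 10 CpGs -> 50 regions

head(regions[, .(chrom, start, end, length, n_cpgs)], 3)
#>     chrom  start    end length n_cpgs
#> 1:   chr1  10980  11398    419     17
#> 2:   chr1  54984  55399    416     18
#> 3:   chr1 102549 102947    399     17

## a healthy plasma read set, and the same set spiked with 2% tumor reads
prof   <- make_profiles(genome, c("healthy_plasma", "tumor_tissue"), seed = 101)
plasma <- emit_reads(prof[, 1], genome, seed = 201)
tumor  <- emit_reads(prof[, 2], genome, seed = 202)
spiked <- mix_reads(plasma, tumor, fraction = 0.02, seed = 301)

score_sample(spiked, regions[, .(chrom, start, end)],
             total_mapped_reads = attr(plasma, "total_mapped_reads"))
#> ctCandi score: 2.35 over 50 regions (47 candidate reads, 400,000 mapped reads)
score_sample(plasma, regions[, .(chrom, start, end)],
             total_mapped_reads = attr(plasma, "total_mapped_reads"))
#> ctCandi score: 0 over 50 regions (0 candidate reads, 400,000 mapped reads)
```

The pure healthy sample scores 0 (no read in a marker region is densely
methylated), while 2% spiked tumor reads yield 47 candidate reads and a
ctCandi of 2.35 CPM — the separation the classifier exploits.

## Command line

A launcher script is installed under `inst/scripts/cashcandi`:

```sh
cashcandi synth --seed 1 --out demo/                # synthetic inputs + truth
cashcandi discover --tumor a.tsv,b.tsv --normal c.tsv,d.tsv \
    --plasma e.tsv,f.tsv --direction hyper -o regions.bed
cashcandi score --reads sample.reads.tsv --regions regions.bed \
    --total-reads 400000 --out score.tsv
cashcandi simulate-dilution --plasma plasma.reads.tsv --tumor tumor.reads.tsv \
    --regions regions.bed --fractions 0.001,0.005,0.01,0.02,0.03,0.05 \
    --reps 6 --seed 1 --out dilution.tsv
cashcandi classify --features features.tsv --labels labels.tsv --folds 3 \
    --seed 7 --out metrics.json
cashcandi monitor --scores longitudinal.tsv --out monitor.tsv
```

Options can also come from a YAML/JSON file via `--config` (explicit
flags win); every run writes its resolved configuration as JSON next to
the outputs.

### File formats

* **Cytosine reports** — headerless TSV: chrom, 1-based position,
  strand (`+`/`-`), methylated count, unmethylated count, context; only
  `CpG`/`CG` rows are used. Minus-strand rows are collapsed onto the
  plus-strand C (position − 1).
* **Regions** — BED (0-based half-open) on disk, 1-based inclusive
  internally.
* **Reads (TSV dialect)** — headerless TSV: chrom, start, end (1-based
  inclusive), call string of `M`/`u`, comma-separated 0-based CpG
  offsets from start. The line
  `chr1  100  249  MuM  10,50,100` is a read spanning chr1:100–249 with
  a methylated call at 110, unmethylated at 150, methylated at 200
  (RMD = 2/3). A read without CpG calls uses `.` in both fields.
* **Reads (SAM/BAM)** — alignments with Bismark-style `XM` tags
  (`Z` methylated CpG, `z` unmethylated CpG, other symbols ignored);
  each mate of a pair is scored as an independent read.

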