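# txrank

Expression ranking of transcript isoforms across human tissues.

Most protein-coding genes express several alternatively spliced isoforms,
but their expression is far from uniform: in bulk tissue panels such as
GTEx, one *dominant* isoform typically carries the majority of a gene's
output, and the curated representative transcript (MANE-select) is usually
— but not always — that dominant isoform. `txrank` is for
transcriptomicists who want to (i) identify the top-ranked expressed
isoform of each gene as a data-driven reference transcript, (ii) quantify
how much of each gene's expression its ranked isoforms carry, and (iii)
find genes whose dominant isoform *switches* in particular tissues (the
classic example being GLRX2-type genes, where a normally minor isoform
takes over in testis).

## The statistic at the core

For a gene *g* with expressed isoforms *t = 1..k* and tissue panel
*s = 1..T* (tissue-level TPM `x[t, s]`, typically the mean over a tissue's
samples):

* **Rank.** Within each gene and scope (a single tissue, or the
  cross-tissue average), isoforms are sorted by descending TPM; exact
  expression ties are broken by descending CDS length, then descending
  transcript length, then ascending transcript ID — fully deterministic.
* **Expression fraction.** `f[t, s] = x[t, s] / sum_t' x[t', s]`, the share
  of the gene's output isoform *t* carries in scope *s* (undefined, never
  0, where the gene is silent).
* **CV.** Per isoform, `cv = sd(x[t, ·]) / mean(x[t, ·])` over tissues
  (sample sd, n−1), a tissue-modulation score; also computed on the rank
  profile.
* **Rank1 switch event.** A gene whose overall rank1 isoform holds
  per-tissue rank 1 in only `c < T` tissues; with one switching tissue and
  `T = 54`, `c = 53`. `rank1_tissue_count + #switch tissues = T` exactly.

Inputs are GTEx-style GCT 1.2 transcript TPM matrices, a sample-to-tissue
map, GENCODE-style annotation (GTF or flat TSV), and optionally a
MANE-select summary. A fully seeded synthetic-data generator with known
ground truth (Dirichlet isoform usage, lognormal gene levels, injected
switches) backs the test suite and lets you exercise the pipeline without
the multi-gigabyte GTEx download.

## Worked example

```r
library(txrank)

sim <- simulate_expression(sim_config(n_genes = 300, n_switch_genes = 15,
                                      seed = 42))
fe <- filter_expressed(sim$tpm)          # drop never-expressed transcripts
rt <- build_rank_table(fe$matrix, sim$annotation)
rt
#> rank_table: 1259 transcripts, 296 genes, 54 tissues
#>   overall rank1 transcripts: 296 (mean TPM 45.592)

rank_summary(rt, max_rank = 5)
#>   rank   mean_tpm   n
#> 1    1 45.5924802 296
#> 2    2 11.9730223 226
#> 3    3  5.3611502 189
#> 4    4  1.6902648 155
#> 5    5  0.2873116 120

ev <- detect_switch_events(rt, min_count = 53, max_count = 53)
nrow(ev)          # 15 -- exactly the injected switch genes
ev[1, c("gene_id", "overall_rank1_transcript", "rank1_tissue_count",
        "switch_tissues", "switching_transcripts")]
#>           gene_id overall_rank1_transcript rank1_tissue_count switch_tissues
#> 1 ENSG00000000063          ENST00000000324                 53       tissue15
#>   switching_transcripts
#> 1       ENST00000000325

res <- coding_noncoding_test(rt)
sprintf("p = %.3g (coding %.2f vs noncoding %.2f TPM)",
        res$p_value, res$mean_coding, res$mean_noncoding)
#> "p = 8.36e-16 (coding 18.93 vs noncoding 5.43 TPM)"
```

The rank-class means fall steeply (rank1 carries ~4x rank2), the 15
injected tissue switches are recovered exactly at tissue count 53, and
coding isoforms significantly out-express the noncoding isoforms of the
same genes — the three headline behaviours of dominant-isoform analysis on
real tissue panels.

## Command line

```sh
txrank simulate --out sim --n-genes 500 --n-switch-genes 20 --seed 1
txrank rank   --gct sim/expression.gct --annotation sim/annotation.tsv \
              --sample-map sim/sample_map.tsv --out results
txrank switch --out results --min-count 50 --max-count 53
txrank mane   --out results --mane sim/mane_summary.tsv
```

`rank` writes the download-schema transcript table, per-rank mean TPM,
dominance-by-isoform-class, per-tissue rank fractions and the counting
summary; `switch` and `mane` reuse its cached rank table. Exit codes: 0
success, 1 validation error, 2 runtime error. Real GTEx inputs work the
same way (`--already-collapsed` accepts a pre-averaged tissue-level GCT).

## Documentation

See `vignettes/transcript-isoform-ranking.Rmd` for the model, parameter
choices, what the synthetic generator does and does not emulate, and known
limitations.
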