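# annocomplex

Gene annotations are internally redundant: duplicated genes carry identical
sequence, and isoforms of one gene share exons. A short RNA-seq read drawn
from a shared region is compatible with several transcripts, and every
downstream analysis — quantification, differential expression (DE) —
inherits that ambiguity. `annocomplex` measures this redundancy as a
per-transcript (or per-gene) **mappability** statistic and quantifies, on a
fully controlled synthetic benchmark, how much accuracy it costs.

## The mappability statistic

For an entity with sequence length ℓ and read length *L*, all
*n* = ℓ − *L* + 1 sliding windows (step 1) are searched as exact substrings
of the whole transcriptome. A window occurring at *N* distinct
(transcript, offset) locations contributes 1/*N* to each; the entity's *m*
is the fractional mass its own windows place back inside itself, and its
mappability is *m*/*n*:

* fully unique sequence → 1;
* a transcript duplicated across *k* genes → exactly 1/*k*;
* identical isoforms of the *same* gene → 1/2 at transcript level but 1 at
  gene level, separating isoform ambiguity from paralog ambiguity;
* windows containing `N` bases count in *n* but never match.

## Worked example

Everything below is reproducible: the synthetic fixture generator is
deterministic in its seed.

```r
library(annocomplex)

fx <- makeFixture(nGenes = 30, chromLength = 60000, seed = 1)
txome <- extractTranscriptSequences(fx$annotation, fx$genome)
sc <- mappabilityScores(computeMappability(txome, L = 100))
head(sc, 6)
#>         id   n        m mappability short
#> 1 gene1.t1 261 261.0000   1.0000000 FALSE
#> 2 gene1.t2 383 383.0000   1.0000000 FALSE
#> 3 gene1.t3 244 244.0000   1.0000000 FALSE
#> 4 gene2.t1 463 330.6667   0.7141829 FALSE
#> 5 gene2.t2 497 364.6667   0.7337357 FALSE
#> 6 gene2.t3 351 219.6667   0.6258310 FALSE
```

`gene1`'s isoforms happen to share no window of length 100, so they are
fully mappable; `gene2`'s isoforms share exons and lose mass to each other.
Duplicated genes hit the analytic 1/2 bound exactly, visible at gene level:

```r
gs <- mappabilityScores(computeMappability(txome, L = 100, level = "gene"))
head(gs[order(gs$mappability), ], 4)
#>        id    n      m mappability short
#> 4   gene4  445  222.5         0.5 FALSE
#> 8   gene8 3277 1638.5         0.5 FALSE
#> 13 gene13 1430  715.0         0.5 FALSE
#> 17 gene17 3690 1845.0         0.5 FALSE
```

Annotation complexity summary of the same fixture:

```r
summarizeAnnotation(fx$annotation,
                    structure(Biostrings::width(fx$genome),
                              names = names(fx$genome)))
#>   n_genes n_transcripts exon_genomic_coverage avg_tx_per_gene
#> 1      34            69             0.2026458        2.029412
#>   avg_pct_unique_exons
#> 1             84.49346
```

## The full benchmark

`runDemo()` runs the whole workflow — fixture, mappability, NB ground-truth
counts, origin-tracked error-free reads, exact alignment, equivalence-class
EM quantification, Welch-test DE — and stratifies every metric by
mappability tercile and true-abundance tercile. At the default scale
(seed 1: 230 genes, 488 transcripts, 497,578 reads, 3 replicates per
group; about a minute of runtime):

```r
demo <- runDemo(seed = 1)
demo$overall$quant
#> $spearman_rho  0.8868...
#> $nrmse         0.0828...
subset(demo$report, step == "quantification" & metric == "spearman_rho" &
       facet == "low")[, c("map_group", "value")]
#>   map_group     value
#>         low 0.1043761
#>      middle 0.9043968
#>        high 0.9984380
```

Reads are error-free and the aligner is exact, so alignment recall and
precision are 1 by construction and *all* remaining error is annotation
ambiguity. Quantification accuracy rises sharply with mappability in every
abundance stratum, and the penalty is worst for low-abundance transcripts
(Spearman's rho 0.10 → 1.00 across mappability terciles above). DE ranking
(AUC) shows the same overall direction (overall AUC 0.859), though
individual tercile cells of a single desk-scale run are noisy; see the
vignette (`vignettes/annotation-complexity.Rmd`) for the model, parameter
rationale and limitations.

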