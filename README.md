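# annomerge

Integration of multiple gene-prediction sets into consensus loci, and
characterization of the merged gene set — composition, gene structure,
intronless genes and candidate disease-resistance genes.

## What it does

Genome annotation projects commonly run two or more independent
gene-prediction pipelines and must reconcile their outputs. `annomerge`
merges prediction sets by co-location: gene models on the same scaffold and
strand are grouped into a locus by single-linkage clustering on the overlap
statistic

```
ov(a, b) = shared span length / min(span a, span b)
```

with the overlap threshold chosen by sweeping 60–95% in 5% steps and
reading the knee of the single-model:multi-model locus ratio. Models
shorter than 300 nt of CDS are excluded; models are kept only with both
protein homology support (identity ≥ 50, bit score ≥ 100, both coverages
≥ 80%) and transcriptome support (identity > 90); each locus's
representative is the member with the lowest-E-value protein hit after
description-blacklist and E-value (≤ 1e-10) filtering; loci on
unsupported bacterial/plastid-looking scaffolds are dropped as
contaminants.

The merged gene set is then characterized:

* **Composition** — GC3 = (C3+G3)/(L/3), CG3-skew = (C3−G3)/(C3+G3), CpG
  genomic signature ρ<sub>CG</sub> = f<sub>CG</sub>/(f<sub>C</sub>·f<sub>G</sub>),
  GC3-rich/poor decile classes, positional gradients along the ORF,
  multinomial / position-specific / codon-position-periodic Markov models
  of coding sequence, and a per-category chi-squared goodness-of-fit test.
* **Gene structure** — exon-count statistics, intronless genes (mono-exonic
  complete ORFs), their projection onto the domains of life (archaea /
  bacteria / eukaryote, with a green-plants/fungi/animals breakdown and
  ORFans), and intronless-ortholog fractions.
* **Resistance genes** — the six-class domain rule table (CNL, TNL, Kinase,
  RLP, RLK, Mlo-like; a gene must carry *all* class domains) and physical
  CNL clusters (< 200 kb apart, ≤ 8 intervening non-NBS-LRR genes).

A synthetic-data generator plants genomes, gene models with controlled GC3
profiles, perturbed two-pipeline prediction copies and mock evidence
tables with known ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(annomerge)

cfg   <- sim_config(seed = 11, n_loci = 50, jitter_sd = 15)
truth <- plant_gene_models(cfg, generate_genome(cfg))
preds <- emulate_pipelines(truth, cfg)
hits  <- synthesize_hits(c(preds$pipelines[[1]], preds$pipelines[[2]]), cfg)

merged <- merge_predictions(preds$pipelines, hits, threshold = 0.85)
merged
#> <locus_merge> 50 loci from 100 models at overlap threshold 0.85
```

The 50 planted loci are recovered exactly from the two 50-model prediction
sets. Downstream:

```r
profs <- composition_profiles(truth$genome, truth$models)
head(profile_table(profs)[, c("gene", "n_codons", "gc3", "cg3_skew")], 3)
#>     gene n_codons       gc3     cg3_skew
#> 1 tg0001      301 0.3421927 -0.145631068
#> 2 tg0002      790 0.7354430  0.008605852
#> 3 tg0003      318 0.5723270  0.000000000

ig <- find_intronless(truth$models, truth$genome)
length(ig)   # mono-exonic complete ORFs among the planted genes
#> [1] 5

genomic_signature("CGCG")$rho_cg
#> [1] 2.666667
```

`write_merged_gff3()` writes the merged loci as GFF3 with `locus_id` and
`representative=true` attributes; `read_gff3()` / `write_gff3()` round-trip
gene models losslessly (1-based inclusive on disk, 0-based half-open in
memory).

### Evidence-table formats

Four tab-separated tables with fixed headers are consumed
(`read_evidence_tables()`):

| table | columns |
| --- | --- |
| hits | `query subject description database e_value bit_score pct_identity query_cov subject_cov` |
| domains | `gene domain` (CC, TIR, NBS, LRR, STK, TM, MLO, OTHER) |
| tm | `gene tm_helices` |
| taxonomy | `scaffold best_hit support_sister support_transcriptome support_newer` |

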