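---
title: "Merging gene predictions into loci and characterizing the merged gene set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging gene predictions into loci and characterizing the merged gene set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annomerge)
```

## The problem

Gene-prediction pipelines disagree. Two independent annotations of the same
plant genome will place overlapping, shifted, split or merged gene models at
many of the same genomic locations, and downstream analyses need a single
consensus gene per location. `annomerge` implements the integration strategy
of combining prediction sets by *co-location*: models on the same scaffold
and strand whose genomic spans overlap strongly enough are grouped into one
locus, and the best-supported member of each locus becomes its
representative model. The package then characterizes the merged gene set in
the ways a genome-annotation survey typically needs: third-codon-position
composition, nucleotide models of coding sequence, intronless genes, and
candidate disease-resistance genes.

Everything operates on standard formats (FASTA, GFF3, tab-separated
evidence tables) and on a synthetic data generator that plants known ground
truth, so every stage can be validated end to end without any external
database.

## Locus integration

### Overlap statistic and single-linkage clustering

Two models overlap by the fraction

$$\mathrm{ov}(a,b) \;=\; \frac{|\,\mathrm{span}(a)\cap \mathrm{span}(b)\,|}
{\min(|\mathrm{span}(a)|, |\mathrm{span}(b)|)},$$

where spans are genomic extents including introns. Using the shorter gene
as the denominator makes the statistic symmetric and sensitive to nested
models (a short model fully inside a long one has overlap 1). We use spans
rather than summed exon overlap because the integration criterion is
physical co-location of loci, not exon agreement; an exon-level mode would
systematically under-merge models that disagree on intron boundaries while
clearly describing the same gene.

A locus is a connected component of the graph with an edge wherever
$\mathrm{ov} \ge t$: single linkage, so each member need only overlap one
other member. Predictions with CDS shorter than 300 nt are discarded before
clustering — such fragments are mostly prediction noise and would otherwise
act as bridges between unrelated loci. Components are computed per
scaffold+strand via `igraph`; the test suite checks the partition against
an independent brute-force union-find oracle over the all-pairs overlap
matrix on a thousand random instances.

### Choosing the threshold

The threshold $t$ is swept from 0.60 to 0.95 in 0.05 steps
(`sweep_and_select()`). As $t$ rises, edges disappear and loci split; the
locus count is non-decreasing in $t$ (an edge set at a higher threshold is
a subset of the edge set at a lower one — this monotonicity is
property-tested). The informative signal is the ratio of single-model to
multi-model loci: it stays flat while $t$ is below the typical agreement
level of the two pipelines, then rises sharply once genuinely co-located
pairs start being separated. We formalize the usual visual "knee" reading
as *the threshold immediately before the largest forward jump of the
ratio*, with ties resolved toward the smaller threshold.

Two numerical conventions matter here. Where a threshold produces no
multi-model locus at all, the ratio is undefined; we flag it `NA` and skip
differences involving it rather than propagating an infinity that would
always win the argmax. And when no defined positive jump exists — for
example when the two prediction sets are identical and the counts never
change — the selection itself is flagged undefined rather than silently
returning an arbitrary grid point; `merge_predictions()` then falls back to
0.85 with a warning, which is the conventional operating point for this
kind of integration.

### Evidence filtering and representatives

Models are kept only with both protein and transcript support: a RefSeq
protein hit with identity ≥ 50, bit score ≥ 100 and coverage of both query
and subject ≥ 80%, *and* a transcriptome hit with identity strictly above
90%. The conjunction is the default because the integration is meant to
produce a high-confidence set; a union mode exists for exploratory use.

Within each locus the representative is the member whose best RefSeq hit
has the lowest E-value, after removing hits with E-value above 1e-10 and
hits whose description contains `predicted`, `putative`, `hypothetical`,
`unnamed` or `uncharacterized` (case-insensitive substring — the blacklist
is a word list, so substring matching is the least surprising reading).
E-value ties break by higher bit score, then lexicographic model id, making
the output deterministic. Loci with no surviving hit are discarded.
Finally, loci on scaffolds whose best whole-scaffold hit is bacterial or
plastid *and* which have no support from a sister genome, the transcriptome
or a newer assembly are removed as contaminants; removal requires failure
at all three levels.

### Worked example

```{r merge-example}
cfg <- sim_config(seed = 11, n_loci = 50, jitter_sd = 15)
truth <- plant_gene_models(cfg, generate_genome(cfg))
preds <- emulate_pipelines(truth, cfg)
hits <- synthesize_hits(c(preds$pipelines[[1]], preds$pipelines[[2]]), cfg)
merged <- merge_predictions(preds$pipelines, hits, threshold = 0.85)
merged
length(truth$models)  # planted loci
```

## Composition statistics

For a coding sequence of length $L$ with $C_3$ cytosines and $G_3$ guanines
at third codon positions,

$$\mathrm{GC}_3 = \frac{C_3 + G_3}{L/3}, \qquad
\mathrm{CG}_3^{skew} = \frac{C_3 - G_3}{C_3 + G_3}, \qquad
\rho_{CG} = \frac{f_{CG}}{f_C\, f_G}.$$

The skew's sign convention puts cytosine excess positive; it is undefined
(`NA`, never 0) when $C_3 + G_3 = 0$, and $\rho_{CG}$ is likewise undefined
when $f_C f_G = 0$. Codons containing N and any trailing partial codon are
excluded from every count: including them would require a convention for
undefined third bases, and exclusion leaves the estimators unbiased for the
sequence that is actually known. The effective denominator is the number of
*valid* codons, which equals $L/3$ on clean sequence.

Genes are ranked by GC$_3$ and the top and bottom 10% designated rich and
poor. The class size is `round(0.1 * N)` with half-up rounding (26,059
genes give exactly 2,606 per class); boundary ties break by gene id so the
class sizes are always exact. Positional gradients average the
third-base G/C indicator (and the signed C/G indicator for skew) at each
codon index over the genes long enough to contribute there — no padding,
no smoothing, and the per-index gene count is reported so that means over
few genes can be judged for what they are. A conservation identity ties
the curve back to the pooled statistic: the gene-count-weighted mean of
the GC$_3$ curve equals the pooled GC$_3$ over all counted codons.

Three nucleotide models of coding sequence are fitted by maximum
likelihood: a multinomial over bases (codon position ignored, so every
non-N base counts), a position-specific multinomial (3 × 4), and a
first-order codon-position-periodic Markov chain (three 4 × 4 transition
matrices, indexed by the codon position of the *current* base; the first
base of each sequence has no predecessor and is skipped). Add-one-style
smoothing is available but off by default, so unseen transitions are
reported as they are rather than silently regularized.
`sample_markov3_cds()` draws sequence from known matrices; at $10^5$ codons
the fit recovers every entry within ±0.02, which the test suite checks.

The per-category goodness-of-fit test compares, for each functional
category, the observed split of genes between the rich and poor classes
against the split expected if category membership were independent of
composition class. With equal-sized deciles the default expectation is an
even split; explicit background weights can replace it. Each category is a
2-cell chi-squared test with df = 1; p-values come from `pchisq` and are
cross-checked in the tests against direct numerical integration of the
chi-squared density.

```{r composition-example}
profs <- composition_profiles(truth$genome, truth$models)
head(profile_table(profs)[, c("gene", "L", "n_codons", "gc3", "cg3_skew")])
enrichment_test(c(stress = 10), c(stress = 30))[, c("chi_squared", "p_value")]
```

## Intronless genes and taxonomic sharing

An intronless gene (IG) is a mono-exonic model whose CDS is a complete
ORF. "Complete ORF" is formalized as: starts with ATG, ends with
TAA/TAG/TGA, length divisible by 3, and no internal in-frame stop. This
is deliberately pipeline-independent — it can be evaluated on any model
from the sequence alone, and it is exactly the invariant the synthetic
generator plants, so IG detection on synthetic truth must achieve
precision and recall 1.

IG are then projected onto the domains of life by homology: a kingdom
(archaea, bacteria, eukaryote) counts as hit when at least one hit in that
database is at E-value ≤ 1e-5 (inclusive, the conventional reading of a
BLAST cutoff). Categories follow subset logic — conserved across all three
domains, eukaryote+bacteria, eukaryote+archaea, eukaryote-only (with a
green plants / fungi / animals breakdown), green-plants-only, and ORFan for
genes with no hit at the cutoff. Eukaryote-level hits that name no group
are labelled `eukaryote-other` rather than forced into a group. The
categories partition the IG set, and relaxing the cutoff can only add
kingdoms (monotonicity, property-tested). The fraction of IG whose
orthologs are also intronless is reported with the denominator restricted
to IG that have orthologs at all (default) or over all IG — both modes
exist because surveys differ in which they quote.

## Resistance genes

Candidate R genes are classified from their protein-domain content under
the rule that a gene must carry *all* the domains of a class:
TNL = TIR+NBS+LRR, CNL = CC+NBS+LRR, RLK = TM+LRR+STK, RLP = TM+LRR
without STK, Mlo-like = MLO domain with 6 or 7 transmembrane helices,
Kinase = STK without TM/LRR/NBS. Rules are applied in the priority order
TNL > CNL > RLK > RLP > Mlo-like > Kinase, so the TIR domain discriminates
TNL from CNL and the kinase domain RLK from RLP; anything else is
unclassified. The classifier is a pure function of the per-gene domain set
and helix count, so input order cannot change assignments.

Physical CNL clusters are maximal runs of CNL genes in which every
adjacent pair is less than 200 kb apart with at most eight intervening
genes that carry neither an NBS nor an LRR domain. Distance is measured
gene start to gene start by default (the measuring points are otherwise a
matter of convention; an end-to-start mode is provided). Genes carrying
either domain do not count against the intervening budget, the literal
reading of "non NBS-LRR". Cluster detection is checked against a
brute-force all-pairs-then-chain oracle on hundreds of random layouts.

## The synthetic-data generator

The generator emulates the inputs of a two-pipeline plant annotation
project at desk scale. Its defaults are the package's fixed study
conditions: five 200-kb scaffolds of i.i.d. background sequence at 37% GC
(a typical plant genome-wide value), 200 planted loci, an exon-count mix
with 14% mono-exonic and 16% two-exon genes (mean ≈ 4.4 exons), CDS
lengths uniform on 300–3000 nt, introns 100–1000 nt, and per-gene GC$_3$
targets uniform on 0.30–0.90 to give the broad composition spread that
makes decile classification meaningful. Planted genes never overlap one
another, so clustering ground truth is unambiguous; overlap structure
between the two emulated pipelines arises only from perturbation
(Gaussian boundary jitter, model splitting, model dropping — all zero by
default, as rates the study conditions do not fix are best exercised
explicitly per experiment). Each generator draws from its own named
sub-stream of the global seed, so adding a generator never shifts the
streams of existing ones, and every generator is a pure function of
(config, seed).

The generator does *not* attempt realistic splice-site motifs, repeat
families, isoforms, or sequencing error. Consequently, passing tests
demonstrate the correctness of the algorithms — coordinate handling,
clustering, threshold selection, composition arithmetic, rule tables — on
inputs with known answers; they do not demonstrate that any particular
real genome satisfies the generator's assumptions (e.g. that boundary
disagreement between real pipelines is Gaussian, which is a modelling
choice, not an empirical claim).

One generator subtlety is worth recording: gradient-recovery experiments
use a *fixed* CDS length across genes. The planted per-codon GC$_3$
gradient is centered on each gene's middle codon; with variable lengths,
the genes that survive to high codon indices have systematically larger
centering offsets, and the pooled curve's slope is attenuated below the
planted slope. Fixing the length removes this length–composition
confound, so the regression on the curve is an unbiased check of the
planted slope.

## Numerical and scale choices

- Internal coordinates are 0-based half-open; GFF3 I/O converts to
  1-based inclusive at the file boundary only. The conversion is a
  bijection and the GFF3 round trip is property-tested to be the
  identity.
- Segments are stored in ascending genomic order for both strands;
  strand is applied only at sequence extraction (reverse complement of
  the ascending concatenation).
- Undefined statistics (skew with no C/G third bases, signature with no
  C or G, sweep selection with no knee) are `NA`, never a sentinel value.
- Test problem sizes are chosen so the statistical checks are sharp but
  the suite stays quick: 1,000 random clustering instances of up to 50
  models, $10^5$ codons for Markov recovery (per-entry standard error
  ≈ 0.003 against the ±0.02 tolerance), 500 fixed-length genes for
  gradient recovery, 500 random layouts for cluster detection.

## Known limitations

- Models are CDS-only; UTRs and non-coding features are out of scope, as
  are the upstream predictors themselves (the package consumes their GFF3
  and tabular outputs).
- The homology-evidence tables are consumed as given; E-values are never
  recomputed.
- The kinase-class motif-level checks (activation-domain residues,
  autophosphorylation sites) require curated alignments and are not
  computed; the Kinase class here is domain-level only.
- `overlap_fraction` on spans means two models sharing an intron-dense
  region can merge even with modest exon agreement; this is intentional
  (see above) but worth knowing when interpreting merged loci.
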