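---
title: "Building cytokine response dictionaries and scoring user data against them"
author: "cytodict maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building cytokine response dictionaries and scoring user data against them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytodict)
```

# The problem

Cytokines are secreted signalling proteins that reprogram the
transcriptomes of the cells that sense them. A perturbational single-cell
RNA-seq compendium — many immune cell types profiled under systematic
in vivo stimulation with individual cytokines, alongside vehicle (PBS)
controls from replicate animals — lets us build, per cell type, a
reference of what each cytokine does. `cytodict` implements that
construction end to end and the companion enrichment machinery that scores
any user expression dataset against the reference: which cytokines were
likely active, which polarization state the cells occupy, and which
cell–cell communication channels can explain the observed response.

The package is organised around a `CytokineCompendium` (a
`SingleCellExperiment` whose column data carry `cell_type`, `condition`
and `replicate`, with `"PBS"` as the reserved control token) and a
`CytokineCatalog` mapping each of 86 cytokines to its encoding gene(s)
and receptor complexes. All downstream stages consume these two objects.

# Preprocessing

Cells are gated on three strict inequalities (more than 500 detected
genes, more than 1,000 UMIs, less than 10% mitochondrial content;
`qcFilter`). Counts are then scaled per cell to a total of 10,000 and
transformed with the natural logarithm of (value + 1)
(`normalizeLog`). The +1 pseudocount follows the convention of the
standard single-cell toolchains; the per-cell de-logged total of 10,000
is enforced as a class invariant so downstream stages can trust their
input scale. Gene exclusion policies (`exclusionPolicy`) remove
ribosomal (`Rps*`/`Rpl*`), mitochondrial (`mt-*`), unlabelled
(predicted-model `Gm####` and Riken `*Rik` symbols, both patterns
user-overridable because there is no canonical definition), dissociation
stress and cell-cycle genes (small packaged fixture lists), optionally
globally overabundant genes (top 0.1% of counts, off by default), and
genes detected in fewer than 10 cells.

# Signatures

`differentialExpression` contrasts, per gene, cytokine-treated against
PBS-treated cells of one cell type with a two-sided Wilcoxon rank-sum
test on normalized expression. The kernel (`rankSumTest`) computes exact
tie-aware p-values by dynamic programming over the observed rank multiset
whenever both groups have at most eight cells, and a tie-corrected normal
approximation without continuity correction otherwise; the exact path is
validated against brute-force enumeration in the test suite. Fold changes
use the common single-cell convention
`log2((mean(expm1 x) + 1) / (mean(expm1 y) + 1))`.

`buildSignature` applies the filter cascade in a fixed order: BH FDR <
0.05, |log2FC| > 0.25, expression in more than 10% of treated cells (for
upregulated genes) or control cells (for downregulated genes), the same
fold-change threshold satisfied in the pooled direction by at least 2 of
3 replicate mice, and finally the category exclusions. Replicate pairing
matches treated mouse *r* with PBS mouse *r* when that replicate ID
exists among controls and with all PBS cells otherwise. Attrition is
logged per filter.

The response-magnitude map (`responseMagnitude`) samples at most 100
cells per condition (seeded), measures the Euclidean distance between
treated and PBS centroids over all genes (the centroid uses every gene
rather than a variable-gene subset, keeping the measure parameter-free),
winsorizes distances at the 95th percentile (type-7 linear-interpolation
quantile, computed within each cell type since cell types are analysed
independently) and rescales so the maximum is 100. Combinations with
fewer than five cells are omitted.

`geneSetScore` sums normalized expression over a gene set per cell
(absent genes contribute zero with a warning); `accessAuc` turns treated
and control scores into a rank-based AUC — the standard check that a
stimulus physically reached a cell population, e.g. with an
interferon-stimulated-gene score. `secondaryResponseScore` builds a
strict donor signature (FDR < 0.001, log2FC > 1) per cell type and
reports, for every other treatment, the log2 fold change of the mean
per-cell score versus PBS with a rank-sum FDR; scores are compared on the
de-logged (expm1) scale so that a doubling of signature-gene means reads
as a fold change of ~1 on the log2 scale.

# Gene programmes

`fitPrograms` factorizes the (policy-filtered, per-group-capped)
expression matrix into k non-negative programmes with Frobenius-loss
multiplicative updates from a deterministic NNDSVD initialization
(variant "a": zeros backfilled with the matrix mean), making fits
reproducible without relying on the random stream. Loadings are
normalized to unit L2 norm so per-cell weights are in expression units.
The cytokine-centric wrapper defaults to k = 40 (fitting one cytokine —
or a related pair, such as the two type I interferons or IL-1a/IL-1b,
via the condition argument — together with PBS controls across cell
types); the cell-type-centric wrapper defaults to k = 10 (one cell type
across all conditions). `programSignificance` rank-sum-tests per-cell
weights (treated versus PBS, per cell type), with the mean weight
difference as effect size, displayed capped at 10 with the raw value
retained, and flags a programme as upregulated when any cell type shows
effect size > 1 at FDR < 0.01. `topProgramGenes` returns the 30
highest-loading genes (ties broken lexicographically), and
`overRepresentation` provides the generic upper-tail hypergeometric
interface for annotating them with any GMT collection. Full pre-ranked
KS-statistic enrichment is intentionally out of scope; top-gene
over-representation covers the same decisions at this scale.

# Polarization states

`discriminatingGenes` keeps genes whose |log2FC| versus PBS exceeds a
per-cell-type threshold (default 0.75, sensibly varied in [0.75, 1.5])
under at least one cytokine, minus dissociation, cell-cycle,
mitochondrial and ribosomal genes. `subcluster` runs PCA (10 components
by default) and Louvain community detection on a 20-nearest-neighbour
graph at resolution 0.5 — the paper-era defaults for graph clustering —
merging singleton clusters into their nearest centroid. `callStates`
tests every (cluster, cytokine) pair with an upper-tail hypergeometric
(population: all cells of the type; successes: the cytokine's cells;
draws: the cluster), BH-corrects across all pairs within the cell type,
and promotes clusters with any driver at FDR < 0.01 to states.
`nameStates` applies the canonical convention
`<cell-type-abbrev>-<letter>`, reserving a–d for type I interferon,
type II interferon, IL-1a/IL-1b and TNF drivers respectively (the
largest state wins a contested letter) and assigning e, f, … to the
rest by decreasing size. `stateSimilarity` computes Pearson correlations
between PBS-subtracted state profiles, Jaccard similarities of the up-
and downregulated gene sets (|log2FC| > 0.5, computed separately), a
uniqueness score (inverse mean Jaccard against the other states, taken
on the signed union of up- and down-sets so a state without
downregulated genes is not penalized by an empty-set convention), and an
average-linkage dendrogram on Euclidean distances between correlation
rows, exportable as Newick.

Statistically called states are all reported, ranked by driver FDR; the
biological-relevance curation the original procedure performs by hand is
explicitly left to the user.

# Production, receptors and interactomes

`productionMap` averages each catalog ligand gene over all conditions
(stimulated conditions included, to capture induced expression), drops
genes detected in fewer than 50 cells, caps cell-type means at 1
expression unit, row-normalizes to the maximum cell type, and flags
expression where the normalized value exceeds 0.1. A heteromeric
cytokine counts as expressed when at least one subunit is expressed (its
edges carry an asterisk flag in exports). `receptorMap` declares a
receptor complex expressed only when every component exceeds the
threshold (default 0.1 expression units, on raw cell-type means since
the rule is stated in expression units) and a cytokine receptor-positive
when any of its receptor options is expressed. The ligand–response
interactome joins producers (expressed flag) to responders with strictly
more than 10 signature DEGs; the ligand–receptor interactome joins the
same producers to receptor-positive cell types; `compareInteractomes`
partitions the two edge sets exactly. The abundance–production analysis
samples an equal number of cells per cell type, counts cytokines whose
ligand genes exceed the 0.1 detection threshold, and reports the Pearson
correlation with log10 PBS abundance together with its two-sided t-test
p-value.

# Enrichment of user data

`enrichGeneSet` scores a user gene set against each reference cytokine by
rank-sum-testing per-cell set scores (treated versus PBS) with BH
correction across all cytokines, or by hypergeometric overlap with each
cytokine's FDR < 0.01 DEGs. `enrichTranscriptome` reduces a user
condition/control matrix pair (normalized to 10,000-unit log1p values
unless already normalized) to one differential vector, restricts genes to
those whose reference cell-type average exceeds 0.25 expression units,
and computes per reference cell a projection score: the cosine similarity
between the user differential and the cell's PBS-centred profile.
Centring the reference cells by the PBS mean of their cell type makes
both vectors differentials, so a gene upregulated in one dataset and
downregulated in the other contributes negative weight; the option is
configurable to uncentred profiles. Effect size is the mean projection
difference between a cytokine's cells and PBS cells, significance is the
shared rank-sum kernel with BH across the cytokines of the reference,
and per-gene contribution weights (product of user and reference
differential components) are attached for inspection. Cosine projections
are bounded in [-1, 1], invariant to positive rescaling of the user
differential and exactly antisymmetric under swapping condition and
control — properties the test suite asserts. A zero differential vector
projects to zero everywhere and returns effect sizes of zero with
p-values of one.

`enrichPolarization` reuses the same machinery, contrasting projection
scores on each state's member cells against the other cells of the cell
type. When at least one state reaches FDR < 0.05 the positive effect
sizes are normalized by their maximum to [0, 1] (so the top state scores
exactly 1, satisfying the bounded radar-plot convention); otherwise every
normalized score is 0, reading as "unpolarized input". Max-normalization
was chosen over a fixed scale because it is the only convention that
guarantees the stated [0, 1] bound for arbitrary inputs.
`communicationNetwork` combines per-cell-type enrichment results
(responder edges at FDR < 0.01 with positive effect) with user-side
transcript evidence of production (any ligand subunit above 0.1, with
heteromer asterisks) and receptor flags at the 0.05 threshold used for
user data, which is deliberately more permissive than the 0.1 reference
threshold because user datasets are typically shallower. `mapHomologs`
applies one-to-one mouse/human symbol mappings from a packaged curated
subset (or any user table), dropping one-to-many mappings with a
warning.

# The synthetic compendium

`generateCompendium` draws counts from a negative binomial
(gene dispersion 0.5, the typical droplet-data overdispersion) around
per-gene lognormal base means modulated by per-(gene, cell type)
identity factors, multiplies planted module genes by 2^log2FC in a
responding fraction of treated cells, applies a shared lognormal
replicate factor per (condition, replicate, gene) (sd 0.05 — small, but
enough to give the 2-of-3-mice filter something real to test) and a
per-cell lognormal library factor (sd 0.3). Ligand genes of the
simulated cytokines are planted as constitutively produced by one
designated producer cell type each; receptor genes are moderately
expressed everywhere; a handful of ribosomal/mitochondrial/unlabelled
decoy symbols exercise the exclusion policies and are never used in
planted modules. The default benchmark (`defaultBenchmarkSpec`) is 6
cytokines x 4 cell types x 3 replicates, 200 cells per (cell type,
condition) and 2,000 genes with 30-gene modules at log2FC 2 in 80% of
treated cells — sized so that the full pipeline, the acceptance script
and the test suite run comfortably on a single CPU (the whole test suite
takes under two minutes).

What the generator does not emulate: ambient RNA, doublets, batch
chemistry, gene–gene correlation beyond the planted modules, and
realistic cell-type marker structure. Passing the recovery tests
therefore demonstrates correctness of the statistical machinery under a
faithful noise model, not performance on real tissue data.

Two properties of the generator are worth understanding when reading
test output. First, because expression is library-normalized, planting
up-modules makes every other gene genuinely lower in normalized units;
the signature pipeline correctly reports a few such compositional
down-genes, which the counts-space ground truth counts against
precision. The effect shrinks with the gene universe (at 2,000 genes the
benchmark stays above 0.9 precision) and is a property of
normalized-scale differential expression generally. Second, conditions
are confounded with replicate animals, exactly as in the real design,
and discriminating-gene selection reuses the data that the subsequent
hypergeometric enrichment tests; the polarization path is therefore
slightly anticonservative on null data and can emit an occasional
spurious state.

# Numerical choices and degenerate inputs

Exact rank-sum enumeration runs on doubled midranks so tied data stay on
an integer lattice; two-sided p-values are twice the smaller tail, capped
at 1. BH is used wherever the procedures say "FDR". Quantiles are type-7.
NMF convergence is declared when the relative Frobenius error improves by
less than 1e-6 over ten iterations (200 iterations maximum). Zero-norm
vectors in cosine projections score 0; zero-variance profiles yield NA
correlations with a warning; empty similarity unions score 1 on the
matrix diagonal convention and 0 uniqueness contribution via the signed
union. All-zero cells are a hard error in normalization (the scaling is
undefined), and every seeded stage (sampling, clustering, generation)
takes an explicit seed and restores the caller's random stream.

# Known limitations

Receptor listings in the packaged catalog are a curated convenience, not
an exhaustive registry. The polarization workflow operates on the cell
type labels it is given and does not re-derive homogeneous subsets of
heterogeneous types. The enrichment reference shipped here is synthetic;
real analyses require building the reference from a real perturbational
compendium with the same functions.
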