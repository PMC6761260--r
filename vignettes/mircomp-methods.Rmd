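---
title: "Methods: comparative miRNA genomics with mircomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative miRNA genomics with mircomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`mircomp` implements a comparative analysis of microRNA repertoires across
a species phylogeny, of the kind used to contrast evolutionarily conserved
and recently arisen (lineage-specific) miRNAs in a clade of closely related
fishes. The workflow takes per-species mature/precursor miRNA sets,
precursor genomic coordinates, a dated species tree, per-gene multi-species
3' UTR alignments and per-individual expression counts, and asks:

* how do mature miRNAs group into families and isomiR genes, and which
  genes are conserved across all species vs specific to one lineage;
* where in the genome do precursors cluster, and does clustering differ by
  conservation class;
* where do seed-match target sites fall along 3' UTRs, and are conserved
  sites biased toward the 5' end;
* are miRNA and target mRNA expression negatively coupled, both across
  individuals and across species after removing phylogenetic covariance;
* which genes accumulate species-specific target sites fastest, and what
  functions are enriched among them.

Upstream read processing, mapping, hairpin discovery, transcriptome
assembly, ortholog calling and alignment computation are out of scope: the
package consumes their standard outputs (FASTA, BED6, newick, aligned
FASTA, TSV).

## Catalog construction

**Families.** Mature miRNAs are compared all-against-all by optimal local
(Smith–Waterman) alignment with affine gaps, scoring (match 5, mismatch
−4, gap open −10, gap extend −4). Two matures are linked when the optimal
alignment has identity ≥ 0.75 over ≥ 14 aligned columns; families are the
single-linkage components of this graph. The original e-value rule of a
database search tool depends on its statistical calibration and database
size; a fixed identity/coverage rule is deterministic and reproducible.
Both thresholds are arguments of `build_families()`. Family and gene ids
are the lexicographically smallest member id, so output is invariant to
input order. Note that single linkage percolates: on sequence sets with
many unrelated ~22-nt matures, chance local similarities can chain distinct
families into one component. Gene-level assignments are robust to this
(see below), but raw family counts should be read with that caveat.

**IsomiR genes.** Within a family, matures sharing an identical seed
(nucleotides 2–8 from the 5' end, 1-based inclusive) are isomiRs of one
miRNA gene. A gene is *variable* when it carries ≥ 2 distinct mature
sequences, pooling intra- and inter-species variants. Because genes are
keyed by (family, seed) and the seed is a 7-nt exact match, accidental
family merging renames components but cannot merge two genes with
different seeds — which is why gene-level conservation calls stay exact
even when family linkage percolates.

**Conservation classes.** A gene present in every tip of the tree is
*conserved*; present in exactly one species, *species-specific*; otherwise
*non-conserved*. The classes partition the genes.

**Known vs novel.** A gene is *known* when any member aligns to a
reference mature set with identity ≥ 0.9 computed over the full length of
the shorter sequence; the threshold is strict (0.89 is novel).

**Gain/loss.** Presence/absence of each gene on the tree is explained by
Dollo parsimony: one gain, any number of losses. The gain is placed on
the branch above the MRCA of the present tips (placing it higher strictly
adds losses, so the optimum is unique), and losses are the maximal
subtrees below the gain without present tips. Dollo rather than Fitch
matches the biological asymmetry — novel miRNAs arise readily but are
unlikely to arise twice identically.

## Genomic clusters

Within each (scaffold, strand), precursors sorted by start are chained
when the intergenic gap (next start − previous end) is below `max_gap`
(default 5,000 bp; 50,000 is available as an argument for the wider
grouping convention). Chains of ≥ 2 are clusters; chaining is
single-linkage, so a cluster's span may exceed the gap threshold —
matching the polycistron intuition. Gap is measured end-to-start rather
than start-to-start because precursors are only ~70 nt, so the choice
rarely matters; it is configurable through the interval coordinates
themselves. Cluster density is members per kb of span (first start to
last end). A cluster's class label is unanimous-or-`mixed`; mixed clusters
are excluded from the density comparison. Clustered fractions by class are
compared with a Yates-corrected chi-square, densities with a two-sided
Welch t-test.

## Target sites and spatial statistics

**Site types.** For a mature miRNA, the four canonical site strings on the
target strand (5'→3') are: `6mer` = reverse complement of positions 2–7;
`7mer-m8` = reverse complement of 2–8; `7mer-A1` = 6mer followed by `A`;
`8mer` = both. Scanning anchors on every (overlapping) 6mer occurrence and
reports the strongest supported type at that locus
(8mer > 7mer-m8 > 7mer-A1 > 6mer); distinct loci may overlap. Only perfect
seed matches count — no context scoring, no ORF or 5' UTR sites.

**Conservation of sites.** A site is conserved when every species in that
gene's alignment has a site of the same miRNA gene whose match window
overlaps it by ≥ 6 alignment columns. The overlap rule (rather than exact
column equality) tolerates ±1 column of alignment jitter; the site *type*
may differ between species.

**Spatial distribution.** Each site's relative position is its midpoint
scaled to [0, 1] (0 at the stop codon). The positional density is a
Gaussian KDE with Silverman's reference bandwidth
0.9·min(s, IQR/1.34)·n^(−1/5), evaluated on an even 512-point grid over
[0, 1]; an OLS line is fitted to the density restricted to the 10–90%
window and its slope reported. The interior window makes KDE edge
treatment irrelevant. The midpoint convention is symmetric for all site
lengths; endpoint conventions give near-identical densities. Genes are
split into *long* (strictly greater than the median UTR length) and
*short* (the rest), which is deterministic under ties.

**Emergence rates.** Per target gene: the number of sites whose miRNA gene
is species-specific, summed over species, divided by the summed ungapped
UTR length over the aligned species. The cross-species sum is used because
species-specific targets are pooled per transcript; a per-species mean is a
trivial rescaling. The top 5% of genes (ceiling, ties broken by gene id)
feed a GO over-representation test: one hypergeometric upper-tail test per
term with ≥ 1 test-set hit, Benjamini–Hochberg corrected. BH is used in
place of service-specific multiple-testing schemes that have no closed-form
specification.

## Expression and correlation

miRNA counts are RPM-normalised (library size only; matures are
near-constant length), mRNA counts TPM-normalised (length, then library).
Functional pairs — (miRNA gene, target gene) with a site conserved in all
species — are correlated across individuals with Pearson's r on
log2(x + 1) values (the transform is an argument; correlations assume a
roughly additive scale). P-values use the t-distribution with n − 2 df; no
multiple-testing correction is applied at this stage because the read-out
is the sign count, not per-pair claims.

For the across-species analysis, per-species means of log2(x + 1)
expression are reduced to phylogenetically independent contrasts
(Felsenstein pruning, standardized by the square root of the summed
adjusted branch lengths) and correlated through the origin,
r = Σxy / √(Σx²·Σy²), since contrasts have arbitrary sign. The excess of
negative over positive coefficients is tested with an uncorrected 50:50
goodness-of-fit chi-square; zeros and undefined correlations are excluded.
By default all non-NA pairs enter the count (restricting to nominally
significant pairs is a flag), since the sign census is the quantity of
interest.

## The synthetic study generator

`simulate_study()` generates a complete study with planted ground truth so
every stage is testable without any external data. Its defaults are the
study conditions: 8 species on a fixed two-clade tree (five “African”, three
“Neotropical” tips, all at depth 1 in relative time), 200 miRNA
families, 300 target genes, 6 individuals per species (48 samples).

**Repertoires.** Each family is gained exactly once — at the root with
probability 0.4, otherwise on a branch drawn uniformly among the 14
edges — and lost independently on each descendant branch with probability
0.15, so every presence pattern is Dollo-consistent by construction. With
these rates roughly 8–10 families survive in all 8 species, and about half
of the non-root families originate on terminal branches, giving a large
species-specific class — mirroring the strong skew toward lineage-specific
miRNAs that motivates the analysis. Mature sequences are 22 nt; family
seeds are drawn unique across families (rejection sampling), and per-branch
seed mutations (probability 0.02 for root-origin, 0.2 for novel-origin
lineages) also re-draw on collision. Unique seeds make gene identity
(family × seed) unambiguous, so conservation-class recovery is exact by
construction rather than up to stochastic slack. IsomiR variants are drawn
once per family (probability 0.45 root-origin, 0.05 tip-origin) as 3'-end
trims of 1–2 nt or non-seed substitutions; 5'-end variants exist in real
data but would shift the 2–8 seed and split the gene under the very rule
being tested, so the generator omits them to keep planted labels
well-defined. At the defaults this yields ~50% variable conserved genes vs
~2–5% variable species-specific genes.

**Coordinates.** Per species, each precursor joins an open cluster chain
(same scaffold/strand, gap uniform in [200, 4000) bp) with probability
0.45 for root-origin and 0.15 for tip-origin families, or opens a new
location several hundred kb from everything else. Planted gaps are all
below 4 kb and isolated placements far beyond 5 kb, so detection at the
default threshold recovers the planted chains exactly. Because clustering
propensity is keyed to root origin while “conserved” is the stricter
realized condition (root origin *and* no loss anywhere), the realized
clustered-fraction contrast between conserved and non-conserved precursors
is attenuated relative to the planted 0.45 : 0.15 ratio; the
clustered-fraction machinery is therefore exercised separately on
table-scale fixtures in the tests.

**UTRs and sites.** Each gene's ancestral UTR (log-normal length, median
~1 kb, floor 200 nt) evolves down the tree with per-site substitutions
(rate 0.3 per unit time) and short deletions (0.005 events/site/unit,
1–3 nt); the true alignment is emitted directly, so no aligner runs and
site-conservation calls are exactly recoverable. Insertions are omitted:
they would only add columns gapped in all but one lineage, which carry no
comparative signal here. Sites of conserved miRNAs (Poisson mean 12 per
miRNA) are written into the ancestor at Beta(1, 3) relative positions —
5'-skewed, mean 0.25 — and protected from mutation, with flanking bases
fixed so a scanner reports exactly the planted type; species-specific
sites (Poisson mean 3) are written into the single carrier species at
Beta(1, 1) (uniform) positions. Chance seed matches arise freely in the
evolving background, as in real UTRs, so "all sites" are dominated by
unplanted, uniformly placed matches (flat density, |slope| small) while
conserved-site calls are dominated by planted sites (strongly negative
slope): the generator reproduces the qualitative spatial contrast without
hard-coding it.

**Expression.** Per individual, miRNA log-expression is a family base
(log 600 for root-origin vs log 150 for novel families), a per-species
effect (SD 0.25) and noise (SD 0.3 default); counts are Poisson draws of
the exponentiated values, and absent miRNAs count zero. mRNA
log-expression is a gene base minus `repression_gamma` × Σ over planted
targeting miRNAs of (site count × the individual's standardized latent
miRNA expression) plus noise. Coupling acts on standardized expression so
γ has a scale-free meaning. The default γ = 0.3 represents moderate
repression; the strong-coupling regime (γ = 1, noise 0.05) makes > 90% of
planted pairs read out negative and is used for the recovery check.

**Annotation.** Genes get 1–4 random GO terms from a 40-term vocabulary;
one planted term is attached with probability 0.8 (vs 0.05 background) to
the top decile of genes by realized species-specific seed-match density,
so the enrichment stage has a recoverable signal.

**What the generator does not emulate.** No rate heterogeneity across
sites or lineages, no indel-driven alignment error (true alignments are
emitted), no hairpin secondary structure, no site turnover (planted sites
are mutation-protected), no expression batch effects or overdispersion
beyond Poisson. Passing the recovery tests therefore demonstrates the
correctness of the algorithms under a faithful generative model, not the
robustness of the pipeline to alignment error or expression noise in real
data.

## Numerical choices

* Yates correction clamps at zero, Σ max(|O−E|−0.5, 0)²/E, so near-null
  tables cannot be inflated.
* Mann–Whitney p-values are exact (full enumeration) up to combined
  n = 10 with no ties, otherwise normal approximation with tie and
  continuity correction; the variant used is recorded in the result.
* KDE is evaluated on [0, 1] only; the 10–90% regression window keeps the
  estimate clear of boundary effects.
* PCA centres features and uses SVD; the sign of each component is fixed
  by making its largest-magnitude loading positive, and zero-variance
  input returns all-zero shares instead of an error.
* Ties everywhere break lexicographically (family/gene ids, top-fraction
  selection), so every output is deterministic; a single integer seed
  drives all simulation stages, with fixed per-stage offsets so each stage
  is independently reproducible.
* Degenerate inputs error early and informatively: empty FASTA, duplicate
  ids, start ≥ end with line number, all-zero expression columns by
  sample name, all-absent presence patterns, zero branch lengths in
  contrasts.

## Problem sizes

The test suite exercises reduced studies (40 families, 50 genes, 3
individuals per species) for unit-level checks and the full default study
(200 families, 300 genes, 48 samples, ~40–45k predicted sites) for
end-to-end recovery; the whole suite runs in about a minute on one core.
The oracle-equivalence checks compare against brute force at the largest
sizes where brute force is comfortable: 10 kb UTRs for the site scanner,
200 intervals for clustering, all presence patterns on trees up to 6 tips
for Dollo, combined n ≤ 8 for the exact rank test, N ≤ 60 for the
hypergeometric tail.

## Known limitations

* Single-linkage families percolate on large random-sequence sets; gene
  assignments are insulated from this, but family counts are not.
* The identity/coverage linkage rule is a deterministic stand-in for
  calibrated e-value searches and will not match their borderline
  decisions.
* The clustered-fraction contrast in the generator is attenuated (see
  above); the statistic itself is validated on fixed tables.
* GO enrichment treats the annotation as flat — no GO-graph propagation.
* Site conservation requires the same miRNA gene but not the same site
  type across species; requiring equal types is a stricter, easily added
  variant.
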