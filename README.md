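# mircomp

Comparative miRNA genomics across a species phylogeny: families and
isomiRs, conservation classes and gain/loss histories, genomic precursor
clusters, seed-match target sites on aligned 3′ UTRs with spatial
statistics, miRNA–mRNA expression coupling, and species-specific target
"emergence rates" with GO enrichment.

The package is written for researchers comparing small-RNA repertoires
across closely related species — the motivating system is a clade of eight
cichlid fishes spanning an African and a Neotropical radiation — who want
to contrast deeply conserved miRNAs with recently arisen, lineage-specific
ones. It consumes standard upstream outputs (FASTA, BED6, newick, aligned
FASTA, count TSVs) and ships a synthetic-study generator with planted
ground truth so the entire workflow is testable end to end without any
external download.

## The methods in brief

* **Families and genes.** Mature miRNAs are linked by optimal local
  (Smith–Waterman) alignment — identity ≥ 0.75 over ≥ 14 columns, scoring
  (5, −4, −10, −4) — and families are single-linkage components. Within a
  family, matures sharing an identical seed (nucleotides 2–8) are isomiRs
  of one miRNA *gene*; a gene with ≥ 2 distinct mature sequences is
  *variable*.
* **Conservation.** A gene in all tree tips is *conserved*; in exactly one
  species, *species-specific*; otherwise *non-conserved*. Gain/loss
  histories follow Dollo parsimony (one gain above the MRCA of the present
  tips, minimal losses).
* **Clusters.** Precursors on one scaffold and strand chain into clusters
  when intergenic gaps are < 5 kb; clustered fractions by class are
  compared by Yates-corrected χ², per-cluster densities (members/kb) by
  Welch *t*.
* **Target sites.** Canonical seed matches on ungapped UTRs — 6mer
  (positions 2–7), 7mer-m8 (2–8), 7mer-A1 (2–7 + A1), 8mer — with the
  strongest type reported per locus. A site is conserved when every
  aligned species has a site of the same miRNA gene overlapping it by ≥ 6
  alignment columns. Site midpoints scaled to [0, 1] enter a Gaussian KDE
  (Silverman bandwidth); the OLS slope of the density over the 10–90%
  window summarises 5′ bias.
* **Expression.** miRNA counts → RPM, mRNA counts → TPM. Functional pairs
  (sites conserved in all species) are correlated across individuals
  (Pearson, log2(x+1)) and across species via phylogenetically independent
  contrasts correlated through the origin, r = Σxy/√(Σx²Σy²); the excess
  of negative coefficients is tested against 50:50 (χ², df = 1).
* **Emergence.** Per gene: species-specific sites / summed 3′ UTR length.
  The top 5% of genes are tested for GO over-representation
  (hypergeometric upper tail, Benjamini–Hochberg).

See `vignettes/mircomp-methods.Rmd` for assumptions, parameter defaults
and numerical choices.

## Worked example

Simulate the default study (8 species, 200 miRNA families, 300 genes,
48 samples) and run the whole analysis:

```r
library(mircomp)
study <- simulate_study(sim_config(rng_seed = 1))
res   <- analyze_study(study)

table(res$catalog$conservation$class)
#>        conserved    non-conserved species-specific
#>               10               86              125

res$catalog$variability$percent_variable
#>        conserved species-specific
#>             50.0              2.4

res$spatial$slope_all        # all sites: near-flat positional density
#> [1] -0.0299
res$spatial$slope_conserved  # conserved sites: strongly 5'-biased
#> [1] -2.974

res$correlation$sign_bias$test
#> chi2_gof: statistic = 97.0396, df = 1, p = 6.795e-23, n = 101

head(res$emergence$enrichment, 1)
#>         term  k  n  K   N            p            q
#> 1 GO:0000001 13 15 45 300 3.131168e-10 7.514804e-09
```

Reading the output: of 221 recovered miRNA genes, the 10 conserved ones
are far more often variable (multiple isomiRs) than the 125
species-specific ones (50% vs 2.4%); target sites overall sit uniformly
along UTRs (slope ≈ 0) while sites conserved in all eight species pile up
near the stop codon (negative slope); 100 of 101 conserved miRNA–mRNA
pairs correlate negatively across individuals, decisively rejecting a
50:50 sign split; and the planted GO term tops the enrichment table for
the high-emergence gene set. Every one of these read-outs matches the
generator's planted truth — conservation classes and cluster memberships
are recovered exactly (see the test suite).

The same analysis can be run stage by stage through the numbered scripts,
which exchange standard-format files under `results/`:

```sh
Rscript analysis/01_simulate.R 1     # write inputs + truth to results/study/
Rscript analysis/02_catalog.R        # families.tsv, conservation.tsv, gainloss.tsv
Rscript analysis/03_clusters.R       # clusters.tsv, cluster_tests.json
Rscript analysis/04_targets.R        # sites.tsv, spatial.json
Rscript analysis/05_expression.R     # correlations.tsv, pic_correlations.tsv
Rscript analysis/06_emergence.R      # emergence.tsv, top_genes.txt, go_enrichment.tsv
```

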