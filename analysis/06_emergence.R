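#!/usr/bin/env Rscript

# Stage 6 — emergence of species-specific targets and GO enrichment.
#
# Scores each gene's emergence rate (species-specific sites per summed 3'
# UTR nt), selects the top 5% of genes, and tests GO terms for
# over-representation against the whole gene set (hypergeometric test,
# Benjamini-Hochberg correction). Writes emergence.tsv, top_genes.txt and
# go_enrichment.tsv.

suppressMessages(library(mircomp))

for (f in c("results/sites.tsv", "results/conservation.tsv")) {
  if (!file.exists(f)) stop("missing ", f, ": run the earlier stages first")
}
study <- load_study("results/study")
sites <- read.table("results/sites.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
cons <- read.table("results/conservation.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
ss_mirnas <- cons$gene_id[cons$class == "species-specific"]

utr_lengths <- do.call(rbind, lapply(names(study$utrs$alignments),
                                     function(g) {
  a <- study$utrs$alignments[[g]]
  data.frame(gene_id = g, species = names(a),
             length = nchar(gsub("-", "", a, fixed = TRUE)),
             stringsAsFactors = FALSE)
}))
em <- emergence_rates(sites, ss_mirnas, utr_lengths)
write_tsv(em, "results/emergence.tsv")
top <- select_top_fraction(em, 0.05)
writeLines(top, "results/top_genes.txt")
cat(sprintf("Top %d of %d genes by species-specific target emergence rate;\nhighest rate %.2e sites/nt.\n",
            length(top), nrow(em), max(em$rate)))

enr <- go_enrichment(top, em$gene_id, study$annotation$annotation)
write_tsv(enr, "results/go_enrichment.tsv")
cat("Top enriched GO terms:\n")
print(head(enr, 5))
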