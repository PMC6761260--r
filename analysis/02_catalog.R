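#!/usr/bin/env Rscript

# Stage 2 — build the miRNA catalog.
#
# Groups matures into families by all-against-all local alignment, splits
# families into isomiR genes by the shared 2-8 seed, classifies
# phylogenetic conservation, cross-tabulates sequence variability by class,
# and infers each gene's Dollo gain/loss history. Writes families.tsv,
# conservation.tsv, gainloss.tsv and variability.json under results/.

suppressMessages(library(mircomp))

if (!dir.exists("results/study")) {
  stop("missing results/study: run analysis/01_simulate.R first")
}
study <- load_study("results/study")
cat_res <- build_catalog(study$repertoires$matures, study$config$tree)

write_tsv(cat_res$matures[, c("id", "species", "family_id", "gene_id",
                              "seed", "variable")],
          "results/families.tsv")
write_tsv(cat_res$conservation, "results/conservation.tsv")
write_tsv(cat_res$gainloss, "results/gainloss.tsv")
jsonlite::write_json(list(
  table = as.data.frame(as.table(cat_res$variability$table)),
  percent_variable = as.list(cat_res$variability$percent_variable),
  chi2 = if (!is.null(cat_res$variability$test))
    unclass(cat_res$variability$test) else NULL
), "results/variability.json", auto_unbox = TRUE, digits = NA)

cls <- table(cat_res$conservation$class)
cat(sprintf("Cataloged %d matures into %d families / %d genes.\n",
            nrow(cat_res$matures),
            length(unique(cat_res$matures$family_id)),
            nrow(cat_res$conservation)))
print(cls)
cat("Percent variable by class:\n")
print(cat_res$variability$percent_variable)
if (!is.null(cat_res$variability$test)) print(cat_res$variability$test)
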