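#!/usr/bin/env Rscript

# Stage 5 — expression normalisation and miRNA-mRNA coupling.
#
# Normalises the count matrices (RPM for miRNAs, TPM for mRNAs), runs PCA
# on both layers, correlates functional pairs (sites conserved in every
# species) across individuals, repeats the correlation on phylogenetically
# independent contrasts of per-species means, and tests for an excess of
# negative coefficients. Writes correlations.tsv, pic_correlations.tsv and
# sign_bias.json.

suppressMessages(library(mircomp))

if (!file.exists("results/sites.tsv")) {
  stop("missing results/sites.tsv: run analysis/04_targets.R first")
}
study <- load_study("results/study")
sites <- read.table("results/sites.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)

rpm <- rpm_normalize(study$expression$mirna_counts)
tpm <- tpm_normalize(study$expression$mrna_counts,
                     study$expression$gene_lengths)
p_mi <- pca(log2(rpm + 1))
p_mr <- pca(log2(tpm + 1))
cat(sprintf("PC1 explains %.1f%% (miRNA) and %.1f%% (mRNA) of the variance.\n",
            100 * p_mi$variance_explained[1],
            100 * p_mr$variance_explained[1]))

co <- sites[sites$conserved_site, ]
pairs <- unique(data.frame(mirna_gene = co$mirna_gene,
                           target_gene = co$target_gene,
                           stringsAsFactors = FALSE))
if (nrow(pairs) == 0) stop("no conserved functional pairs to correlate")
pc <- pair_correlations(rpm, tpm, pairs)
write_tsv(pc, "results/correlations.tsv")
sb <- sign_bias_test(pc$r)
cat(sprintf("Across individuals: %d of %d pair correlations negative.\n",
            sb$n_negative, sb$n_negative + sb$n_positive))
print(sb$test)

sm <- species_mean_expression(rpm, study$expression$species_of_sample)
gm <- species_mean_expression(tpm, study$expression$species_of_sample)
tree <- study$config$tree
pic_r <- vapply(seq_len(nrow(pc)), function(i) {
  cx <- pic_contrasts(tree, sm[pc$mirna_gene[i], ])
  cy <- pic_contrasts(tree, gm[pc$target_gene[i], ])
  pic_correlation(cx$contrast, cy$contrast)
}, 0)
write_tsv(data.frame(pc[, c("mirna_gene", "target_gene")], pic_r = pic_r),
          "results/pic_correlations.tsv")
sb_pic <- sign_bias_test(pic_r)
cat(sprintf("Across species (contrasts): %d of %d negative.\n",
            sb_pic$n_negative, sb_pic$n_negative + sb_pic$n_positive))
print(sb_pic$test)

jsonlite::write_json(list(
  individuals = list(n_negative = sb$n_negative, n_positive = sb$n_positive,
                     chi2 = unclass(sb$test)),
  contrasts = list(n_negative = sb_pic$n_negative,
                   n_positive = sb_pic$n_positive,
                   chi2 = unclass(sb_pic$test)),
  pca = list(mirna_pc1 = p_mi$variance_explained[1],
             mrna_pc1 = p_mr$variance_explained[1])
), "results/sign_bias.json", auto_unbox = TRUE, digits = NA)
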