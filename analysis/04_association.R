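#!/usr/bin/env Rscript
# Single-variant association: covariate-adjusted logistic trend tests
# (age, study, 10 eigenvectors, region-average local ancestry), the
# Rsq >= 0.3 imputation filter, genotype-class ORs for the top signal, and
# study-heterogeneity tests.

suppressMessages(library(admixfine))

out <- "results/assoc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dm <- read_genotypes("results/qc/genotypes_qc.tsv", format = "tsv")
ph <- read_phenotypes("results/qc/phenotypes_qc.tsv")
ph <- ph[match(sample_ids(dm), ph$sample_id), ]
ev <- utils::read.table("results/ancestry/eigenvectors.tsv", header = TRUE,
                        sep = "\t")
ev <- ev[match(sample_ids(dm), ev$sample_id), ]
laa <- utils::read.table("results/ancestry/local_ancestry_region_avg.tsv",
                         header = TRUE, sep = "\t")
covars <- cbind(data.frame(age = ph$age),
                as.data.frame(stats::model.matrix(~study, ph)[, -1]),
                ev[, -1],
                la = laa$region_avg[match(sample_ids(dm), laa$sample_id)])

scan <- assoc_scan(dm, ph$status, covars, rsq_min = 0.3)
scan <- scan[order(scan$p_trend), ]
utils::write.table(scan, file.path(out, "association.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
top <- scan[1, ]
cat(sprintf("%d variants tested (Rsq >= 0.3); top signal %s: OR %.2f (%.2f-%.2f), p = %.2g\n",
            sum(!is.na(scan$p_trend)), top$variant_id, top$or, top$ci_lo,
            top$ci_hi, top$p_trend))

# genotype-class ORs for the top typed variant
typed_top <- scan$variant_id[scan$variant_id %in%
                               variant_ids(dm)[dm$variants$typed]][1]
gc <- genotype_class_test(dm$dosages[, typed_top], ph$status, covars,
                          variant_id = typed_top)
cat(sprintf("genotype classes at %s: het OR %.2f, hom OR %.2f\n",
            typed_top, gc$or_het, gc$or_hom))
utils::write.table(gc, file.path(out, "genotype_class.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# heterogeneity of the top 10 signals across studies
het <- do.call(rbind, lapply(head(scan$variant_id, 10), function(v)
  tryCatch(suppressWarnings(
    heterogeneity_by_study(dm$dosages[, v], ph$status, covars, ph$study,
                           variant_id = v)),
    error = function(e) NULL)))
utils::write.table(het, file.path(out, "heterogeneity.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("heterogeneity p < 0.05 for %d of %d top signals\n",
            sum(het$p_het < 0.05), nrow(het)))
cat("wrote", out, "\n")
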