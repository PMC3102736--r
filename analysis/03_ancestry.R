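#!/usr/bin/env Rscript
# Global ancestry by principal components (with the 4-SD outlier rule on
# the first two eigenvectors) and region-average local ancestry, including
# its association with case status.

suppressMessages(library(admixfine))

qc <- "results/qc"
out <- "results/ancestry"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dm <- read_genotypes(file.path(qc, "genotypes_qc.tsv"), format = "tsv")
ph <- read_phenotypes(file.path(qc, "phenotypes_qc.tsv"))
ph <- ph[match(sample_ids(dm), ph$sample_id), ]

ga <- compute_pca(dm, k = 10)
ve <- sum(ga$values[1:10]) / sum(ga$values)
cat(sprintf("top 10 eigenvectors explain %.1f%% of genetic variability\n",
            100 * ve))

outl <- flag_ancestry_outliers(ga, n_sd = 4)
cat(sprintf("%d ancestry outliers at 4 SD on EV1/EV2\n", length(outl)))
if (length(outl)) {
  dm <- subset_dosage(dm, samples = setdiff(sample_ids(dm), outl))
  ph <- ph[match(sample_ids(dm), ph$sample_id), ]
  ga <- compute_pca(dm, k = 10)
}

la <- read_local_ancestry("results/data/local_ancestry.tsv")
la <- la[sample_ids(dm), variant_ids(dm), drop = FALSE]
anc_frac <- rowMeans(la) / 2
cat(sprintf("correlation of EV1 with the true population-1 fraction: %.3f\n",
            cor(ga$vectors[, 1], anc_frac)))

# genome-average local ancestry vs case status, adjusted for age, study
# and the eigenvectors
rg <- read_regions("results/data/regions.tsv")
region <- list(region_name = rg$region_name[1], start = rg$start[1],
               end = rg$end[1])
la_avg <- summarize_local_ancestry(la, dm$variants, region)
covars <- cbind(data.frame(age = ph$age),
                as.data.frame(stats::model.matrix(~study, ph)[, -1]),
                as.data.frame(ga$vectors[, 3:10]))
assoc <- local_ancestry_association(la_avg, ph$status, covars)
cat(sprintf("OR per population-1 chromosome at %s: %.2f (%.2f-%.2f), p = %.3g\n",
            region$region_name, assoc$or, assoc$ci_lo, assoc$ci_hi,
            assoc$p))

utils::write.table(cbind(sample_id = rownames(ga$vectors),
                         as.data.frame(ga$vectors)),
                   file.path(out, "eigenvectors.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(sample_id = names(la_avg),
                              region_avg = la_avg),
                   file.path(out, "local_ancestry_region_avg.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(assoc, file.path(out, "local_ancestry_assoc.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
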