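#!/usr/bin/env Rscript
# Regional fine-mapping: the 500 kb window around the index marker (with
# D-prime block extension), the index-correlated set (r2 >= 0.2), greedy
# tag selection (r2 >= 0.8), the two-tier significance thresholds, and
# stepwise selection with mean-filled no-calls.

suppressMessages(library(admixfine))

out <- "results/finemap"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dm <- read_genotypes("results/qc/genotypes_qc.tsv", format = "tsv")
ph <- read_phenotypes("results/qc/phenotypes_qc.tsv")
ph <- ph[match(sample_ids(dm), ph$sample_id), ]
ev <- utils::read.table("results/ancestry/eigenvectors.tsv", header = TRUE,
                        sep = "\t")
ev <- ev[match(sample_ids(dm), ev$sample_id), ]
laa <- utils::read.table("results/ancestry/local_ancestry_region_avg.tsv",
                         header = TRUE, sep = "\t")
# stepwise covariates: age, study, global ancestry (EV1), local ancestry
covars <- cbind(data.frame(age = ph$age),
                as.data.frame(stats::model.matrix(~study, ph)[, -1]),
                EV1 = ev$EV1,
                la = laa$region_avg[match(sample_ids(dm), laa$sample_id)])

rg <- read_regions("results/data/regions.tsv")
index_id <- rg$index_variants[[1]][1]
idx_pos <- dm$variants$pos[match(index_id, variant_ids(dm))]

typed_dm <- subset_dosage(dm, variants = which(dm$variants$typed))
blocks <- infer_ld_blocks(typed_dm, threshold = 0.9)
win <- build_window(idx_pos, flank = 250000, blocks = blocks)
cat(sprintf("window around %s: %d-%d (%d kb)\n", index_id, win$start[1],
            win$end[1], round((win$end[1] - win$start[1]) / 1000)))

inside <- dm$variants$pos >= win$start[1] & dm$variants$pos <= win$end[1]
sub <- subset_dosage(dm, variants = which(inside))
cset <- correlated_set(sub, index_id, r2_index = 0.2)
ldm <- ld_matrix(sub)
tags <- greedy_tags(cset, ldm, r2_tag = 0.8,
                    pos = setNames(sub$variants$pos, variant_ids(sub)))
all_tags <- greedy_tags(variant_ids(sub), ldm, r2_tag = 0.8,
                        pos = setNames(sub$variants$pos,
                                       variant_ids(sub)))
al <- derive_alphas(setNames(length(tags), rg$region_name[1]),
                    total_tags = length(all_tags))
cat(sprintf("correlated set: %d variants, %d tags -> alpha_a = %.2g; %d total tags -> alpha_b = %.2g\n",
            length(cset), length(tags), al$alpha_a[1], length(all_tags),
            al$alpha_b))

sw <- stepwise_select(sub, variant_ids(sub), ph$status, covars,
                      alpha_a = al$alpha_a[1], alpha_b = al$alpha_b,
                      correlated_ids = cset)
if (length(sw$selected)) {
  cat("stepwise selected:", paste(sw$selected, collapse = ", "), "\n")
  print(sw$final_model, digits = 3)
  # conditional analysis: is any other variant independent of the selected?
  cond <- do.call(rbind, lapply(setdiff(variant_ids(sub), sw$selected)[1:5],
                                function(v)
    conditional_test(sub, v, sw$selected, ph$status, covars)))
  utils::write.table(cond, file.path(out, "conditional.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  r2o <- variance_explained_by_others(sub, sw$selected[1],
                                      setdiff(variant_ids(sub),
                                              sw$selected[1]))
  cat(sprintf("dosage variance of %s explained by the rest of the region: %.2f\n",
              sw$selected[1], r2o))
} else {
  cat("no variant passed its threshold in the stepwise procedure\n")
}

plan <- list(region = rg$region_name[1], window = win,
             correlated_set = cset, tags = tags,
             alpha_a = unname(al$alpha_a[1]), alpha_b = al$alpha_b,
             selected = sw$selected,
             final_model = sw$final_model)
jsonlite::write_json(plan, file.path(out, "tagplan_stepwise.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     force = TRUE)
cat("wrote", out, "\n")
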