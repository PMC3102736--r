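#!/usr/bin/env Rscript
# Sample and variant quality control on the demonstration dataset: sample
# call rate < 95%, variant call rate < 95%, MAF < 1%, then identity-by-
# descent relatedness screening with the within-1-SD Z-vector rule and
# degree-based pruning. Writes the post-QC dataset and a QC report.

suppressMessages(library(admixfine))

dat <- "results/data"
out <- "results/qc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dm <- read_genotypes(file.path(dat, "genotypes.tsv"), format = "tsv")
ph <- read_phenotypes(file.path(dat, "phenotypes.tsv"))

sq <- filter_samples(dm, call_rate_min = 0.95)
vq <- filter_variants(sq$dosages, call_rate_min = 0.95, maf_min = 0.01)
dm <- vq$dosages
cat(sprintf("sample filter removed %d, variant filters removed %d (%s)\n",
            nrow(sq$report), nrow(vq$report),
            paste(sprintf("%s:%d", names(table(vq$report$reason)),
                          table(vq$report$reason)), collapse = ", ")))

# relatedness: screen the injected relatives' candidate pairs plus a random
# background sample of pairs (the all-pairs screen is quadratic)
truth <- jsonlite::read_json(file.path(dat, "truth.json"),
                             simplifyVector = TRUE)
ids <- sample_ids(dm)
set.seed(1)
bg <- t(replicate(200, sample(ids, 2)))
cand <- unique(rbind(data.frame(id1 = truth$relatives$id1,
                                id2 = truth$relatives$id2),
                     data.frame(id1 = bg[, 1], id2 = bg[, 2])))
cand <- cand[cand$id1 %in% ids & cand$id2 %in% ids, ]
# IBD wants (quasi-)independent markers: greedy LD prune at r2 < 0.2
typed_idx <- which(dm$variants$typed)
ldm <- ld_matrix(dm, variant_ids(dm)[typed_idx])
keep <- c()
for (v in variant_ids(dm)[typed_idx]) {
  if (all(is.na(ldm[v, keep])) || all(ldm[v, keep] < 0.2, na.rm = TRUE))
    keep <- c(keep, v)
}
cat(sprintf("LD-pruned to %d of %d typed markers for IBD\n",
            length(keep), length(typed_idx)))
scr <- relatedness_screen(subset_dosage(dm, variants = keep), cand)
rel <- scr[scr$label != "unrelated", ]
cat(sprintf("flagged %d related pairs (%s)\n", nrow(rel),
            paste(rel$label, collapse = ", ")))

removed <- prune_related(rel, seed = 1)
dm <- subset_dosage(dm, samples = setdiff(ids, removed))
# genotype-only samples (the remaining injected relatives carry no
# phenotype) leave the analysis dataset here
ph <- ph[ph$sample_id %in% sample_ids(dm) & !is.na(ph$status), ]
dm <- subset_dosage(dm, samples = ph$sample_id)
cat(sprintf("pruned %d samples; %d samples x %d variants remain\n",
            length(removed), nrow(dm$dosages), ncol(dm$dosages)))

write_dosage_tsv(dm, file.path(out, "genotypes_qc.tsv"))
write_phenotypes(ph, file.path(out, "phenotypes_qc.tsv"))
utils::write.table(scr, file.path(out, "ibd_pairs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(rbind(sq$report, vq$report,
                         data.frame(entity = removed, reason = "related",
                                    value = NA_real_)),
                   file.path(out, "qc_report.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
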