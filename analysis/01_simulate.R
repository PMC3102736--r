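#!/usr/bin/env Rscript
# Generates the demonstration dataset used by the downstream analysis
# scripts: an admixed case-control cohort (600 cases / 600 controls, 400
# variants in founder-haplotype LD blocks, ~20% population-1 admixture,
# Balding-Nichols divergence F = 0.15) with one planted causal variant,
# injected duplicate and full-sibling pairs, missing calls, and a block of
# imputed dosages. Everything is written as plain text under results/data/.

suppressMessages(library(admixfine))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_cases = 600, n_controls = 600,
  n_variants = 800, block_len_mean = 3,
  theta = 0.2, switch_rate = 6, fst = 0.15,
  causal = data.frame(variant_id = "v00400", log_or = log(1.6)),
  prevalence = 0.1, miss_rate = 0.02, imputed_frac = 0.25,
  relatives = data.frame(relationship = c("duplicate", "full-sibling"),
                         count = c(2L, 2L)),
  seed = 20260927L)

co <- simulate_case_control(cfg)

write_dosage_tsv(co$dosages, file.path(out, "genotypes.tsv"))
write_phenotypes(co$samples, file.path(out, "phenotypes.tsv"))
write_local_ancestry(co$local_ancestry, file.path(out, "local_ancestry.tsv"))

# the "index" marker plays the GWAS-reported role: the best LD proxy of
# the causal variant among the other typed markers
pos <- co$dosages$variants$pos[400]
near <- which(abs(co$dosages$variants$pos - pos) < 100000 &
                co$dosages$variants$typed &
                variant_ids(co$dosages) != "v00400")
r2 <- vapply(near, function(j)
  pairwise_r2(co$dosages$dosages[, j], co$dosages$dosages[, "v00400"]),
  numeric(1))
index_id <- variant_ids(co$dosages)[near[which.max(r2)]]
writeLines(c("region_name\tchrom\tstart\tend\tindex_variants",
             sprintf("demo_region\t1\t%d\t%d\t%s", pos - 250000,
                     pos + 250000, index_id)),
           file.path(out, "regions.tsv"))

truth <- list(causal = cfg$causal,
              relatives = co$truth$relatives,
              seed = cfg$seed,
              theta = cfg$theta, fst = cfg$fst)
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("simulated %d samples x %d variants (%d with injected relatives)\n",
            nrow(co$dosages$dosages), ncol(co$dosages$dosages),
            nrow(co$truth$relatives)))
cat(sprintf("planted causal variant v00400, per-allele OR 1.6; index marker %s (r2 = %.2f)\n", index_id, max(r2, na.rm = TRUE)))
cat("wrote", out, "\n")
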