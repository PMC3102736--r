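#!/usr/bin/env Rscript
# Cumulative risk modeling: the unweighted risk-allele count over the
# selected variants (2xRAF fill for missing calls), per-allele and
# control-quartile ORs with family-history stratification, the case-only
# severity test, the independence check of per-variant betas, and the
# closed-form fraction of familial relative risk explained by the score.

suppressMessages(library(admixfine))

out <- "results/riskscore"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dm <- read_genotypes("results/qc/genotypes_qc.tsv", format = "tsv")
ph <- read_phenotypes("results/qc/phenotypes_qc.tsv")
ph <- ph[match(sample_ids(dm), ph$sample_id), ]
ev <- utils::read.table("results/ancestry/eigenvectors.tsv", header = TRUE,
                        sep = "\t")
ev <- ev[match(sample_ids(dm), ev$sample_id), ]
covars <- cbind(data.frame(age = ph$age),
                as.data.frame(stats::model.matrix(~study, ph)[, -1]),
                ev[, -1])

fm <- jsonlite::read_json("results/finemap/tagplan_stepwise.json",
                          simplifyVector = TRUE)
fm$selected <- as.character(unlist(fm$selected))
# score variants: the stepwise-selected signal(s) plus the strongest
# mutually independent (r2 < 0.2) markers elsewhere on the map
scan <- utils::read.table("results/assoc/association.tsv", header = TRUE,
                          sep = "\t")
scan <- scan[!is.na(scan$p_trend), ]
sel <- fm$selected
for (v in scan$variant_id) {
  if (length(sel) >= 10) break
  if (v %in% sel) next
  r2 <- vapply(sel, function(s2)
    pairwise_r2(dm$dosages[, v], dm$dosages[, s2]), numeric(1))
  if (all(is.na(r2)) || all(r2 < 0.2, na.rm = TRUE)) sel <- c(sel, v)
}
# orient every score variant to its risk (risk-increasing) allele
for (v in sel) {
  b <- scan$beta[scan$variant_id == v]
  if (length(b) == 1 && !is.na(b) && b < 0) {
    dm$dosages[, v] <- 2 - dm$dosages[, v]
    j <- match(v, dm$variants$variant_id)
    oa <- dm$variants$other_allele[j]
    dm$variants$other_allele[j] <- dm$variants$risk_allele[j]
    dm$variants$risk_allele[j] <- oa
  }
}
raf <- allele_freq(dm, sample_ids(dm)[ph$status == 0])[sel]
sv <- data.frame(variant_id = sel, raf = unname(raf))

counts <- build_score(dm, sv)
utils::write.table(data.frame(sample_id = names(counts), count = counts),
                   file.path(out, "score.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)

pa <- per_allele_or(counts, ph$status, covars)
cat(sprintf("per-allele OR over %d variants: %.2f (%.2f-%.2f), p = %.2g\n",
            nrow(sv), pa$or, pa$ci_lo, pa$ci_hi, pa$p))

qa <- quartile_analysis(counts, ph$status, covars,
                        family_history = ph$family_history)
cat(sprintf("control quartile cutpoints: %s\n",
            paste(round(qa$cutpoints, 1), collapse = ", ")))
print(qa$overall, digits = 3)

sev <- severity_case_only_test(counts[ph$status == 1],
                               ph$severity[ph$status == 1])
cat(sprintf("case-only severity test: OR %.2f (%.2f-%.2f), p = %.2g\n",
            sev$or, sev$ci_lo, sev$ci_hi, sev$p))

chk <- independence_check(dm, sv$variant_id, ph$status, covars)
cat(sprintf("independence check: max |joint - single| = %.2f single-model SEs\n",
            chk$max_abs_rel_diff))

fr_obs <- familial_rr_estimate(ph$status, ph$family_history, covars)
cat(sprintf("familial RR from reported family history: %.2f (%.2f-%.2f)\n",
            fr_obs$or, fr_obs$ci_lo, fr_obs$ci_hi))

fam <- familial_risk_explained(m0 = mean(counts[ph$status == 0]),
                               m1 = mean(counts[ph$status == 1]),
                               lambda = pa$or, rho_obs = fr_obs$or)
print(fam)

jsonlite::write_json(
  list(variants = sv, per_allele = pa, cutpoints = qa$cutpoints,
       quartiles = qa$overall, by_family_history = qa$by_family_history,
       severity = sev, independence_max_rel_diff = chk$max_abs_rel_diff,
       familial_rr = fr_obs, familial_risk = unclass(fam)),
  file.path(out, "score_model.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE, force = TRUE)
cat("wrote", out, "\n")
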