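#' Pipeline configuration
#'
#' Bundles input paths and the analysis thresholds. All thresholds are
#' validated on construction and echoed into every output's metadata.
#'
#' @param genotypes path to a dosage TSV (or VCF with `format = "vcf"`)
#' @param phenotypes path to the phenotype TSV
#' @param local_ancestry optional path to the local-ancestry TSV
#' @param regions optional path to the region configuration TSV
#' @param format genotype file format
#' @param out_dir output directory
#' @param call_rate_min,maf_min,rsq_min,r2_index,r2_tag,outlier_sd,alpha_a,alpha_b,multi_retain_p
#'   analysis thresholds (defaults: 0.95, 0.01, 0.3, 0.2, 0.8, 4, 0.004,
#'   5.6e-6, 0.001)
#' @param n_eigenvectors eigenvectors used as covariates in single-variant
#'   models (default 10)
#' @param n_eigenvectors_stepwise eigenvectors used in stepwise models
#'   (default 1; the two counts are deliberately independent settings)
#' @param score_variants optional data.frame (`variant_id`, `raf`) for the
#'   risk score; when NULL the stepwise-selected variants are used with
#'   control RAFs
#' @param seed seed for the tie-breaking RNG in relatedness pruning
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(genotypes, phenotypes, local_ancestry = NULL,
                            regions = NULL, format = "tsv",
                            out_dir = "admixfine_out",
                            call_rate_min = 0.95, maf_min = 0.01,
                            rsq_min = 0.3, r2_index = 0.2, r2_tag = 0.8,
                            outlier_sd = 4, alpha_a = 0.004,
                            alpha_b = 5.6e-6, multi_retain_p = 0.001,
                            n_eigenvectors = 10,
                            n_eigenvectors_stepwise = 1,
                            score_variants = NULL, seed = 1L) {
  frac <- function(x, nm) if (!is.numeric(x) || x < 0 || x > 1)
    stop(nm, " must be in [0,1]", call. = FALSE)
  frac(call_rate_min, "call_rate_min"); frac(maf_min, "maf_min")
  frac(rsq_min, "rsq_min"); frac(r2_index, "r2_index")
  frac(r2_tag, "r2_tag"); frac(alpha_a, "alpha_a"); frac(alpha_b, "alpha_b")
  frac(multi_retain_p, "multi_retain_p")
  if (outlier_sd <= 0) stop("outlier_sd must be positive")
  cfg <- as.list(environment())
  cfg$frac <- NULL
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: sample/variant QC (call rate, MAF, relatedness
#' pruning), global ancestry (PCA with outlier exclusion), per-region
#' association scans with local-ancestry adjustment, tag-based threshold
#' derivation and stepwise fine-mapping, risk score with quartile and
#' familial-risk analyses. Per-stage TSV/JSON outputs, a structured log,
#' and a summary JSON (with config echo and seed) are written to
#' `config$out_dir`. A stage failure aborts with a stage-labelled message;
#' outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) the summary list
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "pipeline.log")
  cat("", file = logf)
  logmsg <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, paste0(...))
    cat(line, "\n", file = logf, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  summary <- list(config = unclass(config)[!vapply(unclass(config),
                                                   is.data.frame, TRUE)],
                  seed = config$seed)

  dm <- stage("read", read_genotypes(config$genotypes, config$format))
  ph <- stage("read", read_phenotypes(config$phenotypes))
  ph <- ph[match(sample_ids(dm), ph$sample_id), ]
  logmsg("read", nrow(dm$dosages), " samples, ", ncol(dm$dosages),
         " variants")

  # --- QC ---
  sq <- stage("qc", filter_samples(dm, config$call_rate_min))
  vq <- stage("qc", filter_variants(sq$dosages, config$call_rate_min,
                                    config$maf_min))
  dm <- vq$dosages
  qc_rep <- rbind(sq$report, vq$report)
  rel <- stage("qc", {
    if (nrow(dm$dosages) <= 200) {
      scr <- relatedness_screen(dm)
      scr[scr$label != "unrelated", , drop = FALSE]
    } else NULL       # all-pairs screen reserved for modest sample counts
  })
  if (!is.null(rel) && nrow(rel)) {
    rm_ids <- prune_related(rel, seed = config$seed)
    qc_rep <- rbind(qc_rep, .qc_report(rm_ids, rep("related", length(rm_ids)),
                                       rep(NA_real_, length(rm_ids))))
    dm <- subset_dosage(dm, samples = setdiff(sample_ids(dm), rm_ids))
    utils::write.table(rel, file.path(config$out_dir, "ibd_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ph <- ph[match(sample_ids(dm), ph$sample_id), ]
  logmsg("qc", nrow(qc_rep), " removals; ", nrow(dm$dosages),
         " samples x ", ncol(dm$dosages), " variants remain")

  # --- ancestry ---
  k <- min(config$n_eigenvectors, nrow(dm$dosages) - 1)
  ga <- stage("ancestry", compute_pca(dm, k = k))
  outl <- flag_ancestry_outliers(ga, n_sd = config$outlier_sd)
  if (length(outl)) {
    qc_rep <- rbind(qc_rep, .qc_report(outl, rep("ancestry_outlier",
                                                 length(outl)),
                                       rep(NA_real_, length(outl))))
    dm <- subset_dosage(dm, samples = setdiff(sample_ids(dm), outl))
    ph <- ph[match(sample_ids(dm), ph$sample_id), ]
    ga <- compute_pca(dm, k = min(k, nrow(dm$dosages) - 1))
  }
  ev <- as.data.frame(ga$vectors)
  utils::write.table(cbind(sample_id = rownames(ga$vectors), ev),
                     file.path(config$out_dir, "eigenvectors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qc_rep, file.path(config$out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logmsg("ancestry", length(outl), " outliers removed; k=", ga$k)

  la <- NULL
  if (!is.null(config$local_ancestry)) {
    la <- stage("ancestry", read_local_ancestry(config$local_ancestry))
    la <- la[sample_ids(dm), , drop = FALSE]
  }

  covars <- cbind(age = ph$age,
                  as.data.frame(stats::model.matrix(~study, ph)[, -1,
                                                                drop = FALSE]),
                  ev)
  status <- ph$status

  # --- association + fine-mapping per region ---
  regions <- if (!is.null(config$regions)) read_regions(config$regions)
             else NULL
  assoc_all <- list(); stepwise_all <- list()
  if (!is.null(regions)) {
    for (r in seq_len(nrow(regions))) {
      rg <- regions[r, ]
      idx_ids <- rg$index_variants[[1]]
      stage(paste0("region:", rg$region_name), {
        pos_idx <- dm$variants$pos[match(idx_ids, variant_ids(dm))]
        win <- build_window(pos_idx)
        cv <- covars
        if (!is.null(la)) {
          cv$local_ancestry <- summarize_local_ancestry(
            la, dm$variants, list(region_name = rg$region_name,
                                  start = win$start[1],
                                  end = max(win$end)))
        }
        inside <- dm$variants$pos >= min(win$start) &
          dm$variants$pos <= max(win$end)
        sub <- subset_dosage(dm, variants = which(inside))
        sc <- assoc_scan(sub, status, cv, rsq_min = config$rsq_min)
        sc$region <- rg$region_name
        assoc_all[[rg$region_name]] <- sc
        cs <- correlated_set(sub, idx_ids, window = win,
                             r2_index = config$r2_index)
        ldm <- ld_matrix(sub)
        tags <- greedy_tags(cs, ldm, r2_tag = config$r2_tag,
                            pos = stats::setNames(sub$variants$pos,
                                                  variant_ids(sub)))
        cv_step <- cv[, c("age", grep("^study", names(cv), value = TRUE),
                          "EV1",
                          if (!is.null(la)) "local_ancestry"),
                      drop = FALSE]
        sw <- stepwise_select(sub, variant_ids(sub), status, cv_step,
                              alpha_a = config$alpha_a,
                              alpha_b = config$alpha_b,
                              correlated_ids = cs)
        stepwise_all[[rg$region_name]] <- list(
          region = rg$region_name, correlated_set = cs, tags = tags,
          selected = sw$selected,
          final_model = sw$final_model)
      })
    }
    assoc_tab <- do.call(rbind, assoc_all)
    utils::write.table(assoc_tab,
                       file.path(config$out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(stepwise_all,
                         file.path(config$out_dir, "stepwise.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    logmsg("finemap", length(stepwise_all), " regions analysed")
  }

  # --- risk score ---
  sv <- config$score_variants
  if (is.null(sv) && length(stepwise_all)) {
    sel <- unique(unlist(lapply(stepwise_all, `[[`, "selected")))
    if (length(sel))
      sv <- data.frame(variant_id = sel,
                       raf = allele_freq(dm, sample_ids(dm)[status == 0])[sel])
  }
  score_out <- NULL
  if (!is.null(sv) && nrow(sv) > 0) {
    stage("riskscore", {
      counts <- build_score(dm, sv)
      pa <- per_allele_or(counts, status, covars)
      qa <- quartile_analysis(counts, status, covars,
                              family_history = ph$family_history)
      fr <- tryCatch(
        familial_rr_estimate(status, ph$family_history, covars),
        error = function(e) NULL)
      fam <- NULL
      if (!is.null(fr) && fr$or > 1)
        fam <- familial_risk_explained(
          m0 = mean(counts[status == 0]), m1 = mean(counts[status == 1]),
          lambda = pa$or, rho_obs = fr$or)
      score_out <- list(variants = sv, per_allele = pa,
                         cutpoints = qa$cutpoints, quartiles = qa$overall,
                         familial_rr = fr,
                         familial_risk = if (!is.null(fam))
                           unclass(fam) else NULL)
      utils::write.table(data.frame(sample_id = sample_ids(dm),
                                    count = counts),
                         file.path(config$out_dir, "score.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(score_out,
                           file.path(config$out_dir, "score_model.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    })
    logmsg("riskscore", "score built on ", nrow(sv), " variants")
  }

  summary$n_samples <- nrow(dm$dosages)
  summary$n_variants <- ncol(dm$dosages)
  summary$qc_removals <- nrow(qc_rep)
  summary$regions <- names(stepwise_all)
  summary$selected <- unlist(lapply(stepwise_all, `[[`, "selected"),
                             use.names = FALSE)
  summary$score <- if (!is.null(score_out))
    list(or_per_allele = score_out$per_allele$or,
         fraction_familial_pct = if (!is.null(score_out$familial_risk))
           score_out$familial_risk$fraction_pct else NULL)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
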