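# Canned simulation scenarios exercising the analyses end-to-end. These fix
# the study conditions (sample sizes, effect sizes, LD geometry) once; tests
# and the reproduction script consume them unchanged.

#' Two-locus founder set with a target haplotype correlation
#'
#' Builds a founder block in which a designated "index" and "causal" variant
#' pair has haplotype correlation `r` (so LD r-squared `r^2`), with both
#' allele frequencies `p`. Four founder haplotypes over the block carry the
#' four index/causal allele combinations at the haplotype frequencies implied
#' by `D = r * p * (1 - p)`; any extra variants in the block are assigned
#' alleles matching the index variant (perfect proxies of the index).
#'
#' @param r target haplotype correlation between index and causal alleles
#' @param p allele frequency for both loci
#' @param n_extra extra index-proxy variants in the block
#' @return list with `founders` (matrix), `weights`, and column order
#'   `c(index, causal, extras)`
#' @keywords internal
.two_locus_founders <- function(r, p, n_extra = 0L) {
  D <- r * p * (1 - p)
  h11 <- p * p + D
  h10 <- p * (1 - p) - D
  h01 <- h10
  h00 <- (1 - p)^2 + D
  w <- c(h11, h10, h01, h00)
  if (any(w < -1e-12)) stop("infeasible (r, p) combination")
  w <- pmax(w, 0); w <- w / sum(w)
  fo <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  if (n_extra > 0L)
    fo <- cbind(fo, matrix(rep(fo[, 1L], n_extra), nrow = 4L))
  list(founders = fo, weights = w)
}

#' Ancestral panels with ancestry-dependent index/causal LD
#'
#' The central fine-mapping phenomenon: an index variant strongly correlated
#' with the causal allele in population 1 (European-like haplotypes) but
#' weakly in population 2 (African-like), embedded in a region of background
#' variants. Population-level frequencies of index and causal are `p` in
#' both panels; background variants are independent single-variant blocks.
#'
#' @param r2_pop1 index-causal r-squared in panel 1 (default 0.9)
#' @param r2_pop2 index-causal r-squared in panel 2 (default 0.05)
#' @param p allele frequency of index and causal variants
#' @param n_background independent background variants
#' @param pool_size pool haplotypes per panel
#' @return list with `panels` (pop1/pop2), `index_id`, `causal_id`
#' @export
scenario_ld_asymmetry_panels <- function(r2_pop1 = 0.9, r2_pop2 = 0.05,
                                         p = 0.3, n_background = 28,
                                         pool_size = 5000) {
  m <- 2L + n_background
  ids <- sprintf("v%05d", seq_len(m))
  pos <- seq(100000L, by = 10000L, length.out = m)
  variants <- data.frame(variant_id = ids, chrom = "1", pos = pos,
                         stringsAsFactors = FALSE)
  # index and causal occupy the middle of the region
  mid <- floor(m / 2)
  ord <- c(mid, mid + 1L)          # index, causal positions in the map
  blocks <- c(list(ord), as.list(setdiff(seq_len(m), ord)))
  bg_freq <- stats::runif(n_background, 0.1, 0.9)
  build <- function(r2) {
    fw <- .two_locus_founders(sqrt(r2), p)
    founders <- c(list(fw$founders),
                  lapply(bg_freq, function(q) matrix(c(0L, 1L), nrow = 2)))
    weights <- c(list(fw$weights),
                 lapply(bg_freq, function(q) c(1 - q, q)))
    list(founders = founders, weights = weights)
  }
  b1 <- build(r2_pop1); b2 <- build(r2_pop2)
  panels <- list(
    pop1 = make_ancestral_panel("pop1", variants, b1$founders, b1$weights,
                                blocks, pool_size),
    pop2 = make_ancestral_panel("pop2", variants, b2$founders, b2$weights,
                                blocks, pool_size))
  list(panels = panels, index_id = ids[ord[1]], causal_id = ids[ord[2]])
}

#' Null cohort scenario (calibration)
#'
#' No causal effects, no frequency divergence between the ancestral panels
#' (`fst = 0`), independent variants: downstream association p-values should
#' be uniform.
#'
#' @param n_cases,n_controls sample sizes
#' @param n_variants number of null variants
#' @param seed RNG seed
#' @return a [simulate_case_control()] result
#' @export
scenario_null_cohort <- function(n_cases = 1000, n_controls = 1000,
                                 n_variants = 1000, seed = 1L) {
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    n_variants = n_variants, block_len_mean = 1,
                    fst = 0, causal = NULL, miss_rate = 0,
                    imputed_frac = 0, prevalence = 0.1, seed = seed)
  simulate_case_control(cfg)
}

#' Fine-mapping recovery scenario
#'
#' One replicate of the ancestry-asymmetric LD region: the causal variant
#' carries a per-allele odds ratio `or`, the cohort is admixed with
#' population-1 proportion `theta` (default 0.2, i.e. an 80:20
#' African:European mixture), and stepwise selection over the region is
#' expected to prefer the causal variant (or a better admixed-sample proxy
#' of it) over the index variant.
#'
#' @param panels output of [scenario_ld_asymmetry_panels()]
#' @param or per-allele odds ratio at the causal variant
#' @param n_cases,n_controls sample sizes
#' @param theta population-1 admixture proportion
#' @return a [simulate_case_control()] result
#' @export
scenario_finemap_cohort <- function(panels, or = 1.3,
                                    n_cases = 3000, n_controls = 3000,
                                    theta = 0.2) {
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    n_variants = nrow(panels$panels$pop1$variants),
                    theta = theta, fst = 0,
                    switch_rate = 0.05,   # a sub-megabase region: switches rare
                    causal = data.frame(variant_id = panels$causal_id,
                                        log_or = log(or)),
                    miss_rate = 0, imputed_frac = 0, prevalence = 0.1)
  simulate_case_control(cfg, panels = panels$panels)
}

#' Risk-score recovery scenario
#'
#' Simulates unlinked score variants whose summed risk-allele count carries
#' a true per-allele log odds ratio `log(or)` for case status, at the scale
#' of the study being emulated (27 variants, ~3,400 cases / ~3,300
#' controls). Genotypes are independent binomials at the given risk-allele
#' frequencies; ascertainment is case-control.
#'
#' @param or true per-allele odds ratio of the aggregate count
#' @param n_cases,n_controls sample sizes
#' @param n_variants number of score variants
#' @param raf_range risk-allele frequency range (uniform)
#' @param prevalence baseline prevalence for the logistic model
#' @return list with `counts` (per-sample risk-allele count), `status`,
#'   `genotypes` (samples x variants), `raf` (true frequencies)
#' @export
scenario_score_cohort <- function(or = 1.17, n_cases = 3400,
                                  n_controls = 3300, n_variants = 27,
                                  raf_range = c(0.2, 0.8),
                                  prevalence = 0.1) {
  raf <- stats::runif(n_variants, raf_range[1], raf_range[2])
  need_ca <- n_cases; need_co <- n_controls
  gs <- list(); st <- list()
  got_ca <- 0L; got_co <- 0L
  beta <- log(or)
  attempts <- 0L
  while (got_ca < need_ca || got_co < need_co) {
    attempts <- attempts + 1L
    if (attempts > 50L) stop("ascertainment failed")
    nb <- ceiling(1.5 * max(need_ca / prevalence, need_co))
    g <- sapply(raf, function(p) stats::rbinom(nb, 2L, p))
    cnt <- rowSums(g)
    eta <- beta * cnt
    icpt <- .solve_intercept(eta, prevalence)
    status <- stats::rbinom(nb, 1L, stats::plogis(icpt + eta))
    ca <- which(status == 1L)[seq_len(min(need_ca - got_ca,
                                          sum(status == 1L)))]
    co <- which(status == 0L)[seq_len(min(need_co - got_co,
                                          sum(status == 0L)))]
    keep <- c(ca, co)
    gs[[length(gs) + 1L]] <- g[keep, , drop = FALSE]
    st[[length(st) + 1L]] <- status[keep]
    got_ca <- got_ca + length(ca); got_co <- got_co + length(co)
  }
  g <- do.call(rbind, gs)
  colnames(g) <- sprintf("rs%03d", seq_len(n_variants))
  list(counts = rowSums(g), status = unlist(st), genotypes = g, raf = raf)
}

#' Null-calibration experiment
#'
#' Simulates a null cohort (no causal effects, no panel divergence), runs
#' the covariate-adjusted trend test at every variant, and summarizes the
#' type-I error at `alpha` plus the study-heterogeneity false-positive
#' count over the first `n_het` variants.
#'
#' @param n_cases,n_controls,n_variants cohort dimensions
#' @param alpha nominal level examined (default 0.05)
#' @param n_het number of variants taken into the heterogeneity screen
#'   (default 76)
#' @param seed RNG seed
#' @return list with `type1_rate`, `n_tested`, `ks_p` (uniformity of the
#'   p-values), `het_sig_count`, `n_het`, and the scan itself
#' @export
experiment_null_calibration <- function(n_cases = 1000, n_controls = 1000,
                                        n_variants = 1000, alpha = 0.05,
                                        n_het = 76, seed = 1L) {
  co <- scenario_null_cohort(n_cases, n_controls, n_variants, seed = seed)
  ph <- co$samples
  ga <- compute_pca(co$dosages, k = 2)
  covars <- cbind(data.frame(age = ph$age),
                  as.data.frame(stats::model.matrix(~study, ph)[, -1,
                                                                drop = FALSE]),
                  as.data.frame(ga$vectors),
                  la = rowMeans(co$local_ancestry))
  scan <- assoc_scan(co$dosages, ph$status, covars)
  p <- scan$p_trend[!is.na(scan$p_trend)]
  het_ids <- scan$variant_id[!is.na(scan$p_trend)][seq_len(n_het)]
  het_p <- vapply(het_ids, function(v) {
    res <- tryCatch(suppressWarnings(
      heterogeneity_by_study(co$dosages$dosages[, v], ph$status,
                             covars, ph$study, variant_id = v)),
      error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$p_het
  }, numeric(1))
  list(type1_rate = mean(p < alpha), n_tested = length(p),
       ks_p = suppressWarnings(stats::ks.test(p, "punif")$p.value),
       het_sig_count = sum(het_p < alpha, na.rm = TRUE),
       n_het = sum(!is.na(het_p)), scan = scan)
}

#' Fine-mapping proxy-recovery experiment
#'
#' Repeats the ancestry-asymmetric LD scenario: in each replicate an
#' admixed case-control cohort is simulated around a causal variant whose
#' index marker tags it well only in the minority ancestry, and stepwise
#' selection is run over the region. A replicate counts as a success when
#' the first selected variant is the causal variant itself or a proxy with
#' higher admixed-sample r-squared to it than the index marker has.
#'
#' @param n_reps replicates (default 100)
#' @param or per-allele odds ratio at the causal variant
#' @param n_cases,n_controls per-replicate sample sizes
#' @param alpha_a stepwise threshold for the (index-correlated) candidates
#' @param seed RNG seed
#' @return list with `success_rate`, `n_selected_first` (table of first
#'   picks), `n_reps`
#' @export
experiment_finemap_recovery <- function(n_reps = 100, or = 1.3,
                                        n_cases = 3000, n_controls = 3000,
                                        alpha_a = 0.004, seed = 1L) {
  set.seed(seed)
  sc <- scenario_ld_asymmetry_panels()
  wins <- 0L
  firsts <- character(0)
  for (r in seq_len(n_reps)) {
    co <- scenario_finemap_cohort(sc, or = or, n_cases = n_cases,
                                  n_controls = n_controls)
    cv <- data.frame(age = co$samples$age)
    sw <- stepwise_select(co$dosages, variant_ids(co$dosages),
                          co$samples$status, cv,
                          alpha_a = alpha_a, alpha_b = alpha_a)
    first <- if (length(sw$selected)) sw$selected[1] else NA_character_
    firsts <- c(firsts, first)
    if (!is.na(first)) {
      d <- co$dosages$dosages
      r2_first <- pairwise_r2(d[, first], d[, sc$causal_id])
      r2_index <- pairwise_r2(d[, sc$index_id], d[, sc$causal_id])
      if (first == sc$causal_id ||
          (!is.na(r2_first) && r2_first > r2_index)) wins <- wins + 1L
    }
  }
  list(success_rate = wins / n_reps, n_selected_first = table(firsts),
       n_reps = n_reps)
}

#' Risk-score recovery experiment
#'
#' Repeats the unlinked-score scenario: per replicate, risk-allele counts
#' with a true per-allele odds ratio `or` are simulated at the emulated
#' study scale, the per-allele OR is re-estimated, and the control-quartile
#' ORs are checked for monotonicity.
#'
#' @param n_reps replicates (default 100)
#' @param or true per-allele odds ratio (default 1.17)
#' @param n_cases,n_controls per-replicate sample sizes
#' @param seed RNG seed
#' @return list with `ci_coverage` (fraction of replicates whose 95% CI
#'   covers `or`), `monotone_rate` (fraction with non-decreasing quartile
#'   ORs), `mean_or`, `n_reps`
#' @export
experiment_score_recovery <- function(n_reps = 100, or = 1.17,
                                      n_cases = 3400, n_controls = 3300,
                                      seed = 1L) {
  set.seed(seed)
  cover <- 0L; monotone <- 0L
  ors <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- scenario_score_cohort(or = or, n_cases = n_cases,
                                 n_controls = n_controls)
    fit <- per_allele_or(sim$counts, sim$status)
    ors[r] <- fit$or
    if (fit$ci_lo <= or && or <= fit$ci_hi) cover <- cover + 1L
    qa <- quartile_analysis(sim$counts, sim$status)
    if (all(diff(qa$overall$or) >= 0)) monotone <- monotone + 1L
  }
  list(ci_coverage = cover / n_reps, monotone_rate = monotone / n_reps,
       mean_or = mean(ors), n_reps = n_reps)
}
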