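#' Simulation configuration
#'
#' Collects every tunable of the synthetic admixed-cohort generator. Defaults
#' emulate a large African American prostate-cancer case-control study: two
#' ancestral populations ("pop1", European-like; "pop2", African-like) with
#' Balding-Nichols allele-frequency divergence, founder-haplotype LD blocks,
#' ~20% population-1 admixture, case-control ascertainment from a logistic
#' disease model, and imputed dosages with a per-variant quality (Rsq).
#'
#' @param n_cases,n_controls target case/control counts after ascertainment.
#' @param theta admixture proportion of population 1 in \[0,1\] (expected
#'   fraction of chromosomes drawn from the population-1 pool).
#' @param switch_rate expected number of ancestry switches per haplotype
#'   along the simulated segment (Poisson; a morgan-equivalent coordinate
#'   over the variant index).
#' @param n_variants number of variants.
#' @param block_len_mean mean LD-block length in variants (geometric).
#' @param founders_range integer range for founder haplotypes per block.
#' @param fst Balding-Nichols divergence F in \[0,1).
#' @param anc_freq_range range of ancestral allele frequencies (uniform).
#' @param pos_spacing_mean mean inter-variant spacing in bp (exponential).
#' @param causal data.frame with `variant_id` and `log_or` (per-allele), or
#'   NULL for a null model.
#' @param prevalence baseline disease probability at covariate/genotype means.
#' @param age_mean,age_sd,age_range age distribution (truncated normal).
#' @param age_beta log-OR per 10 years of age.
#' @param studies character vector of study labels (uniform assignment).
#' @param study_effects per-study log-OR offsets (first study is reference).
#' @param miss_rate missing-call rate for typed variants.
#' @param imputed_frac fraction of variants emitted as imputed dosages.
#' @param rsq_range target imputation Rsq drawn uniformly from this range.
#' @param fh_base baseline family-history probability in controls.
#' @param fh_status_logor log-OR linking case status to family history
#'   (defaults to log(1.55), the familial relative risk being emulated).
#' @param fh_score_beta log-OR per risk allele linking the causal allele
#'   count to family history (0 = none).
#' @param sev_frac marginal fraction of cases labelled advanced.
#' @param sev_score_beta log-OR per risk allele for advanced vs non-advanced
#'   disease among cases.
#' @param relatives data.frame with `relationship`
#'   (duplicate/parent-offspring/full-sibling/half-sibling) and `count`,
#'   or NULL.
#' @param meiosis_crossovers expected crossovers per transmitted haplotype
#'   when constructing relatives.
#' @param pool_size haplotypes per ancestral panel pool.
#' @param max_attempts maximum ascertainment batches before giving up.
#' @param seed integer seed recorded in output metadata; NULL leaves the RNG
#'   state untouched.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 3425, n_controls = 3290,
                       theta = 0.2, switch_rate = 6,
                       n_variants = 1000, block_len_mean = 5,
                       founders_range = c(2L, 8L),
                       fst = 0.15, anc_freq_range = c(0.05, 0.95),
                       pos_spacing_mean = 3000,
                       causal = NULL, prevalence = 0.1,
                       age_mean = 65, age_sd = 7, age_range = c(45, 80),
                       age_beta = 0,
                       studies = paste0("study", 1:4), study_effects = NULL,
                       miss_rate = 0.01, imputed_frac = 0.3,
                       rsq_range = c(0.5, 0.99),
                       fh_base = 0.1, fh_status_logor = log(1.55),
                       fh_score_beta = 0,
                       sev_frac = 0.36, sev_score_beta = 0,
                       relatives = NULL, meiosis_crossovers = 3,
                       pool_size = 5000, max_attempts = 50, seed = NULL) {
  chk01 <- function(x, nm, open_hi = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && x >= 0 &&
      (if (open_hi) x < 1 else x <= 1)
    if (!ok) stop(nm, " must be in [0,1", if (open_hi) ")" else "]",
                  call. = FALSE)
  }
  if (n_variants < 1) stop("n_variants must be >= 1")
  chk01(theta, "theta"); chk01(fst, "fst", open_hi = TRUE)
  chk01(miss_rate, "miss_rate"); chk01(imputed_frac, "imputed_frac")
  chk01(prevalence, "prevalence"); chk01(fh_base, "fh_base")
  chk01(sev_frac, "sev_frac")
  if (any(rsq_range <= 0) || any(rsq_range > 1) ||
      rsq_range[1] > rsq_range[2])
    stop("rsq_range must be an increasing range within (0,1]")
  if (!is.null(causal)) {
    stopifnot(is.data.frame(causal),
              all(c("variant_id", "log_or") %in% names(causal)))
  }
  if (is.null(study_effects)) study_effects <- rep(0, length(studies))
  if (length(study_effects) != length(studies))
    stop("study_effects must match studies in length")
  if (!is.null(relatives)) {
    stopifnot(is.data.frame(relatives),
              all(c("relationship", "count") %in% names(relatives)))
    bad <- setdiff(relatives$relationship,
                   c("duplicate", "parent-offspring", "full-sibling",
                     "half-sibling"))
    if (length(bad)) stop("unknown relationship label(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(
    n_cases = n_cases, n_controls = n_controls, theta = theta,
    switch_rate = switch_rate, n_variants = as.integer(n_variants),
    block_len_mean = block_len_mean,
    founders_range = as.integer(founders_range), fst = fst,
    anc_freq_range = anc_freq_range, pos_spacing_mean = pos_spacing_mean,
    causal = causal, prevalence = prevalence, age_mean = age_mean,
    age_sd = age_sd, age_range = age_range, age_beta = age_beta,
    studies = studies, study_effects = study_effects,
    miss_rate = miss_rate, imputed_frac = imputed_frac,
    rsq_range = rsq_range, fh_base = fh_base,
    fh_status_logor = fh_status_logor, fh_score_beta = fh_score_beta,
    sev_frac = sev_frac, sev_score_beta = sev_score_beta,
    relatives = relatives, meiosis_crossovers = meiosis_crossovers,
    pool_size = as.integer(pool_size), max_attempts = max_attempts,
    seed = seed), class = "sim_config")
}

#' Construct an ancestral haplotype panel from explicit founders
#'
#' Low-level constructor used both by [simulate_ancestral_panels()] and by
#' scenario builders that need exact control of within-block LD (e.g. an
#' index/causal pair whose correlation differs between ancestries).
#'
#' @param pop population label.
#' @param variants data.frame with `variant_id`, `chrom`, `pos`.
#' @param founders list, one element per block: binary matrix of founder
#'   haplotypes (founders x block variants).
#' @param weights list of founder sampling probabilities per block
#'   (each summing to 1).
#' @param blocks list of integer vectors partitioning `seq_len(nrow(variants))`.
#' @param pool_size number of pool haplotypes to sample.
#' @return object of class `ancestral_panel` with fields `pop`, `variants`,
#'   `freq` (declared per-variant frequency, the founder-weighted allele
#'   mean), `haps` (pool, haplotypes x variants), `blocks`.
#' @export
make_ancestral_panel <- function(pop, variants, founders, weights, blocks,
                                 pool_size = 5000) {
  m <- nrow(variants)
  stopifnot(length(founders) == length(blocks),
            length(weights) == length(blocks))
  if (!identical(as.integer(sort(unlist(blocks))), seq_len(m)))
    stop("blocks must partition the variant index")
  haps <- matrix(0L, nrow = pool_size, ncol = m)
  freq <- numeric(m)
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    fo <- founders[[b]]
    w <- weights[[b]]
    stopifnot(ncol(fo) == length(idx), nrow(fo) == length(w),
              abs(sum(w) - 1) < 1e-8)
    pick <- sample.int(nrow(fo), pool_size, replace = TRUE, prob = w)
    haps[, idx] <- fo[pick, , drop = FALSE]
    freq[idx] <- as.numeric(crossprod(w, fo))
  }
  colnames(haps) <- variants$variant_id
  structure(list(pop = pop, variants = variants, freq = freq, haps = haps,
                 blocks = blocks), class = "ancestral_panel")
}

#' @export
print.ancestral_panel <- function(x, ...) {
  cat(sprintf("<ancestral_panel> pop=%s, %d variants, %d blocks, pool=%d\n",
              x$pop, ncol(x$haps), length(x$blocks), nrow(x$haps)))
  invisible(x)
}

# Pick the founder subset whose total weight is closest to the target
# frequency; exhaustive over 2^K subsets (K <= 8).
.founder_alleles_for_freq <- function(weights, p) {
  k <- length(weights)
  best <- NULL
  best_err <- Inf
  for (s in 0:(2^k - 1L)) {
    sel <- as.logical(bitwAnd(s, 2^(0:(k - 1L))))
    err <- abs(sum(weights[sel]) - p)
    if (err < best_err) {
      best_err <- err
      best <- sel
    }
  }
  as.integer(best)
}

#' Simulate a pair of divergent ancestral panels
#'
#' Shared variant list and block structure; per-population allele frequencies
#' drawn from a Balding-Nichols model around shared ancestral frequencies
#' (variance `fst * p * (1 - p)`). Within a block, haplotypes are composed
#' from a small founder set (high within-block LD); blocks are independent.
#' Single-variant blocks use two founders with weights `(1 - p, p)`, so the
#' declared frequency is exact.
#'
#' @param config a [sim_config()]
#' @return list of two `ancestral_panel` objects (`pop1`, `pop2`)
#' @export
simulate_ancestral_panels <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_variants
  if (m < 1) stop("empty variant list")
  ids <- sprintf("v%05d", seq_len(m))
  pos <- cumsum(ceiling(stats::rexp(m, 1 / config$pos_spacing_mean)) + 1L)
  variants <- data.frame(variant_id = ids, chrom = "1", pos = pos,
                         stringsAsFactors = FALSE)
  # block partition: geometric lengths
  blocks <- list()
  i <- 1L
  while (i <= m) {
    len <- min(1L + stats::rgeom(1, 1 / config$block_len_mean), m - i + 1L)
    blocks[[length(blocks) + 1L]] <- seq.int(i, i + len - 1L)
    i <- i + len
  }
  p_anc <- stats::runif(m, config$anc_freq_range[1], config$anc_freq_range[2])
  fst <- config$fst
  draw_freq <- function(p) {
    if (fst == 0) return(p)
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    stats::rbeta(length(p), a, b)
  }
  build <- function(pop) {
    p_pop <- draw_freq(p_anc)
    founders <- vector("list", length(blocks))
    weights <- vector("list", length(blocks))
    for (bi in seq_along(blocks)) {
      idx <- blocks[[bi]]
      if (length(idx) == 1L) {
        founders[[bi]] <- matrix(c(0L, 1L), nrow = 2)
        weights[[bi]] <- c(1 - p_pop[idx], p_pop[idx])
      } else {
        k <- sample.int(config$founders_range[2] -
                          config$founders_range[1] + 1L, 1L) +
          config$founders_range[1] - 1L
        w <- stats::rgamma(k, 2, 1)
        w <- w / sum(w)
        fo <- matrix(0L, nrow = k, ncol = length(idx))
        for (j in seq_along(idx))
          fo[, j] <- .founder_alleles_for_freq(w, p_pop[idx[j]])
        founders[[bi]] <- fo
        weights[[bi]] <- w
      }
    }
    make_ancestral_panel(pop, variants, founders, weights, blocks,
                         pool_size = config$pool_size)
  }
  list(pop1 = build("pop1"), pop2 = build("pop2"))
}

# One mosaic haplotype: ancestry switches as a Poisson process over a [0,1]
# coordinate mapped to the variant index; each segment copies a random pool
# haplotype from its ancestry's panel. Returns alleles and per-variant
# ancestry indicator (1 = pop1).
.mosaic_haplotype <- function(panels, theta, switch_rate, m,
                              n_sw = stats::rpois(1L, switch_rate)) {
  cuts <- sort(stats::runif(n_sw))
  bounds <- c(0, cuts, 1)
  allele <- integer(m)
  anc <- integer(m)
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- floor(bounds[s] * m) + 1L
    hi <- floor(bounds[s + 1L] * m)
    if (s == length(bounds) - 1L) hi <- m
    if (hi < lo) next
    a <- stats::rbinom(1L, 1L, theta)
    pool <- if (a == 1L) panels$pop1$haps else panels$pop2$haps
    hap <- pool[sample.int(nrow(pool), 1L), ]
    allele[lo:hi] <- hap[lo:hi]
    anc[lo:hi] <- a
  }
  list(allele = allele, anc = anc, n_switches = n_sw)
}

#' Simulate admixed individuals
#'
#' Each individual carries two mosaic haplotypes over the shared panel
#' variant list; ancestry switches occur as a Poisson process at
#' `config$switch_rate` per haplotype, with the ancestry of each tract drawn
#' Bernoulli(`theta`) for population 1. Emits hard genotypes with missing
#' calls for typed variants and noisy continuous dosages for imputed
#' variants, plus the true local-ancestry track and a truth record.
#'
#' @param panels output of [simulate_ancestral_panels()] (or a compatible
#'   list of two `ancestral_panel`s sharing a variant list)
#' @param config a [sim_config()]
#' @param n number of individuals to simulate (defaults to
#'   `n_cases + n_controls`)
#' @param id_prefix prefix for generated sample ids
#' @return list with elements
#'   * `dosages`: a [dosage_matrix()] (observed data: missing calls, noisy
#'     imputed dosages)
#'   * `local_ancestry`: samples x variants matrix, true count of
#'     population-1 chromosomes in \[0,2\]
#'   * `truth`: list with true genotypes (`genotype`), haplotypes (`h1`,
#'     `h2`), ancestry indicators, per-variant `typed`/`rsq_target`,
#'     switch counts, the causal model, and the config
#' @export
simulate_admixed_cohort <- function(panels, config,
                                    n = config$n_cases + config$n_controls,
                                    id_prefix = "S") {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(panels$pop1$variants$variant_id,
                 panels$pop2$variants$variant_id))
    stop("panels do not share a variant list")
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- nrow(panels$pop1$variants)
  variants <- panels$pop1$variants
  # fixed per-dataset variant metadata
  meta <- .variant_emission_meta(variants, config)
  sim <- .sim_individuals(panels, config, n)
  ids <- paste0(id_prefix, seq_len(n))
  rownames(sim$g) <- ids
  rownames(sim$h1) <- ids
  rownames(sim$h2) <- ids
  obs <- .emit_dosages(sim$g, meta, config)
  la <- sim$anc1 + sim$anc2
  dimnames(la) <- dimnames(sim$g)
  truth <- list(genotype = sim$g, h1 = sim$h1, h2 = sim$h2,
                anc1 = sim$anc1, anc2 = sim$anc2,
                n_switches = sim$n_switches,
                typed = meta$typed, rsq_target = meta$rsq,
                causal = config$causal, relatives = NULL,
                seed = config$seed, config = config)
  list(dosages = dosage_matrix(obs, meta$variants),
       local_ancestry = la, truth = truth)
}

.variant_emission_meta <- function(variants, config) {
  m <- nrow(variants)
  n_imp <- round(config$imputed_frac * m)
  imputed <- rep(FALSE, m)
  if (n_imp > 0) imputed[sample.int(m, n_imp)] <- TRUE
  rsq <- rep(NA_real_, m)
  rsq[imputed] <- stats::runif(n_imp, config$rsq_range[1],
                               config$rsq_range[2])
  v <- variants
  v$risk_allele <- "A"
  v$other_allele <- "G"
  v$typed <- !imputed
  v$rsq <- rsq
  list(variants = v, typed = !imputed, rsq = rsq)
}

# All 2n haplotypes at once. Haplotypes without an ancestry switch (the
# common case at regional switch rates) are drawn in two vectorized gathers;
# only haplotypes with >= 1 switch take the per-segment path.
.sim_individuals <- function(panels, config, n) {
  m <- ncol(panels$pop1$haps)
  H <- 2L * n
  nsw <- stats::rpois(H, config$switch_rate)
  X <- matrix(0L, H, m)
  A <- matrix(0L, H, m)
  simple <- which(nsw == 0L)
  if (length(simple)) {
    a <- stats::rbinom(length(simple), 1L, config$theta)
    for (pop in 0:1) {
      rows <- simple[a == pop]
      if (!length(rows)) next
      pool <- if (pop == 1L) panels$pop1$haps else panels$pop2$haps
      pick <- sample.int(nrow(pool), length(rows), replace = TRUE)
      X[rows, ] <- pool[pick, , drop = FALSE]
      if (pop == 1L) A[rows, ] <- 1L
    }
  }
  for (i in which(nsw > 0L)) {
    hp <- .mosaic_haplotype(panels, config$theta, config$switch_rate, m,
                            n_sw = nsw[i])
    X[i, ] <- hp$allele
    A[i, ] <- hp$anc
  }
  h1 <- X[seq_len(n), , drop = FALSE]
  h2 <- X[n + seq_len(n), , drop = FALSE]
  anc1 <- A[seq_len(n), , drop = FALSE]
  anc2 <- A[n + seq_len(n), , drop = FALSE]
  g <- h1 + h2
  colnames(g) <- panels$pop1$variants$variant_id
  list(g = g, h1 = h1, h2 = h2, anc1 = anc1, anc2 = anc2,
       n_switches = cbind(nsw[seq_len(n)], nsw[n + seq_len(n)]))
}

# Observed dosages from true genotypes: typed -> integer with missing calls;
# imputed -> true + Gaussian noise with variance var(g)*(1-R)/R, clipped to
# [0,2], so cor(d, g)^2 ~= R.
.emit_dosages <- function(g, meta, config) {
  n <- nrow(g); m <- ncol(g)
  obs <- matrix(NA_real_, n, m, dimnames = dimnames(g))
  typed <- meta$typed
  if (any(typed)) {
    d <- g[, typed, drop = FALSE] * 1.0
    if (config$miss_rate > 0) {
      miss <- matrix(stats::runif(length(d)) < config$miss_rate, nrow(d))
      d[miss] <- NA_real_
    }
    obs[, typed] <- d
  }
  for (j in which(!typed)) {
    r <- meta$rsq[j]
    v <- stats::var(g[, j])
    if (v == 0) { obs[, j] <- g[, j] * 1.0; next }
    eps <- stats::rnorm(n)
    # clipping to [0,2] raises the realized correlation above the
    # unclipped solution sqrt(v (1-r)/r), so calibrate the noise scale by
    # bisection against the clipped correlation actually achieved
    f <- function(s) {
      d <- pmin(2, pmax(0, g[, j] + s * eps))
      if (stats::sd(d) == 0) return(-r)
      stats::cor(d, g[, j])^2 - r
    }
    s_lo <- sqrt(v * (1 - r) / r)
    s_hi <- s_lo * 4
    f_lo <- f(s_lo); f_hi <- f(s_hi)
    s <- if (n < 30 || f_lo <= 0) s_lo   # tiny batches: closed form only
         else if (f_hi >= 0) s_hi
         else stats::uniroot(f, c(s_lo, s_hi), tol = 1e-4)$root
    obs[, j] <- pmin(2, pmax(0, g[, j] + s * eps))
  }
  obs
}

#' Assign phenotypes and covariates under a logistic disease model
#'
#' Case status is drawn from
#' `logit P(case) = intercept + sum(beta_i * genotype_i) + covariate terms`,
#' with the intercept solved so the average probability equals
#' `config$prevalence`. Ages, study labels, family history (optionally
#' depending on status and/or the causal allele count), and a severity label
#' (cases only) are also assigned.
#'
#' @param cohort output of [simulate_admixed_cohort()] (truth genotypes used)
#' @param config a [sim_config()]
#' @return data.frame with columns `sample_id`, `status`, `age`, `study`,
#'   `family_history`, `severity`, `sex`
#' @export
assign_phenotypes <- function(cohort, config) {
  g <- cohort$truth$genotype
  n <- nrow(g)
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  study <- sample(config$studies, n, replace = TRUE)
  eta <- rep(0, n)
  score <- rep(0, n)
  if (!is.null(config$causal) && nrow(config$causal) > 0) {
    idx <- match(config$causal$variant_id, colnames(g))
    if (anyNA(idx))
      stop("causal variants absent from panel: ",
           paste(config$causal$variant_id[is.na(idx)], collapse = ", "))
    score <- as.numeric(g[, idx, drop = FALSE] %*% config$causal$log_or)
    eta <- eta + score
  }
  eta <- eta + config$age_beta * (age - config$age_mean) / 10 +
    config$study_effects[match(study, config$studies)]
  icpt <- .solve_intercept(eta, config$prevalence)
  p <- stats::plogis(icpt + eta)
  status <- stats::rbinom(n, 1L, p)
  fh_eta <- stats::qlogis(config$fh_base) +
    config$fh_status_logor * status +
    config$fh_score_beta * (score - mean(score))
  family_history <- stats::rbinom(n, 1L, stats::plogis(fh_eta))
  severity <- rep(NA_integer_, n)
  is_case <- status == 1L
  if (any(is_case)) {
    sv_eta <- stats::qlogis(config$sev_frac) +
      config$sev_score_beta * (score[is_case] - mean(score[is_case]))
    severity[is_case] <- stats::rbinom(sum(is_case), 1L,
                                       stats::plogis(sv_eta))
  }
  data.frame(sample_id = rownames(g), status = status, age = age,
             study = study, family_history = family_history,
             severity = severity, sex = "M", stringsAsFactors = FALSE)
}

# Solve the logistic intercept so mean(plogis(icpt + eta)) == target.
.solve_intercept <- function(eta, target) {
  f <- function(c0) mean(stats::plogis(c0 + eta)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0)
    stop("unreachable prevalence: linear predictor drives probabilities to 0/1")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Simulate an ascertained case-control dataset
#'
#' Master wrapper: generates admixed individuals in batches, assigns
#' phenotypes, and keeps the first `n_cases` cases and `n_controls` controls
#' (rejection-sampling ascertainment). Errors after `config$max_attempts`
#' batches if the quotas cannot be reached.
#'
#' @param config a [sim_config()]
#' @param panels optional pre-built panels ([simulate_ancestral_panels()]
#'   is called when NULL; note the panel draw consumes random numbers, so
#'   pass panels explicitly to hold LD structure fixed across replicates)
#' @return list with `dosages` ([dosage_matrix()]), `local_ancestry` matrix,
#'   `samples` (phenotype table), `truth`, and `panels`
#' @export
simulate_case_control <- function(config, panels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(panels)) {
    cfg_nested <- config
    cfg_nested$seed <- NULL
    panels <- simulate_ancestral_panels(cfg_nested)
  }
  need_ca <- config$n_cases; need_co <- config$n_controls
  # batch sized by expected yield of the rarer class
  batch <- max(200L, ceiling(1.5 * max(need_ca / config$prevalence,
                                       need_co / (1 - config$prevalence))))
  cfg <- config
  cfg$seed <- NULL
  kept <- list()
  got_ca <- 0L; got_co <- 0L
  attempt <- 0L
  offset <- 0L
  while ((got_ca < need_ca || got_co < need_co) &&
         attempt < config$max_attempts) {
    attempt <- attempt + 1L
    co <- simulate_admixed_cohort(panels, cfg, n = batch,
                                  id_prefix = paste0("B", attempt, "_S"))
    ph <- assign_phenotypes(co, cfg)
    take_ca <- which(ph$status == 1L)[seq_len(min(need_ca - got_ca,
                                                  sum(ph$status == 1L)))]
    take_co <- which(ph$status == 0L)[seq_len(min(need_co - got_co,
                                                  sum(ph$status == 0L)))]
    take <- sort(c(take_ca, take_co))
    if (length(take)) {
      kept[[length(kept) + 1L]] <- list(
        d = co$dosages$dosages[take, , drop = FALSE],
        la = co$local_ancestry[take, , drop = FALSE],
        ph = ph[take, , drop = FALSE],
        g = co$truth$genotype[take, , drop = FALSE],
        h1 = co$truth$h1[take, , drop = FALSE],
        h2 = co$truth$h2[take, , drop = FALSE],
        meta = co$dosages$variants, truth = co$truth)
      got_ca <- got_ca + length(take_ca)
      got_co <- got_co + length(take_co)
    }
    offset <- offset + batch
  }
  if (got_ca < need_ca || got_co < need_co)
    stop("ascertainment failed after ", attempt, " batches (",
         got_ca, "/", need_ca, " cases, ", got_co, "/", need_co,
         " controls)")
  d <- do.call(rbind, lapply(kept, `[[`, "d"))
  la <- do.call(rbind, lapply(kept, `[[`, "la"))
  ph <- do.call(rbind, lapply(kept, `[[`, "ph"))
  g <- do.call(rbind, lapply(kept, `[[`, "g"))
  h1 <- do.call(rbind, lapply(kept, `[[`, "h1"))
  h2 <- do.call(rbind, lapply(kept, `[[`, "h2"))
  ids <- paste0("S", seq_len(nrow(d)))
  rownames(d) <- ids; rownames(la) <- ids; rownames(g) <- ids
  rownames(h1) <- ids; rownames(h2) <- ids
  ph$sample_id <- ids
  rownames(ph) <- NULL
  meta <- kept[[1L]]$meta
  truth <- list(genotype = g, h1 = h1, h2 = h2,
                typed = meta$typed, rsq_target = meta$rsq,
                causal = config$causal, relatives = NULL,
                seed = config$seed, config = config)
  out <- list(dosages = dosage_matrix(d, meta), local_ancestry = la,
              samples = ph, truth = truth, panels = panels)
  if (!is.null(config$relatives))
    out <- inject_relatives(out, config)
  out
}

# Transmit one haplotype from a parent with Poisson crossovers between the
# parent's two haplotypes along the variant index.
.transmit <- function(h1, h2, crossovers) {
  m <- length(h1)
  n_x <- stats::rpois(1L, crossovers)
  cuts <- sort(stats::runif(n_x))
  bounds <- c(0, cuts, 1)
  cur <- stats::rbinom(1L, 1L, 0.5)
  out <- integer(m)
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- floor(bounds[s] * m) + 1L
    hi <- if (s == length(bounds) - 1L) m else floor(bounds[s + 1L] * m)
    if (hi < lo) { cur <- 1L - cur; next }
    out[lo:hi] <- if (cur == 0L) h1[lo:hi] else h2[lo:hi]
    cur <- 1L - cur
  }
  out
}

#' Inject related samples into a simulated dataset
#'
#' Appends new samples constructed from existing ones: duplicates (MZ) copy
#' both haplotypes; parent-offspring transmit one recombined haplotype (the
#' other is a fresh admixed haplotype); full siblings receive one recombined
#' haplotype from each of two existing "parents"; half siblings share one
#' parent. Transmission uses Poisson crossovers
#' (`config$meiosis_crossovers`). Truth records the injected pairs.
#'
#' @param cohort output of [simulate_case_control()] or a compatible list
#'   with `dosages`, `samples`, `truth` (haplotypes), `panels`
#' @param config a [sim_config()] with a `relatives` table
#' @return the cohort with appended samples and `truth$relatives` set
#' @export
inject_relatives <- function(cohort, config) {
  rel <- config$relatives
  if (is.null(rel) || nrow(rel) == 0) return(cohort)
  h1 <- cohort$truth$h1; h2 <- cohort$truth$h2
  m <- ncol(h1)
  meta <- cohort$dosages$variants
  pairs <- list()
  new_h1 <- list(); new_h2 <- list(); new_ids <- character(0)
  ctr <- 0L
  fresh_hap <- function() .mosaic_haplotype(cohort$panels, config$theta,
                                            config$switch_rate, m)$allele
  for (r in seq_len(nrow(rel))) {
    relname <- rel$relationship[r]
    for (k in seq_len(rel$count[r])) {
      ctr <- ctr + 1L
      if (relname == "duplicate") {
        src <- sample.int(nrow(h1), 1L)
        nid <- sprintf("REL%03d_MZ", ctr)
        new_h1[[nid]] <- h1[src, ]; new_h2[[nid]] <- h2[src, ]
        pairs[[length(pairs) + 1L]] <-
          data.frame(id1 = rownames(h1)[src], id2 = nid,
                     relationship = "duplicate")
      } else if (relname == "parent-offspring") {
        src <- sample.int(nrow(h1), 1L)
        nid <- sprintf("REL%03d_PO", ctr)
        new_h1[[nid]] <- .transmit(h1[src, ], h2[src, ],
                                   config$meiosis_crossovers)
        new_h2[[nid]] <- fresh_hap()
        pairs[[length(pairs) + 1L]] <-
          data.frame(id1 = rownames(h1)[src], id2 = nid,
                     relationship = "parent-offspring")
      } else if (relname %in% c("full-sibling", "half-sibling")) {
        pa <- sample.int(nrow(h1), 1L)
        pb <- sample.int(nrow(h1), 1L)
        tag <- if (relname == "full-sibling") "FS" else "HS"
        mk_sib <- function(full) {
          a <- .transmit(h1[pa, ], h2[pa, ], config$meiosis_crossovers)
          b <- if (full) .transmit(h1[pb, ], h2[pb, ],
                                   config$meiosis_crossovers) else fresh_hap()
          list(a = a, b = b)
        }
        s1 <- mk_sib(relname == "full-sibling")
        s2 <- mk_sib(relname == "full-sibling")
        id1 <- sprintf("REL%03d_%s_a", ctr, tag)
        id2 <- sprintf("REL%03d_%s_b", ctr, tag)
        new_h1[[id1]] <- s1$a; new_h2[[id1]] <- s1$b
        new_h1[[id2]] <- s2$a; new_h2[[id2]] <- s2$b
        pairs[[length(pairs) + 1L]] <-
          data.frame(id1 = id1, id2 = id2, relationship = relname)
      }
    }
  }
  if (!length(new_h1)) return(cohort)
  nh1 <- do.call(rbind, new_h1); nh2 <- do.call(rbind, new_h2)
  ng <- nh1 + nh2
  colnames(ng) <- colnames(h1) <- colnames(cohort$truth$genotype)
  meta_list <- list(variants = meta, typed = meta$typed, rsq = meta$rsq)
  nobs <- .emit_dosages(ng, meta_list, config)
  rownames(nobs) <- rownames(ng)
  d <- rbind(cohort$dosages$dosages, nobs)
  cohort$dosages <- dosage_matrix(d, meta)
  cohort$truth$h1 <- rbind(h1, nh1)
  cohort$truth$h2 <- rbind(h2, nh2)
  g_all <- rbind(cohort$truth$genotype, ng)
  cohort$truth$genotype <- g_all
  cohort$truth$relatives <- do.call(rbind, pairs)
  extra <- data.frame(sample_id = rownames(ng), status = NA_integer_,
                      age = NA_real_, study = NA_character_,
                      family_history = NA_integer_, severity = NA_integer_,
                      sex = "M", stringsAsFactors = FALSE)
  cohort$samples <- rbind(cohort$samples, extra)
  if (!is.null(cohort$local_ancestry)) {
    pad <- matrix(NA_real_, nrow(ng), ncol(cohort$local_ancestry),
                  dimnames = list(rownames(ng),
                                  colnames(cohort$local_ancestry)))
    cohort$local_ancestry <- rbind(cohort$local_ancestry, pad)
  }
  cohort
}
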