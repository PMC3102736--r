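#' Unweighted risk-allele count score
#'
#' Sums risk-allele dosages over the score variants for each sample;
#' missing genotypes contribute the expected count `2 * RAF` (risk-allele
#' frequency in controls) for that variant.
#'
#' @param dm a [dosage_matrix()]
#' @param score_variants data.frame with `variant_id` and `raf` (control
#'   risk-allele frequency used for the missing fill)
#' @return named numeric vector of per-sample counts in \[0, 2m\]
#' @export
build_score <- function(dm, score_variants) {
  idx <- match(score_variants$variant_id, variant_ids(dm))
  if (anyNA(idx))
    stop("score variants absent from panel: ",
         paste(score_variants$variant_id[is.na(idx)], collapse = ", "))
  d <- dm$dosages[, idx, drop = FALSE]
  for (j in seq_len(ncol(d))) {
    mis <- is.na(d[, j])
    if (any(mis)) d[mis, j] <- 2 * score_variants$raf[j]
  }
  rowSums(d)
}

#' Per-allele odds ratio of the aggregate score
#'
#' Logistic regression of case status on the risk-allele count with
#' covariate adjustment; Wald CI and p-value.
#'
#' @param counts per-sample risk-allele counts
#' @param status 0/1 case status
#' @param covars covariate data.frame or NULL
#' @return one-row data.frame `or`, `ci_lo`, `ci_hi`, `beta`, `se`, `p`, `n`
#' @export
per_allele_or <- function(counts, status, covars = NULL) {
  if (stats::var(counts, na.rm = TRUE) == 0)
    stop("count variance is zero")
  .logistic_fit(counts, status, covars, term = "risk_allele_count")
}

#' Quartile analysis of the risk score
#'
#' Cutpoints are the control-sample quartiles of the count (empirical
#' quantiles with linear interpolation, `stats::quantile` type 7). Overall:
#' logistic fit of status on quartile indicators (Q1 reference) with
#' covariates. When a family-history column is given, an additional
#' stratified fit crosses quartile with family history, with
#' family-history-negative Q1 as the common reference; rows with missing
#' family history are dropped from that fit.
#'
#' @param counts per-sample risk-allele counts
#' @param status 0/1 case status
#' @param covars covariate data.frame or NULL
#' @param family_history optional 0/1/NA vector
#' @return list with `cutpoints` (3 values), `overall` (data.frame:
#'   quartile, n_cases, n_controls, or, ci_lo, ci_hi, p) and, when
#'   stratified, `by_family_history` (stratum x quartile rows, OR vs
#'   FH-negative Q1)
#' @export
quartile_analysis <- function(counts, status, covars = NULL,
                              family_history = NULL) {
  ctrl <- counts[status == 0]
  if (!length(ctrl)) stop("no controls")
  cut3 <- stats::quantile(ctrl, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  q <- cut(counts, breaks = c(-Inf, cut3, Inf),
           labels = paste0("Q", 1:4), right = TRUE)
  fit_q <- function(sel, strat = NULL) {
    df <- data.frame(.y = status[sel], q = droplevels(q[sel]))
    if (!is.null(strat)) df$grp <- droplevels(strat[sel]) else df$grp <- df$q
    df$q <- NULL
    if (!is.null(covars))
      df <- cbind(df, as.data.frame(covars)[sel, , drop = FALSE])
    df <- df[stats::complete.cases(df), , drop = FALSE]
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    co <- summary(fit)$coefficients
    co
  }
  tab <- table(q, factor(status, 0:1))
  co <- fit_q(rep(TRUE, length(counts)))
  overall <- do.call(rbind, lapply(levels(q), function(lv) {
    nm <- paste0("grp", lv)
    if (lv == "Q1" || !nm %in% rownames(co)) {
      data.frame(quartile = lv, n_cases = tab[lv, "1"],
                 n_controls = tab[lv, "0"],
                 or = if (lv == "Q1") 1 else NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_)
    } else {
      b <- co[nm, "Estimate"]; s <- co[nm, "Std. Error"]
      data.frame(quartile = lv, n_cases = tab[lv, "1"],
                 n_controls = tab[lv, "0"], or = exp(b),
                 ci_lo = exp(b - 1.96 * s), ci_hi = exp(b + 1.96 * s),
                 p = stats::pchisq((b / s)^2, 1, lower.tail = FALSE))
    }
  }))
  out <- list(cutpoints = cut3, overall = overall)
  if (!is.null(family_history)) {
    sel <- !is.na(family_history)
    lv_all <- paste0(rep(c("FHneg", "FHpos"), each = 4), ".",
                     rep(paste0("Q", 1:4), 2))
    strat_full <- factor(
      ifelse(sel, paste0(ifelse(family_history == 1, "FHpos", "FHneg"),
                         ".", as.character(q)), NA),
      levels = lv_all)
    strat_full <- stats::relevel(strat_full, ref = "FHneg.Q1")
    co2 <- fit_q(sel, strat = strat_full)
    lv <- levels(droplevels(strat_full))
    rows <- lapply(lv, function(l) {
      nm <- paste0("grp", l)
      parts <- strsplit(l, ".", fixed = TRUE)[[1]]
      base <- data.frame(stratum = parts[1], quartile = parts[2])
      if (l == "FHneg.Q1" || !nm %in% rownames(co2))
        cbind(base, or = if (l == "FHneg.Q1") 1 else NA_real_,
              ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_)
      else {
        b <- co2[nm, "Estimate"]; s <- co2[nm, "Std. Error"]
        cbind(base, or = exp(b), ci_lo = exp(b - 1.96 * s),
              ci_hi = exp(b + 1.96 * s),
              p = stats::pchisq((b / s)^2, 1, lower.tail = FALSE))
      }
    })
    out$by_family_history <- do.call(rbind, rows)
  }
  out
}

#' Case-only severity test of the score
#'
#' Logistic regression of advanced (1) vs non-advanced (0) disease on the
#' risk-allele count, among cases only.
#'
#' @param counts risk-allele counts among cases
#' @param severity 0/1 severity labels (NA dropped)
#' @param covars covariate data.frame or NULL
#' @return one-row data.frame as [per_allele_or()]
#' @export
severity_case_only_test <- function(counts, severity, covars = NULL) {
  ok <- !is.na(severity)
  if (length(unique(severity[ok])) < 2)
    stop("both severity classes must be present")
  cv <- if (is.null(covars)) NULL else as.data.frame(covars)[ok, , drop = FALSE]
  .logistic_fit(counts[ok], severity[ok], cv, term = "risk_allele_count")
}

#' Familial relative risk from reported family history
#'
#' Logistic odds ratio of case status on a first-degree family-history
#' indicator, with covariates; rows with missing family history are
#' dropped.
#'
#' @param status 0/1 case status
#' @param family_history 0/1/NA indicator
#' @param covars covariate data.frame or NULL
#' @return one-row data.frame as [per_allele_or()]
#' @export
familial_rr_estimate <- function(status, family_history, covars = NULL) {
  ok <- !is.na(family_history) & !is.na(status)
  if (length(unique(family_history[ok])) < 2)
    stop("no variation in family history")
  cv <- if (is.null(covars)) NULL else as.data.frame(covars)[ok, , drop = FALSE]
  .logistic_fit(family_history[ok], status[ok], cv, term = "family_history")
}

#' Fraction of familial relative risk explained by the score
#'
#' Closed form. Assuming risk alleles are inherited independently, the
#' correlation of the allele count between first-degree relatives is
#' `r = 0.5`; the expected count in unaffected relatives of cases is the
#' mixture `m_rel = m0 * (1 - r^2) + m1 * r^2`, where `m0`/`m1` are the
#' control/case means. The score-implied familial relative risk is
#' `rho_score = exp(log(lambda) * (m_rel - m0))` with `lambda` the
#' per-allele odds ratio, and the fraction of the observed familial
#' relative risk `rho_obs` explained is
#' `f = (rho_score - 1) / (rho_obs - 1)`.
#'
#' Both a full-precision path and a display path that rounds `m_rel`,
#' `delta`, and `rho_score` to 2 decimals before each subsequent step (the
#' convention of the worked example this reproduces) are returned.
#'
#' @param m0 mean risk-allele count in controls
#' @param m1 mean risk-allele count in cases
#' @param lambda per-allele odds ratio of the score (> 0)
#' @param rho_obs observed familial relative risk (> 1)
#' @param r relative correlation of the count between first-degree
#'   relatives (default 0.5)
#' @return list of class `familial_risk` with `m0`, `m1`, `r`, `m_rel`,
#'   `delta`, `rho_score`, `rho_obs`, `fraction` (proportion),
#'   `fraction_pct`, and `rounded` (the 2-dp display path:
#'   `m_rel`, `delta`, `rho_score`, `fraction_pct` whole-percent)
#' @export
familial_risk_explained <- function(m0, m1, lambda, rho_obs, r = 0.5) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (rho_obs <= 1) stop("fraction undefined: rho_obs must exceed 1")
  if (r < 0 || r > 1) stop("r must be in [0,1]")
  m_rel <- m0 * (1 - r^2) + m1 * r^2
  delta <- m_rel - m0
  rho_score <- exp(log(lambda) * delta)
  fraction <- (rho_score - 1) / (rho_obs - 1)
  m_rel_r <- round(m_rel, 2)
  delta_r <- round(m_rel_r - m0, 2)
  rho_r <- round(exp(log(lambda) * delta_r), 2)
  frac_r <- round((rho_r - 1) / (rho_obs - 1) * 100)
  structure(list(m0 = m0, m1 = m1, r = r, m_rel = m_rel, delta = delta,
                 rho_score = rho_score, rho_obs = rho_obs,
                 fraction = fraction, fraction_pct = 100 * fraction,
                 rounded = list(m_rel = m_rel_r, delta = delta_r,
                                rho_score = rho_r, fraction_pct = frac_r)),
            class = "familial_risk")
}

#' @export
print.familial_risk <- function(x, ...) {
  cat(sprintf(paste0(
    "<familial_risk> m0 = %.2f, m1 = %.2f, r = %.2f\n",
    "  expected count in first-degree relatives of cases: %.2f ",
    "(+%.2f alleles)\n",
    "  score-implied familial RR: %.2f; observed: %.2f\n",
    "  fraction of familial risk explained: %.1f%% (~%d%% at display ",
    "rounding)\n"),
    x$m0, x$m1, x$r, x$rounded$m_rel, x$rounded$delta,
    x$rounded$rho_score, x$rho_obs, x$fraction_pct,
    x$rounded$fraction_pct))
  invisible(x)
}

#' Independence check of score-variant effects
#'
#' Compares each variant's single-variant log odds ratio with its
#' coefficient when all score variants enter one joint model; near-equality
#' supports the independent-effects assumption behind the unweighted count.
#'
#' @param dm a [dosage_matrix()]
#' @param variant_idv character vector of >= 2 score variant ids
#' @param status 0/1 case status
#' @param covars covariate data.frame or NULL
#' @return list with `table` (variant_id, beta_single, se_single,
#'   beta_joint, se_joint, collinear flag) and `max_abs_rel_diff`
#'   (max |beta_joint - beta_single| / se_single over non-collinear
#'   variants)
#' @export
independence_check <- function(dm, variant_idv, status, covars = NULL) {
  ids <- as.character(variant_idv)
  if (length(ids) < 2) stop("need >= 2 variants")
  d <- dm$dosages[, ids, drop = FALSE]
  # collinearity screen
  collinear <- rep(FALSE, length(ids))
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    r2 <- pairwise_r2(d[, i], d[, j])
    if (!is.na(r2) && r2 >= 1 - 1e-12) collinear[i] <- TRUE
  }
  singles <- lapply(ids, function(v)
    trend_test(dm$dosages[, v], status, covars, variant_id = v))
  singles <- do.call(rbind, singles)
  df <- data.frame(.y = status)
  for (v in ids[!collinear]) df[[v]] <- {
    xv <- d[, v]
    xv[is.na(xv)] <- mean(xv, na.rm = TRUE)
    xv
  }
  if (!is.null(covars)) df <- cbind(df, as.data.frame(covars))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  co <- summary(fit)$coefficients
  tab <- data.frame(variant_id = ids,
                    beta_single = singles$beta, se_single = singles$se,
                    beta_joint = NA_real_, se_joint = NA_real_,
                    collinear = collinear, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    rn <- make.names(ids[i])
    if (!collinear[i] && rn %in% rownames(co)) {
      tab$beta_joint[i] <- co[rn, "Estimate"]
      tab$se_joint[i] <- co[rn, "Std. Error"]
    }
  }
  okrows <- !tab$collinear & !is.na(tab$beta_joint) & !is.na(tab$beta_single)
  mard <- if (any(okrows))
    max(abs(tab$beta_joint[okrows] - tab$beta_single[okrows]) /
          tab$se_single[okrows])
  else NA_real_
  list(table = tab, max_abs_rel_diff = mard)
}
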