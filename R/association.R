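#' Single-variant logistic trend test
#'
#' Unconditional logistic regression of case status on the risk-allele
#' dosage with covariate adjustment; the per-allele odds ratio is tested by
#' a 1-df Wald chi-square trend statistic `(beta / se)^2`. Complete cases
#' for the variant are used (the stepwise machinery instead mean-fills;
#' see [stepwise_select()]). Imputed variants enter as continuous dosages.
#'
#' @param dosage per-sample dosage vector in \[0,2\] (NA = missing)
#' @param status 0/1 case status
#' @param covars data.frame of covariates (age, study indicators,
#'   eigenvectors, region-average local ancestry), or NULL
#' @param variant_id label carried into the result
#' @return one-row data.frame with `variant_id`, `beta`, `se`, `or`,
#'   `ci_lo`, `ci_hi`, `p_trend`, `n`, `raf_cases`, `raf_controls`,
#'   `flag` ("" or a skip/diagnostic reason; skipped fits carry NA
#'   estimates)
#' @export
trend_test <- function(dosage, status, covars = NULL, variant_id = "variant") {
  skip <- function(why) data.frame(
    variant_id = variant_id, beta = NA_real_, se = NA_real_, or = NA_real_,
    ci_lo = NA_real_, ci_hi = NA_real_, p_trend = NA_real_,
    n = sum(!is.na(dosage) & !is.na(status)),
    raf_cases = NA_real_, raf_controls = NA_real_, flag = why,
    stringsAsFactors = FALSE)
  ok <- !is.na(dosage) & !is.na(status)
  if (sum(ok) < 2 || stats::var(dosage[ok]) == 0)
    return(skip("constant dosage"))
  res <- tryCatch(.logistic_fit(dosage, status, covars, term = variant_id),
                  error = function(e) NULL)
  if (is.null(res)) return(skip("separation"))
  data.frame(variant_id = variant_id, beta = res$beta, se = res$se,
             or = res$or, ci_lo = res$ci_lo, ci_hi = res$ci_hi,
             p_trend = res$p, n = res$n,
             raf_cases = mean(dosage[ok & status == 1]) / 2,
             raf_controls = mean(dosage[ok & status == 0]) / 2,
             flag = "", stringsAsFactors = FALSE)
}

#' Association scan over a dosage matrix
#'
#' Runs [trend_test()] for every variant passing the imputation-quality
#' filter (imputed variants with Rsq below `rsq_min` are excluded before
#' testing).
#'
#' @param dm a [dosage_matrix()]
#' @param status 0/1 case status aligned with the samples
#' @param covars covariate data.frame or NULL
#' @param rsq_min imputation-quality threshold (default 0.3)
#' @return data.frame, one row per tested variant, plus `chrom`/`pos`
#' @export
assoc_scan <- function(dm, status, covars = NULL, rsq_min = 0.3) {
  keep <- dm$variants$typed | (!is.na(dm$variants$rsq) &
                                 dm$variants$rsq >= rsq_min)
  v <- dm$variants[keep, , drop = FALSE]
  d <- dm$dosages[, keep, drop = FALSE]
  rows <- lapply(seq_len(nrow(v)), function(j)
    trend_test(d[, j], status, covars, variant_id = v$variant_id[j]))
  out <- do.call(rbind, rows)
  cbind(out, chrom = v$chrom, pos = v$pos)
}

#' Genotype-class association test
#'
#' Logistic fit with indicator variables for heterozygotes and risk-allele
#' homozygotes against the reference-homozygote class, for typed variants.
#' An absent class yields `NA` for that contrast.
#'
#' @param dosage integer genotype vector (0/1/2; NA = missing)
#' @param status 0/1 case status
#' @param covars covariate data.frame or NULL
#' @param variant_id label
#' @return one-row data.frame with het and hom ORs/CIs/p-values
#' @export
genotype_class_test <- function(dosage, status, covars = NULL,
                                variant_id = "variant") {
  g <- round(dosage)
  ok <- !is.na(g) & !is.na(status)
  out <- data.frame(variant_id = variant_id,
                    or_het = NA_real_, ci_lo_het = NA_real_,
                    ci_hi_het = NA_real_, p_het_class = NA_real_,
                    or_hom = NA_real_, ci_lo_hom = NA_real_,
                    ci_hi_hom = NA_real_, p_hom_class = NA_real_,
                    stringsAsFactors = FALSE)
  if (sum(ok & g == 0) == 0) return(out)   # no reference class
  df <- data.frame(.y = status[ok], het = as.integer(g[ok] == 1),
                   hom = as.integer(g[ok] == 2))
  has_het <- any(df$het == 1); has_hom <- any(df$hom == 1)
  if (!has_het) df$het <- NULL
  if (!has_hom) df$hom <- NULL
  if (is.null(df$het) && is.null(df$hom)) return(out)
  if (!is.null(covars))
    df <- cbind(df, as.data.frame(covars)[ok, , drop = FALSE])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  co <- summary(fit)$coefficients
  fill <- function(nm) {
    if (!nm %in% rownames(co)) return(NULL)
    b <- co[nm, "Estimate"]; s <- co[nm, "Std. Error"]
    c(exp(b), exp(b - 1.96 * s), exp(b + 1.96 * s),
      stats::pchisq((b / s)^2, 1, lower.tail = FALSE))
  }
  if (has_het) {
    v <- fill("het")
    out$or_het <- v[1]; out$ci_lo_het <- v[2]; out$ci_hi_het <- v[3]
    out$p_het_class <- v[4]
  }
  if (has_hom) {
    v <- fill("hom")
    out$or_hom <- v[1]; out$ci_lo_hom <- v[2]; out$ci_hi_hom <- v[3]
    out$p_hom_class <- v[4]
  }
  out
}

#' Cochran's Q heterogeneity-by-study test
#'
#' Fits the trend model separately within each study stratum and combines
#' the per-study log odds ratios with inverse-variance weights into
#' Cochran's Q; p from a chi-square with (number of estimable strata - 1)
#' degrees of freedom. Strata where the effect is inestimable (constant
#' dosage, separation) are dropped with a warning.
#'
#' @param dosage per-sample dosage
#' @param status 0/1 case status
#' @param covars covariate data.frame or NULL (study indicators are removed
#'   automatically if present as a `study` column)
#' @param study per-sample study labels
#' @param variant_id label
#' @return one-row data.frame `variant_id`, `q`, `df`, `p_het`, `n_studies`
#' @export
heterogeneity_by_study <- function(dosage, status, covars = NULL, study,
                                   variant_id = "variant") {
  strata <- unique(study)
  if (length(strata) < 2) stop("need >= 2 studies")
  betas <- c(); ses <- c()
  for (s in strata) {
    sel <- study == s
    cv <- covars
    if (!is.null(cv)) {
      cv <- as.data.frame(cv)[sel, , drop = FALSE]
      cv$study <- NULL
      cv <- cv[, vapply(cv, function(x) length(unique(x)) > 1, TRUE),
               drop = FALSE]
      if (ncol(cv) == 0) cv <- NULL
    }
    r <- tryCatch({
      if (stats::var(dosage[sel], na.rm = TRUE) == 0) NULL
      else .logistic_fit(dosage[sel], status[sel], cv, term = variant_id)
    }, error = function(e) NULL)
    if (is.null(r)) {
      warning("study ", s, " inestimable for ", variant_id, "; dropped")
      next
    }
    betas <- c(betas, r$beta); ses <- c(ses, r$se)
  }
  k <- length(betas)
  if (k < 2) stop("fewer than 2 estimable strata")
  qs <- cochran_q(betas, ses)
  data.frame(variant_id = variant_id, q = qs$q, df = qs$df,
             p_het = qs$p, n_studies = k, stringsAsFactors = FALSE)
}

#' Cochran's Q statistic over stratum effect estimates
#'
#' Inverse-variance weighted heterogeneity statistic:
#' `Q = sum(w * (beta - beta_bar)^2)` with `w = 1 / se^2` and `beta_bar`
#' the weighted mean; p from chi-square with (k - 1) df.
#'
#' @param betas stratum log odds ratios
#' @param ses stratum standard errors
#' @return list with `q`, `df`, `p`
#' @export
cochran_q <- function(betas, ses) {
  stopifnot(length(betas) == length(ses), length(betas) >= 2)
  w <- 1 / ses^2
  bbar <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - bbar)^2)
  list(q = q, df = length(betas) - 1,
       p = stats::pchisq(q, length(betas) - 1, lower.tail = FALSE))
}
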