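#' Principal components of genotype data (global ancestry)
#'
#' Standardizes each variant by centring at twice the sample allele
#' frequency and scaling by `sqrt(2 p (1 - p))` (the usual genotype-PCA
#' normalization), mean-imputes missing dosages for the decomposition,
#' drops monomorphic variants, and returns the top-`k` sample eigenvectors
#' of the genetic covariance with their eigenvalues. The sign of each
#' eigenvector is fixed by making the first sample's coordinate
#' non-negative.
#'
#' @param dm a [dosage_matrix()]
#' @param k number of eigenvectors (default 10)
#' @return list of class `global_ancestry`: `vectors` (samples x k,
#'   zero-mean columns), `values` (all eigenvalues, descending),
#'   `k`, `n_variants_used`
#' @export
compute_pca <- function(dm, k = 10) {
  d <- dm$dosages
  n <- nrow(d)
  if (k < 1) stop("k must be >= 1")
  if (k > n - 1) stop("k exceeds the maximum rank (n samples - 1)")
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- which(p > 0 & p < 1 & !is.na(p))
  if (length(poly) == 0) stop("no polymorphic variants: degenerate input")
  x <- d[, poly, drop = FALSE]
  p <- p[poly]
  for (j in seq_along(poly)) {
    xj <- x[, j]
    xj[is.na(xj)] <- 2 * p[j]
    x[, j] <- (xj - 2 * p[j]) / sqrt(2 * p[j] * (1 - p[j]))
  }
  sv <- svd(x, nu = min(n, ncol(x)), nv = 0)
  values <- sv$d^2 / ncol(x)
  if (sum(values > 1e-12) == 0) stop("zero genetic variance: degenerate input")
  vec <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) if (vec[1, j] < 0) vec[, j] <- -vec[, j]
  rownames(vec) <- rownames(d)
  colnames(vec) <- paste0("EV", seq_len(k))
  structure(list(vectors = vec, values = values, k = k,
                 n_variants_used = length(poly)),
            class = "global_ancestry")
}

#' @export
print.global_ancestry <- function(x, ...) {
  ve <- sum(x$values[seq_len(x$k)]) / sum(x$values)
  cat(sprintf("<global_ancestry> %d samples, top %d eigenvectors (%.1f%% of variance, %d variants)\n",
              nrow(x$vectors), x$k, 100 * ve, x$n_variants_used))
  invisible(x)
}

#' Flag ancestry outliers on the leading eigenvectors
#'
#' A sample is flagged iff its coordinate on eigenvector 1 or 2 lies more
#' than `n_sd` standard deviations from that eigenvector's mean.
#'
#' @param ga a `global_ancestry` from [compute_pca()]
#' @param n_sd flagging threshold in SD units (default 4)
#' @param evs eigenvector indices examined (default 1:2)
#' @return character vector of flagged sample ids
#' @export
flag_ancestry_outliers <- function(ga, n_sd = 4, evs = 1:2) {
  v <- ga$vectors
  if (nrow(v) < 10) warning("fewer than 10 samples; outlier SDs unstable")
  evs <- evs[evs <= ncol(v)]
  flagged <- rep(FALSE, nrow(v))
  for (j in evs) {
    s <- stats::sd(v[, j])
    if (s == 0) next
    flagged <- flagged | abs(v[, j] - mean(v[, j])) / s > n_sd
  }
  rownames(v)[flagged]
}

#' Region-average local ancestry
#'
#' Arithmetic mean, per sample, of the local-ancestry estimates (expected
#' population-1 chromosome count, in \[0,2\]) at all variants whose position
#' falls within the region bounds.
#'
#' @param track samples x variants matrix of local-ancestry values
#' @param variants data.frame with `variant_id`, `pos` matching the track
#'   columns
#' @param region list or one-row data.frame with `region_name`, `start`,
#'   `end` (1-based, closed)
#' @return named numeric vector, one average per sample
#' @export
summarize_local_ancestry <- function(track, variants, region) {
  within <- variants$pos >= region$start & variants$pos <= region$end
  if (!any(within))
    stop("region ", region$region_name, " contains no local-ancestry estimates")
  rowMeans(track[, within, drop = FALSE])
}

#' Association of region-average local ancestry with case status
#'
#' Logistic regression of case status on the per-sample region-average
#' number of population-1 chromosomes, adjusted for the supplied covariates
#' (typically age, study, global eigenvectors). The OR is per
#' population-1 chromosome.
#'
#' @param la_avg per-sample region-average local ancestry
#' @param status 0/1 case status
#' @param covars data.frame of covariates (may be NULL)
#' @return one-row data.frame `or`, `ci_lo`, `ci_hi`, `beta`, `se`, `p`, `n`
#' @export
local_ancestry_association <- function(la_avg, status, covars = NULL) {
  fit <- .logistic_fit(la_avg, status, covars, term = "la_avg")
  fit
}

# Shared logistic ML fit with Wald inference on a single focal term.
# Returns a one-row data.frame; errors on separation.
.logistic_fit <- function(x, status, covars, term = "x") {
  df <- data.frame(.y = status, .x = x)
  if (!is.null(covars) && ncol(as.data.frame(covars)) > 0)
    df <- cbind(df, as.data.frame(covars))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)) > 30, na.rm = TRUE))
    stop("separation or non-convergence in logistic fit for ", term)
  co <- summary(fit)$coefficients
  if (!".x" %in% rownames(co)) stop("focal term dropped (collinear): ", term)
  beta <- co[".x", "Estimate"]; se <- co[".x", "Std. Error"]
  chisq <- (beta / se)^2
  data.frame(term = term, beta = beta, se = se, or = exp(beta),
             ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
             p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
             n = nrow(df), stringsAsFactors = FALSE)
}
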