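#' Stepwise variant selection within a region
#'
#' Forward selection with optional backward elimination: at each step every
#' remaining candidate is added to the current model in turn and the one
#' with the smallest Wald p-value enters if that p-value is below its
#' applicable threshold (`alpha_a` for index-correlated candidates,
#' `alpha_b` for novel candidates); after each entry, any selected variant
#' whose p-value has risen above its own threshold is dropped. Ties are
#' broken toward the smaller p then the lower position. Missing dosages are
#' mean-filled from typed subjects (preserving the sample size) when
#' `mean_fill = TRUE`. Candidates perfectly collinear (r-squared 1) with an
#' already selected variant are skipped with a reason.
#'
#' @param dm a [dosage_matrix()]
#' @param candidates character vector of candidate variant ids
#' @param status 0/1 case status
#' @param covars covariate data.frame or NULL (age, study, global ancestry,
#'   region-average local ancestry)
#' @param alpha_a threshold for index-correlated candidates (default 0.004)
#' @param alpha_b threshold for novel candidates (default 5.6e-6)
#' @param correlated_ids candidates belonging to the index-correlated set
#'   (the rest are treated as novel); default: all candidates correlated
#' @param mean_fill mean-fill missing dosages (default TRUE)
#' @param backward drop selected variants whose p rises above their alpha
#'   after each entry (default TRUE)
#' @return list of class `stepwise_result`: `selected` (ids in entry
#'   order), `entry_p`, `final_model` (per-variant beta/se/or/ci/p in the
#'   final joint fit), `skipped` (id + reason), `alpha_used` (named)
#' @export
stepwise_select <- function(dm, candidates, status, covars = NULL,
                            alpha_a = 0.004, alpha_b = 5.6e-6,
                            correlated_ids = candidates,
                            mean_fill = TRUE, backward = TRUE) {
  ids <- as.character(candidates)
  idx <- match(ids, variant_ids(dm))
  if (anyNA(idx)) stop("unknown candidates: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  x <- dm$dosages[, idx, drop = FALSE]
  pos <- stats::setNames(dm$variants$pos[idx], ids)
  if (mean_fill) {
    for (j in seq_len(ncol(x))) {
      mis <- is.na(x[, j])
      if (any(mis)) x[mis, j] <- mean(x[!mis, j])
    }
  }
  alpha <- stats::setNames(ifelse(ids %in% correlated_ids, alpha_a, alpha_b),
                           ids)
  cv <- if (is.null(covars)) NULL else as.data.frame(covars)
  selected <- character(0)
  entry_p <- numeric(0)
  skipped <- data.frame(variant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  # Wald p for each column of `terms` in a joint logistic fit
  joint_fit <- function(sel) {
    df <- data.frame(.y = status)
    for (v in sel) df[[v]] <- x[, v]
    if (!is.null(cv)) df <- cbind(df, cv)
    df <- df[stats::complete.cases(df), , drop = FALSE]
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    co <- summary(fit)$coefficients
    co
  }
  term_name <- function(v) if (make.names(v) == v) v else paste0("`", v, "`")
  repeat {
    remaining <- setdiff(ids, c(selected, skipped$variant_id))
    if (!length(remaining)) break
    best_p <- Inf; best_v <- NULL
    for (v in remaining) {
      if (length(selected)) {
        r2 <- vapply(selected, function(s) pairwise_r2(x[, v], x[, s]),
                     numeric(1))
        if (any(!is.na(r2) & r2 >= 1 - 1e-12)) {
          skipped <- rbind(skipped,
                           data.frame(variant_id = v, reason = "collinear"))
          next
        }
      }
      co <- tryCatch(joint_fit(c(selected, v)), error = function(e) NULL)
      rn <- make.names(v)
      if (is.null(co) || !rn %in% rownames(co)) next
      pv <- stats::pchisq((co[rn, "Estimate"] / co[rn, "Std. Error"])^2,
                          1, lower.tail = FALSE)
      if (pv < best_p - 1e-15 ||
          (abs(pv - best_p) <= 1e-15 && !is.null(best_v) &&
             pos[v] < pos[best_v])) {
        best_p <- pv; best_v <- v
      }
    }
    if (is.null(best_v) || best_p >= alpha[best_v]) break
    selected <- c(selected, best_v)
    entry_p <- c(entry_p, best_p)
    if (backward && length(selected) > 1) {
      repeat {
        co <- joint_fit(selected)
        pv <- vapply(selected, function(v) {
          rn <- make.names(v)
          stats::pchisq((co[rn, "Estimate"] / co[rn, "Std. Error"])^2, 1,
                        lower.tail = FALSE)
        }, numeric(1))
        worst <- which(pv > alpha[selected])
        if (!length(worst)) break
        drop_v <- selected[worst[which.max(pv[worst])]]
        keepers <- selected != drop_v
        entry_p <- entry_p[keepers]
        selected <- selected[keepers]
        if (length(selected) <= 1) break
      }
    }
  }
  final <- NULL
  if (length(selected)) {
    co <- joint_fit(selected)
    rows <- lapply(selected, function(v) {
      rn <- make.names(v)
      b <- co[rn, "Estimate"]; s <- co[rn, "Std. Error"]
      data.frame(variant_id = v, beta = b, se = s, or = exp(b),
                 ci_lo = exp(b - 1.96 * s), ci_hi = exp(b + 1.96 * s),
                 p = stats::pchisq((b / s)^2, 1, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    })
    final <- do.call(rbind, rows)
  }
  structure(list(selected = selected, entry_p = entry_p,
                 final_model = final, skipped = skipped,
                 alpha_used = alpha,
                 partition = list(correlated = intersect(ids, correlated_ids),
                                  novel = setdiff(ids, correlated_ids))),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result> %d selected", length(x$selected)))
  if (length(x$selected))
    cat(":", paste(x$selected, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Multi-signal scan of a dense region (8q24-style)
#'
#' Restricts the candidate pool to variants with a single-variant trend p
#' below `entry_p`, then runs the stepwise machinery with a single
#' retention threshold `retain_p` (default 0.001) for every candidate.
#'
#' @param dm a [dosage_matrix()]
#' @param status 0/1 case status
#' @param covars covariate data.frame or NULL
#' @param entry_p single-variant pool threshold (default 0.05)
#' @param retain_p multivariate retention threshold (default 0.001)
#' @param window optional data.frame (`start`, `end`) restricting positions
#' @param rsq_min imputation-quality filter before testing (default 0.3)
#' @param ... passed to [stepwise_select()]
#' @return a `stepwise_result`, with the pool recorded in `$pool`
#' @export
region_scan_multi <- function(dm, status, covars = NULL, entry_p = 0.05,
                              retain_p = 0.001, window = NULL,
                              rsq_min = 0.3, ...) {
  v <- dm$variants
  keep <- v$typed | (!is.na(v$rsq) & v$rsq >= rsq_min)
  if (!is.null(window)) {
    inside <- rep(FALSE, nrow(v))
    for (w in seq_len(nrow(window)))
      inside <- inside | (v$pos >= window$start[w] & v$pos <= window$end[w])
    keep <- keep & inside
  }
  sub <- subset_dosage(dm, variants = which(keep))
  scan <- assoc_scan(sub, status, covars, rsq_min = 0)
  pool <- scan$variant_id[!is.na(scan$p_trend) & scan$p_trend < entry_p]
  if (!length(pool)) {
    res <- structure(list(selected = character(0), entry_p = numeric(0),
                          final_model = NULL,
                          skipped = data.frame(variant_id = character(0),
                                               reason = character(0)),
                          alpha_used = numeric(0),
                          partition = list(correlated = character(0),
                                           novel = character(0))),
                     class = "stepwise_result")
    res$pool <- character(0)
    return(res)
  }
  res <- stepwise_select(sub, pool, status, covars,
                         alpha_a = retain_p, alpha_b = retain_p, ...)
  res$pool <- pool
  res
}

#' Conditional association test
#'
#' Trend test of a variant with the dosages of a conditioning set included
#' as covariates. With an empty conditioning set this reduces exactly to
#' [trend_test()].
#'
#' @param dm a [dosage_matrix()]
#' @param variant_id tested variant
#' @param conditioning_ids variant ids conditioned on (excluding the
#'   tested variant)
#' @param status 0/1 case status
#' @param covars covariate data.frame or NULL
#' @return one-row data.frame as [trend_test()], plus `n_conditioned`
#' @export
conditional_test <- function(dm, variant_id, conditioning_ids, status,
                             covars = NULL) {
  conditioning_ids <- setdiff(conditioning_ids, variant_id)
  # a perfect proxy in the conditioning set leaves no residual information
  for (v in conditioning_ids) {
    r2 <- pairwise_r2(dm$dosages[, variant_id], dm$dosages[, v])
    if (!is.na(r2) && r2 >= 1 - 1e-12) {
      out <- trend_test(rep(0, length(status)), status,
                        variant_id = variant_id)
      out$beta <- 0; out$p_trend <- 1; out$flag <- "collinear"
      out$n_conditioned <- length(conditioning_ids)
      return(out)
    }
  }
  cv <- if (is.null(covars)) data.frame(row.names = seq_along(status))
        else as.data.frame(covars)
  for (v in conditioning_ids)
    cv[[paste0("cond_", v)]] <- dm$dosages[, v]
  if (ncol(cv) == 0) cv <- NULL
  out <- trend_test(dm$dosages[, variant_id], status, cv,
                    variant_id = variant_id)
  out$n_conditioned <- length(conditioning_ids)
  out
}

#' Dosage variance explained by other variants
#'
#' Coefficient of determination from a least-squares regression of the
#' variant's dosage on the other variants' dosages (complete cases);
#' rank-deficient designs are handled by the pseudo-inverse and the result
#' clipped to \[0,1\].
#'
#' @param dm a [dosage_matrix()]
#' @param variant_id focal variant
#' @param other_ids explanatory variants (>= 1)
#' @return R-squared in \[0,1\]
#' @export
variance_explained_by_others <- function(dm, variant_id, other_ids) {
  other_ids <- setdiff(other_ids, variant_id)
  if (length(other_ids) < 1) stop("need >= 1 other variant")
  y <- dm$dosages[, variant_id]
  x <- dm$dosages[, other_ids, drop = FALSE]
  ok <- stats::complete.cases(cbind(y, x))
  y <- y[ok]; x <- x[ok, , drop = FALSE]
  if (stats::var(y) == 0) return(0)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  # pseudo-inverse least squares (robust to collinear columns)
  sv <- svd(xc)
  keep <- sv$d > max(sv$d) * 1e-10
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], yc)) / sv$d[keep])
  fitted <- xc %*% coef
  r2 <- sum(fitted^2) / sum(yc^2)
  min(max(r2, 0), 1)
}
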