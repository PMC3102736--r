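# Shared fixture builders: all fixtures are constructed in code.

# Wrap a plain samples x variants matrix as a dosage_matrix.
dm_from_matrix <- function(mat, pos = NULL, typed = TRUE, rsq = NA_real_,
                           chrom = "1") {
  m <- ncol(mat)
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("v%03d", seq_len(m))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("S%03d", seq_len(nrow(mat)))
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = m)
  v <- data.frame(variant_id = colnames(mat), chrom = chrom, pos = pos,
                  risk_allele = "A", other_allele = "G",
                  typed = rep_len(typed, m), rsq = rep_len(rsq, m),
                  stringsAsFactors = FALSE)
  dosage_matrix(mat, v)
}

# Independent-oracle logistic ML via general-purpose optimization.
optim_logistic <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  nll <- function(b) {
    eta <- X %*% b
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  grad <- function(b) {
    p <- 1 / (1 + exp(-X %*% b))
    as.numeric(crossprod(X, p - y))
  }
  fit <- optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  # Newton polish to machine precision
  b <- fit$par
  for (it in 1:50) {
    p <- as.numeric(1 / (1 + exp(-X %*% b)))
    step <- solve(crossprod(X, X * (p * (1 - p))), crossprod(X, p - y))
    b <- b - as.numeric(step)
    if (max(abs(step)) < 1e-12) break
  }
  b
}

# Brute-force minimum set cover over all subsets (<= 12 elements).
brute_min_cover <- function(cov) {
  n <- nrow(cov)
  best <- n
  best_set <- seq_len(n)
  for (s in 1:(2^n - 1)) {
    sel <- which(as.logical(bitwAnd(s, 2^(0:(n - 1)))))
    if (length(sel) >= best) next
    if (all(colSums(cov[sel, , drop = FALSE]) > 0)) {
      best <- length(sel)
      best_set <- sel
    }
  }
  list(size = best, set = best_set)
}

# 10-variant toy panel with engineered failures: v001/v002 low call rate,
# v003 MAF below 1%; v004 sits exactly at MAF = 0.01 (retained: the rule is
# strictly "< 1%").
toy_panel <- function() {
  set.seed(7)
  n <- 100
  mat <- sapply(1:10, function(j) rbinom(n, 2, 0.3)) * 1.0
  mat[1:10, 1] <- NA           # call rate 0.90
  mat[1:6, 2] <- NA            # call rate 0.94
  mat[, 3] <- 0; mat[1, 3] <- 1          # MAF 0.005
  mat[, 4] <- 0; mat[1:2, 4] <- 1        # MAF exactly 0.01
  dm_from_matrix(mat)
}
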