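#' Dosage matrix container
#'
#' Samples-by-variants risk-allele dosages in \[0, 2\] (NA = missing call),
#' with per-variant metadata: genomic coordinates, allele labels, whether the
#' variant was directly typed, and the imputation quality (Rsq, defined as
#' observed dosage variance over the variance expected under Hardy-Weinberg)
#' for imputed variants.
#'
#' @param dosages numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids).
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `risk_allele`, `other_allele`, `typed` (logical), `rsq`
#'   (numeric, `NA` for typed variants). Row order must match the columns
#'   of `dosages`.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), is.data.frame(variants))
  req <- c("variant_id", "chrom", "pos", "risk_allele", "other_allele",
           "typed", "rsq")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols) > 0L)
    stop("variants table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns (", ncol(dosages), ") != variant rows (",
         nrow(variants), ")")
  if (ncol(dosages) > 0) {
    if (is.null(colnames(dosages))) colnames(dosages) <- variants$variant_id
    if (!identical(colnames(dosages), as.character(variants$variant_id)))
      stop("dosage colnames do not match variant ids")
  }
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  if (length(dosages) && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages outside [0, 2]")
  }
  structure(list(dosages = dosages, variants = variants),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d samples x %d variants (%d typed, %d imputed)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$variants$typed),
              sum(!x$variants$typed)))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Sample ids of a dosage matrix
#' @param dm a `dosage_matrix`
#' @return character vector of sample ids
#' @export
sample_ids <- function(dm) rownames(dm$dosages)

#' Variant ids of a dosage matrix
#' @param dm a `dosage_matrix`
#' @return character vector of variant ids
#' @export
variant_ids <- function(dm) as.character(dm$variants$variant_id)

#' Subset a dosage matrix
#'
#' @param dm a `dosage_matrix`
#' @param samples sample ids (or indices) to keep; NULL keeps all
#' @param variants variant ids (or indices) to keep; NULL keeps all
#' @return a `dosage_matrix`
#' @export
subset_dosage <- function(dm, samples = NULL, variants = NULL) {
  d <- dm$dosages
  v <- dm$variants
  if (!is.null(samples)) {
    if (is.character(samples)) {
      miss <- setdiff(samples, rownames(d))
      if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    }
    d <- d[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    if (is.character(variants)) {
      idx <- match(variants, v$variant_id)
      if (anyNA(idx)) stop("unknown variants: ",
                           paste(variants[is.na(idx)], collapse = ", "))
    } else idx <- variants
    d <- d[, idx, drop = FALSE]
    v <- v[idx, , drop = FALSE]
    rownames(v) <- NULL
  }
  dosage_matrix(d, v)
}

#' Per-variant risk-allele frequency
#'
#' Computed from non-missing dosages (dosage mean / 2).
#'
#' @param dm a `dosage_matrix`
#' @param samples optional sample ids to restrict to (e.g. controls)
#' @return named numeric vector of allele frequencies
#' @export
allele_freq <- function(dm, samples = NULL) {
  d <- dm$dosages
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' Minor allele frequency per variant
#' @param dm a `dosage_matrix`
#' @param samples optional sample subset
#' @return named numeric vector, `pmin(p, 1 - p)`
#' @export
maf <- function(dm, samples = NULL) {
  p <- allele_freq(dm, samples)
  pmin(p, 1 - p)
}
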