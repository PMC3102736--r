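#' Pairwise r-squared between two dosage vectors
#'
#' Squared Pearson correlation over samples with both values non-missing
#' (composite LD; valid for unphased and imputed data).
#'
#' @param a,b dosage vectors
#' @return r-squared in \[0,1\], or NA if either vector is constant or
#'   fewer than 2 complete pairs exist
#' @export
pairwise_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])^2
}

#' Pairwise r-squared matrix
#'
#' @param dm a [dosage_matrix()] (or plain dosage matrix)
#' @param variants optional variant ids to restrict to
#' @return symmetric matrix of r-squared values with unit diagonal for
#'   polymorphic variants
#' @export
ld_matrix <- function(dm, variants = NULL) {
  d <- if (inherits(dm, "dosage_matrix")) dm$dosages else dm
  if (!is.null(variants)) d <- d[, variants, drop = FALSE]
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
  diag(r)[!is.na(diag(r))] <- 1
  r
}

#' D-prime between two typed variants
#'
#' Haplotype frequencies are estimated from the 3x3 genotype table by
#' expectation-maximization (the only ambiguous class is the double
#' heterozygote); `D' = |D| / D_max`.
#'
#' @param ga,gb integer genotype vectors (0/1/2, NA = missing)
#' @param max_iter,tol EM controls
#' @return D-prime in \[0,1\], or NA for monomorphic input
#' @export
dprime <- function(ga, gb, max_iter = 200, tol = 1e-10) {
  ok <- !is.na(ga) & !is.na(gb)
  ga <- round(ga[ok]); gb <- round(gb[ok])
  n <- length(ga)
  if (n < 2) return(NA_real_)
  pa <- mean(ga) / 2; pb <- mean(gb) / 2
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) return(NA_real_)
  h <- .em_haplotypes(ga, gb, max_iter = max_iter, tol = tol)
  .dprime_from_h(h)
}

# EM haplotype frequencies (h11, h10, h01, h00) for two biallelic loci from
# unphased genotypes. Alleles coded 1 (risk) / 0.
.em_haplotypes <- function(ga, gb, max_iter = 200, tol = 1e-10) {
  n <- length(ga)
  # counts of unambiguous haplotypes contributed by each genotype combo
  tab <- table(factor(ga, 0:2), factor(gb, 0:2))
  pa <- mean(ga) / 2; pb <- mean(gb) / 2
  # initialize at linkage equilibrium
  h <- c(h11 = pa * pb, h10 = pa * (1 - pb), h01 = (1 - pa) * pb,
         h00 = (1 - pa) * (1 - pb))
  n_dh <- tab["1", "1"]           # double heterozygotes
  # fixed haplotype counts from unambiguous genotypes
  fixed <- c(h11 = 2 * tab["2", "2"] + tab["2", "1"] + tab["1", "2"],
             h10 = 2 * tab["2", "0"] + tab["2", "1"] + tab["1", "0"],
             h01 = 2 * tab["0", "2"] + tab["0", "1"] + tab["1", "2"],
             h00 = 2 * tab["0", "0"] + tab["0", "1"] + tab["1", "0"])
  total <- 2 * n
  for (it in seq_len(max_iter)) {
    # E: split double hets between (11,00) and (10,01) phases
    p_cis <- h["h11"] * h["h00"]
    p_trans <- h["h10"] * h["h01"]
    w <- if (p_cis + p_trans == 0) 0.5 else p_cis / (p_cis + p_trans)
    cnt <- fixed + n_dh * c(w, 1 - w, 1 - w, w)
    h_new <- cnt / total
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  h
}

.dprime_from_h <- function(h) {
  pa <- h["h11"] + h["h10"]; pb <- h["h11"] + h["h01"]
  D <- h["h11"] - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  if (dmax <= 0) return(NA_real_)
  unname(abs(D) / dmax)
}

#' Infer simple LD blocks from adjacent-pair D-prime
#'
#' Chains consecutive variants whose adjacent-pair D-prime meets the
#' threshold into blocks; used to decide whether a fine-mapping window must
#' be extended beyond its flank to cover a containing block.
#'
#' @param dm a [dosage_matrix()] of typed variants (positions sorted)
#' @param threshold D-prime threshold for chaining (default 0.8)
#' @return data.frame `start`, `end` (positions, 1-based closed) and
#'   `first`, `last` (variant indices), one row per block of >= 2 variants
#' @export
infer_ld_blocks <- function(dm, threshold = 0.8) {
  d <- dm$dosages
  pos <- dm$variants$pos
  m <- ncol(d)
  if (m < 2) return(data.frame(start = integer(0), end = integer(0),
                               first = integer(0), last = integer(0)))
  dp <- vapply(seq_len(m - 1), function(j) {
    v <- dprime(d[, j], d[, j + 1])
    if (is.na(v)) 0 else v
  }, numeric(1))
  linked <- dp >= threshold
  blocks <- list()
  j <- 1L
  while (j <= m - 1L) {
    if (linked[j]) {
      k <- j
      while (k <= m - 1L && linked[k]) k <- k + 1L
      blocks[[length(blocks) + 1L]] <- c(j, k)
      j <- k + 1L
    } else j <- j + 1L
  }
  if (!length(blocks)) return(data.frame(start = integer(0),
                                         end = integer(0),
                                         first = integer(0),
                                         last = integer(0)))
  do.call(rbind, lapply(blocks, function(b)
    data.frame(start = pos[b[1]], end = pos[b[2]],
               first = b[1], last = b[2])))
}

#' Build a fine-mapping window around index variants
#'
#' Takes the union of `pos +/- flank` intervals around each index variant;
#' if an index variant lies inside a supplied LD block that extends beyond
#' the flanked interval, the window is extended to cover the whole block.
#' Overlapping windows are merged. Intervals are 1-based and closed.
#'
#' @param index_pos positions of the index variants
#' @param flank flank size in bp (default 250000)
#' @param blocks optional data.frame of LD blocks (`start`, `end`), e.g.
#'   from [infer_ld_blocks()]
#' @return data.frame `start`, `end`, one row per merged window
#' @export
build_window <- function(index_pos, flank = 250000, blocks = NULL) {
  # half-open flank convention: (pos - flank, pos + flank] as a closed
  # 1-based interval of exactly 2 * flank positions
  iv <- data.frame(start = pmax(1, index_pos - flank + 1),
                   end = index_pos + flank)
  if (!is.null(blocks) && nrow(blocks) > 0) {
    for (i in seq_along(index_pos)) {
      inb <- blocks$start <= index_pos[i] & blocks$end >= index_pos[i]
      if (any(inb)) {
        iv$start[i] <- min(iv$start[i], min(blocks$start[inb]))
        iv$end[i] <- max(iv$end[i], max(blocks$end[inb]))
      }
    }
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv$start[i] <= merged$end[last] + 1) {
      merged$end[last] <- max(merged$end[last], iv$end[i])
    } else merged <- rbind(merged, iv[i, ])
  }
  rownames(merged) <- NULL
  merged
}

#' Index-correlated variant set
#'
#' All variants inside the window whose r-squared with any index variant
#' meets `r2_index`, computed on the designated reference samples (all
#' samples by default; a haplotype reference panel can be supplied as a
#' plain dosage matrix instead).
#'
#' @param dm a [dosage_matrix()] or plain samples x variants matrix used as
#'   the LD reference
#' @param variants variant metadata (`variant_id`, `pos`); taken from `dm`
#'   when it is a `dosage_matrix`
#' @param index_ids ids of the index variants
#' @param window data.frame (`start`, `end`) from [build_window()];
#'   NULL = no positional restriction
#' @param r2_index inclusion threshold (default 0.2, inclusive)
#' @return character vector of variant ids (always includes any index
#'   variant inside the window)
#' @export
correlated_set <- function(dm, index_ids, window = NULL, r2_index = 0.2,
                           variants = NULL) {
  if (inherits(dm, "dosage_matrix")) {
    variants <- dm$variants
    d <- dm$dosages
  } else d <- dm
  ids <- as.character(variants$variant_id)
  inside <- rep(TRUE, length(ids))
  if (!is.null(window)) {
    inside <- rep(FALSE, length(ids))
    for (w in seq_len(nrow(window)))
      inside <- inside | (variants$pos >= window$start[w] &
                            variants$pos <= window$end[w])
  }
  out <- character(0)
  idx_cols <- match(index_ids, ids)
  if (anyNA(idx_cols)) stop("index variants not found: ",
                            paste(index_ids[is.na(idx_cols)], collapse = ", "))
  for (j in which(inside)) {
    r2 <- vapply(idx_cols, function(i) pairwise_r2(d[, j], d[, i]),
                 numeric(1))
    if (any(!is.na(r2) & r2 >= r2_index) || ids[j] %in% index_ids)
      out <- c(out, ids[j])
  }
  out
}

#' Greedy tag-SNP selection
#'
#' Greedy maximum coverage: repeatedly pick the variant covering the most
#' uncovered set members at `r2 >= r2_tag` (a variant covers itself), ties
#' broken toward the lowest genomic position, until every member is
#' covered.
#'
#' @param ids variant ids of the set to cover
#' @param ld symmetric r-squared matrix over (at least) `ids`
#' @param r2_tag coverage threshold (default 0.8, inclusive)
#' @param pos named positions for tie-breaking (default: order of `ids`)
#' @return character vector of tag ids
#' @export
greedy_tags <- function(ids, ld, r2_tag = 0.8, pos = NULL) {
  if (length(ids) == 0) return(character(0))
  if (is.null(pos)) pos <- stats::setNames(seq_along(ids), ids)
  cov <- ld[ids, ids, drop = FALSE] >= r2_tag
  cov[is.na(cov)] <- FALSE
  diag(cov) <- TRUE
  uncovered <- rep(TRUE, length(ids))
  names(uncovered) <- ids
  tags <- character(0)
  while (any(uncovered)) {
    gain <- rowSums(cov[, uncovered, drop = FALSE])
    best <- which(gain == max(gain))
    pick <- names(best)[order(pos[names(best)])][1]
    tags <- c(tags, pick)
    uncovered <- uncovered & !cov[pick, ]
  }
  tags
}

#' Derive the two-tier significance thresholds from tag counts
#'
#' The lenient per-region threshold `alpha_a` corrects for the effective
#' number of independent tests among index-correlated variants: 0.05
#' divided by the cross-region average tag count (default mode, matching a
#' single global threshold of ~0.004), or per region's own count when
#' `mode = "per_region"`. The stringent threshold for novel signals is
#' `alpha_b = 0.05 / total tags across all regions`.
#'
#' @param tag_counts named per-region tag counts for the correlated sets
#' @param total_tags total tag count across all regions (all common
#'   alleles)
#' @param mode `"global_average"` (default) or `"per_region"` for alpha_a
#' @return list with `alpha_a` (named per region), `alpha_b`, and the
#'   inputs used
#' @export
derive_alphas <- function(tag_counts, total_tags,
                          mode = c("global_average", "per_region")) {
  mode <- match.arg(mode)
  if (any(tag_counts < 1) || total_tags < 1) stop("tag counts must be >= 1")
  alpha_a <- if (mode == "global_average")
    stats::setNames(rep(0.05 / mean(tag_counts), length(tag_counts)),
                    names(tag_counts))
  else 0.05 / tag_counts
  list(alpha_a = alpha_a, alpha_b = 0.05 / total_tags,
       tag_counts = tag_counts, total_tags = total_tags, mode = mode)
}
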