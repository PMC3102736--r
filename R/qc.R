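#' Sample call-rate filter
#'
#' Removes samples whose fraction of non-missing calls across typed variants
#' falls below `call_rate_min`. Applied before variant filters, mirroring the
#' usual exclusion order (samples first).
#'
#' @param dm a [dosage_matrix()]
#' @param call_rate_min minimum per-sample call rate (default 0.95)
#' @return list with `dosages` (filtered) and `report` (entity, reason, value)
#' @export
filter_samples <- function(dm, call_rate_min = 0.95) {
  typed <- dm$variants$typed
  d <- dm$dosages[, typed, drop = FALSE]
  if (ncol(d) == 0) {
    return(list(dosages = dm, report = .qc_report()))
  }
  cr <- rowMeans(!is.na(d))
  bad <- which(cr < call_rate_min)
  rep <- .qc_report(entity = rownames(dm$dosages)[bad],
                    reason = rep("call_rate", length(bad)),
                    value = cr[bad])
  keep <- setdiff(seq_len(nrow(dm$dosages)), bad)
  list(dosages = subset_dosage(dm, samples = keep), report = rep)
}

.qc_report <- function(entity = character(0), reason = character(0),
                       value = numeric(0)) {
  data.frame(entity = as.character(entity), reason = as.character(reason),
             value = as.numeric(value), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Variant quality-control filters
#'
#' Removes variants failing any of: call rate below `call_rate_min`
#' (typed variants; imputed dosages have no missing calls by construction),
#' minor allele frequency strictly below `maf_min` (computed on non-missing
#' calls), or more than `max_qc_mismatch` discordant genotype calls across
#' the supplied replicate pairs. Each removal cites the first rule that
#' triggered, in the order call rate, MAF, QC mismatch.
#'
#' @param dm a [dosage_matrix()]
#' @param call_rate_min minimum variant call rate (default 0.95)
#' @param maf_min MAF threshold; variants with MAF strictly below are
#'   removed (default 0.01, i.e. "< 1%")
#' @param replicate_pairs optional data.frame (`id1`, `id2`) of replicate
#'   sample pairs for the mismatch rule
#' @param max_qc_mismatch maximum tolerated discordant calls per variant
#'   across replicate pairs (default 1, i.e. "> 1 mismatch" removed)
#' @return list with `dosages` (filtered) and `report`
#' @export
filter_variants <- function(dm, call_rate_min = 0.95, maf_min = 0.01,
                            replicate_pairs = NULL, max_qc_mismatch = 1L) {
  if (nrow(dm$dosages) == 0 || ncol(dm$dosages) == 0)
    stop("empty dosage matrix")
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1)
  d <- dm$dosages
  cr <- colMeans(!is.na(d))
  mf <- maf(dm)
  mism <- rep(0L, ncol(d))
  if (!is.null(replicate_pairs) && nrow(replicate_pairs) > 0) {
    for (k in seq_len(nrow(replicate_pairs))) {
      g1 <- d[replicate_pairs$id1[k], ]
      g2 <- d[replicate_pairs$id2[k], ]
      cmp <- !is.na(g1) & !is.na(g2)
      mism <- mism + as.integer(cmp & (round(g1) != round(g2)))
    }
  }
  reason <- rep(NA_character_, ncol(d))
  value <- rep(NA_real_, ncol(d))
  hit <- function(cond, why, val) {
    new <- cond & is.na(reason)
    reason[new] <<- why
    value[new] <<- val[new]
  }
  hit(cr < call_rate_min, "call_rate", cr)
  hit(!is.na(mf) & mf < maf_min, "maf", mf)
  hit(mism > max_qc_mismatch, "qc_mismatch", as.numeric(mism))
  bad <- which(!is.na(reason))
  rep <- .qc_report(entity = variant_ids(dm)[bad], reason = reason[bad],
                    value = value[bad])
  keep <- setdiff(seq_len(ncol(d)), bad)
  list(dosages = subset_dosage(dm, variants = keep), report = rep)
}

#' Replicate genotype concordance
#'
#' Fraction of matching non-missing integer genotype calls between each
#' replicate pair, over typed variants. Pairs with no comparable calls get
#' `NA`.
#'
#' @param dm a [dosage_matrix()]
#' @param pairs data.frame with `id1`, `id2`
#' @return data.frame `id1`, `id2`, `n_compared`, `concordance`
#' @export
replicate_concordance <- function(dm, pairs) {
  miss <- setdiff(c(pairs$id1, pairs$id2), sample_ids(dm))
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  typed <- dm$variants$typed
  d <- dm$dosages[, typed, drop = FALSE]
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    g1 <- round(d[pairs$id1[k], ]); g2 <- round(d[pairs$id2[k], ])
    cmp <- !is.na(g1) & !is.na(g2)
    n <- sum(cmp)
    data.frame(id1 = pairs$id1[k], id2 = pairs$id2[k], n_compared = n,
               concordance = if (n == 0) NA_real_ else
                 sum(g1[cmp] == g2[cmp]) / n)
  })
  do.call(rbind, out)
}

#' Method-of-moments IBD estimation for a sample pair
#'
#' Estimates the probabilities (Z0, Z1, Z2) that the pair shares 0, 1 or 2
#' alleles identical by descent, from identity-by-state counts over typed,
#' jointly non-missing, polymorphic variants and sample allele frequencies.
#' The moment solve inverts the expected IBS-given-IBD distribution
#' variant by variant; components are clipped to \[0,1\] and renormalized.
#' Frequencies computed from the full sample (cases included) unless
#' supplied.
#'
#' @param dm a [dosage_matrix()]
#' @param pair character vector of two sample ids
#' @param freqs optional named per-variant allele frequencies to use
#' @param min_variants warn below this many informative variants (default
#'   1000)
#' @return list of class `ibd_estimate` with `id1`, `id2`, `z` (length-3),
#'   `n_variants`
#' @export
estimate_ibd <- function(dm, pair, freqs = NULL, min_variants = 1000L) {
  stopifnot(length(pair) == 2L)
  typed <- dm$variants$typed
  d <- dm$dosages[, typed, drop = FALSE]
  if (is.null(freqs)) freqs <- colMeans(d, na.rm = TRUE) / 2
  else freqs <- freqs[colnames(d)]
  g1 <- round(d[pair[1], ]); g2 <- round(d[pair[2], ])
  ok <- !is.na(g1) & !is.na(g2) & !is.na(freqs) & freqs > 0 & freqs < 1
  if (!any(ok)) stop("no overlapping informative calls for pair ",
                     pair[1], " / ", pair[2])
  if (sum(ok) < min_variants)
    warning("only ", sum(ok), " informative variants for IBD estimation")
  g1 <- g1[ok]; g2 <- g2[ok]; p <- freqs[ok]; q <- 1 - p
  ibs <- 2L - abs(g1 - g2)
  ibs[(g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0)] <- 0L
  n0 <- sum(ibs == 0L); n1 <- sum(ibs == 1L); n2 <- sum(ibs == 2L)
  # expected P(IBS = i | IBD = j) summed over variants
  e00 <- sum(2 * p^2 * q^2)
  e10 <- sum(4 * p^3 * q + 4 * p * q^3)
  e20 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e11 <- sum(2 * p^2 * q + 2 * p * q^2)
  e21 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  e22 <- length(p)
  z0 <- n0 / e00
  z1 <- (n1 - z0 * e10) / e11
  z2 <- (n2 - z0 * e20 - z1 * e21) / e22
  z <- pmin(pmax(c(z0, z1, z2), 0), 1)
  z <- z / sum(z)
  structure(list(id1 = pair[1], id2 = pair[2], z = z,
                 n_variants = length(p)), class = "ibd_estimate")
}

#' @export
print.ibd_estimate <- function(x, ...) {
  cat(sprintf("<ibd_estimate> %s / %s: Z = (%.3f, %.3f, %.3f) on %d variants\n",
              x$id1, x$id2, x$z[1], x$z[2], x$z[3], x$n_variants))
  invisible(x)
}

# Expected Z vectors per relationship.
.rel_expected <- function() {
  rbind(MZ = c(0, 0, 1),
        `parent-offspring` = c(0, 1, 0),
        `full-sibling` = c(0.25, 0.5, 0.25),
        `half-sibling` = c(0.5, 0.5, 0))
}

#' Classify a relationship from an IBD Z vector
#'
#' A relationship label is assigned iff every component of the observed Z
#' vector lies within `sd` of that relationship's expected vector
#' (MZ (0,0,1); parent-offspring (0,1,0); full-sibling (0.25,0.5,0.25);
#' half-sibling (0.5,0.5,0)). If no relationship matches, "unrelated"; if
#' several match, the one with the smallest Euclidean distance wins.
#'
#' @param estimate an `ibd_estimate` or numeric length-3 Z vector
#' @param sd per-component tolerance (default 0.1)
#' @return character label
#' @export
classify_relationship <- function(estimate, sd = 0.1) {
  z <- if (inherits(estimate, "ibd_estimate")) estimate$z else estimate
  stopifnot(length(z) == 3L)
  exp <- .rel_expected()
  within <- apply(exp, 1, function(e) all(abs(z - e) <= sd))
  if (!any(within)) return("unrelated")
  cand <- rownames(exp)[within]
  if (length(cand) == 1L) return(cand)
  dist <- apply(exp[cand, , drop = FALSE], 1,
                function(e) sqrt(sum((z - e)^2)))
  cand[which.min(dist)]
}

#' Prune related samples from a pair graph
#'
#' Iteratively removes the sample connected to the most related pairs until
#' no pairs remain; degree ties (including isolated pairs, where both
#' members have degree 1) are resolved by a seeded random choice.
#'
#' @param pairs data.frame with `id1`, `id2` (related pairs)
#' @param seed integer seed for the tie-breaking RNG
#' @return character vector of sample ids to remove
#' @export
prune_related <- function(pairs, seed = 1L) {
  if (is.null(pairs) || nrow(pairs) == 0) return(character(0))
  edges <- unique(data.frame(
    id1 = pmin(as.character(pairs$id1), as.character(pairs$id2)),
    id2 = pmax(as.character(pairs$id1), as.character(pairs$id2)),
    stringsAsFactors = FALSE))
  rng <- .seeded_rng(seed)
  removed <- character(0)
  while (nrow(edges) > 0) {
    deg <- table(c(edges$id1, edges$id2))
    top <- names(deg)[deg == max(deg)]
    pick <- if (length(top) == 1L) top else top[rng(length(top))]
    removed <- c(removed, pick)
    edges <- edges[edges$id1 != pick & edges$id2 != pick, , drop = FALSE]
  }
  removed
}

# Local RNG stream (Park-Miller in double arithmetic) that does not disturb
# the global seed.
.seeded_rng <- function(seed) {
  state <- as.numeric(seed) %% 2147483646 + 1
  function(n) {
    state <<- (state * 16807) %% 2147483647
    as.integer(state %% n) + 1L
  }
}

#' Full relatedness screen over all sample pairs
#'
#' Estimates IBD for every pair (or a supplied candidate list), classifies
#' relationships, and returns the related pairs with labels.
#'
#' @param dm a [dosage_matrix()]
#' @param candidate_pairs optional data.frame (`id1`, `id2`) limiting the
#'   pairs examined; all pairs when NULL
#' @param sd classification tolerance, see [classify_relationship()]
#' @return data.frame `id1`, `id2`, `z0`, `z1`, `z2`, `label`
#' @export
relatedness_screen <- function(dm, candidate_pairs = NULL, sd = 0.1) {
  ids <- sample_ids(dm)
  if (is.null(candidate_pairs)) {
    cmb <- utils::combn(ids, 2)
    candidate_pairs <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
                                  stringsAsFactors = FALSE)
  }
  typed <- dm$variants$typed
  freqs <- colMeans(dm$dosages[, typed, drop = FALSE], na.rm = TRUE) / 2
  out <- lapply(seq_len(nrow(candidate_pairs)), function(k) {
    est <- suppressWarnings(
      estimate_ibd(dm, c(candidate_pairs$id1[k], candidate_pairs$id2[k]),
                   freqs = freqs))
    data.frame(id1 = est$id1, id2 = est$id2, z0 = est$z[1], z1 = est$z[2],
               z2 = est$z[3], label = classify_relationship(est, sd = sd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
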