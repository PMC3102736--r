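# File formats: a TSV dosage dialect (header row of sample ids; one row per
# variant: variant_id, chrom, pos, risk_allele, other_allele, typed{0,1},
# rsq, dosages with "NA" for missing), VCF (GT for typed variants, DS for
# imputed, INFO key RSQ), a phenotype TSV, a local-ancestry TSV, a region
# config TSV, and a truth JSON.

#' Write genotypes as the TSV dosage dialect
#'
#' @param dm a [dosage_matrix()]
#' @param path output file
#' @export
write_dosage_tsv <- function(dm, path) {
  v <- dm$variants
  hdr <- c("variant_id", "chrom", "pos", "risk_allele", "other_allele",
           "typed", "rsq", sample_ids(dm))
  ch <- matrix(sprintf("%.10g", dm$dosages), nrow = nrow(dm$dosages))
  ch[is.na(dm$dosages)] <- "NA"
  rs <- sprintf("%.10g", v$rsq)
  rs[is.na(v$rsq)] <- "NA"
  body <- cbind(v$variant_id, v$chrom, v$pos, v$risk_allele, v$other_allele,
                as.integer(v$typed), rs, t(ch))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes
#'
#' Reads the TSV dosage dialect or a VCF into a [dosage_matrix()], with
#' dosages oriented to the declared risk allele. For VCF, typed variants
#' are read from GT (risk allele = ALT unless `risk_alleles` says
#' otherwise, in which case the dosage is flipped), imputed variants from
#' the DS format field, and the imputation quality from the INFO key RSQ.
#'
#' @param path input file
#' @param format `"tsv"` or `"vcf"`
#' @param risk_alleles optional data.frame (`variant_id`, `risk_allele`)
#'   declaring the risk allele; a mismatch with both REF and ALT is an
#'   error naming the variant
#' @return a [dosage_matrix()]
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           risk_alleles = NULL) {
  format <- match.arg(format)
  if (format == "tsv") .read_dosage_tsv(path, risk_alleles)
  else .read_vcf(path, risk_alleles)
}

.read_dosage_tsv <- function(path, risk_alleles = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "NA")
  meta_cols <- c("variant_id", "chrom", "pos", "risk_allele",
                 "other_allele", "typed", "rsq")
  if (!all(meta_cols %in% names(tab)[1:7]))
    stop("malformed dosage TSV header in ", path)
  ids <- names(tab)[-(1:7)]
  d <- t(as.matrix(tab[, -(1:7), drop = FALSE]))
  storage.mode(d) <- "double"
  rownames(d) <- ids
  colnames(d) <- tab$variant_id
  v <- tab[, meta_cols]
  v$typed <- as.logical(v$typed)
  v$chrom <- as.character(v$chrom)
  dm <- dosage_matrix(d, v)
  .orient_risk(dm, risk_alleles)
}

.orient_risk <- function(dm, risk_alleles) {
  if (is.null(risk_alleles)) return(dm)
  idx <- match(risk_alleles$variant_id, dm$variants$variant_id)
  for (k in which(!is.na(idx))) {
    j <- idx[k]
    want <- risk_alleles$risk_allele[k]
    if (want == dm$variants$risk_allele[j]) next
    if (want != dm$variants$other_allele[j])
      stop("risk allele mismatch for variant ",
           dm$variants$variant_id[j], ": declared ", want,
           " but alleles are ", dm$variants$risk_allele[j], "/",
           dm$variants$other_allele[j])
    dm$dosages[, j] <- 2 - dm$dosages[, j]
    oa <- dm$variants$other_allele[j]
    dm$variants$other_allele[j] <- dm$variants$risk_allele[j]
    dm$variants$risk_allele[j] <- oa
  }
  dm
}

#' Write genotypes as VCF
#'
#' Typed variants carry GT (risk allele written as ALT); imputed variants
#' carry DS dosages and an INFO key RSQ.
#'
#' @param dm a [dosage_matrix()]
#' @param path output file
#' @export
write_vcf <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=RSQ,Number=1,Type=Float,Description=\"Imputation quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids(dm)), collapse = "\t")),
             con)
  v <- dm$variants
  for (j in seq_len(ncol(dm$dosages))) {
    x <- dm$dosages[, j]
    if (v$typed[j]) {
      gt <- ifelse(is.na(x), "./.",
                   c("0/0", "0/1", "1/1")[round(x) + 1])
      info <- "."
      fmt <- "GT"
      vals <- gt
    } else {
      info <- sprintf("RSQ=%.4f", v$rsq[j])
      fmt <- "DS"
      vals <- ifelse(is.na(x), ".", sprintf("%.4f", x))
    }
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j],
                       v$other_allele[j], v$risk_allele[j], ".", "PASS",
                       info, fmt, vals), collapse = "\t"), con)
  }
  invisible(path)
}

.read_vcf <- function(path, risk_alleles = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vc@fix, stringsAsFactors = FALSE)
  ids <- colnames(vc@gt)[-1]
  m <- nrow(fix)
  d <- matrix(NA_real_, length(ids), m,
              dimnames = list(ids, fix$ID))
  fmt <- vc@gt[, "FORMAT"]
  typed <- rep(TRUE, m)
  rsq <- rep(NA_real_, m)
  gt_mat <- vc@gt[, -1, drop = FALSE]
  for (j in seq_len(m)) {
    fields <- strsplit(fmt[j], ":", fixed = TRUE)[[1]]
    vals <- gt_mat[j, ]
    if ("DS" %in% fields && !"GT" %in% fields) {
      typed[j] <- FALSE
      d[, j] <- suppressWarnings(as.numeric(ifelse(vals == ".", NA, vals)))
      info <- fix$INFO[j]
      mt <- regmatches(info, regexec("RSQ=([0-9.eE+-]+)", info))[[1]]
      if (length(mt) == 2) rsq[j] <- as.numeric(mt[2])
    } else {
      gt <- sub(":.*$", "", vals)
      d[, j] <- vapply(gt, function(g) {
        if (g %in% c("./.", ".", ".|.")) return(NA_real_)
        sum(as.integer(strsplit(g, "[/|]")[[1]]))
      }, numeric(1), USE.NAMES = FALSE)
    }
  }
  v <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                  pos = as.integer(fix$POS), risk_allele = fix$ALT,
                  other_allele = fix$REF, typed = typed, rsq = rsq,
                  stringsAsFactors = FALSE)
  dm <- dosage_matrix(d, v)
  .orient_risk(dm, risk_alleles)
}

#' Write / read the phenotype TSV
#'
#' Columns: sample_id, status{0,1}, age, study, family_history{0,1,NA},
#' severity{0,1,NA}, sex{M,F}.
#'
#' @param samples phenotype data.frame
#' @param path file path
#' @export
write_phenotypes <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write / read the local-ancestry TSV
#'
#' Long format: sample_id, variant_id, pop1_chromosomes (expected count of
#' population-1 chromosomes, in \[0,2\]).
#'
#' @param track samples x variants matrix
#' @param path file path
#' @export
write_local_ancestry <- function(track, path) {
  long <- data.frame(sample_id = rep(rownames(track), ncol(track)),
                     variant_id = rep(colnames(track), each = nrow(track)),
                     pop1_chromosomes = as.vector(track))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_local_ancestry
#' @export
read_local_ancestry <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  ids <- unique(long$sample_id)
  vars <- unique(long$variant_id)
  track <- matrix(NA_real_, length(ids), length(vars),
                  dimnames = list(ids, vars))
  track[cbind(match(long$sample_id, ids), match(long$variant_id, vars))] <-
    long$pop1_chromosomes
  track
}

#' Read a risk-region configuration TSV
#'
#' Columns: region_name, chrom, start, end, index_variants
#' (comma-separated ids).
#'
#' @param path file path
#' @return data.frame with `index_variants` split into a list column
#' @export
read_regions <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$index_variants <- strsplit(tab$index_variants, ",", fixed = TRUE)
  tab
}
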