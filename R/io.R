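#' Read a VCF into a genotype panel
#'
#' Parses GT genotypes from a VCF (v4.2) via \pkg{vcfR}. Multi-allelic sites
#' and indels are excluded (their counts are attached as attribute
#' `excluded`). Dosages are returned as minor-allele counts: by default the
#' minor allele is determined per variant from this panel's observed allele
#' frequency, with a tie at 0.5 kept on the ALT allele. Missing or half-called
#' genotypes become `NA`.
#'
#' @param vcf_path path to a VCF file
#' @param recode_minor if `TRUE` (default), dosages count the panel's minor
#'   allele; if `FALSE`, dosages count the ALT allele as written in the file
#'   (use together with [match_minor_coding()] to inherit another panel's
#'   coding)
#' @return a [genotype_panel()]; attribute `excluded` holds the counts of
#'   variants removed as indels or multi-allelic sites
#' @export
read_genotypes <- function(vcf_path, recode_minor = TRUE) {
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path)
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", vcf_path, "': ",
                             conditionMessage(e))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(genotype_panel(
      matrix(numeric(0), 0, 0),
      data.frame(variant_id = character(0), chrom = character(0),
                 pos = integer(0), ref = character(0), alt = character(0),
                 minor = character(0), stringsAsFactors = FALSE)
    ))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  indel <- nchar(fix$REF) != 1L | (nchar(fix$ALT) != 1L & !multi)
  keep <- !multi & !indel
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  # "0/0"-style calls to ALT counts; anything containing '.' is missing
  dosage <- matrix(NA_real_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean == "0/0"] <- 0
  dosage[clean %in% c("0/1", "1/0")] <- 1
  dosage[clean == "1/1"] <- 2
  dosage <- t(dosage)  # samples x variants
  rownames(dosage) <- colnames(gt)

  minor <- rep("alt", nrow(fix))
  if (recode_minor) {
    f_alt <- colMeans(dosage, na.rm = TRUE) / 2
    f_alt[!is.finite(f_alt)] <- 0
    flip <- f_alt > 0.5
    dosage[, flip] <- 2 - dosage[, flip]
    minor[flip] <- "ref"
  }
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- sprintf("snp_%s_%s", fix$CHROM[no_id], fix$POS[no_id])
  variants <- data.frame(
    variant_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, minor = minor, stringsAsFactors = FALSE
  )
  panel <- genotype_panel(dosage, variants)
  attr(panel, "excluded") <- c(multiallelic = sum(multi),
                               indel = sum(indel & !multi))
  panel
}

#' Harmonize a panel's minor-allele coding to a reference panel
#'
#' cis-eQTL weights trained on the reference panel only transfer to the test
#' panel if both count the same allele at every shared variant. This flips the
#' dosages of `panel` wherever its counted allele differs from the allele the
#' reference panel counts (matched by variant id and allele labels).
#'
#' @param panel panel to recode (e.g. the test panel read with
#'   `recode_minor = FALSE`)
#' @param ref_panel panel whose coding to adopt
#' @return `panel` with dosages counting the reference panel's minor allele
#' @export
match_minor_coding <- function(panel, ref_panel) {
  i <- match(panel$variants$variant_id, ref_panel$variants$variant_id)
  shared <- !is.na(i)
  rv <- ref_panel$variants[i[shared], ]
  pv <- panel$variants[shared, ]
  # allele the reference counts, as a base letter
  ref_counts <- ifelse(rv$minor == "alt", rv$alt, rv$ref)
  panel_counts <- ifelse(pv$minor == "alt", pv$alt, pv$ref)
  flip_ids <- pv$variant_id[ref_counts != panel_counts]
  j <- match(flip_ids, panel$variants$variant_id)
  panel$dosage[, j] <- 2 - panel$dosage[, j]
  panel$variants$minor[j] <- ifelse(panel$variants$minor[j] == "alt",
                                    "ref", "alt")
  panel
}

#' Read a gene annotation TSV
#'
#' Expects columns gene_id, chrom, start, end (1-based inclusive).
#'
#' @param path TSV path
#' @return annotation data.frame with a midpoint column
#' @export
read_gene_annotation <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  if (nrow(x) == 0L) {
    return(gene_annotation(character(0), character(0), integer(0), integer(0)))
  }
  gene_annotation(x$gene_id, x$chrom, x$start, x$end)
}

#' Read an expression TSV (rows = genes, first column gene_id)
#'
#' @param path TSV path
#' @return genes x samples numeric matrix
#' @export
read_expression_matrix <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read a phenotype/covariate TSV
#'
#' @param path TSV path with a sample_id column
#' @return data.frame
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
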