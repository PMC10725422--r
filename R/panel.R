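#' Genotype panel container
#'
#' A `genotype_panel` holds a sample-by-variant minor-allele dosage matrix
#' together with per-variant metadata. Dosages are counts of the minor allele
#' in \{0, 1, 2\} with `NA` for missing genotypes. Variants are kept in genomic
#' order (chromosome, then position).
#'
#' @param dosage numeric matrix, samples x variants; entries in \{0,1,2,NA\}.
#'   Row names are sample ids, column names variant ids.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, and `minor` (which allele the dosage counts).
#' @param complete_dosage optional matrix of the same shape holding the
#'   pre-missingness genotypes; only attached by the simulator, where it is the
#'   generative truth. Panels read from files never carry it.
#'
#' @return an object of class `genotype_panel` with elements `samples`,
#'   `variants`, `dosage` and optionally `complete_dosage`.
#' @export
genotype_panel <- function(dosage, variants, complete_dosage = NULL) {
  stopifnot(is.matrix(dosage), is.data.frame(variants))
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "minor")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0L) {
    stop("variants table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (ncol(dosage) != nrow(variants)) {
    stop("dosage has ", ncol(dosage), " columns but variants has ",
         nrow(variants), " rows")
  }
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  ord <- order(as.character(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  if (!is.null(complete_dosage)) {
    complete_dosage <- complete_dosage[, ord, drop = FALSE]
    colnames(complete_dosage) <- variants$variant_id
  }
  colnames(dosage) <- variants$variant_id
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "double"
  structure(
    list(samples = rownames(dosage), variants = variants, dosage = dosage,
         complete_dosage = complete_dosage),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants (%d chromosome(s))\n",
              length(x$samples), nrow(x$variants),
              length(unique(x$variants$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing dosage fraction: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a panel to a set of variants
#'
#' @param panel a `genotype_panel`
#' @param variant_ids character vector of variant ids to keep (order ignored;
#'   genomic order is preserved)
#' @return a `genotype_panel` restricted to the requested variants
#' @export
subset_variants <- function(panel, variant_ids) {
  keep <- panel$variants$variant_id %in% variant_ids
  genotype_panel(
    panel$dosage[, keep, drop = FALSE],
    panel$variants[keep, , drop = FALSE],
    complete_dosage = if (!is.null(panel$complete_dosage)) {
      panel$complete_dosage[, keep, drop = FALSE]
    }
  )
}

#' Mean-impute missing dosages
#'
#' Replaces missing entries of the dosage matrix by the per-variant mean of the
#' observed dosages (the standard fill-in before regression-based scans).
#' All-missing variants are filled with 0 and flagged by attribute
#' `all_missing`.
#'
#' @param dosage samples x variants dosage matrix
#' @return numeric matrix without `NA`s
#' @export
impute_mean_dosage <- function(dosage) {
  mu <- colMeans(dosage, na.rm = TRUE)
  allmiss <- !is.finite(mu)
  mu[allmiss] <- 0
  idx <- which(is.na(dosage), arr.ind = TRUE)
  if (nrow(idx) > 0L) dosage[idx] <- mu[idx[, 2L]]
  attr(dosage, "all_missing") <- colnames(dosage)[allmiss]
  dosage
}

#' Gene annotation table
#'
#' @param gene_id character vector of unique gene ids
#' @param chrom chromosome labels
#' @param start,end 1-based inclusive gene body coordinates, `start <= end`
#' @return data.frame with columns gene_id, chrom, start, end, midpoint
#'   (`floor((start + end) / 2)`)
#' @export
gene_annotation <- function(gene_id, chrom, start, end) {
  if (anyDuplicated(gene_id)) stop("gene_id must be unique")
  if (any(end < start)) stop("gene end before start")
  data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    midpoint = as.integer(floor((as.numeric(start) + as.numeric(end)) / 2)),
    stringsAsFactors = FALSE
  )
}
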