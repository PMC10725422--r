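#' Identity-by-state MDS stratification components
#'
#' Computes pairwise identity-by-state `IBS(i, j) = mean((2 - |d_i - d_j|)/2)`
#' over variants non-missing in both samples, converts to a distance
#' `1 - IBS`, and extracts the top `k` coordinates by classical (Torgerson)
#' MDS — eigendecomposition of the double-centered squared-distance matrix,
#' via [stats::cmdscale()]. Sign convention: each component is flipped so its
#' largest-magnitude loading is positive. Used as fixed-effect covariates
#' against population stratification in the association scans.
#'
#' @param panel a [genotype_panel()] with >= 3 samples
#' @param k number of components (default 2); if fewer positive eigenvalues
#'   exist, fewer columns are returned with a warning
#' @return data.frame: sample_id, C1, C2, ... ; attribute `ibs` holds the
#'   IBS matrix
#' @export
compute_ibs_mds <- function(panel, k = 2) {
  n <- length(panel$samples)
  if (n < 3) stop("need at least 3 samples for MDS")
  D <- panel$dosage
  obs <- !is.na(D)
  D0 <- D; D0[!obs] <- 0
  ibs <- matrix(1, n, n, dimnames = list(panel$samples, panel$samples))
  for (i in seq_len(n - 1L)) {
    di <- D0[i, ]; oi <- obs[i, ]
    for (j in (i + 1L):n) {
      both <- oi & obs[j, ]
      m <- sum(both)
      val <- if (m == 0L) NA_real_ else {
        mean((2 - abs(di[both] - D0[j, both])) / 2)
      }
      ibs[i, j] <- ibs[j, i] <- val
    }
  }
  if (anyNA(ibs)) {
    warning("sample pairs with no shared non-missing variants; IBS set to 0")
    ibs[is.na(ibs)] <- 0
  }
  dist_mat <- 1 - ibs
  if (all(dist_mat == 0)) {
    coords <- matrix(0, n, k)
  } else {
    coords <- suppressWarnings(stats::cmdscale(stats::as.dist(dist_mat), k = k))
    if (ncol(coords) < k) {
      warning("only ", ncol(coords), " positive MDS dimension(s) available")
    }
  }
  for (cc in seq_len(ncol(coords))) {
    if (any(coords[, cc] != 0) &&
        coords[which.max(abs(coords[, cc])), cc] < 0) {
      coords[, cc] <- -coords[, cc]
    }
  }
  out <- data.frame(sample_id = panel$samples, coords,
                    stringsAsFactors = FALSE)
  names(out)[-1L] <- paste0("C", seq_len(ncol(coords)))
  attr(out, "ibs") <- ibs
  out
}

# covariate design shared by the two scans: intercept + C1 + C2 + AFC + bwt,
# with rank-deficient columns dropped (warned)
build_covariate_design <- function(pheno, covars, trait) {
  i <- match(pheno$sample_id, covars$sample_id)
  if (anyNA(i)) stop("covariates missing for some phenotyped samples")
  cv <- covars[i, setdiff(names(covars), "sample_id"), drop = FALSE]
  C <- cbind(`(Intercept)` = 1, as.matrix(cv),
             AFC = pheno$AFC, bwt = pheno$bwt)
  y <- pheno[[trait]]
  complete <- stats::complete.cases(C) & is.finite(y)
  n_dropped <- sum(!complete)
  C <- C[complete, , drop = FALSE]
  y <- y[complete]
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    keep <- qrC$pivot[seq_len(qrC$rank)]
    warning("collinear covariate column(s) dropped: ",
            paste(colnames(C)[-keep], collapse = ", "))
    C <- C[, keep, drop = FALSE]
    qrC <- qr(C)
  }
  list(C = C, qrC = qrC, y = y, complete = complete,
       samples = pheno$sample_id[complete], n_dropped = n_dropped)
}

# Wald scan of y on each column of U adjusting for covariates C
# (Frisch-Waugh-Lovell: identical estimates/tests to the joint fit)
scan_units <- function(U, design, alpha = 0.05) {
  y_r <- qr.resid(design$qrC, design$y)
  U_r <- qr.resid(design$qrC, U)
  n <- length(design$y)
  df <- n - ncol(design$C) - 1L
  if (df < 1L) stop("not enough samples for the scan (df < 1)")
  uu <- colSums(U_r^2)
  zero_var <- uu < .Machine$double.eps * n
  uu[zero_var] <- 1
  beta <- colSums(U_r * y_r) / uu
  rss <- sum(y_r^2) - beta^2 * uu
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / uu)
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  beta[zero_var] <- NA_real_
  se[zero_var] <- NA_real_
  p[zero_var] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(beta = beta, se = se, p = p, zero_variance = zero_var, df = df)
}

assemble_results <- function(unit_id, chrom, pos, scan, alpha) {
  m <- length(scan$p)
  out <- data.frame(
    unit_id = unit_id, chrom = as.character(chrom), pos = as.integer(pos),
    beta = unname(scan$beta), se = unname(scan$se),
    p_value = unname(scan$p),
    p_bh = bh_adjust(unname(scan$p)),
    p_bonferroni_significant = unname(scan$p) < bonferroni_threshold(alpha, m),
    zero_variance = unname(scan$zero_variance),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP GWAS linear-model scan
#'
#' For each variant fits `y = b0 + x*b1 + C1*b2 + C2*b3 + AFC*b4 + bwt*b5 + e`
#' by least squares (x = minor-allele dosage, mean-imputed where missing) and
#' tests `H0: b1 = 0` with a two-sided t-test on `n - q` residual degrees of
#' freedom. Samples with missing trait or covariates are dropped listwise
#' (count in attribute `samples_dropped`). Zero-variance SNPs are flagged
#' with p = 1.
#'
#' @param panel QC'd test [genotype_panel()]
#' @param pheno phenotype data.frame with sample_id, the trait column, AFC,
#'   bwt
#' @param covars data.frame with sample_id and MDS components (e.g. from
#'   [compute_ibs_mds()]), or any aligned covariate table
#' @param trait name of the trait column in `pheno`
#' @param alpha family-wise level used for the Bonferroni significance flag
#' @return association results data.frame sorted by (chrom, pos): unit_id,
#'   chrom, pos, beta, se, p_value, p_bh, p_bonferroni_significant
#' @export
gwas_scan <- function(panel, pheno, covars, trait = "trait", alpha = 0.05) {
  i <- match(pheno$sample_id, panel$samples)
  if (anyNA(i)) stop("panel missing phenotyped sample(s)")
  design <- build_covariate_design(pheno, covars, trait)
  X <- impute_mean_dosage(panel$dosage[i, , drop = FALSE])[design$complete, ,
                                                           drop = FALSE]
  scan <- scan_units(X, design, alpha)
  out <- assemble_results(panel$variants$variant_id, panel$variants$chrom,
                          panel$variants$pos, scan, alpha)
  attr(out, "samples_dropped") <- design$n_dropped
  attr(out, "df") <- scan$df
  out
}

#' Per-gene TWAS scan on imputed expression
#'
#' For each gene fits `y = eta * C + beta * GReX + e` (C = intercept, MDS
#' components, AFC, bwt) and tests `H0: beta = 0` with a two-sided t-test.
#' Genes whose GReX is constant (all weights zero or dropped) are flagged
#' with p = 1 and counted in attribute `n_zero_variance`. Positions are
#' reported at the gene midpoint for plotting.
#'
#' @param grex genes x samples GReX matrix from [impute_grex()]
#' @param pheno,covars,trait,alpha as in [gwas_scan()]
#' @param annotation gene annotation table (for chromosome and midpoint)
#' @return association results data.frame sorted by (chrom, pos)
#' @export
twas_scan <- function(grex, pheno, covars, annotation, trait = "trait",
                      alpha = 0.05) {
  i <- match(pheno$sample_id, colnames(grex))
  if (anyNA(i)) stop("GReX matrix missing phenotyped sample(s)")
  design <- build_covariate_design(pheno, covars, trait)
  G <- t(grex[, i, drop = FALSE])[design$complete, , drop = FALSE]
  scan <- scan_units(G, design, alpha)
  ann_i <- match(rownames(grex), annotation$gene_id)
  if (anyNA(ann_i)) stop("annotation missing gene(s) present in GReX")
  out <- assemble_results(rownames(grex), annotation$chrom[ann_i],
                          annotation$midpoint[ann_i], scan, alpha)
  attr(out, "samples_dropped") <- design$n_dropped
  attr(out, "n_zero_variance") <- sum(scan$zero_variance)
  attr(out, "df") <- scan$df
  out
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error level in (0, 1)
#' @param m number of tests, >= 1
#' @return `alpha / m`
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(m) != 1L || m < 1) stop("m must be a single count >= 1")
  alpha / m
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment (`q_i = min_{j >= i} m p_(j) / j`, capped at
#' 1), returned in the input order. Delegates to [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in (0, 1\]
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(p_values) {
  bad <- which(is.na(p_values))
  if (length(bad) > 0L) stop("NaN/NA p-value at index ", bad[1L])
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Genomic inflation factor
#'
#' `lambda_GC` = median of the 1-df chi-squared quantiles implied by the
#' p-values, divided by the null median `qchisq(0.5, 1)` (~0.4549). Values
#' near 1 indicate a well-calibrated scan; inflation above ~1.1 suggests
#' stratification or model misspecification. A QQ table (expected vs observed
#' -log10 p) is returned alongside.
#'
#' @param p_values >= 10 p-values; exact zeros are clamped to the smallest
#'   positive double with a warning
#' @return list: `lambda_gc`, `qq` (data.frame expected, observed)
#' @export
genomic_inflation <- function(p_values) {
  if (length(p_values) < 10) stop("need at least 10 p-values")
  if (any(p_values == 0)) {
    warning("p-values of 0 clamped to smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  m <- length(p_values)
  qq <- data.frame(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(sort(p_values))
  )
  list(lambda_gc = lambda, qq = qq)
}
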