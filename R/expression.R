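#' Median-of-ratios normalization with log transform
#'
#' Computes per-sample size factors as the median across genes of the ratio
#' of each count to the gene's geometric mean, using only genes with strictly
#' positive counts in every sample, then returns
#' `log2(count / size_factor + 1)`. This yields approximately homoskedastic
#' continuous expression suitable for linear cis-eQTL models; a pre-normalized
#' matrix (e.g. a regularized-log transform from an external tool) can be
#' supplied downstream instead.
#'
#' @param raw_counts genes x samples matrix of nonnegative integers, >= 2
#'   samples
#' @return genes x samples matrix of normalized log expression; attribute
#'   `size_factors` holds the per-sample factors
#' @export
normalize_expression <- function(raw_counts) {
  if (ncol(raw_counts) < 2L) stop("need at least 2 samples")
  if (any(raw_counts < 0)) stop("counts must be nonnegative")
  all_pos <- rowSums(raw_counts > 0) == ncol(raw_counts)
  if (!any(all_pos)) stop("no gene has all-positive counts; cannot estimate size factors")
  log_geo <- rowMeans(log(raw_counts[all_pos, , drop = FALSE]))
  sf <- apply(raw_counts[all_pos, , drop = FALSE], 2L, function(cnt) {
    exp(stats::median(log(cnt) - log_geo))
  })
  bad <- !is.finite(sf) | sf <= 0
  if (any(bad)) {
    stop("undefined size factor for sample(s): ",
         paste(colnames(raw_counts)[bad], collapse = ", "))
  }
  out <- log2(sweep(raw_counts, 2L, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Residualize expression on sample-level confounders
#'
#' Per gene, replaces expression by least-squares residuals from a regression
#' on indicator-coded production level and batch (with intercept), removing
#' additive confounder shifts; per-gene residual means are zero and residuals
#' are orthogonal to every factor column. Rank-deficient designs (e.g. batch
#' confounded with production level) are handled by dropping redundant
#' columns, reported via attribute `dropped_columns`.
#'
#' @param expr genes x samples expression matrix
#' @param factors data.frame with sample_id, production_level, batch covering
#'   every expression sample
#' @return residualized genes x samples matrix
#' @export
residualize <- function(expr, factors) {
  i <- match(colnames(expr), factors$sample_id)
  if (anyNA(i)) {
    stop("factors missing for sample(s): ",
         paste(colnames(expr)[is.na(i)], collapse = ", "))
  }
  f <- factors[i, , drop = FALSE]
  indicator_cols <- function(x, prefix) {
    x <- factor(x)
    if (nlevels(x) < 2L) return(NULL)  # single level carries no contrast
    m <- stats::model.matrix(~x)[, -1L, drop = FALSE]
    colnames(m) <- paste0(prefix, levels(x)[-1L])
    m
  }
  mm <- cbind(
    `(Intercept)` = rep(1, nrow(f)),
    indicator_cols(f$production_level, "production_level"),
    indicator_cols(f$batch, "batch")
  )
  qr_mm <- qr(mm)
  dropped <- character(0)
  if (qr_mm$rank < ncol(mm)) {
    keep_cols <- qr_mm$pivot[seq_len(qr_mm$rank)]
    dropped <- colnames(mm)[-keep_cols]
    mm <- mm[, keep_cols, drop = FALSE]
    qr_mm <- qr(mm)
  }
  resid <- t(qr.resid(qr_mm, t(expr)))
  dimnames(resid) <- dimnames(expr)
  attr(resid, "dropped_columns") <- dropped
  resid
}
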