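#' Extract a gene's cis window with training-time SNP exclusions
#'
#' Selects panel variants inside \[max(1, gene start - flank),
#' gene end + flank\] (1-based inclusive on both ends) and applies the
#' training exclusions used for cis-eQTL weight estimation: SNPs with missing
#' rate above `max_missing`, MAF below `maf_min`, or a Hardy-Weinberg exact
#' p-value below `hwe_alpha` are removed. Remaining missing dosages are
#' mean-imputed per variant. A gene with zero surviving cis-SNPs is marked
#' untrainable rather than raising an error.
#'
#' @param panel reference [genotype_panel()]
#' @param gene one row of a gene annotation table
#' @param flank cis-window flank in bp (default 1 Mb)
#' @param max_missing maximum per-variant missing rate (strictly above is
#'   excluded; default 0.2)
#' @param maf_min minimum MAF (below is excluded; default 0.01)
#' @param hwe_alpha HWE exact-test threshold (p below is excluded)
#' @return list: `gene_id`, `chrom`, `window_start`, `window_end`,
#'   `variant_id` (survivors, genomic order), `X` (samples x survivors,
#'   mean-imputed), `excluded` (named removal counts), `untrainable` flag
#' @export
extract_cis_window <- function(panel, gene, flank = 1000000,
                               max_missing = 0.2, maf_min = 0.01,
                               hwe_alpha = 1e-4) {
  ws <- max(1, gene$start - flank)
  we <- gene$end + flank
  v <- panel$variants
  member <- v$chrom == gene$chrom & v$pos >= ws & v$pos <= we
  sub <- subset_variants(panel, v$variant_id[member])
  excluded <- c(missing_rate = 0L, maf = 0L, hwe = 0L)
  if (nrow(sub$variants) > 0L) {
    st <- allele_stats(sub)
    pass_miss <- (1 - st$call_rate) <= max_missing
    pass_maf <- !is.na(st$maf) & st$maf >= maf_min
    pass_hwe <- vapply(seq_len(nrow(st)), function(i) {
      hwe_exact_test(st$n_hom_major[i], st$n_het[i], st$n_hom_minor[i])
    }, numeric(1)) >= hwe_alpha
    excluded <- c(missing_rate = sum(!pass_miss),
                  maf = sum(pass_miss & !pass_maf),
                  hwe = sum(pass_miss & pass_maf & !pass_hwe))
    sub <- subset_variants(sub, st$variant_id[pass_miss & pass_maf & pass_hwe])
  }
  X <- impute_mean_dosage(sub$dosage)
  attr(X, "all_missing") <- NULL
  list(gene_id = gene$gene_id, chrom = gene$chrom,
       window_start = ws, window_end = we,
       variant_id = sub$variants$variant_id,
       variants = sub$variants, X = X, excluded = excluded,
       untrainable = ncol(X) == 0L)
}

new_eqtl_fit <- function(weights, intercept, model, penalty, converged = TRUE) {
  structure(list(weights = weights, intercept = intercept, model = model,
                 penalty = penalty, converged = converged),
            class = "eqtl_fit")
}

#' Fit per-gene cis-eQTL weights by elastic net
#'
#' Minimizes `(1/2n) ||e - b0 - X w||^2 + lambda * [(1-alpha)/2 ||w||_2^2 +
#' alpha ||w||_1]` via \pkg{glmnet}. By default `lambda` is chosen by n-fold
#' cross-validation over glmnet's log-spaced grid (mean squared error), with
#' the mixing parameter either fixed (`alpha_mode = "fixed"`, default
#' alpha = 0.5) or grid-searched over 0.1..0.9 (`alpha_mode = "cv"`).
#' Columns are standardized internally; returned weights are on the original
#' dosage scale.
#'
#' @param X cis dosage matrix (samples x variants), >= 3 rows
#' @param e expression vector, `length(e) == nrow(X)`
#' @param alpha_mode "fixed" (use `alpha`) or "cv" (grid search)
#' @param alpha elastic-net mixing parameter for `alpha_mode = "fixed"`
#' @param n_folds folds for lambda selection; reduced with a warning when
#'   there are fewer samples than folds
#' @param lambda optional fixed penalty; skips cross-validation (0 gives the
#'   unpenalized least-squares limit)
#' @param standardize,intercept passed to glmnet (defaults match routine use)
#' @param seed seed for the CV fold assignment
#' @return an `eqtl_fit`: `weights` (named), `intercept`, `model = "ENET"`,
#'   `penalty` (list with `lambda`, `alpha`)
#' @export
fit_enet <- function(X, e, alpha_mode = c("fixed", "cv"), alpha = 0.5,
                     n_folds = 5, lambda = NULL, standardize = TRUE,
                     intercept = TRUE, seed = 1) {
  alpha_mode <- match.arg(alpha_mode)
  n <- nrow(X)
  if (n != length(e)) stop("X rows and e length differ")
  if (n < 3) stop("need at least 3 samples")
  zero_fit <- function() {
    new_eqtl_fit(stats::setNames(rep(0, ncol(X)), colnames(X)), mean(e),
                 "ENET", list(lambda = NA_real_, alpha = alpha))
  }
  if (ncol(X) == 0L || stats::var(e) == 0) return(zero_fit())
  # glmnet needs >= 2 predictor columns; pad constant-free duplicate if 1
  pad <- ncol(X) == 1L
  Xf <- if (pad) cbind(X, 0) else X

  if (!is.null(lambda)) {
    path <- sort(unique(c(exp(seq(log(max(1, lambda + 1)), log(1e-4),
                                  length.out = 30)), lambda)),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(Xf, e, alpha = alpha, lambda = path,
                          standardize = standardize, intercept = intercept,
                          thresh = 1e-14, maxit = 1e7)
    cf <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = Xf, y = e,
                                 alpha = alpha, standardize = standardize,
                                 intercept = intercept, thresh = 1e-14,
                                 maxit = 1e7))
    sel <- list(lambda = lambda, alpha = alpha)
  } else {
    nf <- n_folds
    if (n < n_folds) {
      nf <- n
      warning("fewer samples than folds; using ", nf, " folds")
    }
    foldid <- with_seed(seed, sample(rep(seq_len(nf), length.out = n)))
    alphas <- if (alpha_mode == "cv") seq(0.1, 0.9, by = 0.1) else alpha
    best <- NULL
    for (a in alphas) {
      cvfit <- glmnet::cv.glmnet(Xf, e, alpha = a, foldid = foldid,
                                 standardize = standardize,
                                 intercept = intercept, grouped = FALSE)
      score <- min(cvfit$cvm)
      if (is.null(best) || score < best$score) {
        best <- list(score = score, fit = cvfit, alpha = a)
      }
    }
    cf <- as.numeric(stats::coef(best$fit, s = "lambda.min"))
    sel <- list(lambda = best$fit$lambda.min, alpha = best$alpha)
  }
  w <- cf[-1L]
  if (pad) w <- w[1L]
  new_eqtl_fit(stats::setNames(w, colnames(X)), cf[1L], "ENET", sel)
}

#' Fit per-gene cis-eQTL weights by Dirichlet-process regression
#'
#' Nonparametric Bayesian shrinkage regression: effect sizes follow a scale
#' mixture of normals, `w_j ~ sum_k pi_k N(0, v_k)`, with a truncated
#' stick-breaking Dirichlet-process prior (concentration 1) on the mixture
#' and inverse-gamma base measures on the component variances and the
#' residual variance. Posterior mean weights are estimated by coordinate
#' ascent variational inference: Gaussian-mixture factors for each weight,
#' multinomial responsibilities for component assignment, Beta factors for
#' the stick proportions, and MAP point updates for the variances.
#' Iteration stops when the relative change of the (monitored) evidence
#' lower bound falls below `tol` or `max_iter` is reached. Responsibility
#' initialization is seeded, making the fit deterministic given `seed`.
#'
#' @param X cis dosage matrix (samples x variants), >= 3 rows; columns are
#'   centered and unit-scaled internally and weights back-transformed to the
#'   dosage scale
#' @param e expression vector
#' @param K truncation level of the stick-breaking prior (default 4)
#' @param tol relative ELBO change at convergence (default 1e-4)
#' @param max_iter iteration cap (default 1000); hitting it returns weights
#'   with `converged = FALSE`
#' @param seed seed for responsibility initialization
#' @return an `eqtl_fit`: `weights`, `intercept`, `model = "DPR"`, `penalty`
#'   (list `K`, `sigma2`, `v` component variances, `pi` component occupancy,
#'   `iterations`), `converged`
#' @export
fit_dpr <- function(X, e, K = 4, tol = 1e-4, max_iter = 1000, seed = 1) {
  n <- nrow(X)
  if (n != length(e)) stop("X rows and e length differ")
  if (n < 3) stop("need at least 3 samples")
  mu_e <- mean(e)
  y <- e - mu_e
  ctr <- colMeans(X)
  sc <- apply(X, 2L, stats::sd)
  keep <- which(is.finite(sc) & sc > 0)
  p <- length(keep)
  w_out <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (p == 0L || stats::var(y) == 0) {
    return(new_eqtl_fit(w_out, mu_e, "DPR",
                        list(K = K, sigma2 = stats::var(y), v = numeric(0),
                             pi = numeric(0), iterations = 0L)))
  }
  Xs <- scale(X[, keep, drop = FALSE], center = ctr[keep], scale = sc[keep])
  d <- colSums(Xs^2)
  vary <- stats::var(y)

  a0 <- 1        # DP concentration
  a_v <- 1e-3; b_v <- 1e-3   # inverse-gamma base on component variances
  a_e <- 1e-3; b_e <- 1e-3   # inverse-gamma prior on residual variance

  gam <- with_seed(seed, {
    g <- matrix(stats::rgamma(p * K, 1), p, K)
    g / rowSums(g)
  })
  v <- vary * 10^seq(-4, -0.5, length.out = K)
  sigma2 <- vary
  wbar <- rep(0, p)
  Ew2 <- rep(0, p)
  r <- y
  elbo_old <- -Inf
  converged <- FALSE
  iter <- 0L

  stick_elogpi <- function(Nk) {
    if (K == 1L) return(0)
    elog_v <- numeric(K); elog_1mv <- numeric(K)
    tail_counts <- rev(cumsum(rev(Nk)))  # sum_{l >= k} N_l
    for (k in seq_len(K - 1L)) {
      a_k <- 1 + Nk[k]
      b_k <- a0 + tail_counts[k + 1L]
      elog_v[k] <- digamma(a_k) - digamma(a_k + b_k)
      elog_1mv[k] <- digamma(b_k) - digamma(a_k + b_k)
    }
    elogpi <- elog_v
    elogpi[K] <- 0
    cum <- c(0, cumsum(elog_1mv[seq_len(K - 1L)]))
    elogpi + cum
  }

  for (iter in seq_len(max_iter)) {
    elogpi <- stick_elogpi(colSums(gam))
    Sk <- rep(0, K)
    Nk_new <- rep(0, K)
    assign_term <- 0
    for (j in seq_len(p)) {
      bj <- sum(Xs[, j] * r) + d[j] * wbar[j]
      prec <- d[j] + sigma2 / v
      s2 <- sigma2 / prec
      mu <- bj / prec
      lrho <- elogpi + 0.5 * log(s2 / v) + mu^2 / (2 * s2)
      lrho <- lrho - max(lrho)
      g <- exp(lrho); g <- g / sum(g)
      w_new <- sum(g * mu)
      ew2 <- g * (mu^2 + s2)
      Sk <- Sk + ew2
      Nk_new <- Nk_new + g
      Ew2[j] <- sum(ew2)
      r <- r - Xs[, j] * (w_new - wbar[j])
      wbar[j] <- w_new
      gam[j, ] <- g
      gl <- g[g > 0]
      assign_term <- assign_term +
        sum(g * (elogpi - 0.5 * log(v))) - sum(ew2 / (2 * v)) -
        sum(gl * log(gl)) + 0.5 * sum(g * (log(s2) + 1))
    }
    v <- (b_v + 0.5 * Sk) / (a_v + 0.5 * Nk_new + 1)
    v <- pmax(v, 1e-12 * vary)
    erss <- sum(r^2) + sum(d * pmax(Ew2 - wbar^2, 0))
    sigma2 <- max((b_e + 0.5 * erss) / (a_e + n / 2 + 1), 1e-12 * vary)
    elbo <- -0.5 * n * log(2 * pi * sigma2) - erss / (2 * sigma2) +
      assign_term
    if (is.finite(elbo_old) &&
        abs(elbo - elbo_old) / (abs(elbo_old) + 1e-8) < tol) {
      converged <- TRUE
      break
    }
    elbo_old <- elbo
  }
  w_out[keep] <- wbar / sc[keep]
  intercept <- mu_e - sum(w_out * ctr)
  new_eqtl_fit(w_out, intercept, "DPR",
               list(K = K, sigma2 = sigma2, v = v, pi = colSums(gam) / p,
                    iterations = iter),
               converged = converged)
}

#' @export
print.eqtl_fit <- function(x, ...) {
  nz <- sum(abs(x$weights) > 1e-8)
  cat(sprintf("eqtl_fit [%s]: %d variants (%d nonzero), converged: %s\n",
              x$model, length(x$weights), nz, x$converged))
  invisible(x)
}

#' Training accuracy with or without cross-validation
#'
#' `mode = "cv5"`: squared Pearson correlation between observed expression
#' and out-of-fold predictions from seeded n-fold splits. `mode = "nocv"`:
#' squared correlation between expression and in-sample fitted values from a
#' single fit on all samples. `mode = "loto"`: rotational leave-two-out
#' (folds of size 2). Zero-variance predictions give an R-squared of 0 with
#' attribute `flagged = TRUE`.
#'
#' @param fitter function(X, e) returning an `eqtl_fit`
#' @param X,e training design and expression
#' @param n_folds folds for `mode = "cv5"` (reduced to n when n < n_folds)
#' @param seed fold-assignment seed
#' @param mode "cv5", "nocv" or "loto"
#' @return numeric training R-squared in \[0, 1\]
#' @export
evaluate_cv <- function(fitter, X, e, n_folds = 5, seed = 1,
                        mode = c("cv5", "nocv", "loto")) {
  mode <- match.arg(mode)
  n <- length(e)
  predict_fit <- function(fit, Xnew) {
    drop(Xnew %*% fit$weights) + fit$intercept
  }
  if (mode == "nocv") {
    pred <- predict_fit(fitter(X, e), X)
  } else {
    nf <- if (mode == "loto") ceiling(n / 2) else min(n_folds, n)
    if (n < nf) stop("need at least as many samples as folds")
    foldid <- with_seed(seed, sample(rep(seq_len(nf), length.out = n)))
    pred <- rep(NA_real_, n)
    for (f in seq_len(nf)) {
      test <- foldid == f
      fit <- fitter(X[!test, , drop = FALSE], e[!test])
      pred[test] <- predict_fit(fit, X[test, , drop = FALSE])
    }
  }
  if (!all(is.finite(pred)) || stats::sd(pred) == 0 || stats::sd(e) == 0) {
    out <- 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  stats::cor(e, pred)^2
}

#' Train cis-eQTL weight models for all genes
#'
#' Runs [extract_cis_window()] + the requested model per gene and reports a
#' long-format weight table (the exchange format between training and
#' imputation) plus per-gene diagnostics. A gene is counted "usable"
#' (imputable) when at least one weight exceeds 1e-8 in absolute value.
#'
#' @param panel_ref reference [genotype_panel()]
#' @param expr genes x samples expression matrix (rows must cover the
#'   annotation's gene ids; columns must match the panel samples)
#' @param annotation gene annotation table
#' @param model "enet" or "dpr"
#' @param cv_mode "cv5" (out-of-fold training R-squared) or "nocv"
#'   (in-sample); weights always come from a fit on all samples
#' @param n_folds folds for training R-squared and lambda selection
#' @param seed seed shared by fold assignment and DPR initialization
#' @param ... passed to [fit_enet()] / [fit_dpr()]
#' @return list: `weights` (data.frame gene_id, variant_id, chrom, pos,
#'   weight, model, cv_mode, training_r2), `genes` (per-gene diagnostics)
#' @export
train_weights <- function(panel_ref, expr, annotation,
                          model = c("enet", "dpr"),
                          cv_mode = c("cv5", "nocv"),
                          n_folds = 5, seed = 1, ...) {
  model <- match.arg(model)
  cv_mode <- match.arg(cv_mode)
  missing_genes <- setdiff(annotation$gene_id, rownames(expr))
  if (length(missing_genes) > 0L) {
    stop("expression matrix lacks gene(s): ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  sample_idx <- match(panel_ref$samples, colnames(expr))
  if (anyNA(sample_idx)) stop("expression matrix lacks reference samples")
  fitter <- if (model == "enet") {
    function(X, e) fit_enet(X, e, n_folds = n_folds, seed = seed, ...)
  } else {
    function(X, e) fit_dpr(X, e, seed = seed, ...)
  }
  wt <- list(); gn <- list()
  for (i in seq_len(nrow(annotation))) {
    gene <- annotation[i, ]
    win <- extract_cis_window(panel_ref, gene)
    if (win$untrainable) {
      gn[[i]] <- data.frame(gene_id = gene$gene_id, model = toupper(model),
                            cv_mode = cv_mode, n_snps = 0L,
                            training_r2 = NA_real_, usable = FALSE,
                            converged = NA, stringsAsFactors = FALSE)
      next
    }
    e <- expr[gene$gene_id, sample_idx]
    fit <- fitter(win$X, e)
    r2 <- evaluate_cv(fitter, win$X, e, n_folds = n_folds, seed = seed,
                      mode = if (cv_mode == "cv5") "cv5" else "nocv")
    usable <- any(abs(fit$weights) > 1e-8)
    wt[[i]] <- data.frame(
      gene_id = gene$gene_id, variant_id = win$variant_id,
      chrom = win$variants$chrom, pos = win$variants$pos,
      weight = unname(fit$weights), model = toupper(model),
      cv_mode = cv_mode, training_r2 = as.numeric(r2),
      stringsAsFactors = FALSE
    )
    gn[[i]] <- data.frame(gene_id = gene$gene_id, model = toupper(model),
                          cv_mode = cv_mode, n_snps = ncol(win$X),
                          training_r2 = as.numeric(r2), usable = usable,
                          converged = isTRUE(fit$converged),
                          stringsAsFactors = FALSE)
  }
  list(weights = do.call(rbind, wt), genes = do.call(rbind, gn))
}

#' Impute genetically regulated expression into a test panel
#'
#' Computes `GReX_g(sample) = sum_j X_test[sample, j] * w_j` per gene from a
#' trained weight table. Weight variants absent from the test panel are
#' dropped with a warning (count in attribute `dropped_variants`); genes
#' whose weights are all dropped are excluded and listed in attribute
#' `excluded_genes`. Missing test dosages are mean-imputed from the test
#' panel.
#'
#' @param weights weight table from [train_weights()] (or the same columns
#'   read back from TSV)
#' @param panel_test test [genotype_panel()]
#' @return genes x samples GReX matrix
#' @export
impute_grex <- function(weights, panel_test) {
  Xt <- impute_mean_dosage(panel_test$dosage)
  genes <- unique(weights$gene_id)
  out <- matrix(NA_real_, length(genes), nrow(Xt),
                dimnames = list(genes, panel_test$samples))
  dropped <- 0L
  excluded <- character(0)
  for (g in genes) {
    wg <- weights[weights$gene_id == g, , drop = FALSE]
    present <- wg$variant_id %in% colnames(Xt)
    dropped <- dropped + sum(!present)
    wg <- wg[present, , drop = FALSE]
    if (nrow(wg) == 0L) {
      excluded <- c(excluded, g)
      next
    }
    out[g, ] <- drop(Xt[, wg$variant_id, drop = FALSE] %*% wg$weight)
  }
  if (dropped > 0L) {
    warning(dropped, " weight variant(s) absent from test panel; dropped")
  }
  out <- out[!(rownames(out) %in% excluded), , drop = FALSE]
  attr(out, "dropped_variants") <- dropped
  attr(out, "excluded_genes") <- excluded
  out
}
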