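test_that("cis-window membership is 1-based inclusive at both boundaries", {
  dos <- random_dosage(30, rep(0.3, 4), seed = 3)
  panel <- make_panel(dos, pos = c(999999L, 1000000L, 2500000L, 3010000L))
  gene <- gene_annotation("g1", "1", 2000000L, 2010000L)[1, ]
  win <- extract_cis_window(panel, gene)
  expect_identical(win$window_start, 1000000)
  expect_identical(win$window_end, 3010000)
  expect_identical(win$variant_id, c("v2", "v3", "v4"))  # 999,999 excluded
})

test_that("training exclusions remove high-missing, rare and HWE-violating cis-SNPs", {
  n <- 60
  good <- random_dosage(n, rep(0.4, 1), seed = 5)[, 1]
  highmiss <- good; highmiss[1:20] <- NA        # missing rate 1/3 > 0.2
  rare <- c(1, rep(0, n - 1))                   # MAF < 0.01
  hwe_bad <- rep(c(0, 2), each = n / 2)         # no heterozygotes
  panel <- make_panel(cbind(a = good, b = highmiss, c = rare, d = hwe_bad),
                      pos = c(1000L, 2000L, 3000L, 4000L))
  gene <- gene_annotation("g1", "1", 1L, 5000L)[1, ]
  win <- extract_cis_window(panel, gene)
  expect_identical(win$variant_id, "a")
  expect_identical(win$excluded,
                   c(missing_rate = 1L, maf = 1L, hwe = 1L))
  expect_false(anyNA(win$X))
})

test_that("a gene with no surviving cis-SNPs is untrainable, not an error", {
  panel <- make_panel(random_dosage(10, rep(0.3, 2), seed = 7),
                      pos = c(100L, 200L))
  gene <- gene_annotation("g1", "2", 1L, 500L)[1, ]  # wrong chromosome
  win <- extract_cis_window(panel, gene)
  expect_true(win$untrainable)
  expect_identical(ncol(win$X), 0L)
})

test_that("elastic net at lambda = 0 reproduces ordinary least squares", {
  withr::with_seed(11, {
    X <- random_dosage(50, runif(5, 0.2, 0.5), seed = 11)
    colnames(X) <- paste0("v", 1:5)
    e <- drop(X %*% rnorm(5)) + rnorm(50)
    fit <- fit_enet(X, e, lambda = 0)
    ols <- coef(lm(e ~ X))
    expect_lt(max(abs(fit$weights - ols[-1])), 1e-8)
    expect_lt(abs(fit$intercept - ols[1]), 1e-8)
  })
})

test_that("lasso on an orthonormal design equals the soft-threshold closed form", {
  withr::with_seed(13, {
    n <- 60; p <- 6
    Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # Q'Q = n I
    colnames(Q) <- paste0("v", 1:p)
    y <- rnorm(n)
    for (lam in c(0.02, 0.08, 0.2)) {
      fit <- fit_enet(Q, y, alpha = 1, lambda = lam, standardize = FALSE,
                      intercept = FALSE)
      b <- drop(crossprod(Q, y)) / n
      expect_lt(max(abs(fit$weights - sign(b) * pmax(abs(b) - lam, 0))), 1e-6)
    }
  })
})

test_that("pure-noise expression at n = 8 yields a near-null elastic net", {
  withr::with_seed(17, {
    X <- random_dosage(8, runif(50, 0.1, 0.5), seed = 17)
    colnames(X) <- paste0("v", 1:50)
    e <- rnorm(8)
    fit <- fit_enet(X, e, seed = 7)
    expect_lt(max(abs(fit$weights)), 0.15)
    expect_gt(fit$penalty$lambda, 0.1)  # CV pushed toward heavy shrinkage
  })
})

test_that("fewer samples than folds reduces the fold count with a warning", {
  X <- random_dosage(4, rep(0.4, 3), seed = 19)
  colnames(X) <- paste0("v", 1:3)
  e <- withr::with_seed(19, rnorm(4))
  expect_warning(fit_enet(X, e, n_folds = 5), "folds")
})

test_that("DPR at K = 1 collapses to ridge regression at the fitted variance ratio", {
  withr::with_seed(23, {
    X <- random_dosage(50, runif(10, 0.2, 0.5), seed = 23)
    colnames(X) <- paste0("v", 1:10)
    e <- drop(X %*% rnorm(10, sd = 0.3)) + rnorm(50)
    fit <- fit_dpr(X, e, K = 1, tol = 1e-12, max_iter = 20000, seed = 5)
    expect_true(fit$converged)
    Xs <- scale(X)
    y <- e - mean(e)
    ridge <- solve(crossprod(Xs) + diag(fit$penalty$sigma2 / fit$penalty$v, 10),
                   crossprod(Xs, y))
    expect_lt(max(abs(fit$weights * apply(X, 2, sd) - ridge)), 1e-4)
  })
})

test_that("DPR shrinks pure-noise weights far below least squares", {
  withr::with_seed(29, {
    X <- random_dosage(50, runif(10, 0.2, 0.5), seed = 29)
    colnames(X) <- paste0("v", 1:10)
    e <- rnorm(50)
    fit <- fit_dpr(X, e, seed = 5)
    ols <- qr.solve(cbind(1, X), e)[-1]
    expect_lt(sqrt(sum(fit$weights^2)), 0.1 * sqrt(sum(ols^2)))
  })
})

test_that("DPR is insensitive to row duplication when the data dominate the prior", {
  withr::with_seed(31, {
    X <- random_dosage(60, runif(10, 0.2, 0.5), seed = 31)
    colnames(X) <- paste0("v", 1:10)
    e <- drop(X %*% rnorm(10)) + rnorm(60, sd = 0.1)
    f1 <- fit_dpr(X, e, tol = 1e-10, max_iter = 10000, seed = 2)
    f2 <- fit_dpr(rbind(X, X), c(e, e), tol = 1e-10, max_iter = 10000,
                  seed = 2)
    expect_lt(max(abs(f1$weights - f2$weights)), 1e-2)
  })
})

test_that("DPR is deterministic given a seed and flags non-convergence", {
  X <- random_dosage(20, runif(8, 0.2, 0.5), seed = 37)
  colnames(X) <- paste0("v", 1:8)
  e <- withr::with_seed(37, rnorm(20))
  expect_identical(fit_dpr(X, e, seed = 9)$weights,
                   fit_dpr(X, e, seed = 9)$weights)
  expect_false(fit_dpr(X, e, max_iter = 2, seed = 9)$converged)
})

test_that("training R2 is 1 for a perfect linear signal and near 0 under the null", {
  withr::with_seed(41, {
    X <- random_dosage(500, runif(5, 0.2, 0.5), seed = 41)
    colnames(X) <- paste0("v", 1:5)
    fitter <- function(X, e) fit_enet(X, e, lambda = 0)
    e_sig <- drop(X %*% c(1, -2, 0.5, 1, 0))
    expect_equal(evaluate_cv(fitter, X, e_sig, mode = "nocv"), 1,
                 tolerance = 1e-10)
    e_null <- rnorm(500)
    r2 <- evaluate_cv(function(X, e) fit_enet(X, e, seed = 3), X, e_null,
                      seed = 3, mode = "cv5")
    expect_lt(r2, 0.05)
  })
})

test_that("in-sample R2 is optimistic relative to cross-validated R2", {
  wins <- withr::with_seed(43, {
    vapply(1:100, function(i) {
      X <- matrix(rbinom(30 * 8, 2, 0.3), 30, 8)
      colnames(X) <- paste0("v", 1:8)
      w <- rnorm(8, sd = 0.5)
      e <- drop(X %*% w) + rnorm(30, sd = 0.5)
      fitter <- function(X, e) fit_enet(X, e, seed = i)
      nocv <- evaluate_cv(fitter, X, e, seed = i, mode = "nocv")
      cv5 <- evaluate_cv(fitter, X, e, seed = i, mode = "cv5")
      nocv >= cv5
    }, logical(1))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("GReX imputation matches hand arithmetic and drops absent variants", {
  dos <- matrix(c(0, 1, 2,
                  2, 1, 0,
                  1, 1, 1,
                  0, 2, 1), 4, 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), c("v1", "v2", "v3")))
  panel <- make_panel(dos)
  weights <- data.frame(
    gene_id = rep(c("gA", "gB"), each = 3),
    variant_id = rep(c("v1", "v2", "v3"), 2),
    chrom = "1", pos = rep(c(1000L, 2000L, 3000L), 2),
    weight = c(1, 0, -0.5, 0.2, 0.3, 0), model = "DPR", cv_mode = "nocv",
    training_r2 = 0.5, stringsAsFactors = FALSE
  )
  grex <- impute_grex(weights, panel)
  expect_equal(grex["gA", ], drop(dos %*% c(1, 0, -0.5)))
  expect_equal(grex["gB", ], drop(dos %*% c(0.2, 0.3, 0)))

  # single variant, weight 1 -> identity; all-zero weights -> zeros
  w1 <- weights[1, ]; w1$weight <- 1
  expect_equal(unname(impute_grex(w1, panel)["gA", ]), unname(dos[, "v1"]))
  w0 <- weights[weights$gene_id == "gB", ]; w0$weight <- 0
  expect_true(all(impute_grex(w0, panel)["gB", ] == 0))

  # absent variant dropped with warning; fully absent gene excluded
  wmix <- weights
  wmix$variant_id[wmix$gene_id == "gB"] <- c("v1", "zz1", "zz2")
  expect_warning(g2 <- impute_grex(wmix, panel), "absent")
  expect_equal(g2["gB", ], drop(dos %*% c(0.2, 0, 0)))
  wgone <- weights[4, ]; wgone$variant_id <- "zz9"
  expect_warning(g3 <- impute_grex(rbind(weights[1:3, ], wgone), panel))
  expect_identical(rownames(g3), "gA")
  expect_identical(attr(g3, "excluded_genes"), "gB")
})

test_that("GReX imputation is linear in the weights", {
  panel <- make_panel(random_dosage(15, runif(6, 0.2, 0.5), seed = 47))
  base <- data.frame(gene_id = "g", variant_id = colnames(panel$dosage),
                     chrom = "1", pos = panel$variants$pos,
                     model = "DPR", cv_mode = "nocv", training_r2 = 0.1,
                     stringsAsFactors = FALSE)
  wa <- withr::with_seed(48, rnorm(6))
  wb <- withr::with_seed(49, rnorm(6))
  ga <- impute_grex(transform(base, weight = wa), panel)
  gb <- impute_grex(transform(base, weight = wb), panel)
  gab <- impute_grex(transform(base, weight = wa + wb), panel)
  expect_equal(gab["g", ], ga["g", ] + gb["g", ], tolerance = 1e-12)
})

test_that("train_weights reports usable genes and per-gene diagnostics", {
  cfg <- sim_config(n_ref = 50, n_test = 2, n_genes = 3, snps_per_gene = 8,
                    he2 = 0.4, pi_causal = 1, missing_rate = 0, seed = 51)
  sim <- simulate_panel(cfg)
  se <- simulate_expression(sim, cfg)
  tr <- train_weights(sim$ref, se$expression, sim$annotation, model = "dpr",
                      cv_mode = "nocv", seed = 1)
  expect_identical(nrow(tr$genes), 3L)
  expect_true(all(tr$genes$usable))
  expect_true(all(tr$genes$training_r2 > 0))
  expect_identical(sort(unique(tr$weights$gene_id)), sim$annotation$gene_id)
  # weight rows only for surviving cis-SNPs of each gene
  expect_true(all(tr$weights$variant_id %in% sim$ref$variants$variant_id))
})
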