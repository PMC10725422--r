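#' Simulation configuration
#'
#' Bundles the parameters of the synthetic genotype/expression/phenotype
#' generator. The generator emulates the data structure a two-stage TWAS
#' assumes: a small reference panel with both genotypes and expression, a
#' larger genotyped test panel, per-gene cis architecture
#' \eqn{E_g = X w + \epsilon} with a configurable expression heritability, and
#' quantitative phenotypes in the test panel driven by genetically regulated
#' expression (GReX) plus covariates plus noise.
#'
#' Defaults mirror the study design the pipeline targets: 8 reference and 136
#' test animals, expression heritability in the low range typical of bulk
#' tissue (0.04-0.2; default 0.12), biallelic SNPs in Hardy-Weinberg
#' equilibrium, and an age-at-first-calving / birth-weight covariate pair.
#'
#' @param n_ref number of reference samples (>= 2)
#' @param n_test number of test samples
#' @param n_genes number of genes
#' @param snps_per_gene cis-SNPs simulated inside each gene's +-1 Mb window
#' @param maf_range length-2 numeric in (0, 0.5]; per-variant allele
#'   frequencies are drawn uniformly from this interval
#' @param missing_rate fraction of genotypes masked as missing, in \[0, 1)
#' @param he2 expression heritability per gene in \[0, 1): the fraction of
#'   expression variance explained by cis-genotypes
#' @param pi_causal fraction of cis-SNPs with nonzero weight, in (0, 1\];
#'   the causal count per gene is `round(pi_causal * snps_per_gene)`
#' @param beta_trait effect of each gene's GReX on the phenotype (trait units
#'   per expression unit); scalar or length `n_genes`
#' @param covariate_effects named numeric `c(AFC = ..., bwt = ...)`: phenotype
#'   effects of age at first calving (per month) and birth weight (per kg)
#' @param batch_effect_sd standard deviation of the per-gene, per-batch
#'   expression shift (expression units)
#' @param noise_sd residual phenotype standard deviation (trait units)
#' @param n_batches number of expression collection batches
#' @param overlap_windows if `TRUE`, genes are packed so their +-1 Mb cis
#'   windows overlap (stress mode); default lays genes out with disjoint
#'   windows on 1-2 synthetic chromosomes
#' @param seed integer seed; identical seed + config give bit-identical output
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_ref = 8, n_test = 136, n_genes = 10,
                       snps_per_gene = 20, maf_range = c(0.05, 0.5),
                       missing_rate = 0.02, he2 = 0.12, pi_causal = 0.2,
                       beta_trait = 0.5,
                       covariate_effects = c(AFC = 0.3, bwt = 0.5),
                       batch_effect_sd = 0.5, noise_sd = 1,
                       n_batches = 2, overlap_windows = FALSE, seed = 42) {
  if (n_ref < 2) stop("n_ref must be >= 2")
  if (snps_per_gene < 1) stop("snps_per_gene must be >= 1")
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5] with min <= max")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (he2 < 0 || he2 >= 1) stop("he2 must be in [0, 1)")
  if (pi_causal <= 0 || pi_causal > 1) stop("pi_causal must be in (0, 1]")
  structure(list(
    n_ref = as.integer(n_ref), n_test = as.integer(n_test),
    n_genes = as.integer(n_genes), snps_per_gene = as.integer(snps_per_gene),
    maf_range = maf_range, missing_rate = missing_rate, he2 = he2,
    pi_causal = pi_causal, beta_trait = beta_trait,
    covariate_effects = covariate_effects, batch_effect_sd = batch_effect_sd,
    noise_sd = noise_sd, n_batches = as.integer(n_batches),
    overlap_windows = isTRUE(overlap_windows), seed = as.integer(seed)
  ), class = "sim_config")
}

# run expr under a local RNG state seeded at `seed`, then restore
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

gene_layout <- function(config) {
  gene_len <- 10000L
  spacing <- if (config$overlap_windows) 500000 else 2250000
  n <- config$n_genes
  if (n == 0L) {
    return(gene_annotation(character(0), character(0), integer(0), integer(0)))
  }
  chrom <- if (n == 1L) "1" else rep(c("1", "2"), length.out = n)
  idx_within <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  start <- as.integer(1000001 + (idx_within - 1) * spacing)
  gene_annotation(sprintf("gene%03d", seq_len(n)), chrom, start,
                  start + gene_len - 1L)
}

#' Simulate reference and test genotype panels
#'
#' Draws biallelic SNP genotypes as two independent allele draws per sample
#' (Hardy-Weinberg proportions) at per-variant allele frequencies sampled
#' uniformly from `maf_range`. Each gene receives `snps_per_gene` variants at
#' positions inside its cis window \[gene start - 1 Mb, gene end + 1 Mb\].
#' Both panels share the variant list and the minor-allele coding, which is
#' fixed from the reference panel's observed allele frequency (a tie at 0.5
#' keeps the alternate allele as minor). Genotypes are masked as missing
#' independently at `missing_rate`.
#'
#' @param config a [sim_config()]
#' @return list with elements `ref` and `test` ([genotype_panel()]s) and
#'   `annotation` (gene table from [gene_annotation()])
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  annotation <- gene_layout(config)
  with_seed(config$seed, {
    per_gene <- lapply(seq_len(nrow(annotation)), function(i) {
      g <- annotation[i, ]
      lo <- max(1, g$start - 1000000)
      hi <- g$end + 1000000
      pos <- sort(sample.int(hi - lo + 1L, config$snps_per_gene)) + lo - 1L
      data.frame(chrom = g$chrom, pos = pos, stringsAsFactors = FALSE)
    })
    vt <- do.call(rbind, per_gene)
    if (is.null(vt)) vt <- data.frame(chrom = character(0), pos = integer(0))
    vt <- unique(vt[order(vt$chrom, vt$pos), , drop = FALSE])
    m <- nrow(vt)
    bases <- c("A", "C", "G", "T")
    ref_al <- sample(bases, m, replace = TRUE)
    alt_al <- vapply(ref_al, function(r) sample(setdiff(bases, r), 1L), "")
    freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])

    draw <- function(n) {
      matrix(stats::rbinom(n * m, 2L, rep(freq, each = n)), nrow = n)
    }
    mask <- function(x) {
      if (config$missing_rate > 0) {
        x[stats::runif(length(x)) < config$missing_rate] <- NA
      }
      x
    }
    g_ref <- draw(config$n_ref)
    g_test <- draw(config$n_test)
    obs_ref <- mask(g_ref)
    obs_test <- mask(g_test)

    # minor-allele coding from the reference panel's observed frequency;
    # ALT frequency > 0.5 flips the coding and swaps the allele labels
    f_alt <- colMeans(obs_ref, na.rm = TRUE) / 2
    f_alt[!is.finite(f_alt)] <- 0
    flip <- f_alt > 0.5
    if (any(flip)) {
      for (mat in c("g_ref", "g_test", "obs_ref", "obs_test")) {
        x <- get(mat)
        x[, flip] <- 2L - x[, flip]
        assign(mat, x)
      }
      tmp <- ref_al[flip]
      ref_al[flip] <- alt_al[flip]
      alt_al[flip] <- tmp
    }

    variants <- data.frame(
      variant_id = sprintf("snp_%s_%d", vt$chrom, vt$pos),
      chrom = vt$chrom, pos = as.integer(vt$pos),
      ref = ref_al, alt = alt_al, minor = rep("alt", m),
      stringsAsFactors = FALSE
    )
    name_mat <- function(x, prefix, n) {
      dimnames(x) <- list(sprintf("%s%03d", prefix, seq_len(n)),
                          variants$variant_id)
      x
    }
    list(
      ref = genotype_panel(name_mat(obs_ref, "ref", config$n_ref), variants,
                           complete_dosage = name_mat(g_ref, "ref", config$n_ref)),
      test = genotype_panel(name_mat(obs_test, "test", config$n_test), variants,
                            complete_dosage = name_mat(g_test, "test", config$n_test)),
      annotation = annotation
    )
  })
}

# dosages used for generative truth: complete matrix when present
truth_dosage <- function(panel) {
  if (!is.null(panel$complete_dosage)) panel$complete_dosage else
    impute_mean_dosage(panel$dosage)
}

cis_member_ids <- function(panel, gene, flank = 1000000) {
  v <- panel$variants
  keep <- v$chrom == gene$chrom &
    v$pos >= max(1, gene$start - flank) & v$pos <= gene$end + flank
  v$variant_id[keep]
}

#' Simulate reference-panel expression with known cis architecture
#'
#' For each gene, `round(pi_causal * m)` of its `m` cis-SNPs receive normal
#' effect sizes; the genetic component \eqn{Xw} is rescaled so its empirical
#' variance fraction equals `he2`, and i.i.d. normal noise with variance
#' `1 - he2` is added, so total expression variance is ~1. An optional batch
#' shift (per gene, per batch, sd `batch_effect_sd`) is added on top.
#'
#' @param panels output of [simulate_panel()] (uses the reference panel and
#'   the annotation; truth genotypes are the pre-missingness dosages)
#' @param config the same [sim_config()]
#' @return list with `expression` (genes x samples matrix), `truth` (per-gene
#'   list: `gene_id`, `variant_id`, `true_weights` on the dosage scale,
#'   `causal_flag`, `true_grex_ref`), and `factors` (data.frame sample_id,
#'   production_level, batch)
#' @export
simulate_expression <- function(panels, config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- panels$ref
  annotation <- panels$annotation
  X_full <- truth_dosage(panel)
  n <- nrow(X_full)
  with_seed(config$seed + 1L, {
    batch <- sprintf("b%d", rep_len(seq_len(config$n_batches), n))
    production <- rep_len(c("high", "low"), n)
    expr <- matrix(0, nrow(annotation), n,
                   dimnames = list(annotation$gene_id, panel$samples))
    truth <- vector("list", nrow(annotation))
    for (i in seq_len(nrow(annotation))) {
      gene <- annotation[i, ]
      ids <- cis_member_ids(panel, gene)
      m <- length(ids)
      if (m == 0L) stop("gene ", gene$gene_id, " has zero cis-SNPs")
      n_causal <- if (config$he2 == 0) 0L else round(config$pi_causal * m)
      w <- numeric(m)
      causal <- rep(FALSE, m)
      if (n_causal > 0L) {
        causal[sample.int(m, n_causal)] <- TRUE
        w[causal] <- stats::rnorm(n_causal)
      }
      X <- X_full[, ids, drop = FALSE]
      g <- drop(X %*% w)
      vg <- stats::var(g)
      if (config$he2 > 0 && vg > 0) {
        w <- w * sqrt(config$he2 / vg)
        g <- g * sqrt(config$he2 / vg)
      } else {
        w <- numeric(m)
        g <- rep(0, n)
        causal <- causal & FALSE
      }
      e <- g + stats::rnorm(n, sd = sqrt(1 - config$he2))
      if (config$batch_effect_sd > 0) {
        shift <- stats::rnorm(config$n_batches, sd = config$batch_effect_sd)
        e <- e + shift[match(batch, sprintf("b%d", seq_len(config$n_batches)))]
      }
      expr[i, ] <- e
      truth[[i]] <- list(gene_id = gene$gene_id, variant_id = ids,
                         true_weights = w, causal_flag = causal,
                         true_grex_ref = g)
    }
    names(truth) <- annotation$gene_id
    list(expression = expr, truth = truth,
         factors = data.frame(sample_id = panel$samples,
                              production_level = production, batch = batch,
                              stringsAsFactors = FALSE))
  })
}

#' True GReX of a panel under the simulated architecture
#'
#' @param truth truth list from [simulate_expression()]
#' @param panel a simulated [genotype_panel()]
#' @return genes x samples matrix of \eqn{X w_{true}}
#' @export
true_grex <- function(truth, panel) {
  X <- truth_dosage(panel)
  out <- matrix(0, length(truth), nrow(X),
                dimnames = list(names(truth), panel$samples))
  for (i in seq_along(truth)) {
    t <- truth[[i]]
    missing_ids <- setdiff(t$variant_id, colnames(X))
    if (length(missing_ids) > 0L) {
      stop("truth/test panel mismatch: ", length(missing_ids),
           " truth variants absent from panel")
    }
    out[i, ] <- drop(X[, t$variant_id, drop = FALSE] %*% t$true_weights)
  }
  out
}

#' Simulate test-panel phenotypes from true GReX plus covariates
#'
#' Generates `y = sum_g beta_g * GReX_g + b_AFC * AFC + b_bwt * bwt + noise`
#' for the test samples, with age at first calving (months) and birth weight
#' (kg) drawn from normal distributions typical of riverine dairy buffalo
#' (AFC ~ N(40, 5^2), bwt ~ N(31, 3^2)).
#'
#' @param truth truth list from [simulate_expression()]
#' @param panel_test the simulated test [genotype_panel()]
#' @param config the same [sim_config()]
#' @return data.frame with sample_id, trait, AFC, bwt
#' @export
simulate_phenotypes <- function(truth, panel_test, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(truth) < 1L) stop("truth must cover at least one gene")
  grex <- true_grex(truth, panel_test)
  n <- ncol(grex)
  beta <- rep_len(config$beta_trait, nrow(grex))
  with_seed(config$seed + 2L, {
    afc <- stats::rnorm(n, 40, 5)
    bwt <- stats::rnorm(n, 31, 3)
    y <- drop(crossprod(grex, beta)) +
      config$covariate_effects[["AFC"]] * afc +
      config$covariate_effects[["bwt"]] * bwt
    if (config$noise_sd > 0) y <- y + stats::rnorm(n, sd = config$noise_sd)
    data.frame(sample_id = colnames(grex), trait = unname(y),
               AFC = afc, bwt = bwt, stringsAsFactors = FALSE)
  })
}

#' Write simulated fixtures to plain-text files
#'
#' Emits one VCF v4.2 (GT field) per panel, a BED-like gene annotation TSV
#' (1-based inclusive), an expression TSV (rows = genes, columns = samples)
#' and a phenotype TSV. Output is byte-identical across runs for the same
#' inputs (no timestamps are written).
#'
#' @param panels list with `ref` and `test` panels (e.g. [simulate_panel()])
#' @param annotation gene annotation table
#' @param expression genes x samples expression matrix
#' @param phenotypes phenotype data.frame
#' @param out_dir output directory, created if needed
#' @return named character vector of file paths
#' @export
write_fixtures <- function(panels, annotation, expression, phenotypes,
                           out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  paths <- c(
    ref_vcf = file.path(out_dir, "ref_panel.vcf"),
    test_vcf = file.path(out_dir, "test_panel.vcf"),
    annotation = file.path(out_dir, "gene_annotation.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv")
  )
  write_panel_vcf(panels$ref, paths[["ref_vcf"]])
  write_panel_vcf(panels$test, paths[["test_vcf"]])
  ann <- annotation[, c("gene_id", "chrom", "start", "end"), drop = FALSE]
  utils::write.table(ann, paths[["annotation"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expr <- data.frame(gene_id = rownames(expression), expression,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr, paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(phenotypes, paths[["phenotypes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' Write a genotype panel as VCF v4.2
#'
#' Genotypes are written as unphased GT calls counting the ALT allele;
#' where the panel's minor allele is the REF allele the dosage is converted
#' accordingly, so the file always encodes the same genotypes the panel holds.
#'
#' @param panel a [genotype_panel()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  alt_dosage <- t(panel$dosage)  # variants x samples
  ref_minor <- v$minor == "ref"
  if (any(ref_minor)) {
    alt_dosage[ref_minor, ] <- 2 - alt_dosage[ref_minor, ]
  }
  gt <- matrix(c("0/0", "0/1", "1/1")[alt_dosage + 1L], nrow = nrow(v))
  gt[is.na(gt)] <- "./."
  chroms <- unique(v$chrom)
  clen <- vapply(chroms, function(cc) {
    max(v$pos[v$chrom == cc]) + 1000000
  }, numeric(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grextwas_simulator",
    sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(clen)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
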