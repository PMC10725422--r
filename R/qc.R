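#' Per-variant allele statistics
#'
#' Computes minor-allele frequency, call rate and genotype counts per variant.
#' MAF is computed over non-missing alleles and folded to \[0, 0.5\] (a panel
#' whose coding was inherited from another panel can carry dosages whose mean
#' exceeds 1). Variants with all genotypes missing get `NA` MAF, which fails
#' any downstream call-rate or MAF filter.
#'
#' @param panel a [genotype_panel()] with at least one sample
#' @return data.frame: variant_id, maf, call_rate, n_hom_major, n_het,
#'   n_hom_minor
#' @export
allele_stats <- function(panel) {
  d <- panel$dosage
  if (nrow(d) < 1L) stop("panel has no samples")
  n_obs <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  f[n_obs == 0L] <- NA_real_
  maf <- pmin(f, 1 - f)
  data.frame(
    variant_id = panel$variants$variant_id,
    maf = unname(maf),
    call_rate = unname(n_obs / nrow(d)),
    n_hom_major = unname(colSums(d == 0, na.rm = TRUE)),
    n_het = unname(colSums(d == 1, na.rm = TRUE)),
    n_hom_minor = unname(colSums(d == 2, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts: conditioning on the observed
#' allele counts, the p-value sums the probabilities of every heterozygote
#' count (same parity as the observed one) whose conditional probability does
#' not exceed that of the observed configuration. Probabilities are evaluated
#' by the standard recurrence over adjacent heterozygote counts
#' (Wigginton-style), without a mid-p correction. A monomorphic site returns
#' p = 1 by convention.
#'
#' @param hom_major,het,hom_minor nonnegative genotype counts, total >= 1
#' @return p-value in (0, 1]
#' @export
hwe_exact_test <- function(hom_major, het, hom_minor) {
  counts <- c(hom_major, het, hom_minor)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1")
  n_minor <- 2 * hom_minor + het
  n_major <- 2 * hom_major + het
  if (n_minor > n_major) {  # fold so 'minor' is the rarer allele
    tmp <- hom_major; hom_major <- hom_minor; hom_minor <- tmp
    n_minor <- 2 * hom_minor + het
  }
  if (n_minor == 0) return(1)

  h_max <- if (n_minor %% 2 == 0) min(n_minor, 2 * n - n_minor) else
    min(n_minor, 2 * n - n_minor)
  h_vals <- seq(n_minor %% 2, h_max, by = 2L)
  probs <- numeric(length(h_vals))
  mid <- which.min(abs(h_vals - n_minor * (2 * n - n_minor) / (2 * n)))
  probs[mid] <- 1
  # upward recurrence: P(h+2)/P(h) = 4 * a(h) * b(h) / ((h+2)(h+1))
  if (mid < length(h_vals)) {
    for (i in mid:(length(h_vals) - 1L)) {
      h <- h_vals[i]
      a <- (n_minor - h) / 2
      b <- (2 * n - n_minor - h) / 2
      probs[i + 1L] <- probs[i] * 4 * a * b / ((h + 2) * (h + 1))
    }
  }
  if (mid > 1L) {
    for (i in mid:2L) {
      h <- h_vals[i]
      a <- (n_minor - h) / 2
      b <- (2 * n - n_minor - h) / 2
      probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (a + 1) * (b + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(het, h_vals)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-10)])
  min(1, p)
}

#' Greedy LD pruning by squared dosage correlation
#'
#' Slides a window of `window` variants in steps of `step` along the genomic
#' order. Within each window, for every pair of retained variants whose
#' squared Pearson correlation of (mean-imputed) dosages exceeds `r2_max`,
#' the member with the lower MAF is dropped; on an MAF tie the variant at the
#' later position is dropped. Zero-variance variants have undefined
#' correlation, treated as r-squared 0 (they are never pruned here; MAF
#' filters handle them). Deterministic.
#'
#' @param panel a [genotype_panel()]
#' @param r2_max prune threshold on r-squared (pairs strictly above are
#'   reduced); default 0.8
#' @param window,step window size and step in variant counts
#' @return character vector of retained variant ids (genomic order)
#' @export
ld_prune <- function(panel, r2_max = 0.8, window = 50L, step = 5L) {
  p <- nrow(panel$variants)
  if (p == 0L) return(character(0))
  X <- impute_mean_dosage(panel$dosage)
  sds <- apply(X, 2L, stats::sd)
  maf <- allele_stats(panel)$maf
  maf[is.na(maf)] <- -1
  pos <- panel$variants$pos
  keep <- rep(TRUE, p)
  starts <- unique(c(seq(1L, max(1L, p - 1L), by = step)))
  for (s in starts) {
    idx <- s:min(s + window - 1L, p)
    idx <- idx[keep[idx] & sds[idx] > 0]
    if (length(idx) < 2L) next
    r2 <- suppressWarnings(stats::cor(X[, idx, drop = FALSE]))^2
    r2[!is.finite(r2)] <- 0
    for (a in seq_len(length(idx) - 1L)) {
      if (!keep[idx[a]]) next
      for (b in (a + 1L):length(idx)) {
        if (!keep[idx[b]]) next
        if (r2[a, b] > r2_max) {
          drop <- if (maf[idx[a]] < maf[idx[b]]) idx[a]
                  else if (maf[idx[b]] < maf[idx[a]]) idx[b]
                  else if (pos[idx[a]] <= pos[idx[b]]) idx[b] else idx[a]
          keep[drop] <- FALSE
          if (!keep[idx[a]]) break
        }
      }
    }
  }
  panel$variants$variant_id[keep]
}

#' Quality-control profiles
#'
#' Three named profiles mirror common TWAS/GWAS practice on ddRAD panels:
#' `set1` (TWAS variant set: call rate > 0.95, HWE exact p >= 1e-4,
#' MAF >= 0.01), `set2` (GWAS variant set: `set1` thresholds with MAF >= 0.05
#' and LD pruning at r-squared < 0.8), and `twas_train` (per-gene training
#' exclusions: missing rate <= 0.2, MAF >= 0.01, HWE p >= 1e-4). Call rate is
#' strictly greater-than; HWE and MAF boundaries pass.
#'
#' @param name one of "set1", "set2", "twas_train", or "none" (no filtering)
#' @param min_call_rate,hwe_alpha,maf_min,ld_r2_max threshold overrides;
#'   `NULL` disables the corresponding rule
#' @param ld_window,ld_step LD pruning window/step (variant counts)
#' @return list of class `qc_profile`
#' @export
qc_profile <- function(name = c("set1", "set2", "twas_train", "none"),
                       min_call_rate = NULL, hwe_alpha = NULL, maf_min = NULL,
                       ld_r2_max = NULL, ld_window = 50L, ld_step = 5L) {
  name <- match.arg(name)
  defaults <- switch(name,
    set1 = list(min_call_rate = 0.95, hwe_alpha = 1e-4, maf_min = 0.01,
                ld_r2_max = NULL),
    set2 = list(min_call_rate = 0.95, hwe_alpha = 1e-4, maf_min = 0.05,
                ld_r2_max = 0.8),
    twas_train = list(min_call_rate = 0.8, hwe_alpha = 1e-4, maf_min = 0.01,
                      ld_r2_max = NULL),
    none = list(min_call_rate = NULL, hwe_alpha = NULL, maf_min = NULL,
                ld_r2_max = NULL)
  )
  if (!is.null(min_call_rate)) defaults$min_call_rate <- min_call_rate
  if (!is.null(hwe_alpha)) defaults$hwe_alpha <- hwe_alpha
  if (!is.null(maf_min)) defaults$maf_min <- maf_min
  if (!is.null(ld_r2_max)) defaults$ld_r2_max <- ld_r2_max
  chk <- function(x, lo, hi) {
    if (!is.null(x) && (x < lo || x > hi)) stop("threshold out of range")
  }
  chk(defaults$min_call_rate, 0, 1); chk(defaults$hwe_alpha, 0, 1)
  chk(defaults$maf_min, 0, 0.5); chk(defaults$ld_r2_max, 0, 1)
  structure(c(list(name = name), defaults,
              list(ld_window = as.integer(ld_window),
                   ld_step = as.integer(ld_step))),
            class = "qc_profile")
}

#' Apply a QC profile to a genotype panel
#'
#' Filters are applied in a fixed order: call rate, HWE exact test, MAF,
#' then optional LD pruning. (Site-type filtering — biallelic SNPs only — is
#' already enforced by [read_genotypes()] and the panel invariants.) The
#' returned report attributes the number of variants removed to each rule;
#' removal counts sum to input minus output size, and re-applying the same
#' profile is the identity.
#'
#' @param panel a [genotype_panel()]
#' @param profile a [qc_profile()]
#' @return list with `panel` (filtered) and `report` (data.frame rule,
#'   removed, remaining)
#' @export
apply_qc_profile <- function(panel, profile) {
  stopifnot(inherits(profile, "qc_profile"))
  report <- data.frame(rule = character(0), removed = integer(0),
                       remaining = integer(0), stringsAsFactors = FALSE)
  log_step <- function(rule, removed, remaining) {
    rbind(report, data.frame(rule = rule, removed = removed,
                             remaining = remaining, stringsAsFactors = FALSE))
  }
  st <- allele_stats(panel)

  keep <- rep(TRUE, nrow(st))
  if (!is.null(profile$min_call_rate)) {
    pass <- st$call_rate > profile$min_call_rate
    report <- log_step("call_rate", sum(keep & !pass), sum(keep & pass))
    keep <- keep & pass
  }
  if (!is.null(profile$hwe_alpha)) {
    hwe_p <- rep(1, nrow(st))
    idx <- which(keep)
    hwe_p[idx] <- vapply(idx, function(i) {
      hwe_exact_test(st$n_hom_major[i], st$n_het[i], st$n_hom_minor[i])
    }, numeric(1))
    pass <- hwe_p >= profile$hwe_alpha
    report <- log_step("hwe", sum(keep & !pass), sum(keep & pass))
    keep <- keep & pass
  }
  if (!is.null(profile$maf_min)) {
    pass <- !is.na(st$maf) & st$maf >= profile$maf_min
    report <- log_step("maf", sum(keep & !pass), sum(keep & pass))
    keep <- keep & pass
  }
  out <- subset_variants(panel, st$variant_id[keep])
  if (!is.null(profile$ld_r2_max) && nrow(out$variants) > 0L) {
    retained <- ld_prune(out, r2_max = profile$ld_r2_max,
                         window = profile$ld_window, step = profile$ld_step)
    report <- log_step("ld_prune", nrow(out$variants) - length(retained),
                       length(retained))
    out <- subset_variants(out, retained)
  }
  if (nrow(out$variants) == 0L) {
    warning("no variants survived QC profile '", profile$name, "'")
  }
  list(panel = out, report = report)
}
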