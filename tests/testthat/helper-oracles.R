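# Independent oracles used to cross-check the package's own routines.

# Hardy-Weinberg exact p-value by direct log-gamma enumeration over all
# heterozygote counts compatible with the observed allele counts.
hwe_oracle <- function(hom_major, het, hom_minor) {
  n <- hom_major + het + hom_minor
  nA <- 2 * hom_minor + het
  nB <- 2 * hom_major + het
  h <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((nB - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(het, h)] * (1 + 1e-10)])
}

# Benjamini-Hochberg step-up by literal definition:
# q_(i) = min_{j >= i} m p_(j) / j, capped at 1, in input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# build a genotype_panel from a dosage matrix with minimal metadata
make_panel <- function(dosage, chrom = "1", pos = NULL) {
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("v", seq_len(ncol(dosage)))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  }
  if (is.null(pos)) pos <- seq_len(ncol(dosage)) * 1000L
  genotype_panel(
    dosage,
    data.frame(variant_id = colnames(dosage),
               chrom = rep_len(chrom, ncol(dosage)), pos = pos,
               ref = "A", alt = "C", minor = "alt", stringsAsFactors = FALSE)
  )
}

# dosage matrix drawn at given allele frequencies, HWE, no missingness
random_dosage <- function(n, freqs, seed) {
  withr::with_seed(seed, {
    m <- length(freqs)
    matrix(rbinom(n * m, 2, rep(freqs, each = n)), n, m)
  })
}
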