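#' Manhattan-plot table
#'
#' Adds -log10 p and a cumulative genome coordinate (per-chromosome offsets
#' of observed chromosome length plus `gap`) to an association result table,
#' plus an above-threshold flag. The threshold is attached as attribute
#' `threshold`.
#'
#' @param results association results (from [gwas_scan()] / [twas_scan()])
#' @param bonferroni_line p-value threshold to flag (e.g.
#'   [bonferroni_threshold()])
#' @param gap spacing added between chromosomes on the cumulative axis (bp)
#' @return data.frame: unit_id, chrom, pos, neg_log10_p, cum_pos,
#'   above_threshold
#' @export
manhattan_table <- function(results, bonferroni_line, gap = 0) {
  if (nrow(results) == 0L) stop("empty result table")
  chroms <- unique(results$chrom)
  len <- vapply(chroms, function(cc) {
    max(results$pos[results$chrom == cc])
  }, numeric(1))
  offset <- stats::setNames(c(0, cumsum(len + gap))[seq_along(chroms)], chroms)
  out <- data.frame(
    unit_id = results$unit_id, chrom = results$chrom, pos = results$pos,
    neg_log10_p = -log10(results$p_value),
    cum_pos = offset[results$chrom] + results$pos,
    above_threshold = results$p_value < bonferroni_line,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "threshold") <- bonferroni_line
  out
}

genes_near_position <- function(annotation, chrom, pos, flank) {
  hit <- annotation$chrom == chrom &
    annotation$start - flank <= pos & pos <= annotation$end + flank
  annotation$gene_id[hit]
}

#' Top association hits with neighborhood gene annotation
#'
#' Selects the `n` lowest-p units (ties broken by chromosome then position)
#' and annotates each with the genes whose body, extended by `flank` on both
#' sides (1-based inclusive), overlaps the unit position. BH adjustment is
#' computed over all tests by default; `bh_scope = "top"` instead adjusts
#' within the selected top-n set only (the within-top-10 convention some
#' GWAS reports use; statistically nonstandard, opt-in).
#'
#' @param results association results
#' @param n number of hits (default 10)
#' @param annotation gene annotation table
#' @param flank neighborhood half-width in bp (default 20 kb)
#' @param bh_scope "all" (default) or "top"
#' @return data.frame ranked by ascending p: unit_id, chrom, pos, p_value,
#'   p_bh, neighbor_genes (comma-separated)
#' @export
top_hits <- function(results, n = 10, annotation, flank = 20000,
                     bh_scope = c("all", "top")) {
  bh_scope <- match.arg(bh_scope)
  if (nrow(results) == 0L) stop("empty result table")
  ord <- order(results$p_value, results$chrom, results$pos)
  top <- results[utils::head(ord, n), , drop = FALSE]
  p_bh <- if (bh_scope == "top") bh_adjust(top$p_value) else top$p_bh
  known_chrom <- top$chrom %in% annotation$chrom
  if (!all(known_chrom)) {
    warning("annotation lacks chromosome(s): ",
            paste(unique(top$chrom[!known_chrom]), collapse = ", "))
  }
  neighbors <- vapply(seq_len(nrow(top)), function(i) {
    paste(genes_near_position(annotation, top$chrom[i], top$pos[i], flank),
          collapse = ",")
  }, "")
  out <- data.frame(unit_id = top$unit_id, chrom = top$chrom, pos = top$pos,
                    p_value = top$p_value, p_bh = p_bh,
                    neighbor_genes = neighbors, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genes within a TWAS hit's midpoint window
#'
#' Returns all genes (the hit included) whose midpoint lies within
#' `half_width` of the hit gene's midpoint on the same chromosome, boundary
#' inclusive — the neighborhood screened for secondary hits around a TWAS
#' peak.
#'
#' @param hit_gene_id gene id present in the annotation
#' @param annotation gene annotation table
#' @param half_width window half-width in bp (default 1.5 Mb)
#' @return character vector of gene ids, genomic order
#' @export
twas_hit_window_genes <- function(hit_gene_id, annotation,
                                  half_width = 1500000) {
  i <- match(hit_gene_id, annotation$gene_id)
  if (is.na(i)) stop("gene ", hit_gene_id, " not in annotation")
  mid <- annotation$midpoint[i]
  hit <- annotation$chrom == annotation$chrom[i] &
    abs(annotation$midpoint - mid) <= half_width
  out <- annotation[hit, , drop = FALSE]
  out$gene_id[order(out$midpoint)]
}

#' Overlap (Venn region) counts for named gene sets
#'
#' For every non-empty combination of the named sets, counts the elements
#' belonging to exactly those sets (exclusive Venn regions). Regions are
#' labelled by the member set names joined with `&`.
#'
#' @param top_lists named list of >= 2 character vectors
#' @return data.frame: region, count
#' @export
shared_gene_counts <- function(top_lists) {
  if (length(top_lists) < 2L || is.null(names(top_lists))) {
    stop("need a named list of at least 2 sets")
  }
  sets <- lapply(top_lists, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  nm <- names(sets)
  combos <- unlist(lapply(seq_along(nm), function(k) {
    utils::combn(nm, k, simplify = FALSE)
  }), recursive = FALSE)
  counts <- vapply(combos, function(cmb) {
    inside <- rowSums(membership[, cmb, drop = FALSE]) == length(cmb)
    outside <- rowSums(membership[, setdiff(nm, cmb), drop = FALSE]) == 0
    sum(inside & outside)
  }, integer(1))
  data.frame(region = vapply(combos, paste, "", collapse = "&"),
             count = counts, stringsAsFactors = FALSE)
}

#' Extreme-weight cis-SNPs of a gene's weight model
#'
#' Reports the variant with the largest positive and the variant with the
#' most negative trained weight (candidate tag SNPs for a TWAS-highlighted
#' gene). Ties are broken toward the earlier genomic position; a slot with no
#' weight of that sign is empty. All-zero weight models return an empty
#' result flagged by attribute `all_zero`.
#'
#' @param weights weight table rows for one gene (columns variant_id, chrom,
#'   pos, weight)
#' @return data.frame with 0-2 rows: direction ("positive"/"negative"),
#'   variant_id, chrom, pos, weight
#' @export
top_weight_snps <- function(weights) {
  w <- weights[abs(weights$weight) > 1e-8, , drop = FALSE]
  empty <- data.frame(direction = character(0), variant_id = character(0),
                      chrom = character(0), pos = integer(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (nrow(w) == 0L) {
    attr(empty, "all_zero") <- TRUE
    return(empty)
  }
  pick <- function(rows, direction) {
    if (nrow(rows) == 0L) return(NULL)
    best <- rows[order(if (direction == "positive") -rows$weight
                       else rows$weight,
                       rows$chrom, rows$pos), ][1L, ]
    data.frame(direction = direction, variant_id = best$variant_id,
               chrom = best$chrom, pos = best$pos, weight = best$weight,
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick(w[w$weight > 0, , drop = FALSE], "positive"),
               pick(w[w$weight < 0, , drop = FALSE], "negative"))
  rownames(out) <- NULL
  out
}
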