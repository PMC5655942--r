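#' Score SNPs by their genes' disease correlation
#'
#' The reprioritization score of a SNP is the sum of the propagated
#' disease correlation scores of its mapped genes (deduplicated, so no
#' gene counts twice for one SNP). Genes absent from the score vector
#' contribute 0 and are logged.
#'
#' @param snpmap an `rg_snpmap` from [map_snp_to_genes()].
#' @param scores an `rg_scores` object or named numeric vector F.
#' @param assoc optional `rg_assoc` table; when supplied, each SNP's
#'   association p-value is carried into the result for tie-breaking.
#' @return data frame of class `rg_snpscores`: `snp`, `score`, `n_genes`,
#'   `p` (NA when no assoc given); `attr(, "missing_genes")` lists genes
#'   without a score.
#' @export
score_snps <- function(snpmap, scores, assoc = NULL) {
  f <- if (inherits(scores, "rg_scores")) scores$F else scores
  gene_sets <- attr(snpmap, "gene_sets")
  if (is.null(gene_sets)) {
    snps <- unique(snpmap$snp)
    gene_sets <- lapply(stats::setNames(snps, snps), function(s)
      unique(snpmap$gene[snpmap$snp == s]))
  }
  missing_genes <- setdiff(unique(unlist(gene_sets)), names(f))
  sc <- vapply(gene_sets, function(gs) {
    if (!length(gs)) return(0)
    sum(f[intersect(gs, names(f))])
  }, numeric(1))
  out <- data.frame(snp = as.character(names(gene_sets)),
                    score = unname(sc),
                    n_genes = unname(lengths(gene_sets)),
                    p = rep(NA_real_, length(gene_sets)),
                    stringsAsFactors = FALSE)
  if (!is.null(assoc))
    out$p <- assoc$p[match(out$snp, assoc$variant)]
  rownames(out) <- NULL
  class(out) <- c("rg_snpscores", "data.frame")
  attr(out, "missing_genes") <- missing_genes
  out
}

#' Rank SNPs and select the top k
#'
#' Under `network_score`, SNPs are ordered by descending reprioritization
#' score, ties broken by ascending association p-value, then lexically by
#' id; under `gwas_p`, by ascending p-value with id tie-break. Zero-score
#' SNPs remain rankable so a top-k set is always well-defined.
#'
#' @param table an `rg_snpscores` data frame (columns `snp`, `score`, `p`).
#' @param k number of SNPs to return; truncated with a warning when it
#'   exceeds the table size.
#' @param strategy `"network_score"` or `"gwas_p"`.
#' @return character vector of SNP ids in rank order, length `min(k, n)`.
#' @export
rank_and_select <- function(table, k,
                            strategy = c("network_score", "gwas_p")) {
  strategy <- match.arg(strategy)
  if (k > nrow(table)) {
    warning("k exceeds table size; returning all ", nrow(table), " SNPs")
    k <- nrow(table)
  }
  p <- table$p
  p[is.na(p)] <- Inf
  ord <- if (strategy == "network_score")
    order(-table$score, p, table$snp) else order(p, table$snp)
  table$snp[ord][seq_len(k)]
}

#' Stability of selected SNP sets across folds
#'
#' Mean pairwise Jaccard index |A intersect B| / |A union B| over all
#' unordered pairs of sets. A pair involving an empty set contributes 0.
#'
#' @param sets list of at least two character vectors.
#' @return a number in [0, 1].
#' @export
overlap_ratio <- function(sets) {
  stopifnot(length(sets) >= 2L)
  pairs <- utils::combn(length(sets), 2L)
  vals <- apply(pairs, 2, function(ij) {
    a <- unique(sets[[ij[1]]]); b <- unique(sets[[ij[2]]])
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
  })
  mean(vals)
}
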