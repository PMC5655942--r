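#' Expand SNPs to their linkage-disequilibrium proxy sets
#'
#' For each query SNP returns itself plus every SNP whose pairwise
#' r-squared with it strictly exceeds `r2_min`. The proxy table is
#' symmetrized on load; transitive closure is deliberately not applied
#' (a proxy of a proxy is not a proxy). SNPs absent from the table get the
#' singleton set.
#'
#' @param snps character vector of SNP ids.
#' @param ld_proxies data frame `snp_a`, `snp_b`, `r2`.
#' @param r2_min threshold; strictly greater-than (default 0.8).
#' @return named list of character vectors.
#' @export
expand_ld_proxies <- function(snps, ld_proxies, r2_min = 0.8) {
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld_proxies)))
  if (any(ld_proxies$r2 < 0 | ld_proxies$r2 > 1, na.rm = TRUE))
    stop("r2 values must lie in [0, 1]")
  sym <- rbind(ld_proxies[, c("snp_a", "snp_b", "r2")],
               stats::setNames(ld_proxies[, c("snp_b", "snp_a", "r2")],
                               c("snp_a", "snp_b", "r2")))
  sym <- sym[!is.na(sym$r2) & sym$r2 > r2_min, , drop = FALSE]
  out <- lapply(snps, function(s) {
    partners <- sym$snp_b[sym$snp_a == s]
    unique(c(s, partners))
  })
  stats::setNames(out, snps)
}

#' Map SNPs to biologically related genes
#'
#' For each SNP, the mapped gene set is the union over the SNP itself and
#' its LD proxies of: genes whose body contains the position; genes whose
#' promoter (2 kb upstream of the TSS, strand-aware) contains it; genes
#' linked to an enhancer containing it; target genes of a miRNA region
#' containing it; and genes with a significant eQTL link to the SNP.
#' Evidence sources and whether the hit came through a proxy are recorded.
#' Containment is by the SNP's point position on 0-based half-open
#' intervals. Unmappable SNPs get an empty set.
#'
#' @param snps character vector of SNP ids to map.
#' @param positions named integer vector of 0-based positions covering the
#'   SNPs and their potential proxies (unknown proxies are skipped for
#'   interval evidence but still used for eQTL evidence).
#' @param bundle an `rg_bundle` annotation bundle.
#' @param r2_min LD proxy threshold (strict; default 0.8).
#' @return object of class `rg_snpmap`: data frame `snp`, `gene`, `source`,
#'   `via_proxy`; `attr(, "gene_sets")` is the deduplicated per-SNP list
#'   (one entry per query SNP, possibly empty).
#' @export
map_snp_to_genes <- function(snps, positions, bundle, r2_min = 0.8) {
  stopifnot(inherits(bundle, "rg_bundle"))
  proxies <- expand_ld_proxies(snps, bundle$ld, r2_min)

  enh_gene <- split(bundle$enhancer_links$gene, bundle$enhancer_links$enhancer)
  mir_gene <- split(bundle$mirna_links$gene, bundle$mirna_links$mirna)
  eqtl <- bundle$eqtl[bundle$eqtl$significant, , drop = FALSE]

  rows <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    s <- snps[i]
    hits <- NULL
    for (member in proxies[[s]]) {
      via <- member != s
      p <- positions[member]
      if (!is.na(p)) {
        gb <- bundle$genes$gene[bundle$genes$start <= p & p < bundle$genes$end]
        if (length(gb))
          hits <- rbind(hits, data.frame(gene = gb, source = "gene_body",
                                         via_proxy = via))
        pr <- bundle$promoters$gene[bundle$promoters$start <= p &
                                      p < bundle$promoters$end]
        if (length(pr))
          hits <- rbind(hits, data.frame(gene = pr, source = "promoter",
                                         via_proxy = via))
        eh <- bundle$enhancers$enhancer[bundle$enhancers$start <= p &
                                          p < bundle$enhancers$end]
        eg <- unique(unlist(enh_gene[eh], use.names = FALSE))
        if (length(eg))
          hits <- rbind(hits, data.frame(gene = eg, source = "enhancer",
                                         via_proxy = via))
        mh <- bundle$mirnas$mirna[bundle$mirnas$start <= p &
                                    p < bundle$mirnas$end]
        mg <- unique(unlist(mir_gene[mh], use.names = FALSE))
        if (length(mg))
          hits <- rbind(hits, data.frame(gene = mg, source = "mirna_target",
                                         via_proxy = via))
      }
      qg <- eqtl$gene[eqtl$snp == member]
      if (length(qg))
        hits <- rbind(hits, data.frame(gene = unique(qg), source = "eqtl",
                                       via_proxy = via))
    }
    if (!is.null(hits) && nrow(hits)) {
      hits$snp <- s
      rows[[i]] <- unique(hits[, c("snp", "gene", "source", "via_proxy")])
    }
  }
  map <- do.call(rbind, rows)
  if (is.null(map))
    map <- data.frame(snp = character(0), gene = character(0),
                      source = character(0), via_proxy = logical(0))
  rownames(map) <- NULL
  gene_sets <- lapply(stats::setNames(snps, snps), function(s)
    sort(unique(map$gene[map$snp == s])))
  class(map) <- c("rg_snpmap", "data.frame")
  attr(map, "gene_sets") <- gene_sets
  attr(map, "r2_min") <- r2_min
  map
}
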