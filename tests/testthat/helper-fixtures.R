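# Shared fixtures (memoized per session) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

# small but complete synthetic study used across test files
small_study <- function(seed = 3) {
  key <- paste0("study", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- simulate_study(
      sim_config(n_samples = 150, n_variants = 300, n_genes = 60,
                 n_causal_snps = 8, seed = seed))
  .fixtures[[key]]
}

# hand-built rg_genotypes from a dosage matrix
make_genotypes <- function(dosage, positions = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  sids <- sprintf("S%03d", seq_len(n))
  vids <- colnames(dosage) %||% sprintf("v%03d", seq_len(m))
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  structure(list(
    dosage = `dimnames<-`(dosage, list(sids, vids)),
    sample_ids = sids, variant_ids = vids,
    positions = stats::setNames(as.integer(positions), vids),
    ref = rep("A", m), alt = rep("G", m), chrom = "chr1"),
    class = "rg_genotypes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -------------------------------------------------

# exact HWE p by direct closed-form combinatorics (choose-based), summing
# probabilities of heterozygote counts no more probable than observed
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (min(nA, 2 * n - nA) == 0) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) -
          lchoose(2 * n, nA))
  }, numeric(1))
  obs <- pr[hets == nAa]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# AUC by brute-force concordant-pair counting, ties counted one half
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# SNP-to-gene map by plain nested-loop enumeration over every table
oracle_map <- function(snps, positions, bundle, r2_min = 0.8) {
  res <- list()
  for (s in snps) {
    members <- s
    for (i in seq_len(nrow(bundle$ld))) {
      row <- bundle$ld[i, ]
      if (row$r2 > r2_min) {
        if (row$snp_a == s) members <- c(members, row$snp_b)
        if (row$snp_b == s) members <- c(members, row$snp_a)
      }
    }
    genes <- character(0)
    for (mb in unique(members)) {
      p <- positions[mb]
      if (!is.na(p)) {
        for (i in seq_len(nrow(bundle$genes)))
          if (bundle$genes$start[i] <= p && p < bundle$genes$end[i])
            genes <- c(genes, bundle$genes$gene[i])
        for (i in seq_len(nrow(bundle$promoters)))
          if (bundle$promoters$start[i] <= p && p < bundle$promoters$end[i])
            genes <- c(genes, bundle$promoters$gene[i])
        for (i in seq_len(nrow(bundle$enhancers)))
          if (bundle$enhancers$start[i] <= p && p < bundle$enhancers$end[i])
            genes <- c(genes, bundle$enhancer_links$gene[
              bundle$enhancer_links$enhancer == bundle$enhancers$enhancer[i]])
        for (i in seq_len(nrow(bundle$mirnas)))
          if (bundle$mirnas$start[i] <= p && p < bundle$mirnas$end[i])
            genes <- c(genes, bundle$mirna_links$gene[
              bundle$mirna_links$mirna == bundle$mirnas$mirna[i]])
      }
      for (i in seq_len(nrow(bundle$eqtl)))
        if (bundle$eqtl$snp[i] == mb && bundle$eqtl$significant[i])
          genes <- c(genes, bundle$eqtl$gene[i])
    }
    res[[s]] <- sort(unique(genes))
  }
  res
}

# breadth-first distances from one source over an undirected edge list
oracle_bfs <- function(edges, source, nodes) {
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  frontier <- source
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      nb <- c(edges$gene_b[edges$gene_a == v], edges$gene_a[edges$gene_b == v])
      new <- nb[dist[nb] == Inf]
      dist[new] <- dist[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  dist
}

# minimal hand-built annotation bundle for boundary tests
tiny_bundle <- function() {
  genes <- data.frame(
    gene = c("Gp", "Gm"),
    start = c(5000L, 8000L), end = c(7000L, 9000L),
    strand = c("+", "-"), tss = c(5000L, 9000L),
    stringsAsFactors = FALSE)
  structure(list(
    genes = genes,
    promoters = promoter_windows(genes),
    enhancers = data.frame(enhancer = "E1", start = 20000L, end = 20800L,
                           stringsAsFactors = FALSE),
    enhancer_links = data.frame(enhancer = "E1", gene = "Gp",
                                stringsAsFactors = FALSE),
    mirnas = data.frame(mirna = "mir1", start = 30000L, end = 30120L,
                        stringsAsFactors = FALSE),
    mirna_links = data.frame(mirna = "mir1", gene = c("Gp", "Gm"),
                             stringsAsFactors = FALSE),
    eqtl = data.frame(snp = "sq", gene = "Gm", tissue = "PBMC",
                      significant = TRUE, stringsAsFactors = FALSE),
    ld = data.frame(snp_a = c("sa", "sa", "sb"),
                    snp_b = c("sb", "sc", "sc"),
                    r2 = c(0.9, 0.3, 0.9), stringsAsFactors = FALSE),
    chrom = "chr1"), class = "rg_bundle")
}
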