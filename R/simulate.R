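#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic cohort,
#' annotation, and disease-network generators. Defaults describe a
#' single-cohort study of early rheumatoid arthritis patients with two hand
#' X-rays each: biallelic autosomal SNPs on one linear chromosome, a small
#' set of causal variants whose mapped genes sit close to disease-prior
#' genes in the interaction network, and six clinical covariates with their
#' own effect on the progression rate.
#'
#' @param n_samples number of patients.
#' @param n_variants number of biallelic variants.
#' @param maf_range length-2 numeric, minor allele frequency range in
#'   (0, 0.5]; per-variant MAFs are drawn uniformly from it.
#' @param missing_rate per-entry genotype missingness probability in [0, 1).
#' @param n_genes number of genes on the synthetic chromosome.
#' @param n_causal_snps number of causal variants.
#' @param causal_odds_ratio per-allele odds ratio on the progression
#'   liability (1 = null).
#' @param clinical_effects named length-6 numeric: liability coefficients,
#'   per standard deviation, for baseline SHS, disease duration, HAQ,
#'   anti-CCP positivity, BMI and ESR.
#' @param network_degree_param preferential-attachment power of the gene
#'   interaction graph (larger = heavier-tailed degree distribution).
#' @param prior_disease_count number of diseases in the similarity table,
#'   including the target disease.
#' @param fraction_unmapped fraction of non-causal variants guaranteed to
#'   map to no gene through any evidence channel.
#' @param proxies_per_causal number of LD proxy variants manufactured for
#'   each causal variant.
#' @param target_r2 target squared correlation between a causal variant and
#'   its manufactured proxies.
#' @param liability_sd standard deviation of the Gaussian liability noise.
#' @param seed integer seed; a fixed config reproduces byte-identical
#'   fixtures.
#'
#' @return an object of class `rg_config` (a validated list).
#' @export
sim_config <- function(n_samples = 240L,
                       n_variants = 2000L,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.02,
                       n_genes = 300L,
                       n_causal_snps = 10L,
                       causal_odds_ratio = 2.0,
                       clinical_effects = c(baseline_shs = 0.35,
                                            disease_duration = 0.20,
                                            haq = 0.40,
                                            anti_ccp = 0.60,
                                            bmi = 0.25,
                                            esr = 0.30),
                       network_degree_param = 1.0,
                       prior_disease_count = 3L,
                       fraction_unmapped = 0.3,
                       proxies_per_causal = 2L,
                       target_r2 = 0.9,
                       liability_sd = 1.0,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              missing_rate = as.numeric(missing_rate),
              n_genes = as.integer(n_genes),
              n_causal_snps = as.integer(n_causal_snps),
              causal_odds_ratio = as.numeric(causal_odds_ratio),
              clinical_effects = as.numeric(clinical_effects),
              network_degree_param = as.numeric(network_degree_param),
              prior_disease_count = as.integer(prior_disease_count),
              fraction_unmapped = as.numeric(fraction_unmapped),
              proxies_per_causal = as.integer(proxies_per_causal),
              target_r2 = as.numeric(target_r2),
              liability_sd = as.numeric(liability_sd),
              seed = as.integer(seed))
  names(cfg$clinical_effects) <- c("baseline_shs", "disease_duration",
                                   "haq", "anti_ccp", "bmi", "esr")
  counts <- c("n_samples", "n_variants", "n_genes", "n_causal_snps",
              "prior_disease_count")
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("invalid config: ", nm, " must be a positive count")
  }
  if (cfg$n_causal_snps > cfg$n_variants)
    stop("invalid config: n_causal_snps exceeds n_variants")
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("invalid config: maf_range must lie in (0, 0.5]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid config: missing_rate must be in [0, 1)")
  if (length(cfg$clinical_effects) != 6L || anyNA(cfg$clinical_effects))
    stop("invalid config: clinical_effects must be six finite coefficients")
  if (cfg$causal_odds_ratio <= 0)
    stop("invalid config: causal_odds_ratio must be positive")
  if (cfg$fraction_unmapped < 0 || cfg$fraction_unmapped > 1)
    stop("invalid config: fraction_unmapped must be in [0, 1]")
  if (cfg$network_degree_param <= 0)
    stop("invalid config: network_degree_param must be positive")
  if (is.na(cfg$seed)) stop("invalid config: seed must be an integer")
  # chromosome long enough that 10 kb genes rarely collide with variants
  cfg$genome_length <- max(2e6, cfg$n_variants * 25000)
  class(cfg) <- "rg_config"
  cfg
}

#' @export
print.rg_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  samples: %d   variants: %d (%d causal, per-allele OR %.2f)\n",
              x$n_samples, x$n_variants, x$n_causal_snps,
              x$causal_odds_ratio))
  cat(sprintf("  genes: %d   diseases in prior: %d   seed: %d\n",
              x$n_genes, x$prior_disease_count, x$seed))
  invisible(x)
}

#' Simulate a radiographic-progression cohort
#'
#' Draws genotypes per variant as binomial(2, MAF) with independent
#' missingness, six clinical covariates, and Sharp/van der Heijde scores at
#' two X-rays such that a latent liability — the sum of causal-allele
#' log-odds, the clinical linear predictor, and Gaussian noise — shifts the
#' yearly progression rate strictly monotonically. Linkage disequilibrium
#' is injected by copying each causal variant's genotypes into its proxy
#' variants with controlled flip noise.
#'
#' @param config an [sim_config()] object.
#' @return an object of class `rg_cohort`: genotypes (`rg_genotypes`),
#'   per-sample SHS at baseline/follow-up, X-ray interval and disease
#'   duration in years, the clinical covariate table, and the causal
#'   variant ids.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "rg_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_variants

  variant_ids <- sprintf("rs%05d", seq_len(m))
  positions <- sort(sample.int(config$genome_length, m)) - 1L  # 0-based
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dosage <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)),
                   nrow = n, ncol = m)

  causal_idx <- sort(sample.int(m, config$n_causal_snps))
  causal_ids <- variant_ids[causal_idx]

  # LD proxies: overwrite nearby non-causal columns with flip-noised copies
  # of the causal column; flip probability tuned so that E[r^2] ~ target_r2.
  proxy_of <- integer(0)
  if (config$proxies_per_causal > 0L) {
    pool <- setdiff(seq_len(m), causal_idx)
    n_proxy <- min(length(pool), config$n_causal_snps * config$proxies_per_causal)
    proxy_cols <- sample(pool, n_proxy)
    flip_p <- (1 - sqrt(config$target_r2)) / 2
    k <- 0L
    proxy_of <- integer(m)
    for (ci in causal_idx) {
      for (j in seq_len(config$proxies_per_causal)) {
        if (k >= n_proxy) break
        k <- k + 1L
        pc <- proxy_cols[k]
        g <- dosage[, ci]
        flips <- stats::rbinom(2L * n, 1L, flip_p)
        # act on the two allele copies independently
        a1 <- pmin(g, 1L); a2 <- g - a1
        a1 <- abs(a1 - flips[seq_len(n)])
        a2 <- abs(a2 - flips[n + seq_len(n)])
        dosage[, pc] <- a1 + a2
        proxy_of[pc] <- ci
        # keep proxies physically close to their index variant
        positions[pc] <- min(max(0L, positions[ci] + sample(c(-1L, 1L), 1L) *
                                   sample.int(5000L, 1L)),
                             as.integer(config$genome_length) - 1L)
      }
    }
  }

  # clinical covariates
  clinical <- data.frame(
    baseline_shs = round(stats::rlnorm(n, log(8), 0.8), 1),
    disease_duration = round(stats::rlnorm(n, log(2), 0.7), 2),
    haq = round(pmax(0, stats::rnorm(n, 1, 0.6)), 2),
    anti_ccp = stats::rbinom(n, 1L, 0.7),
    bmi = round(stats::rnorm(n, 23, 3), 1),
    esr = round(pmax(1, stats::rnorm(n, 30, 15)), 0)
  )
  sample_ids <- sprintf("S%04d", seq_len(n))
  rownames(clinical) <- sample_ids

  z <- scale(as.matrix(clinical))
  z[, apply(as.matrix(clinical), 2, stats::sd) == 0] <- 0
  clin_lp <- drop(z %*% config$clinical_effects)

  beta <- log(config$causal_odds_ratio)
  g_causal <- dosage[, causal_idx, drop = FALSE]
  geno_lp <- drop(g_causal %*% rep(beta, length(causal_idx)))

  liability <- geno_lp + clin_lp +
    stats::rnorm(n, 0, config$liability_sd)

  # yearly damage rate: strictly increasing in liability, in SHS units/year
  lz <- (liability - mean(liability)) / max(stats::sd(liability), 1e-12)
  yearly_rate <- 2 * exp(0.8 * lz)

  interval <- stats::runif(n, 1.5, 4)
  shs_baseline <- clinical$baseline_shs
  shs_followup <- shs_baseline + yearly_rate * interval

  # missingness applied last so LD copies share the same complete draws
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    dosage[miss] <- NA_integer_
  }

  genotypes <- structure(list(
    dosage = `dimnames<-`(dosage, list(sample_ids, variant_ids)),
    sample_ids = sample_ids,
    variant_ids = variant_ids,
    positions = stats::setNames(positions, variant_ids),
    ref = rep("A", m), alt = rep("G", m),
    chrom = "chr1"
  ), class = "rg_genotypes")

  structure(list(
    genotypes = genotypes,
    shs_baseline = stats::setNames(shs_baseline, sample_ids),
    shs_followup = stats::setNames(shs_followup, sample_ids),
    xray_interval_years = stats::setNames(interval, sample_ids),
    disease_duration_years = stats::setNames(clinical$disease_duration,
                                             sample_ids),
    clinical = clinical,
    causal_variant_ids = causal_ids,
    proxy_of = if (length(proxy_of))
      stats::setNames(ifelse(proxy_of > 0, variant_ids[pmax(proxy_of, 1L)],
                             NA_character_), variant_ids)
      else NULL,
    maf = stats::setNames(maf, variant_ids),
    config = config
  ), class = "rg_cohort")
}

#' @export
print.rg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic RA cohort: %d samples x %d variants (%d causal)\n",
              length(x$genotypes$sample_ids), length(x$genotypes$variant_ids),
              length(x$causal_variant_ids)))
  cat(sprintf("  genotype missingness: %.3f\n",
              mean(is.na(x$genotypes$dosage))))
  invisible(x)
}

#' @export
print.rg_genotypes <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d variants on %s\n",
              nrow(x$dosage), ncol(x$dosage), x$chrom))
  invisible(x)
}

# drop intervals covering any forbidden point (0-based half-open)
.drop_covering <- function(df, forbidden) {
  if (!length(forbidden) || !nrow(df)) return(df)
  hit <- vapply(seq_len(nrow(df)), function(i)
    any(forbidden >= df$start[i] & forbidden < df$end[i]), logical(1))
  df[!hit, , drop = FALSE]
}

# place n intervals of given lengths avoiding a set of forbidden points
.place_avoiding <- function(n, len, genome_length, forbidden, max_try = 50L) {
  starts <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_try)) {
      s <- sample.int(genome_length - len[i] - 2001L, 1L) + 2000L
      hit <- any(forbidden >= s - 2000L & forbidden < s + len[i] + 2000L)
      if (!hit) { ok <- TRUE; break }
    }
    starts[i] <- s
    if (!ok) starts[i] <- NA_integer_
  }
  starts
}

#' Simulate annotation tracks and link tables
#'
#' Produces gene-body, promoter, enhancer and miRNA interval tracks on the
#' synthetic chromosome (0-based half-open), enhancer-to-gene and
#' miRNA-to-target link tables, significant cis/trans eQTL links, and an LD
#' proxy table with empirical r-squared values. Every causal variant is
#' guaranteed at least one mapped gene (directly or through a proxy), and a
#' `fraction_unmapped` share of non-causal variants is guaranteed to map to
#' nothing: gene placement rejects positions whose body or promoter would
#' cover a designated unmapped variant.
#'
#' @param config an [sim_config()] object (same seed discipline as the
#'   cohort generator).
#' @param cohort the matching [simulate_cohort()] result.
#' @return an object of class `rg_bundle`.
#' @export
simulate_annotations <- function(config, cohort) {
  stopifnot(inherits(config, "rg_config"), inherits(cohort, "rg_cohort"))
  set.seed(config$seed + 1000L)
  G <- config$n_genes
  pos <- cohort$genotypes$positions
  vids <- cohort$genotypes$variant_ids
  causal <- cohort$causal_variant_ids
  noncausal <- setdiff(vids, causal)
  # LD proxies of causal variants inherit their index variant's mappings,
  # so they can never be guaranteed unmapped
  proxy_ids <- if (!is.null(cohort$proxy_of))
    names(cohort$proxy_of)[!is.na(cohort$proxy_of)] else character(0)
  unmappable_pool <- setdiff(noncausal, proxy_ids)

  n_unmap <- min(length(unmappable_pool),
                 round(config$fraction_unmapped * length(noncausal)))
  unmapped <- if (n_unmap > 0) sample(unmappable_pool, n_unmap)
    else character(0)
  forbidden <- sort(pos[unmapped])

  gene_ids <- sprintf("G%04d", seq_len(G))
  gene_len <- sample(5000:20000, G, replace = TRUE)
  strand <- sample(c("+", "-"), G, replace = TRUE)
  start <- .place_avoiding(G, gene_len, config$genome_length, forbidden)
  keep <- !is.na(start)
  start <- start[keep]; gene_len <- gene_len[keep]
  strand <- strand[keep]; gene_ids <- gene_ids[keep]
  end <- start + gene_len
  tss <- ifelse(strand == "+", start, end)
  genes <- data.frame(gene = gene_ids, start = start, end = end,
                      strand = strand, tss = tss,
                      stringsAsFactors = FALSE)
  promoters <- promoter_windows(genes)

  # enhancers: half sited over mappable variants, half at random
  n_enh <- max(10L, G %/% 3L)
  mappable <- setdiff(noncausal, unmapped)
  enh_anchor <- sample(mappable, min(n_enh %/% 2L, length(mappable)))
  enh_start <- c(pmax(0L, pos[enh_anchor] - sample.int(400L, length(enh_anchor))),
                 .place_avoiding(n_enh - length(enh_anchor),
                                 rep(800L, n_enh - length(enh_anchor)),
                                 config$genome_length, forbidden))
  enh_start <- enh_start[!is.na(enh_start)]
  enhancers <- data.frame(enhancer = sprintf("E%04d", seq_along(enh_start)),
                          start = as.integer(enh_start),
                          end = as.integer(enh_start + 800L),
                          stringsAsFactors = FALSE)
  enhancers <- .drop_covering(enhancers, forbidden)
  enhancer_links <- data.frame(
    enhancer = rep(enhancers$enhancer,
                   times = sample(1:3, nrow(enhancers), replace = TRUE)))
  enhancer_links$gene <- sample(gene_ids, nrow(enhancer_links), replace = TRUE)
  enhancer_links <- unique(enhancer_links)

  # miRNA regions and their target genes
  n_mir <- max(5L, G %/% 10L)
  mir_anchor <- sample(mappable, min(n_mir %/% 2L, length(mappable)))
  mir_start <- c(pmax(0L, pos[mir_anchor] - sample.int(50L, length(mir_anchor))),
                 .place_avoiding(n_mir - length(mir_anchor),
                                 rep(120L, n_mir - length(mir_anchor)),
                                 config$genome_length, forbidden))
  mir_start <- mir_start[!is.na(mir_start)]
  mirnas <- data.frame(mirna = sprintf("mir%03d", seq_along(mir_start)),
                       start = as.integer(mir_start),
                       end = as.integer(mir_start + 120L),
                       stringsAsFactors = FALSE)
  mirnas <- .drop_covering(mirnas, forbidden)
  mirna_links <- data.frame(
    mirna = rep(mirnas$mirna, times = sample(1:4, nrow(mirnas), replace = TRUE)))
  mirna_links$gene <- sample(gene_ids, nrow(mirna_links), replace = TRUE)
  mirna_links <- unique(mirna_links)

  # eQTL links: every causal variant gets a significant link to its causal
  # gene; a sprinkle of mappable non-causal variants get links too
  causal_genes <- stats::setNames(sample(gene_ids, length(causal),
                                         replace = length(gene_ids) < length(causal)),
                                  causal)
  tissues <- c("PBMC", "monocyte", "CD4T", "LCL")
  eqtl <- data.frame(snp = causal,
                     gene = unname(causal_genes),
                     tissue = sample(tissues, length(causal), replace = TRUE),
                     significant = TRUE,
                     stringsAsFactors = FALSE)
  n_extra <- min(length(mappable), max(5L, length(vids) %/% 20L))
  if (n_extra > 0) {
    ex <- sample(mappable, n_extra)
    eqtl <- rbind(eqtl, data.frame(
      snp = ex, gene = sample(gene_ids, n_extra, replace = TRUE),
      tissue = sample(tissues, n_extra, replace = TRUE),
      significant = TRUE, stringsAsFactors = FALSE))
  }

  # LD table: empirical r^2 for causal-proxy pairs plus random background
  ld <- NULL
  dos <- cohort$genotypes$dosage
  if (!is.null(cohort$proxy_of)) {
    pr <- names(cohort$proxy_of)[!is.na(cohort$proxy_of)]
    if (length(pr)) {
      r2 <- vapply(pr, function(p) {
        suppressWarnings(stats::cor(dos[, p], dos[, cohort$proxy_of[[p]]],
                                    use = "complete.obs"))^2
      }, numeric(1))
      ld <- data.frame(snp_a = unname(cohort$proxy_of[pr]), snp_b = pr,
                       r2 = unname(r2), stringsAsFactors = FALSE)
    }
  }
  n_bg <- max(10L, length(vids) %/% 50L)
  bg_a <- sample(vids, n_bg); bg_b <- sample(vids, n_bg)
  keep_bg <- bg_a != bg_b
  bg <- data.frame(snp_a = bg_a[keep_bg], snp_b = bg_b[keep_bg],
                   r2 = round(stats::runif(sum(keep_bg), 0, 0.5), 3),
                   stringsAsFactors = FALSE)
  ld <- unique(rbind(ld, bg))
  ld <- ld[!is.na(ld$r2), , drop = FALSE]
  rownames(ld) <- NULL

  structure(list(genes = genes, promoters = promoters,
                 enhancers = enhancers, enhancer_links = enhancer_links,
                 mirnas = mirnas, mirna_links = mirna_links,
                 eqtl = eqtl, ld = ld,
                 causal_genes = causal_genes,
                 unmapped_variants = unmapped,
                 chrom = "chr1"),
            class = "rg_bundle")
}

#' Promoter windows from gene intervals
#'
#' The promoter is the 2 kb immediately upstream of the transcription start
#' site: `[TSS-2000, TSS)` for plus-strand genes and, mirrored, the 2 kb
#' past the half-open gene end for minus-strand genes. Coordinates are
#' 0-based half-open.
#'
#' @param genes data frame with `gene`, `start`, `end`, `strand`.
#' @param width window width in bases (default 2000).
#' @return data frame `gene`, `start`, `end`.
#' @export
promoter_windows <- function(genes, width = 2000L) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0L, genes$start - width), genes$end)
  end <- ifelse(plus, genes$start, genes$end + width)
  data.frame(gene = genes$gene, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' @export
print.rg_bundle <- function(x, ...) {
  cat(sprintf(paste0("Annotation bundle: %d genes, %d enhancers, %d miRNAs, ",
                     "%d eQTL links, %d LD pairs\n"),
              nrow(x$genes), nrow(x$enhancers), nrow(x$mirnas),
              nrow(x$eqtl), nrow(x$ld)))
  invisible(x)
}

#' Simulate the disease gene network and prior tables
#'
#' Builds a scale-free-like undirected weighted interaction graph over the
#' bundle's genes (preferential attachment), a gene-disease association
#' (GDA) table with scores in [0, 1], and a disease-similarity (DS) table
#' with the target disease at similarity 1. Genes carrying causal variants
#' are guaranteed to lie within two hops of a gene with nonzero GDA; an
#' edge to a prior gene is added where the sampled graph violates this.
#'
#' @param config an [sim_config()] object.
#' @param bundle the matching [simulate_annotations()] result.
#' @return an object of class `rg_network`: `genes`, `edges`
#'   (gene_a, gene_b, weight), `gda`, `ds`, `target`.
#' @export
simulate_network_priors <- function(config, bundle) {
  stopifnot(inherits(config, "rg_config"), inherits(bundle, "rg_bundle"))
  set.seed(config$seed + 2000L)
  gene_ids <- bundle$genes$gene
  G <- length(gene_ids)

  g <- igraph::sample_pa(G, power = config$network_degree_param, m = 2,
                         directed = FALSE)
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(gene_a = gene_ids[el[, 1]], gene_b = gene_ids[el[, 2]],
                      weight = round(stats::runif(nrow(el), 0.5, 1), 3),
                      stringsAsFactors = FALSE)

  # disease priors
  diseases <- c("target", if (config$prior_disease_count > 1L)
    sprintf("D%02d", seq_len(config$prior_disease_count - 1L)))
  ds <- data.frame(disease = diseases,
                   score = c(1, if (length(diseases) > 1L)
                     round(stats::runif(length(diseases) - 1L, 0.3, 0.9), 3)),
                   stringsAsFactors = FALSE)

  n_prior <- max(5L, G %/% 15L)
  prior_genes <- sample(gene_ids, n_prior)
  gda <- do.call(rbind, lapply(diseases, function(d) {
    gs <- if (d == "target") prior_genes else
      sample(gene_ids, max(3L, n_prior %/% 2L))
    data.frame(gene = gs, disease = d,
               score = round(stats::runif(length(gs), 0.4, 1), 3),
               stringsAsFactors = FALSE)
  }))
  rownames(gda) <- NULL

  # enforce the two-hop guarantee for causal genes
  ig <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                      vertices = gene_ids)
  gda_genes <- unique(gda$gene)
  dmat <- igraph::distances(ig, v = unique(bundle$causal_genes),
                            to = gda_genes)
  extra <- NULL
  for (cg in rownames(dmat)) {
    if (min(dmat[cg, ]) > 2) {
      pg <- sample(gda_genes, 1L)
      extra <- rbind(extra, data.frame(gene_a = cg, gene_b = pg,
                                       weight = round(stats::runif(1, 0.5, 1), 3),
                                       stringsAsFactors = FALSE))
    }
  }
  if (!is.null(extra)) {
    edges <- rbind(edges, extra)
    # drop any accidental duplicates irrespective of orientation
    key <- ifelse(edges$gene_a < edges$gene_b,
                  paste(edges$gene_a, edges$gene_b),
                  paste(edges$gene_b, edges$gene_a))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  rownames(edges) <- NULL

  structure(list(genes = gene_ids, edges = edges, gda = gda, ds = ds,
                 target = "target"),
            class = "rg_network")
}

#' @export
print.rg_network <- function(x, ...) {
  cat(sprintf("Disease gene network: %d genes, %d edges, %d GDA rows, %d diseases\n",
              length(x$genes), nrow(x$edges), nrow(x$gda), nrow(x$ds)))
  invisible(x)
}

#' Generate the complete synthetic study
#'
#' Convenience wrapper running the cohort, annotation, and network
#' generators in order under one configuration.
#'
#' @param config an [sim_config()] object.
#' @return list with elements `cohort`, `bundle`, `network`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  cohort <- simulate_cohort(config)
  bundle <- simulate_annotations(config, cohort)
  network <- simulate_network_priors(config, bundle)
  list(cohort = cohort, bundle = bundle, network = network, config = config)
}
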