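test_that("fixtures are byte-identical under a fixed seed", {
  cfg <- sim_config(n_samples = 60, n_variants = 100, n_genes = 30,
                    n_causal_snps = 4, seed = 7)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$cohort$genotypes$dosage, b$cohort$genotypes$dosage)
  expect_identical(a$cohort$clinical, b$cohort$clinical)
  expect_identical(a$bundle[setdiff(names(a$bundle), "chrom")],
                   b$bundle[setdiff(names(b$bundle), "chrom")])
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$network$gda, b$network$gda)
})

test_that("degenerate rates behave: no missingness, null genetics", {
  cfg0 <- sim_config(n_samples = 50, n_variants = 80, n_genes = 20,
                     n_causal_snps = 3, missing_rate = 0, seed = 2)
  co <- simulate_cohort(cfg0)
  expect_false(anyNA(co$genotypes$dosage))
  expect_true(all(co$shs_followup >= 0))
  expect_true(all(co$shs_followup >= co$shs_baseline))

  # null model: liability carries no genotype term
  cfgn <- sim_config(n_samples = 200, n_variants = 50, n_genes = 20,
                     n_causal_snps = 5, causal_odds_ratio = 1,
                     clinical_effects = rep(0, 6), missing_rate = 0,
                     seed = 5)
  con <- simulate_cohort(cfgn)
  rate <- (con$shs_followup - con$shs_baseline) / con$xray_interval_years
  g <- rowSums(con$genotypes$dosage[, con$causal_variant_ids])
  expect_lt(abs(cor(rate, g)), 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_causal_snps = 50, n_variants = 10),
               "n_causal_snps")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_samples = 0), "positive")
})

test_that("promoters span exactly 2 kb upstream of the TSS", {
  st <- small_study()
  pr <- st$bundle$promoters
  ge <- st$bundle$genes
  expect_true(all(pr$end - pr$start <= 2000L))
  plus <- ge$strand == "+"
  full <- ge$start >= 2000L  # windows are clipped at the chromosome start
  expect_equal(pr$end[plus], ge$tss[plus])
  expect_equal(pr$start[plus & full], ge$tss[plus & full] - 2000L)
  expect_equal(pr$start[!plus], ge$tss[!plus])
  expect_equal(pr$end[!plus], ge$tss[!plus] + 2000L)
})

test_that("LD table r2 values are bounded and symmetric in the pair", {
  st <- small_study()
  expect_true(all(st$bundle$ld$r2 >= 0 & st$bundle$ld$r2 <= 1))
  px <- expand_ld_proxies(unique(c(st$bundle$ld$snp_a, st$bundle$ld$snp_b)),
                          st$bundle$ld, 0.8)
  for (a in names(px))
    for (b in setdiff(px[[a]], a))
      expect_true(a %in% px[[b]])
})

test_that("every causal variant maps to a gene; unmapped fraction holds", {
  st <- small_study()
  pos <- st$cohort$genotypes$positions
  mp <- map_snp_to_genes(st$cohort$causal_variant_ids, pos, st$bundle)
  expect_true(all(lengths(attr(mp, "gene_sets")) >= 1))

  un <- st$bundle$unmapped_variants
  mpu <- map_snp_to_genes(un[seq_len(min(20, length(un)))], pos, st$bundle)
  expect_true(all(lengths(attr(mpu, "gene_sets")) == 0))

  # degenerate fraction: only causal variants carry any mapping
  cfg <- sim_config(n_samples = 40, n_variants = 60, n_genes = 15,
                    n_causal_snps = 3, fraction_unmapped = 1,
                    proxies_per_causal = 0, seed = 9)
  co <- simulate_cohort(cfg)
  bu <- simulate_annotations(cfg, co)
  nc <- setdiff(co$genotypes$variant_ids, co$causal_variant_ids)
  m_nc <- map_snp_to_genes(nc, co$genotypes$positions, bu)
  expect_true(all(lengths(attr(m_nc, "gene_sets")) == 0))
  m_c <- map_snp_to_genes(co$causal_variant_ids, co$genotypes$positions, bu)
  expect_true(all(lengths(attr(m_c, "gene_sets")) >= 1))
})

test_that("network generator: sane graph, causal genes near prior genes", {
  st <- small_study()
  nw <- st$network
  expect_false(any(nw$edges$gene_a == nw$edges$gene_b))
  key <- ifelse(nw$edges$gene_a < nw$edges$gene_b,
                paste(nw$edges$gene_a, nw$edges$gene_b),
                paste(nw$edges$gene_b, nw$edges$gene_a))
  expect_false(any(duplicated(key)))
  expect_true(all(nw$gda$score >= 0 & nw$gda$score <= 1))
  expect_equal(nw$ds$score[nw$ds$disease == nw$target], 1)

  # breadth-first-search oracle for the two-hop guarantee
  gda_genes <- unique(nw$gda$gene)
  for (cg in unique(st$bundle$causal_genes)) {
    d <- oracle_bfs(nw$edges, cg, nw$genes)
    expect_lte(min(d[gda_genes]), 2)
  }
})

test_that("single-disease prior collapses to the target GDA column", {
  cfg <- sim_config(n_samples = 40, n_variants = 60, n_genes = 20,
                    n_causal_snps = 3, prior_disease_count = 1, seed = 4)
  co <- simulate_cohort(cfg)
  bu <- simulate_annotations(cfg, co)
  nw <- simulate_network_priors(cfg, bu)
  expect_identical(sort(unique(nw$gda$disease)), "target")
  y <- assign_prior(nw$gda, nw$ds, nw$target, genes = nw$genes)
  direct <- tapply(nw$gda$score, nw$gda$gene, max)
  expect_equal(unname(y[names(direct)]), as.numeric(direct))
})

test_that("stronger causal effects strengthen causal associations", {
  # paired over seeds: mean -log10 p of causal variants under OR 2.5 vs 1.2
  mean_logp <- function(or, seed) {
    cfg <- sim_config(n_samples = 150, n_variants = 40, n_genes = 10,
                      n_causal_snps = 5, causal_odds_ratio = or,
                      proxies_per_causal = 0, missing_rate = 0, seed = seed)
    co <- simulate_cohort(cfg)
    lab <- classify_progression(co$shs_baseline, co$shs_followup,
                                co$xray_interval_years)
    g <- co$genotypes
    keep <- match(co$causal_variant_ids, g$variant_ids)
    gc <- structure(list(dosage = g$dosage[, keep, drop = FALSE],
                         sample_ids = g$sample_ids,
                         variant_ids = g$variant_ids[keep],
                         positions = g$positions[keep],
                         ref = g$ref[keep], alt = g$alt[keep],
                         chrom = g$chrom), class = "rg_genotypes")
    a <- logistic_assoc(gc, lab)
    mean(-log10(a$p), na.rm = TRUE)
  }
  wins <- sum(vapply(1:20, function(s)
    mean_logp(2.5, s) > mean_logp(1.2, s), logical(1)))
  expect_lt(binom.test(wins, 20, alternative = "greater")$p.value, 0.05)
})

test_that("null configuration yields uniform association p-values", {
  # covariate-adjusted, as in the analysis model; with integer dosages and
  # no continuous covariate the score can tie at exactly zero, putting a
  # point mass at p = 1 that is an artifact of discreteness, not bias
  cfg <- sim_config(n_samples = 300, n_variants = 2000, n_genes = 20,
                    n_causal_snps = 2, causal_odds_ratio = 1,
                    clinical_effects = rep(0, 6), proxies_per_causal = 0,
                    missing_rate = 0, seed = 12)
  co <- simulate_cohort(cfg)
  lab <- classify_progression(co$shs_baseline, co$shs_followup,
                              co$xray_interval_years)
  a <- logistic_assoc(co$genotypes, lab, covariates = co$clinical)
  p <- a$p[!a$flagged & !is.na(a$p)]
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})
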