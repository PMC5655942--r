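# Plain-format readers/writers: VCF for genotypes, BED for interval
# tracks, TSV for link/prior tables. Coordinates are 0-based half-open in
# memory and in BED; VCF POS is 1-based on disk.

.write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a cohort to disk
#'
#' Genotypes go to an uncompressed VCF (GT field only), phenotype and
#' clinical covariates to a TSV.
#'
#' @param cohort an `rg_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- cohort$genotypes
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(file.path(dir, "genotypes.vcf"), "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", g$sample_ids),
                     collapse = "\t")), con)
  for (j in seq_along(g$variant_ids)) {
    gt <- g$dosage[, j]
    gts <- ifelse(is.na(gt), "./.", gt_code[as.character(gt)])
    writeLines(paste(c(g$chrom, g$positions[j] + 1L, g$variant_ids[j],
                       g$ref[j], g$alt[j], ".", "PASS", ".", "GT", gts),
                     collapse = "\t"), con)
  }
  close(con)
  ph <- data.frame(sample = g$sample_ids,
                   shs_baseline = cohort$shs_baseline,
                   shs_followup = cohort$shs_followup,
                   xray_interval_years = cohort$xray_interval_years,
                   cohort$clinical[g$sample_ids, , drop = FALSE])
  .write_tsv(ph, file.path(dir, "phenotype.tsv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `genotypes.vcf` and `phenotype.tsv`.
#' @return an `rg_cohort` (without simulation-only fields such as the
#'   causal variant ids).
#' @export
read_cohort <- function(dir) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(file.path(dir, "genotypes.vcf"), verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dos <- matrix(NA_integer_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  code <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L)
  dos[] <- code[t(gt)]
  fix <- vcfR::getFIX(v)
  genotypes <- structure(list(
    dosage = dos, sample_ids = rownames(dos),
    variant_ids = colnames(dos),
    positions = stats::setNames(as.integer(fix[, "POS"]) - 1L,
                                colnames(dos)),
    ref = fix[, "REF"], alt = fix[, "ALT"], chrom = fix[1, "CHROM"]
  ), class = "rg_genotypes")
  ph <- .read_tsv(file.path(dir, "phenotype.tsv"))
  rownames(ph) <- ph$sample
  ph <- ph[genotypes$sample_ids, , drop = FALSE]
  structure(list(
    genotypes = genotypes,
    shs_baseline = stats::setNames(ph$shs_baseline, ph$sample),
    shs_followup = stats::setNames(ph$shs_followup, ph$sample),
    xray_interval_years = stats::setNames(ph$xray_interval_years, ph$sample),
    disease_duration_years = stats::setNames(ph$disease_duration, ph$sample),
    clinical = ph[, c("baseline_shs", "disease_duration", "haq",
                      "anti_ccp", "bmi", "esr")],
    causal_variant_ids = character(0)
  ), class = "rg_cohort")
}

.write_bed <- function(df, path, chrom, name_col) {
  bed <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    name = df[[name_col]],
                    score = 0,
                    strand = if ("strand" %in% names(df)) df$strand else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

.read_bed <- function(path, name_col) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  out <- data.frame(name = bed$name, start = bed$start, end = bed$end,
                    stringsAsFactors = FALSE)
  names(out)[1] <- name_col
  if (any(bed$strand %in% c("+", "-"))) out$strand <- bed$strand
  out
}

#' Write an annotation bundle to disk
#'
#' Interval tracks as BED (0-based half-open), link tables as TSV.
#'
#' @param bundle an `rg_bundle`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_bed(bundle$genes, file.path(dir, "genes.bed"), bundle$chrom, "gene")
  .write_bed(bundle$promoters, file.path(dir, "promoters.bed"),
             bundle$chrom, "gene")
  .write_bed(bundle$enhancers, file.path(dir, "enhancers.bed"),
             bundle$chrom, "enhancer")
  .write_bed(bundle$mirnas, file.path(dir, "mirnas.bed"),
             bundle$chrom, "mirna")
  .write_tsv(bundle$enhancer_links, file.path(dir, "enhancer_links.tsv"))
  .write_tsv(bundle$mirna_links, file.path(dir, "mirna_links.tsv"))
  .write_tsv(bundle$eqtl, file.path(dir, "eqtl_links.tsv"))
  .write_tsv(bundle$ld, file.path(dir, "ld_proxies.tsv"))
  invisible(dir)
}

#' Read an annotation bundle written by [write_bundle()]
#'
#' @param dir directory holding the BED tracks and link TSVs.
#' @return an `rg_bundle`. Gene strand is taken from the BED strand
#'   column; the TSS is recomputed from strand and interval.
#' @export
read_bundle <- function(dir) {
  genes <- .read_bed(file.path(dir, "genes.bed"), "gene")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  structure(list(
    genes = genes,
    promoters = .read_bed(file.path(dir, "promoters.bed"), "gene"),
    enhancers = .read_bed(file.path(dir, "enhancers.bed"), "enhancer"),
    mirnas = .read_bed(file.path(dir, "mirnas.bed"), "mirna"),
    enhancer_links = .read_tsv(file.path(dir, "enhancer_links.tsv")),
    mirna_links = .read_tsv(file.path(dir, "mirna_links.tsv")),
    eqtl = .read_tsv(file.path(dir, "eqtl_links.tsv")),
    ld = .read_tsv(file.path(dir, "ld_proxies.tsv")),
    chrom = "chr1"
  ), class = "rg_bundle")
}

#' Write a disease network to disk
#'
#' @param network an `rg_network`.
#' @param dir output directory; writes `edges.tsv`, `gda.tsv`, `ds.tsv`.
#' @return the directory, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(network$edges, file.path(dir, "edges.tsv"))
  .write_tsv(network$gda, file.path(dir, "gda.tsv"))
  .write_tsv(network$ds, file.path(dir, "ds.tsv"))
  writeLines(network$target, file.path(dir, "target_disease.txt"))
  invisible(dir)
}

#' Read a disease network written by [write_network()]
#'
#' Edge lists without a weight column get unit weights.
#'
#' @param dir directory holding `edges.tsv`, `gda.tsv`, `ds.tsv`.
#' @return an `rg_network`.
#' @export
read_network <- function(dir) {
  edges <- .read_tsv(file.path(dir, "edges.tsv"))
  if (!"weight" %in% names(edges)) edges$weight <- 1
  gda <- .read_tsv(file.path(dir, "gda.tsv"))
  ds <- .read_tsv(file.path(dir, "ds.tsv"))
  target <- readLines(file.path(dir, "target_disease.txt"))[1]
  genes <- sort(unique(c(edges$gene_a, edges$gene_b, gda$gene)))
  structure(list(genes = genes, edges = edges, gda = gda, ds = ds,
                 target = target), class = "rg_network")
}
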