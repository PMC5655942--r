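# polynomial rolling hash (mod 2^31 - 1) of the serialized configuration;
# identifies which config produced an output file without an external
# hashing dependency
.config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config), digits.d = 15)),
             collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline from one configuration
#'
#' Simulates the study (cohort, annotations, disease network), writes the
#' inputs in their standard formats, fits the cross-validated ensemble
#' under each requested prioritization strategy, and writes per-strategy
#' accuracy curves, fold SNP sets, held-out probabilities, and ROC points,
#' plus a comparison report (fold overlap ratios and a paired DeLong test
#' on the pooled ensemble probabilities) when more than one strategy is
#' requested. `metrics.json` captures every headline number; reruns with
#' the same configuration are byte-identical.
#'
#' @param config an [sim_config()], a plain list of its arguments, or the
#'   path to a YAML file holding them.
#' @param out_dir output directory.
#' @param strategies prioritization strategies to fit and compare.
#' @param k_grid,n_folds,w_grid,alpha,... passed to [ragnet_cv()].
#' @param write_inputs write the simulated inputs under `out_dir/inputs`
#'   (default TRUE).
#' @return an object of class `rg_run` (invisibly): per-strategy fits and
#'   the comparison list.
#' @export
run_pipeline <- function(config, out_dir,
                         strategies = c("network_score", "gwas_p"),
                         k_grid = seq(10L, 60L, by = 5L),
                         n_folds = 10L,
                         w_grid = seq(0, 1, by = 0.01),
                         alpha = 0.5, write_inputs = TRUE, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "rg_config")) config <- do.call(sim_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  hdr <- paste0("# config_hash: ", hash)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))

  message("[simulate] seed ", config$seed, ", ", config$n_samples,
          " samples x ", config$n_variants, " variants")
  study <- simulate_study(config)
  if (write_inputs) {
    write_cohort(study$cohort, file.path(out_dir, "inputs"))
    write_bundle(study$bundle, file.path(out_dir, "inputs"))
    write_network(study$network, file.path(out_dir, "inputs"))
  }

  labels <- classify_progression(study$cohort$shs_baseline,
                                 study$cohort$shs_followup,
                                 study$cohort$xray_interval_years,
                                 mode = "two_xray")
  message("[classify] ", sum(labels$label == "no_progression"),
          " no-progression / ", sum(labels$label == "severe"),
          " severe / ", sum(labels$label == "excluded"), " excluded")
  scores <- disease_correlation_scores(study$network, alpha = alpha)

  fits <- list()
  for (st in strategies) {
    message("[cv:", st, "] k grid ", min(k_grid), "..", max(k_grid))
    fit <- ragnet_cv(study$cohort, study$bundle, scores, strategy = st,
                     k_grid = k_grid, n_folds = n_folds, w_grid = w_grid,
                     seed = config$seed, labels = labels, ...)
    fits[[st]] <- fit
    sd <- file.path(out_dir, st)
    dir.create(sd, showWarnings = FALSE)
    .write_tsv(fit$selection$curve, file.path(sd, "accuracy_curve.tsv"), hdr)
    sets <- do.call(rbind, lapply(seq_along(fit$selection$rankings),
      function(f) data.frame(fold = f,
                             snp = utils::head(fit$selection$rankings[[f]],
                                               fit$k_star))))
    .write_tsv(sets, file.path(sd, "fold_snp_sets.tsv"), hdr)
    pr <- data.frame(sample = names(fit$y), y = fit$y,
                     p_snp = fit$probabilities$snp,
                     p_clinical = if (is.null(fit$probabilities$clinical))
                       NA_real_ else fit$probabilities$clinical,
                     p_ensemble = fit$probabilities$ensemble)
    .write_tsv(pr, file.path(sd, "heldout_probabilities.tsv"), hdr)
    .write_tsv(roc_points(fit$probabilities$ensemble, fit$y),
               file.path(sd, "roc_points.tsv"), hdr)
    message(sprintf("[cv:%s] k*=%d w*=%.2f mean accuracy %.4f AUC %.4f",
                    st, fit$k_star, fit$w_star, fit$metrics$mean_accuracy,
                    fit$metrics$auc_ensemble))
  }

  comparison <- NULL
  if (length(strategies) >= 2L) {
    common_k <- min(vapply(fits, function(f) f$k_star, numeric(1)))
    overlaps <- vapply(fits, function(f)
      overlap_ratio(lapply(f$selection$rankings, utils::head, common_k)),
      numeric(1))
    ref <- fits[[strategies[1]]]
    auc_tests <- list()
    for (st in strategies[-1]) {
      auc_tests[[st]] <- compare_auc(ref$probabilities$ensemble,
                                     fits[[st]]$probabilities$ensemble[
                                       names(ref$y)],
                                     ref$y)
    }
    comparison <- list(common_k = common_k, overlap_ratio = overlaps,
                       auc_tests = auc_tests)
  }

  metrics <- list(
    config_hash = hash,
    seed = config$seed,
    n_analysis_samples = length(fits[[1]]$y),
    strategies = lapply(fits, function(f) list(
      k_star = f$k_star, w_star = f$w_star,
      mean_accuracy = f$metrics$mean_accuracy,
      accuracy_snp = f$metrics$accuracy_snp,
      accuracy_clinical = f$metrics$accuracy_clinical,
      accuracy_ensemble = f$metrics$accuracy_ensemble,
      auc_snp = f$metrics$auc_snp,
      auc_clinical = f$metrics$auc_clinical,
      auc_ensemble = f$metrics$auc_ensemble,
      sensitivity = unname(f$metrics$threshold["sensitivity"]),
      specificity = unname(f$metrics$threshold["specificity"]),
      ppv = unname(f$metrics$threshold["ppv"]),
      mean_n_significant = mean(f$selection$n_significant))),
    comparison = if (!is.null(comparison)) list(
      common_k = comparison$common_k,
      overlap_ratio = as.list(comparison$overlap_ratio),
      auc_p_values = lapply(comparison$auc_tests, function(t) t$p_value)))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(list(fits = fits, comparison = comparison,
                           metrics = metrics, labels = labels,
                           study = study, out_dir = out_dir,
                           config_hash = hash),
                      class = "rg_run"))
}

#' @export
print.rg_run <- function(x, ...) {
  cat("Pipeline run (config", x$config_hash, ") ->", x$out_dir, "\n")
  for (st in names(x$fits)) {
    f <- x$fits[[st]]
    cat(sprintf("  %-14s k*=%3d  w*=%.2f  accuracy %.4f  AUC %.4f\n", st,
                f$k_star, f$w_star, f$metrics$mean_accuracy,
                f$metrics$auc_ensemble))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  fold overlap at k=%d: %s\n", x$comparison$common_k,
                paste(sprintf("%s %.4f", names(x$comparison$overlap_ratio),
                              x$comparison$overlap_ratio), collapse = ", ")))
  }
  invisible(x)
}
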