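#' Full fine-mapping pipeline configuration
#'
#' Bundles every stage threshold: SNP QC ([qc_thresholds()]), the
#' regional significance gate (p < 1e-5), core-SNP narrowing (p < 1e-6,
#' 500 kb flank), the secondary-signal rule (conditional p < 1e-5), the
#' NEG penalty (shape 0.05, per-variant type-I error 1e-4, 100
#' iterations), the elastic-net comparison spec, the model-equivalence
#' threshold (r2 0.9) and the variance-explained convention.
#'
#' @param qc A [qc_thresholds()].
#' @param p_gate,p_core,flank,p_secondary Scan thresholds.
#' @param penalty A [neg_penalty_spec()].
#' @param n_iter NEG iterations (default 100).
#' @param altpen An [enet_spec()], or `NULL` to skip the comparison fit.
#' @param prune_r2 LD-pruning threshold before the elastic net (0.95).
#' @param r2_equiv Model-equivalence threshold (0.9).
#' @param variance_method `"linear_predictor"` or `"cox_snell"`.
#' @param seed Master seed for the stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(), p_gate = 1e-5,
                            p_core = 1e-6, flank = 500000,
                            p_secondary = 1e-5,
                            penalty = neg_penalty_spec(),
                            n_iter = 100, altpen = NULL,
                            prune_r2 = 0.95, r2_equiv = 0.9,
                            variance_method = "linear_predictor",
                            seed = 1) {
  stopifnot(p_gate > 0, p_core > 0, flank >= 0, p_secondary > 0,
            n_iter >= 1, r2_equiv > 0, r2_equiv <= 1)
  structure(list(qc = qc, p_gate = p_gate, p_core = p_core, flank = flank,
                 p_secondary = p_secondary, penalty = penalty,
                 n_iter = n_iter, altpen = altpen, prune_r2 = prune_r2,
                 r2_equiv = r2_equiv, variance_method = variance_method,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full fine-mapping pipeline on one region
#'
#' Stages, in order: SNP QC and retention typing; single-SNP scan with
#' the region covariate; the p < `p_gate` significance gate (a region
#' failing the gate is analyzed no further — the result carries
#' `gated = FALSE` and stops there); narrowing to `flank` around core
#' SNPs; conditional scan on the top SNP and the secondary-signal
#' rule; repeated NEG-penalized model search; collapsing into
#' LD-equivalence classes with unpenalized refits; optional
#' lasso/elastic-net comparison on LD-pruned data; variance-explained
#' summary for the top SNP and the modal model. If `out_dir` is given,
#' every stage table is written as a deterministic TSV via
#' [write_reports()] together with a JSON manifest (seed, thresholds,
#' per-stage row counts).
#'
#' @param x A [dosage_data()] object.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for TSV reports.
#' @return A list of class `pipeline_result` with elements `qc_report`,
#'   `scan`, `gated`, `top_snp`, `window`, `conditional_scan`,
#'   `secondary`, `models`, `classes`, `altpen_fit`, `variance`,
#'   `manifest`.
#' @export
run_pipeline <- function(x, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(x, "dosage_data"), inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed,
                   n_variants_in = nrow(x$variants),
                   n_samples = nrow(x$samples))

  qc_res <- run_snp_qc(x, config$qc)
  xq <- qc_res$data
  manifest$n_variants_retained <- nrow(xq$variants)
  if (nrow(xq$variants) == 0) stop("stage qc: no variants retained")

  scan <- single_snp_scan(xq)
  manifest$n_scanned <- sum(!is.na(scan$p))
  gated <- gate_region(scan, config$p_gate)
  result <- list(qc_report = qc_res$report, scan = scan, gated = gated,
                 top_snp = NA_character_, window = NULL,
                 conditional_scan = NULL, secondary = NULL, models = NULL,
                 classes = NULL, altpen_fit = NULL, variance = NULL)
  class(result) <- "pipeline_result"

  if (!gated) {
    manifest$stopped_at <- "gate"
    result$manifest <- manifest
    if (!is.null(out_dir)) write_pipeline_reports(result, out_dir)
    return(result)
  }

  ts <- top_snp(scan)
  result$top_snp <- ts
  window <- narrow_region(scan, config$p_core, config$flank)
  result$window <- window
  in_win <- xq$variants$pos >= window$start & xq$variants$pos <= window$end
  xw <- subset_dosage(xq, variants = in_win)
  manifest$n_variants_window <- nrow(xw$variants)

  cond <- single_snp_scan(xw, condition_on = ts)
  result$conditional_scan <- cond
  result$secondary <- secondary_signal(cond, config$p_secondary)

  iter <- run_iterations(xw, config$penalty, n_iter = config$n_iter,
                         base_seed = config$seed)
  result$models <- iter$models
  result$classes <- collapse_models(iter$models, xw,
                                    r2_equiv = config$r2_equiv)

  if (!is.null(config$altpen)) {
    pruned <- ld_prune(xw, config$prune_r2)
    result$altpen_fit <- fit_elastic_net(pruned$data, config$altpen)
    manifest$n_variants_pruned <- nrow(pruned$data$variants)
  }

  modal <- if (!is.null(result$classes) && nrow(result$classes) > 0) {
    strsplit(result$classes$representative[1], ",")[[1]]
  } else {
    character(0)
  }
  modal <- modal[nzchar(modal)]
  result$variance <- tibble::tibble(
    model = c("top_snp", "modal_class"),
    n_snps = c(1L, length(modal)),
    variance_pct = c(
      variance_explained(xw, ts, method = config$variance_method),
      variance_explained(xw, modal, method = config$variance_method)
    )
  )
  manifest$modal_class_size <- length(modal)
  manifest$stopped_at <- "complete"
  result$manifest <- manifest
  if (!is.null(out_dir)) write_pipeline_reports(result, out_dir)
  result
}

write_pipeline_reports <- function(result, out_dir) {
  tables <- list(qc_report = result$qc_report, scan = result$scan)
  if (!is.null(result$conditional_scan)) {
    tables$conditional_scan <- result$conditional_scan
  }
  if (!is.null(result$models)) tables$models <- result$models
  if (!is.null(result$classes)) {
    tables$classes <- dplyr::select(result$classes, -"refit")
    refits <- purrr::imap_dfr(result$classes$refit, function(rf, i) {
      if (is.null(rf)) return(NULL)
      dplyr::mutate(rf, class_id = result$classes$class_id[i],
                    .before = 1)
    })
    tables$class_refits <- refits
  }
  if (!is.null(result$variance)) tables$variance <- result$variance
  write_reports(tables, out_dir)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(result$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  variants scanned:", x$manifest$n_scanned, "\n")
  if (!x$gated) {
    cat("  stopped at the p-value gate (no SNP below threshold)\n")
    return(invisible(x))
  }
  cat("  top SNP:", x$top_snp, "\n")
  if (!is.null(x$secondary)) {
    cat("  secondary signal:", x$secondary$found, "\n")
  }
  if (!is.null(x$classes) && nrow(x$classes) > 0) {
    cat("  modal model class: {", x$classes$representative[1], "} in ",
        x$classes$frequency[1], " iteration(s)\n", sep = "")
  }
  invisible(x)
}
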