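#' Percentage of risk variance explained by a fitted genetic model
#'
#' Two conventions are provided, both excluding the covariate (region)
#' contribution from the genetic signal:
#' `"linear_predictor"` (default): `100 * Var(s) / (Var(s) + pi^2/3)`
#' where `s` is the genetic part of the linear predictor (dosages times
#' fitted per-allele log-odds) and `pi^2/3` the logistic residual
#' variance; `"cox_snell"`: `100 * (1 - exp(-LR/n))` with `LR` the
#' likelihood-ratio statistic of the genetic terms against the
#' covariate-only model. Both are invariant to allele flipping.
#'
#' @param x A [dosage_data()] object.
#' @param model A fitted model: the tibble returned by [refit_model()]
#'   (which carries its joint fit), or a character vector of variant
#'   ids to refit. An empty set returns 0.
#' @param method `"linear_predictor"` or `"cox_snell"`.
#' @param adjust_region Covariates used in the (re)fit.
#' @return Percentage (scalar, >= 0).
#' @export
variance_explained <- function(x, model,
                               method = c("linear_predictor", "cox_snell"),
                               adjust_region = TRUE) {
  stopifnot(inherits(x, "dosage_data"))
  method <- match.arg(method)
  if (is.character(model)) {
    if (length(model) == 0) return(0)
    model <- refit_model(x, model, adjust_region = adjust_region)
  }
  if (!is.data.frame(model) || is.null(attr(model, "fit"))) {
    stop("model must be a refit_model() result or a character vector of ids")
  }
  if (nrow(model) == 0) return(0)

  if (method == "linear_predictor") {
    d <- dosages(x)
    vi <- match(model$id, x$variants$id)
    s <- drop(crossprod(d[vi, , drop = FALSE], model$beta))
    v <- stats::var(s)
    100 * v / (v + pi^2 / 3)
  } else {
    y <- case_indicator(x$samples)
    z <- base_design(x$samples, adjust_region)
    ll0 <- fit_logistic(z, y)$loglik
    lr <- 2 * (attr(model, "loglik") - ll0)
    100 * (1 - exp(-max(0, lr) / length(y)))
  }
}

#' Regional variance-explained totals and improvement ratios
#'
#' Sums per-region variance-explained percentages over the analyzed
#' regions and computes improvement percentages `100 * (ratio - 1)` on
#' values rounded to `sig_digits` significant figures (matching how
#' such headline numbers are usually presented). Per-region
#' improvements of a multi-SNP model column over the top-SNP column
#' are reported where available. Rows with missing cells are excluded
#' from the affected computation with a warning.
#'
#' @param values Tibble with columns `region`, `reported_snp_r2`,
#'   `top_snp_r2` and optionally `model_r2` (percent units).
#' @param sig_digits Significant figures for rounding (default 2).
#' @return A list with `totals` (tibble: `total_reported_r2`,
#'   `total_top_r2`, `improvement_pct`) and `regions` (tibble:
#'   `region`, `top_snp_r2`, `model_r2`, `improvement_pct`; only
#'   regions with a model value).
#' @export
summarize_regions <- function(values, sig_digits = 2) {
  values <- tibble::as_tibble(values)
  stopifnot(all(c("region", "reported_snp_r2", "top_snp_r2") %in%
                  names(values)))
  ok <- !is.na(values$reported_snp_r2) & !is.na(values$top_snp_r2)
  if (any(!ok)) {
    warning(sum(!ok), " region(s) with missing cells excluded from totals")
  }
  tot_rep <- signif(sum(values$reported_snp_r2[ok]), sig_digits)
  tot_top <- signif(sum(values$top_snp_r2[ok]), sig_digits)
  totals <- tibble::tibble(
    total_reported_r2 = tot_rep,
    total_top_r2 = tot_top,
    improvement_pct = round(100 * (tot_top / tot_rep - 1))
  )
  regions <- tibble::tibble(region = character(0), top_snp_r2 = numeric(0),
                            model_r2 = numeric(0),
                            improvement_pct = numeric(0))
  if ("model_r2" %in% names(values)) {
    withm <- dplyr::filter(values, !is.na(.data$model_r2),
                           !is.na(.data$top_snp_r2))
    regions <- tibble::tibble(
      region = withm$region,
      top_snp_r2 = withm$top_snp_r2,
      model_r2 = withm$model_r2,
      improvement_pct = round(100 * (withm$model_r2 / withm$top_snp_r2 - 1))
    )
  }
  list(totals = totals, regions = regions)
}

#' Published melanoma susceptibility region summaries
#'
#' Per-region published summary statistics for 17 melanoma
#' susceptibility regions from a large European case-control
#' fine-mapping analysis (5,374 cases, 7,691 controls): the SNP first
#' reported for each region and the most significant SNP after
#' imputation, with trend-test p-values and the percentage of risk
#' variance each explains. For two regions the reported SNP remained
#' the top SNP (`top_is_reference`). Thirteen regions were analyzed in
#' depth (`analyzed`): three showed no SNP at p < 1e-5 and one (MC1R)
#' was analyzed separately. Positions are genome build 37. These
#' printed values are inputs to the summary arithmetic in
#' [summarize_regions()]; the package does not re-derive them.
#'
#' @return A tibble with one row per region.
#' @export
melanoma_regions <- function() {
  t1 <- tibble::tribble(
    ~region, ~chrom, ~reported_snp, ~reported_pos, ~reported_p,
    ~reported_snp_r2, ~top_snp, ~top_pos, ~top_p, ~top_snp_r2,
    "ARNT", "1", "rs7412746", 150860471L, 2.6e-4, 0.08,
    "rs3768013", 150815411L, 2.9e-6, 0.13,
    "PARP1", "1", "rs3219090", 226564691L, 6.4e-6, 0.12,
    "rs1858550", 226608104L, 1.7e-7, 0.16,
    "CASP8", "2", "rs13016963", 202162811L, 9.5e-7, 0.14,
    "rs2349073", 202186986L, 6.3e-8, 0.17,
    "TERT", "5", "rs401681", 1322087L, 4.9e-11, 0.25,
    "rs2447853", 1333077L, 5.7e-12, 0.27,
    "SLC45A2", "5", "rs16891982", 33951693L, 2.2e-9, 0.20,
    NA_character_, NA_integer_, NA_real_, NA_real_,
    "IRF4", "6", "rs12203592", 396321L, 0.014, 0.04,
    "rs9405705", 470384L, 1.5e-4, 0.08,
    "CDKN2A", "9", "rs7023329", 21816528L, 8.3e-14, 0.32,
    "rs869330", 21804617L, 3.8e-16, 0.38,
    "TYRP1", "9", "rs2733832", 12704725L, 0.43, 0.01,
    "rs72706189", 11877260L, 1.3e-5, 0.11,
    "CCND1", "11", "rs1485993", 69362414L, 4.5e-9, 0.20,
    "rs12422135", 69378260L, 3.5e-10, 0.22,
    "TYR", "11", "rs1393350", 89011046L, 5.3e-13, 0.30,
    "rs1126809", 89017961L, 9.8e-15, 0.34,
    "ATM", "11", "rs1801516", 108175462L, 1.8e-7, 0.16,
    "rs4753835", 108145249L, 1.7e-7, 0.16,
    "OCA2", "15", "rs1129038", 28356859L, 0.081, 0.02,
    "rs145720174", 28468231L, 4.8e-4, 0.07,
    "FTO", "16", "rs12596638", 54115829L, 5.1e-7, 0.14,
    NA_character_, NA_integer_, NA_real_, NA_real_,
    "MC1R", "16", "rs258322", 89755903L, 6.8e-41, 1.02,
    "rs73283859", 90062520L, 3.6e-52, 1.31,
    "ASIP", "20", "rs2284378", 32818707L, 1.4e-6, 0.13,
    "rs6059655", 32665748L, 2.1e-11, 0.26,
    "MX2", "21", "rs45430", 42746081L, 2.9e-8, 0.18,
    "rs443099", 42743327L, 1.1e-8, 0.19,
    "PLA2G6", "22", "rs6001027", 38545619L, 3.8e-7, 0.15,
    "rs3891103", 38537159L, 2.9e-9, 0.20
  )
  t1 <- dplyr::mutate(
    t1,
    top_is_reference = is.na(.data$top_snp),
    top_snp = dplyr::coalesce(.data$top_snp, .data$reported_snp),
    top_pos = dplyr::coalesce(.data$top_pos, .data$reported_pos),
    top_p = dplyr::coalesce(.data$top_p, .data$reported_p),
    top_snp_r2 = dplyr::coalesce(.data$top_snp_r2, .data$reported_snp_r2),
    analyzed = !.data$region %in% c("IRF4", "TYRP1", "OCA2", "MC1R")
  )
  t1
}

#' Published multi-SNP models for the complex melanoma regions
#'
#' The published per-SNP results for the four regions whose signal
#' needed more than one variant: single-SNP odds ratio and p-value,
#' LD with the region's top SNP, the joint (multiple-variant logistic
#' regression) odds ratio and p-value, and the percentage of risk
#' variance explained by the full model (`model_r2`, one value per
#' region). Inputs to the improvement arithmetic of
#' [summarize_regions()].
#'
#' @return A tibble with one row per SNP.
#' @export
melanoma_multisnp_models <- function() {
  tibble::tribble(
    ~region, ~snp, ~pos, ~gene, ~allele, ~allele_freq, ~or_single,
    ~p_single, ~r2_with_top, ~or_joint, ~p_joint, ~model_r2,
    "TERT", "rs7705526", 1285974L, "TERT", "A", 0.332, 1.13, 2.9e-5,
    0.09, 1.09, 0.026, 0.46,
    "TERT", "rs2736099", 1287340L, "TERT", "A", 0.374, 1.12, 6.6e-5,
    0.14, 1.09, 0.025, 0.46,
    "TERT", "rs1801075", 1317949L, "intergenic", "C", 0.172, 1.23, 2.7e-10,
    0.51, 1.08, 0.050, 0.46,
    "TERT", "rs2447853", 1333077L, "CLPTM1L", "G", 0.468, 1.20, 5.7e-12,
    NA, 1.18, 1.3e-7, 0.46,
    "CDKN2A", "rs869330", 21804617L, "MTAP", "G", 0.513, 0.81, 3.9e-16,
    NA, 0.81, 8.0e-16, 0.65,
    "CDKN2A", "rs3088440", 21968159L, "CDKN2A", "A", 0.089, 1.21, 2.0e-5,
    0.03, 1.13, 0.014, 0.65,
    "CDKN2A", "rs3731204", 21984661L, "CDKN2A", "C", 0.148, 0.81, 2.2e-8,
    0.03, 0.84, 8.1e-6, 0.65,
    "CDKN2A", "rs1011970", 22062134L, "CDKN2B-AS1", "T", 0.166, 1.17, 2.3e-6,
    0.02, 1.09, 0.033, 0.65,
    "CCND1", "rs2290419", 68919649L, "intergenic", "G", 0.057, 0.78, 2.1e-5,
    0.03, 0.76, 7.2e-6, 0.37,
    "CCND1", "rs623110", 69308897L, "intergenic", "T", 0.314, 1.13, 1.3e-5,
    0.35, 1.07, 0.015, 0.37,
    "CCND1", "rs12422135", 69378736L, "intergenic", "A", 0.409, 1.18, 3.5e-10,
    NA, 1.15, 3.1e-7, 0.37,
    "ASIP", "rs74325991", 32547380L, "intergenic", "G", 0.490, 1.18, 8.8e-8,
    0.38, 1.11, 0.0025, 0.31,
    "ASIP", "rs6059655", 32665748L, "RALY", "A", 0.086, 1.33, 2.1e-11,
    NA, 1.26, 4.6e-7, 0.31
  )
}
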