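#' Construct a dosage dataset
#'
#' A `dosage_data` object holds genotype posterior probabilities for one
#' genomic region: three variants-by-samples matrices of posterior
#' probabilities (`p_aa`, `p_ab`, `p_bb`, for 0, 1 and 2 copies of the
#' alternate allele), per-variant metadata and a per-sample table. The
#' expected alternate-allele count ("dosage", in \[0, 2\]) is derived as
#' `p_ab + 2 * p_bb` and is the regression covariate used throughout the
#' package. A missing genotype is a row of `NA`s in all three matrices.
#'
#' @param variants Tibble of per-variant metadata with columns `id`,
#'   `chrom`, `pos` (1-based base pairs, strictly increasing), `a0`
#'   (reference allele), `a1` (alternate allele). Optional columns:
#'   `genotyped_on` (list of array labels the variant was directly typed
#'   on), `info_by_array` (list of named numeric INFO scores in \[0, 1\]),
#'   `retention` (one of `"A"`, `"B"`, `"C"`, `"excluded"`, `"unset"`).
#' @param p_aa,p_ab,p_bb Numeric matrices (variants x samples) of genotype
#'   posterior probabilities. Non-missing triplets must sum to 1 within
#'   `sum_tol`; they are renormalised to sum to 1 exactly. Triplets whose
#'   sum deviates by more than `sum_tol` are set missing (all `NA`).
#' @param samples Tibble with columns `sample_id`, `status` (`"case"` or
#'   `"control"`), `region` (stratification label) and optionally `array`
#'   (genotyping array label; defaults to `"array1"`).
#' @param sum_tol Tolerance on the posterior-triplet sum (default 0.02).
#'
#' @return An object of class `dosage_data`.
#' @export
dosage_data <- function(variants, p_aa, p_ab, p_bb, samples, sum_tol = 0.02) {
  variants <- tibble::as_tibble(variants)
  req <- c("id", "chrom", "pos", "a0", "a1")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    stop("variants is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"genotyped_on" %in% names(variants)) {
    variants$genotyped_on <- replicate(nrow(variants), character(0), simplify = FALSE)
  }
  if (!"info_by_array" %in% names(variants)) {
    variants$info_by_array <- replicate(nrow(variants), numeric(0), simplify = FALSE)
  }
  if (!"retention" %in% names(variants)) variants$retention <- "unset"
  stopifnot(all(variants$pos >= 1))
  if (nrow(variants) > 1 && any(diff(variants$pos) < 0)) {
    stop("variants must be ordered by increasing position")
  }
  info_all <- unlist(variants$info_by_array)
  if (length(info_all) > 0 && (any(info_all < 0) || any(info_all > 1))) {
    stop("INFO scores must lie in [0, 1]")
  }
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")

  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "status", "region") %in% names(samples))) {
    stop("samples needs columns sample_id, status, region")
  }
  if (!all(samples$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'")
  }
  if (!"array" %in% names(samples)) samples$array <- "array1"

  p_aa <- as.matrix(p_aa); p_ab <- as.matrix(p_ab); p_bb <- as.matrix(p_bb)
  dims <- c(nrow(variants), nrow(samples))
  for (m in list(p_aa, p_ab, p_bb)) {
    if (!all(dim(m) == dims)) stop("posterior matrices must be variants x samples")
  }
  s <- p_aa + p_ab + p_bb
  bad <- !is.na(s) & abs(s - 1) > sum_tol
  if (any(bad)) {
    p_aa[bad] <- NA_real_; p_ab[bad] <- NA_real_; p_bb[bad] <- NA_real_
    s[bad] <- NA_real_
  }
  ok <- !is.na(s)
  p_aa[ok] <- p_aa[ok] / s[ok]
  p_ab[ok] <- p_ab[ok] / s[ok]
  p_bb[ok] <- p_bb[ok] / s[ok]
  dimnames(p_aa) <- dimnames(p_ab) <- dimnames(p_bb) <-
    list(variants$id, samples$sample_id)

  structure(
    list(variants = variants, p_aa = p_aa, p_ab = p_ab, p_bb = p_bb,
         samples = samples),
    class = "dosage_data"
  )
}

#' @export
print.dosage_data <- function(x, ...) {
  cat("<dosage_data> ", nrow(x$variants), " variants x ", nrow(x$samples),
      " samples\n", sep = "")
  cat("  cases: ", sum(x$samples$status == "case"),
      ", controls: ", sum(x$samples$status == "control"),
      ", regions: ", length(unique(x$samples$region)),
      ", arrays: ", length(unique(x$samples$array)), "\n", sep = "")
  invisible(x)
}

#' Expected-dosage matrix of a dosage dataset
#'
#' @param x A [dosage_data()] object.
#' @param impute_missing If `TRUE` (default), missing genotypes are
#'   mean-imputed with `2 * alt_freq` of the variant, so design matrices
#'   stay complete (the expected dosage of an individual about whom
#'   nothing is known). If `FALSE`, they stay `NA`.
#' @return Numeric matrix (variants x samples) with entries in \[0, 2\].
#' @export
dosages <- function(x, impute_missing = TRUE) {
  stopifnot(inherits(x, "dosage_data"))
  d <- x$p_ab + 2 * x$p_bb
  if (impute_missing && anyNA(d)) {
    af <- rowMeans(d, na.rm = TRUE) / 2
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- 2 * af[idx[, 1]]
  }
  d
}

#' Per-variant alternate-allele frequency and minor-allele frequency
#'
#' Frequencies are computed from expected dosages over all samples
#' (cases and controls pooled).
#'
#' @param x A [dosage_data()] object.
#' @return A tibble with columns `id`, `alt_freq`, `maf`.
#' @export
allele_freqs <- function(x) {
  d <- dosages(x, impute_missing = FALSE)
  af <- rowMeans(d, na.rm = TRUE) / 2
  tibble::tibble(id = x$variants$id, alt_freq = af, maf = pmin(af, 1 - af))
}

#' Subset a dosage dataset by variant and/or sample
#'
#' @param x A [dosage_data()] object.
#' @param variants Variant ids or logical/integer index; `NULL` keeps all.
#' @param samples Sample ids or logical/integer index; `NULL` keeps all.
#' @return A [dosage_data()] object.
#' @export
subset_dosage <- function(x, variants = NULL, samples = NULL) {
  stopifnot(inherits(x, "dosage_data"))
  vi <- seq_len(nrow(x$variants))
  si <- seq_len(nrow(x$samples))
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, x$variants$id) else vi[variants]
    if (anyNA(vi)) stop("unknown variant id(s)")
    vi <- sort(vi)
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples$sample_id) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  structure(
    list(variants = x$variants[vi, , drop = FALSE],
         p_aa = x$p_aa[vi, si, drop = FALSE],
         p_ab = x$p_ab[vi, si, drop = FALSE],
         p_bb = x$p_bb[vi, si, drop = FALSE],
         samples = x$samples[si, , drop = FALSE]),
    class = "dosage_data"
  )
}

#' Hard-call genotypes (best guess) from posteriors
#'
#' @param x A [dosage_data()] object.
#' @return Integer matrix (variants x samples) with values 0/1/2 or `NA`.
#' @export
hard_calls <- function(x) {
  stopifnot(inherits(x, "dosage_data"))
  g <- matrix(NA_integer_, nrow(x$p_aa), ncol(x$p_aa), dimnames = dimnames(x$p_aa))
  ok <- !is.na(x$p_aa)
  which_max3 <- (x$p_ab > x$p_aa & x$p_ab >= x$p_bb) * 1L +
    (x$p_bb > x$p_aa & x$p_bb > x$p_ab) * 2L
  g[ok] <- which_max3[ok]
  g
}

# Region-indicator design columns: one-hot minus the reference level
# (first label alphabetically). Returns a (samples x k-1) matrix.
region_design <- function(samples) {
  lev <- sort(unique(as.character(samples$region)))
  if (length(lev) == 1) {
    return(matrix(numeric(0), nrow = nrow(samples), ncol = 0))
  }
  m <- vapply(lev[-1], function(l) as.numeric(samples$region == l),
              numeric(nrow(samples)))
  colnames(m) <- paste0("region", lev[-1])
  m
}

case_indicator <- function(samples) as.numeric(samples$status == "case")

# intercept plus (optionally) region indicator columns, always n rows
base_design <- function(samples, adjust_region = TRUE) {
  icpt <- matrix(1, nrow(samples), 1, dimnames = list(NULL, "intercept"))
  if (adjust_region) cbind(icpt, region_design(samples)) else icpt
}
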