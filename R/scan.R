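#' Single-SNP (and conditional) dosage logistic scan
#'
#' For each variant, fits `status ~ dosage + region + conditioning
#' dosages` by logistic regression on expected dosages and reports the
#' per-allele log-odds ratio with its Wald test (the additive trend
#' test). The stratification region enters as one-hot indicators minus
#' the reference level (first label alphabetically). Under
#' quasi-separation the Wald test is unreliable and the score test
#' p-value is reported instead (`note = "separated"`). A constant
#' dosage column yields a flagged record with no p-value. Variants in
#' the conditioning set are skipped with a note.
#'
#' @param x A [dosage_data()] object (QC/retention already applied).
#' @param condition_on Character vector of variant ids whose dosages are
#'   added as covariates (conditional scan); default none.
#' @param test `"wald"` (default) or `"score"` for the dosage term.
#' @param adjust_region Include the region covariate (default `TRUE`).
#' @return A tibble with one row per variant: `id`, `chrom`, `pos`,
#'   `retention`, `beta`, `se`, `or`, `p`, `n_used`, `conditioned_on`
#'   (comma-joined), `note`.
#' @export
single_snp_scan <- function(x, condition_on = character(0),
                            test = c("wald", "score"),
                            adjust_region = TRUE) {
  stopifnot(inherits(x, "dosage_data"))
  test <- match.arg(test)
  y <- case_indicator(x$samples)
  if (all(y == 1) || all(y == 0)) stop("need at least one case and one control")
  d <- dosages(x)
  base <- base_design(x$samples, adjust_region)
  if (length(condition_on) > 0) {
    ci <- match(condition_on, x$variants$id)
    if (anyNA(ci)) stop("unknown conditioning variant id(s)")
    cond <- t(d[ci, , drop = FALSE])
    colnames(cond) <- paste0("cond_", condition_on)
    base <- cbind(base, cond)
  }
  cond_str <- paste(condition_on, collapse = ",")
  null_fit <- fit_logistic(base, y)

  m <- nrow(x$variants)
  out <- tibble::tibble(
    id = x$variants$id, chrom = x$variants$chrom, pos = x$variants$pos,
    retention = x$variants$retention,
    beta = NA_real_, se = NA_real_, or = NA_real_, p = NA_real_,
    n_used = length(y), conditioned_on = cond_str, note = NA_character_
  )
  for (i in seq_len(m)) {
    if (out$id[i] %in% condition_on) {
      out$note[i] <- "in_conditioning_set"
      next
    }
    g <- d[i, ]
    if (stats::sd(g) == 0) {
      out$note[i] <- "constant_dosage"
      next
    }
    if (test == "score") {
      st <- score_test(base, g, y, null_fit = null_fit)
      fit <- fit_logistic(cbind(base, dosage = g), y)
      out$beta[i] <- fit$coefficients[["dosage"]]
      out$se[i] <- fit$se[["dosage"]]
      out$p[i] <- st$p
    } else {
      fit <- fit_logistic(cbind(base, dosage = g), y)
      if (fit$separated || "dosage" %in% fit$dropped) {
        st <- score_test(base, g, y, null_fit = null_fit)
        out$p[i] <- st$p
        out$note[i] <- "separated"
        next
      }
      out$beta[i] <- fit$coefficients[["dosage"]]
      out$se[i] <- fit$se[["dosage"]]
      z <- out$beta[i] / out$se[i]
      out$p[i] <- 2 * pnorm(-abs(z))
    }
    out$or[i] <- exp(out$beta[i])
  }
  out
}

#' Most significant SNP of a scan
#'
#' Minimum p-value; ties broken by smaller position, then lexicographic
#' id. Flagged records (no p-value) are ignored.
#'
#' @param records A scan tibble from [single_snp_scan()].
#' @return The top variant id (length-1 character).
#' @export
top_snp <- function(records) {
  usable <- dplyr::filter(records, !is.na(.data$p))
  if (nrow(usable) == 0) stop("no usable scan records")
  usable <- dplyr::arrange(usable, .data$p, .data$pos, .data$id)
  usable$id[1]
}

#' Regional significance gate
#'
#' `TRUE` iff any scan p-value is strictly below `p_gate`. Regions that
#' fail the gate are analyzed no further.
#'
#' @param records Scan tibble.
#' @param p_gate Gate threshold (default 1e-5).
#' @return Logical scalar.
#' @export
gate_region <- function(records, p_gate = 1e-5) {
  p <- records$p[!is.na(records$p)]
  length(p) > 0 && min(p) < p_gate
}

#' Narrow a region around its core SNPs
#'
#' The analysis window is the interval covering `flank` base pairs on
#' either side of any SNP with p-value strictly below `p_core`, clipped
#' at position 1. If no SNP reaches `p_core` (but the region passed the
#' gate), the window falls back to the top SNP plus/minus `flank`.
#'
#' @param records Scan tibble.
#' @param p_core Core-SNP threshold (default 1e-6).
#' @param flank Flank in base pairs (default 500000).
#' @return A tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
narrow_region <- function(records, p_core = 1e-6, flank = 500000) {
  usable <- dplyr::filter(records, !is.na(.data$p))
  if (nrow(usable) == 0) stop("no usable scan records")
  core <- dplyr::filter(usable, .data$p < p_core)
  if (nrow(core) == 0) {
    core <- dplyr::filter(usable, .data$id == top_snp(records))
  }
  tibble::tibble(
    chrom = core$chrom[1],
    start = max(1, min(core$pos) - flank),
    end = max(core$pos) + flank
  )
}

#' Detect a secondary association signal after conditioning
#'
#' Given a conditional scan (top SNP(s) in the model), reports whether
#' any variant outside the conditioning set reaches a p-value strictly
#' below `p_secondary`, and which.
#'
#' @param records_conditional Conditional scan tibble.
#' @param p_secondary Threshold (default 1e-5).
#' @return A list with `found` (logical), `id`, `p` (of the best
#'   secondary variant; `NA` if none usable).
#' @export
secondary_signal <- function(records_conditional, p_secondary = 1e-5) {
  usable <- dplyr::filter(records_conditional, is.na(.data$note) |
                            .data$note == "separated", !is.na(.data$p))
  if (nrow(usable) == 0) {
    return(list(found = FALSE, id = NA_character_, p = NA_real_))
  }
  usable <- dplyr::arrange(usable, .data$p, .data$pos, .data$id)
  list(found = usable$p[1] < p_secondary, id = usable$id[1], p = usable$p[1])
}
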