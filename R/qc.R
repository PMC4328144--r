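#' SNP-level QC thresholds
#'
#' Container for the SNP quality-control and post-imputation retention
#' thresholds: exclude a genotyped SNP if its exact Hardy-Weinberg test
#' p-value in controls is below `hwe_p_min`, its call rate below
#' `call_rate_min`, or its minor allele frequency below `maf_min`;
#' retain an imputed SNP as Type B when its minimum INFO across arrays
#' is at least `info_high`, or as Type C when the minimum INFO is at
#' least `info_low` (but below `info_high`) and MAF is at least
#' `maf_min`.
#'
#' @param hwe_p_min HWE exact-test p-value floor in controls (default 1e-4).
#' @param call_rate_min Minimum hard-call rate for genotyped SNPs (0.97).
#' @param maf_min Minimum minor allele frequency (0.03).
#' @param info_high,info_low INFO-score cutpoints (0.8, 0.5).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-4, call_rate_min = 0.97,
                          maf_min = 0.03, info_high = 0.8, info_low = 0.5) {
  stopifnot(hwe_p_min > 0, call_rate_min > 0, maf_min > 0,
            info_low > 0, info_low <= info_high, info_high <= 1)
  structure(list(hwe_p_min = hwe_p_min, call_rate_min = call_rate_min,
                 maf_min = maf_min, info_high = info_high,
                 info_low = info_low),
            class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, enumerate
#' every compatible heterozygote count, compute its conditional
#' probability under random mating by recurrence, and sum the
#' probabilities of all outcomes no more probable than the observed one
#' (two-sided, by probability ordering).
#'
#' @param n_aa,n_ab,n_bb Non-negative integer genotype counts.
#' @return A p-value in (0, 1\]. Monomorphic input (minor allele count
#'   zero) returns 1 by convention.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("total genotype count must be >= 1")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)

  # heterozygote counts share the parity of the rare allele count;
  # anchor the recurrence at the modal count so ratios never overflow
  het_obs <- n_ab
  hets <- seq(rare %% 2, rare, by = 2)
  k <- length(hets)
  mode_h <- round(rare * (2 * n - rare) / (2 * n))
  if (mode_h %% 2 != rare %% 2) mode_h <- mode_h + 1
  mode_i <- which.min(abs(hets - mode_h))
  probs <- numeric(k)
  probs[mode_i] <- 1
  # downwards: P(h-2)/P(h) = h(h-1) / (4 (n_rr+1)(n_cc+1))
  if (mode_i >= 2) for (i in mode_i:2) {
    h <- hets[i]
    n_rr <- (rare - h) / 2
    n_cc <- n - h - n_rr
    probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (n_rr + 1) * (n_cc + 1))
  }
  # upwards: P(h+2)/P(h) = 4 n_rr n_cc / ((h+2)(h+1))
  if (mode_i <= k - 1) for (i in mode_i:(k - 1)) {
    h <- hets[i]
    n_rr <- (rare - h) / 2
    n_cc <- n - h - n_rr
    probs[i + 1] <- probs[i] * 4 * n_rr * n_cc / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(het_obs, hets)]
  if (is.na(p_obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Imputation INFO score of one variant
#'
#' Ratio-of-variances imputation quality: `1 - mean(v_i) / (2 theta (1 -
#' theta))`, where `e_i` is the expected dosage of individual `i`, `v_i
#' = (p_AB + 4 p_BB) - e_i^2` its posterior dosage variance, and `theta
#' = mean(e_i) / 2` the alternate-allele frequency. 1 means perfectly
#' observed genotypes, 0 means the posteriors carry no information
#' beyond the allele frequency.
#'
#' @param p_aa,p_ab,p_bb Numeric vectors of genotype posteriors for one
#'   variant (missing genotypes `NA`, dropped).
#' @return INFO in \[0, 1\] (clipped). A monomorphic variant (`theta` 0
#'   or 1) returns 1 with attribute `monomorphic = TRUE`.
#' @export
info_score <- function(p_aa, p_ab, p_bb) {
  ok <- !is.na(p_aa) & !is.na(p_ab) & !is.na(p_bb)
  if (!any(ok)) stop("no non-missing posterior triplets")
  p_ab <- p_ab[ok]; p_bb <- p_bb[ok]
  e <- p_ab + 2 * p_bb
  v <- (p_ab + 4 * p_bb) - e^2
  theta <- mean(e) / 2
  if (theta <= 0 || theta >= 1) {
    return(structure(1, monomorphic = TRUE))
  }
  info <- 1 - mean(v) / (2 * theta * (1 - theta))
  min(1, max(0, info))
}

#' SNP-level QC filter
#'
#' Applies the genotyped-SNP exclusion rules: exact HWE p-value in
#' controls below threshold, call rate below threshold, or MAF below
#' threshold. Reasons are assigned in fixed priority order (HWE, call
#' rate, MAF). Imputed variants (no `genotyped_on` entry) are exempt
#' from the HWE and call-rate rules — they are complete by construction
#' — but still subject to the MAF rule. MAF is computed from dosages
#' over all samples.
#'
#' @param x A [dosage_data()] object.
#' @param thresholds A [qc_thresholds()] object.
#' @return A tibble with one row per variant: `id`, `maf`, `hwe_p`
#'   (controls; `NA` for imputed variants), `call_rate`, `kept`,
#'   `reason` (`NA` if kept).
#' @export
snp_qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "dosage_data"))
  th <- thresholds
  af <- allele_freqs(x)
  g <- hard_calls(x)
  is_control <- x$samples$status == "control"
  genotyped <- lengths(x$variants$genotyped_on) > 0

  m <- nrow(x$variants)
  hwe_p <- rep(NA_real_, m)
  call_rate <- rep(NA_real_, m)
  for (i in which(genotyped)) {
    gi <- g[i, ]
    call_rate[i] <- mean(!is.na(gi))
    gc <- gi[is_control & !is.na(gi)]
    if (length(gc) > 0) {
      hwe_p[i] <- hwe_exact_test(sum(gc == 0), sum(gc == 1), sum(gc == 2))
    }
  }

  reason <- rep(NA_character_, m)
  fail_hwe <- genotyped & !is.na(hwe_p) & hwe_p < th$hwe_p_min
  fail_cr <- genotyped & !is.na(call_rate) & call_rate < th$call_rate_min
  fail_maf <- af$maf < th$maf_min
  reason[fail_maf] <- "MAF"
  reason[fail_cr] <- "call_rate"
  reason[fail_hwe] <- "HWE"

  tibble::tibble(id = x$variants$id, maf = af$maf, hwe_p = hwe_p,
                 call_rate = call_rate, kept = is.na(reason),
                 reason = reason)
}

#' Post-imputation retention type of one variant
#'
#' Classifies a variant into the retention classes: Type A if genotyped
#' on all configured arrays; Type B if imputed with INFO at least
#' `info_high` on all arrays; Type C if imputed with INFO at least
#' `info_low` (but not all at least `info_high`) on all arrays and MAF
#' at least `maf_min`; otherwise excluded. A variant genotyped on an
#' array counts as INFO 1 on that array.
#'
#' @param genotyped_on Character vector of arrays the variant was
#'   directly genotyped on.
#' @param info_by_array Named numeric vector of INFO scores by array.
#' @param maf Minor allele frequency.
#' @param arrays Character vector of all configured array labels.
#' @param thresholds A [qc_thresholds()] object.
#' @return One of `"A"`, `"B"`, `"C"`, `"excluded"`.
#' @export
classify_retention <- function(genotyped_on, info_by_array, maf, arrays,
                               thresholds = qc_thresholds()) {
  stopifnot(length(arrays) >= 1)
  if (all(arrays %in% genotyped_on)) return("A")
  info <- vapply(arrays, function(a) {
    if (a %in% genotyped_on) return(1)
    if (!a %in% names(info_by_array)) {
      stop("no INFO entry for array '", a, "'")
    }
    unname(info_by_array[[a]])
  }, numeric(1))
  min_info <- min(info)
  if (min_info >= thresholds$info_high) return("B")
  if (min_info >= thresholds$info_low && maf >= thresholds$maf_min) return("C")
  "excluded"
}

#' Run full SNP QC and retention typing over a dataset
#'
#' Combines [snp_qc_filter()] and [classify_retention()]: a variant's
#' retention type is `"excluded"` if it fails genotyped-SNP QC,
#' otherwise its A/B/C class. Returns the QC report and a dataset
#' restricted to retained variants with the `retention` metadata column
#' filled in.
#'
#' A variant with neither `genotyped_on` nor `info_by_array` metadata
#' (e.g. read from a bare GEN file with no imputation sidecar) is
#' treated as directly genotyped on every configured array.
#'
#' @param x A [dosage_data()] object.
#' @param thresholds A [qc_thresholds()] object.
#' @return A list with `report` (tibble: QC columns plus `min_info`,
#'   `retention`) and `data` (filtered [dosage_data()]).
#' @export
run_snp_qc <- function(x, thresholds = qc_thresholds()) {
  bare <- lengths(x$variants$genotyped_on) == 0 &
    lengths(x$variants$info_by_array) == 0
  if (any(bare)) {
    arrays_all <- sort(unique(x$samples$array))
    x$variants$genotyped_on[bare] <- replicate(sum(bare), arrays_all,
                                               simplify = FALSE)
  }
  rep_ <- snp_qc_filter(x, thresholds)
  arrays <- sort(unique(x$samples$array))
  m <- nrow(x$variants)
  ret <- character(m)
  min_info <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (!rep_$kept[i]) {
      ret[i] <- "excluded"
      next
    }
    ret[i] <- classify_retention(x$variants$genotyped_on[[i]],
                                 x$variants$info_by_array[[i]],
                                 rep_$maf[i], arrays, thresholds)
    inf <- x$variants$info_by_array[[i]]
    gen <- x$variants$genotyped_on[[i]]
    vals <- vapply(arrays, function(a) {
      if (a %in% gen) 1 else if (a %in% names(inf)) unname(inf[[a]]) else NA_real_
    }, numeric(1))
    min_info[i] <- if (anyNA(vals)) NA_real_ else min(vals)
  }
  report <- dplyr::mutate(rep_, min_info = min_info, retention = ret)
  keep <- ret != "excluded"
  data <- subset_dosage(x, variants = keep)
  data$variants$retention <- ret[keep]
  list(report = report, data = data)
}
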