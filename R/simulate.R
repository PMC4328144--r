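#' Configuration for a synthetic case-control region
#'
#' Describes everything needed to generate one fine-mapping region:
#' haplotype-block LD (a Li-Stephens-style founder mosaic), geographic
#' stratification with Balding-Nichols allele-frequency drift,
#' additive logistic disease risk with configurable causal variants
#' (typed or untyped), retrospective case-control sampling to
#' per-region quotas, and per-array imputation quality targets.
#'
#' The defaults emulate a European consortium-style region: a 2 Mb
#' span, 7 geographic regions with unequal case/control quotas (so
#' stratification is a real confounder when `f_st > 0`), founder
#' allele frequencies drawn uniformly on `maf_range`, and drift
#' `f_st = 0.01` typical of within-European differentiation.
#'
#' @param n_variants Number of variants in the region.
#' @param region_span Span in base pairs (positions are sampled
#'   uniformly and sorted; 1-based).
#' @param founder_pool Number of founder haplotypes per region.
#' @param switch_rate Per-base mosaic switch rate; the probability of
#'   switching founders between adjacent variants at distance `d` is
#'   `1 - exp(-switch_rate * d)`. Larger values mean faster LD decay.
#' @param maf_range Interval the ancestral allele frequencies are
#'   drawn from.
#' @param f_st Balding-Nichols drift parameter in \[0, 1).
#' @param regions Tibble with columns `region`, `n_cases`,
#'   `n_controls` (the retrospective sampling quotas).
#' @param causal_spec Tibble with columns `variant` (index into the
#'   simulated variants), `or` (per-allele odds ratio) and `typed`
#'   (logical; untyped causal variants drive risk but are dropped from
#'   the emitted dataset). Empty (default) gives a null region.
#' @param baseline_intercept Baseline log-odds of disease (recycled
#'   per region, or a named vector by region label).
#' @param arrays Character vector of genotyping array labels.
#' @param imputation_spec `NULL` (every variant genotyped on every
#'   array) or a tibble with columns `variant`, `array`, `target_info`
#'   (a `target_info` of 1 means genotyped on that array; below 1 the
#'   emitted posteriors are degraded so the realized INFO score is
#'   within 0.02 of target).
#' @param seed Master seed; all stage streams are derived from it by
#'   fixed offsets, so every artifact is reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 150,
                       region_span = 2e6,
                       founder_pool = 20,
                       switch_rate = 1e-5,
                       maf_range = c(0.05, 0.5),
                       f_st = 0.01,
                       regions = default_sim_regions(),
                       causal_spec = NULL,
                       baseline_intercept = -2,
                       arrays = "array1",
                       imputation_spec = NULL,
                       seed = 1) {
  regions <- tibble::as_tibble(regions)
  stopifnot(all(c("region", "n_cases", "n_controls") %in% names(regions)),
            all(regions$n_cases >= 0), all(regions$n_controls >= 0),
            switch_rate >= 0, f_st >= 0, f_st < 1,
            founder_pool >= 2, n_variants >= 1,
            maf_range[1] > 0, maf_range[2] < 1)
  if (is.null(causal_spec)) {
    causal_spec <- tibble::tibble(variant = integer(0), or = numeric(0),
                                  typed = logical(0))
  }
  causal_spec <- tibble::as_tibble(causal_spec)
  if (!"typed" %in% names(causal_spec)) causal_spec$typed <- TRUE
  stopifnot(all(causal_spec$or > 0),
            all(causal_spec$variant >= 1),
            all(causal_spec$variant <= n_variants))
  if (!is.null(imputation_spec)) {
    imputation_spec <- tibble::as_tibble(imputation_spec)
    stopifnot(all(c("variant", "array", "target_info") %in%
                    names(imputation_spec)),
              all(imputation_spec$target_info > 0),
              all(imputation_spec$target_info <= 1),
              all(imputation_spec$array %in% arrays))
  }
  structure(
    list(n_variants = n_variants, region_span = region_span,
         founder_pool = founder_pool, switch_rate = switch_rate,
         maf_range = maf_range, f_st = f_st, regions = regions,
         causal_spec = causal_spec, baseline_intercept = baseline_intercept,
         arrays = arrays, imputation_spec = imputation_spec, seed = seed),
    class = "sim_config"
  )
}

#' Default stratification quotas for the simulator
#'
#' Seven geographic regions with deliberately unequal case/control
#' ratios (one region supplies a large shared control series), so
#' that allele-frequency drift translates into genuine case-control
#' confounding unless the region covariate is adjusted for.
#'
#' @param scale Multiplier on the default quotas (total 2000 + 2000
#'   at `scale = 1`); quotas are rounded.
#' @return A tibble with `region`, `n_cases`, `n_controls`.
#' @export
default_sim_regions <- function(scale = 1) {
  q <- tibble::tribble(
    ~region, ~n_cases, ~n_controls,
    "UK", 600, 1000,
    "France", 250, 150,
    "Spain", 200, 150,
    "Scandinavia", 250, 200,
    "Italy", 200, 150,
    "Poland", 300, 200,
    "Israel", 200, 150
  )
  q$n_cases <- round(q$n_cases * scale)
  q$n_controls <- round(q$n_controls * scale)
  q
}

#' Balding-Nichols allele-frequency drift
#'
#' Draws one allele frequency per subpopulation from
#' `Beta(p (1 - F)/F, (1 - p)(1 - F)/F)`, which has mean `p` and
#' variance `F p (1 - p)`. `f_st = 0` returns `p` for every region.
#'
#' @param p Ancestral allele frequency, strictly between 0 and 1.
#' @param f_st Drift parameter in \[0, 1).
#' @param n_regions Number of subpopulations.
#' @return Numeric vector of length `n_regions`.
#' @export
drift_frequencies <- function(p, f_st, n_regions) {
  if (p <= 0 || p >= 1) stop("ancestral frequency must be in (0, 1)")
  stopifnot(f_st >= 0, f_st < 1, n_regions >= 1)
  if (f_st == 0) return(rep(p, n_regions))
  a <- p * (1 - f_st) / f_st
  b <- (1 - p) * (1 - f_st) / f_st
  stats::rbeta(n_regions, a, b)
}

#' Simulate mosaic haplotypes from a founder panel
#'
#' Li-Stephens-style copying: each output haplotype copies one founder
#' and switches to a uniformly chosen founder between adjacent
#' variants with probability `1 - exp(-switch_rate * distance)`. LD
#' between variants therefore decays with distance; `switch_rate = 0`
#' returns exact founder copies, very large rates give linkage
#' equilibrium.
#'
#' @param founders Binary matrix (founder haplotypes x variants).
#' @param positions Increasing integer positions (base pairs).
#' @param n_hap Number of haplotypes to generate.
#' @param switch_rate Per-base switch rate.
#' @return Binary matrix (`n_hap` x variants).
#' @export
simulate_haplotypes <- function(founders, positions, n_hap, switch_rate) {
  founders <- as.matrix(founders)
  k <- nrow(founders)
  m <- ncol(founders)
  stopifnot(length(positions) == m, k >= 1, n_hap >= 1)
  if (m > 1) stopifnot(all(diff(positions) >= 0))
  p_switch <- if (m > 1) 1 - exp(-switch_rate * diff(positions)) else numeric(0)
  out <- matrix(0L, n_hap, m)
  for (i in seq_len(n_hap)) {
    if (m == 1) {
      out[i, ] <- founders[sample.int(k, 1), ]
      next
    }
    sw <- stats::runif(m - 1) < p_switch
    seg <- cumsum(c(1L, sw))
    f <- sample.int(k, max(seg), replace = TRUE)
    out[i, ] <- founders[cbind(f[seg], seq_len(m))]
  }
  out
}

#' Calibrate posterior triplets to a target INFO score
#'
#' Emulates imputation noise without running an imputer: each emitted
#' posterior triplet is the mixture `w * one-hot(true genotype) +
#' (1 - w) * HWE prior` at the supplied allele frequency, with the
#' mixture weight `w` calibrated by bisection so the realized INFO
#' score ([info_score()]) is within 0.02 of `target_info`.
#'
#' @param genotypes Integer vector of true 0/1/2 genotypes.
#' @param target_info Target INFO in (0, 1\].
#' @param allele_freq Alternate-allele frequency used for the prior.
#' @return A list with `p_aa`, `p_ab`, `p_bb` (numeric vectors), `w`
#'   and `realized_info`.
#' @export
degrade_to_dosage <- function(genotypes, target_info, allele_freq) {
  stopifnot(all(genotypes %in% 0:2), target_info > 0, target_info <= 1,
            allele_freq >= 0, allele_freq <= 1)
  if (length(unique(genotypes)) == 1 || allele_freq <= 0 || allele_freq >= 1) {
    stop("target INFO unreachable for monomorphic input")
  }
  prior <- c((1 - allele_freq)^2, 2 * allele_freq * (1 - allele_freq),
             allele_freq^2)
  onehot <- cbind(genotypes == 0, genotypes == 1, genotypes == 2) * 1
  mix <- function(w) {
    list(p_aa = w * onehot[, 1] + (1 - w) * prior[1],
         p_ab = w * onehot[, 2] + (1 - w) * prior[2],
         p_bb = w * onehot[, 3] + (1 - w) * prior[3])
  }
  realized <- function(w) {
    tr <- mix(w)
    as.numeric(info_score(tr$p_aa, tr$p_ab, tr$p_bb))
  }
  if (target_info >= 1) {
    tr <- mix(1)
    return(c(tr, list(w = 1, realized_info = realized(1))))
  }
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (realized(mid) < target_info) lo <- mid else hi <- mid
  }
  w <- (lo + hi) / 2
  tr <- mix(w)
  c(tr, list(w = w, realized_info = realized(w)))
}

#' Simulate a complete case-control fine-mapping region
#'
#' Generates the region described by a [sim_config()]: ancestral
#' frequencies are drawn on `maf_range` and drifted per region
#' (Balding-Nichols); each region gets its own founder panel (in
#' linkage equilibrium at the drifted frequencies) from which
#' individual haplotypes are copied as distance-decaying mosaics;
#' disease status follows the additive logistic model `P(case) =
#' expit(intercept_region + sum_c log(OR_c) g_c)`; individuals are
#' rejection-sampled until every region's case and control quotas are
#' met; finally, per-array imputation noise is applied to reach the
#' configured target INFO scores. Untyped causal variants contribute
#' to risk but are removed from the emitted dataset.
#'
#' All randomness derives from `config$seed` through fixed stage
#' offsets (+1 frequencies/founders, +2 sampling, +3 imputation).
#'
#' @param config A [sim_config()].
#' @param max_batches Rejection-sampling batch cap per region before
#'   declaring the quotas unattainable.
#' @return A list with `data` (a [dosage_data()]), `truth` (tibble:
#'   `variant`, `id`, `pos`, `or`, `typed`) and `config`.
#' @export
simulate_case_control <- function(config, max_batches = 200) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_variants
  nreg <- nrow(config$regions)

  set.seed(config$seed + 1)
  positions <- sort(sample.int(config$region_span, m))
  anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  freqs <- vapply(anc, drift_frequencies, numeric(nreg),
                  f_st = config$f_st, n_regions = nreg) # nreg x m
  if (nreg == 1) freqs <- matrix(freqs, nrow = 1)
  founders <- lapply(seq_len(nreg), function(r) {
    matrix(stats::rbinom(config$founder_pool * m, 1,
                         rep(freqs[r, ], each = config$founder_pool)),
           nrow = config$founder_pool)
  })

  set.seed(config$seed + 2)
  cs <- config$causal_spec
  log_or <- stats::setNames(log(cs$or), cs$variant)
  intercepts <- config$baseline_intercept
  if (is.null(names(intercepts))) {
    intercepts <- stats::setNames(rep_len(intercepts, nreg),
                                  config$regions$region)
  }

  geno <- list(); status <- list(); region_of <- list()
  for (r in seq_len(nreg)) {
    need_ca <- config$regions$n_cases[r]
    need_co <- config$regions$n_controls[r]
    got_ca <- 0; got_co <- 0
    acc_g <- list(); acc_y <- integer(0)
    batches <- 0
    while ((got_ca < need_ca || got_co < need_co)) {
      batches <- batches + 1
      if (batches > max_batches) {
        stop("region '", config$regions$region[r],
             "' quotas unattainable after ", max_batches, " batches")
      }
      b <- max(50, 3 * (need_ca - got_ca + need_co - got_co))
      h1 <- simulate_haplotypes(founders[[r]], positions, b,
                                config$switch_rate)
      h2 <- simulate_haplotypes(founders[[r]], positions, b,
                                config$switch_rate)
      g <- h1 + h2
      eta <- rep(intercepts[[config$regions$region[r]]], b)
      if (nrow(cs) > 0) {
        eta <- eta + drop(g[, cs$variant, drop = FALSE] %*% log_or)
      }
      y <- stats::rbinom(b, 1, plogis(eta))
      take_ca <- which(y == 1)[seq_len(min(sum(y == 1), need_ca - got_ca))]
      take_co <- which(y == 0)[seq_len(min(sum(y == 0), need_co - got_co))]
      take <- c(take_ca, take_co)
      if (length(take) > 0) {
        acc_g[[length(acc_g) + 1]] <- g[take, , drop = FALSE]
        acc_y <- c(acc_y, y[take])
        got_ca <- got_ca + length(take_ca)
        got_co <- got_co + length(take_co)
      }
    }
    geno[[r]] <- do.call(rbind, acc_g)
    status[[r]] <- acc_y
    region_of[[r]] <- rep(config$regions$region[r], length(status[[r]]))
  }
  g_all <- do.call(rbind, geno) # samples x variants
  y_all <- unlist(status)
  reg_all <- unlist(region_of)
  n <- length(y_all)

  samples <- tibble::tibble(
    sample_id = sprintf("s%05d", seq_len(n)),
    status = ifelse(y_all == 1, "case", "control"),
    region = reg_all
  )
  set.seed(config$seed + 3)
  samples$array <- if (length(config$arrays) == 1) {
    config$arrays
  } else {
    sample(config$arrays, n, replace = TRUE)
  }

  ids <- sprintf("v%04d", seq_len(m))
  af <- colMeans(g_all) / 2

  # imputation targets: variant x array matrix of target INFO (1 = typed)
  target <- matrix(1, m, length(config$arrays),
                   dimnames = list(ids, config$arrays))
  if (!is.null(config$imputation_spec)) {
    for (k in seq_len(nrow(config$imputation_spec))) {
      target[config$imputation_spec$variant[k],
             config$imputation_spec$array[k]] <-
        config$imputation_spec$target_info[k]
    }
  }

  p_aa <- matrix(NA_real_, m, n); p_ab <- p_aa; p_bb <- p_aa
  genotyped_on <- vector("list", m)
  info_by_array <- vector("list", m)
  for (j in seq_len(m)) {
    gen_arrays <- config$arrays[target[j, ] >= 1]
    genotyped_on[[j]] <- gen_arrays
    info <- numeric(0)
    for (a in config$arrays) {
      si <- which(samples$array == a)
      if (length(si) == 0) next
      if (target[j, a] >= 1) {
        p_aa[j, si] <- as.numeric(g_all[si, j] == 0)
        p_ab[j, si] <- as.numeric(g_all[si, j] == 1)
        p_bb[j, si] <- as.numeric(g_all[si, j] == 2)
      } else {
        tr <- degrade_to_dosage(g_all[si, j], target[j, a], af[j])
        p_aa[j, si] <- tr$p_aa
        p_ab[j, si] <- tr$p_ab
        p_bb[j, si] <- tr$p_bb
        info[a] <- tr$realized_info
      }
    }
    info_by_array[[j]] <- info
  }

  variants <- tibble::tibble(
    id = ids, chrom = "1", pos = positions,
    a0 = "A", a1 = "G",
    genotyped_on = genotyped_on, info_by_array = info_by_array,
    retention = "unset"
  )

  truth <- tibble::tibble(
    variant = cs$variant,
    id = ids[cs$variant],
    pos = positions[cs$variant],
    or = cs$or,
    typed = cs$typed
  )

  keep <- rep(TRUE, m)
  if (nrow(cs) > 0) keep[cs$variant[!cs$typed]] <- FALSE
  dat <- dosage_data(variants[keep, ],
                     p_aa[keep, , drop = FALSE],
                     p_ab[keep, , drop = FALSE],
                     p_bb[keep, , drop = FALSE],
                     samples)
  list(data = dat, truth = truth, config = config)
}
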