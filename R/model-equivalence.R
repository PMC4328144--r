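#' Squared dosage correlation between two variants
#'
#' The LD measure used for model equivalence: squared Pearson
#' correlation of expected-dosage vectors. Invariant to allele
#' flipping (`dosage -> 2 - dosage`).
#'
#' @param a,b Numeric dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
dosage_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("dosage_r2 undefined for a constant dosage vector")
  }
  stats::cor(a, b)^2
}

#' D-prime between two variants from hard-call genotypes
#'
#' Estimates the two-locus haplotype frequencies from unphased
#' genotype counts by EM (the only ambiguous class being the double
#' heterozygote) and returns `|D| / D_max` with the standard
#' normalization. Low r-squared with D-prime near 1 is the signature
#' of two minor alleles that almost never co-occur on a haplotype.
#'
#' @param g_a,g_b Integer vectors of 0/1/2 alternate-allele counts
#'   (`NA` pairs dropped).
#' @param max_iter,tol EM controls.
#' @return D-prime in \[0, 1\].
#' @export
dprime <- function(g_a, g_b, max_iter = 200, tol = 1e-10) {
  ok <- !is.na(g_a) & !is.na(g_b)
  g_a <- g_a[ok]; g_b <- g_b[ok]
  n <- length(g_a)
  stopifnot(n > 0, all(g_a %in% 0:2), all(g_b %in% 0:2))
  pa <- mean(g_a) / 2
  pb <- mean(g_b) / 2
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) {
    stop("dprime undefined for a monomorphic variant")
  }
  # haplotypes 00, 01, 10, 11 (alleles of a then b); start at equilibrium
  h <- c((1 - pa) * (1 - pb), (1 - pa) * pb, pa * (1 - pb), pa * pb)
  counts <- table(factor(g_a, 0:2), factor(g_b, 0:2))
  dh <- counts[2, 2] # double heterozygotes: phase-ambiguous
  for (it in seq_len(max_iter)) {
    # P(phase 00/11) vs P(phase 01/10) for double heterozygotes
    p_cis <- h[1] * h[4]
    p_trans <- h[2] * h[3]
    f_cis <- if (p_cis + p_trans > 0) p_cis / (p_cis + p_trans) else 0.5
    n00 <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1] + dh * f_cis
    n01 <- 2 * counts[1, 3] + counts[1, 2] + counts[2, 3] + dh * (1 - f_cis)
    n10 <- 2 * counts[3, 1] + counts[2, 1] + counts[3, 2] + dh * (1 - f_cis)
    n11 <- 2 * counts[3, 3] + counts[2, 3] + counts[3, 2] + dh * f_cis
    hnew <- c(n00, n01, n10, n11) / (2 * n)
    if (max(abs(hnew - h)) < tol) {
      h <- hnew
      break
    }
    h <- hnew
  }
  pa_h <- h[3] + h[4]
  pb_h <- h[2] + h[4]
  d <- h[4] - pa_h * pb_h
  dmax <- if (d >= 0) {
    min(pa_h * (1 - pb_h), (1 - pa_h) * pb_h)
  } else {
    min(pa_h * pb_h, (1 - pa_h) * (1 - pb_h))
  }
  if (dmax <= 0) return(0)
  min(1, abs(d) / dmax)
}

# TRUE iff two equal-size variant-id sets admit a perfect matching with
# every matched pair at dosage r2 >= threshold. Model sizes are small
# (<= ~5), so exact search over permutations is cheap.
sets_equivalent <- function(ids_a, ids_b, dmat, ids, r2_equiv) {
  if (length(ids_a) != length(ids_b)) return(FALSE)
  k <- length(ids_a)
  if (k == 0) return(TRUE) # two empty models are trivially equivalent
  ia <- match(ids_a, ids); ib <- match(ids_b, ids)
  r2 <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    r2[i, j] <- suppressWarnings(stats::cor(dmat[ia[i], ], dmat[ib[j], ])^2)
  }
  ok <- !is.na(r2) & r2 >= r2_equiv
  if (any(rowSums(ok) == 0) || any(colSums(ok) == 0)) return(FALSE)
  if (k == 1) return(ok[1, 1])
  perms <- permutations_of(k)
  for (p in perms) {
    if (all(ok[cbind(seq_len(k), p)])) return(TRUE)
  }
  FALSE
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

#' Collapse selected models into LD-equivalence classes
#'
#' Two selected models are statistically equivalent when they have the
#' same size and their variant sets can be perfectly matched pair-wise
#' at dosage r-squared of at least `r2_equiv` (swapping a variant for a
#' near-perfect proxy does not change the model's meaning). Classes
#' are single-linkage closures of this relation over the distinct
#' variant sets of the converged models. Each class is refit without
#' penalization; the representative is the member set with the
#' smallest product of refit p-values.
#'
#' @param models Tibble from [run_iterations()] (`$models`), or any
#'   tibble with `converged` and comma-joined `variants` columns.
#' @param x The [dosage_data()] the models were fitted to.
#' @param r2_equiv Equivalence threshold (default 0.9).
#' @param adjust_region Covariates for the refits.
#' @return A tibble of classes, one row per class, ordered by
#'   decreasing frequency: `class_id`, `size`, `frequency`,
#'   `n_distinct_sets`, `representative` (comma-joined ids), `refit`
#'   (list column of [refit_model()] tibbles).
#' @export
collapse_models <- function(models, x, r2_equiv = 0.9,
                            adjust_region = TRUE) {
  stopifnot(inherits(x, "dosage_data"))
  conv <- dplyr::filter(models, .data$converged)
  if (nrow(conv) == 0) {
    return(tibble::tibble(class_id = integer(0), size = integer(0),
                          frequency = integer(0),
                          n_distinct_sets = integer(0),
                          representative = character(0), refit = list()))
  }
  sets <- lapply(strsplit(conv$variants, ","), function(v) {
    sort(v[nzchar(v)])
  })
  keys <- vapply(sets, paste, character(1), collapse = ",")
  uk <- unique(keys)
  usets <- sets[match(uk, keys)]
  counts <- as.integer(table(factor(keys, levels = uk)))
  nu <- length(uk)

  d <- dosages(x)
  ids <- x$variants$id

  # union-find over distinct sets
  parent <- seq_len(nu)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(nu)) {
    for (j in seq_len(nu)) {
      if (j <= i) next
      if (length(usets[[i]]) != length(usets[[j]])) next
      if (find(i) == find(j)) next
      if (sets_equivalent(usets[[i]], usets[[j]], d, ids, r2_equiv)) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(nu), find, integer(1))

  out <- purrr::map_dfr(unique(roots), function(r) {
    members <- which(roots == r)
    refits <- purrr::map(members, function(i) {
      tryCatch(refit_model(x, usets[[i]], adjust_region = adjust_region),
               error = function(e) NULL)
    })
    logp <- vapply(refits, function(rf) {
      if (is.null(rf)) return(Inf)
      sum(log(rf$p))
    }, numeric(1))
    best <- members[which.min(logp)]
    tibble::tibble(
      size = length(usets[[best]]),
      frequency = sum(counts[members]),
      n_distinct_sets = length(members),
      representative = paste(usets[[best]], collapse = ","),
      refit = list(refits[[which.min(logp)]])
    )
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$frequency), .data$size)
  dplyr::mutate(out, class_id = dplyr::row_number(),
                .before = dplyr::everything())
}

#' Unpenalized joint refit of a selected variant set
#'
#' Logistic regression of case status on the dosages of all variants
#' in the set plus covariates, with per-variant Wald odds ratios and
#' p-values. Near-collinear sets (any pairwise dosage r-squared of
#' 0.99 or more) are refused, naming the offending pair.
#'
#' @param x A [dosage_data()] object.
#' @param variant_ids Character vector of variant ids.
#' @param adjust_region Include region indicators (default `TRUE`).
#' @return A tibble with one row per variant: `id`, `beta`, `se`,
#'   `or`, `p`; attributes `loglik`, `fit` carry the joint model.
#' @export
refit_model <- function(x, variant_ids, adjust_region = TRUE) {
  stopifnot(inherits(x, "dosage_data"), length(variant_ids) >= 1)
  vi <- match(variant_ids, x$variants$id)
  if (anyNA(vi)) stop("unknown variant id(s): ",
                      paste(variant_ids[is.na(vi)], collapse = ", "))
  d <- dosages(x)
  if (length(vi) > 1) {
    for (i in seq_along(vi)) {
      for (j in seq_along(vi)) {
        if (j <= i) next
        r2 <- suppressWarnings(stats::cor(d[vi[i], ], d[vi[j], ])^2)
        if (!is.na(r2) && r2 >= 0.99) {
          stop("collinear pair in refit set: ", variant_ids[i], " and ",
               variant_ids[j], " (r2 = ", signif(r2, 3), ")")
        }
      }
    }
  }
  y <- case_indicator(x$samples)
  gd <- t(d[vi, , drop = FALSE])
  colnames(gd) <- variant_ids
  xmat <- cbind(base_design(x$samples, adjust_region), gd)
  fit <- fit_logistic(xmat, y)
  est <- fit$coefficients[variant_ids]
  se <- fit$se[variant_ids]
  z <- est / se
  out <- tibble::tibble(id = variant_ids, beta = unname(est),
                        se = unname(se), or = unname(exp(est)),
                        p = unname(2 * pnorm(-abs(z))))
  attr(out, "loglik") <- fit$loglik
  attr(out, "fit") <- fit
  out
}
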