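#' Fit one NEG-penalized logistic model by stochastic coordinate ascent
#'
#' Maximizes the penalized log-likelihood: logistic log-likelihood of
#' case status on standardized genotype dosages (mean 0, variance 1)
#' minus the NEG penalty on each genotype coefficient. The intercept
#' and region indicators are unpenalized. Coordinates are visited
#' cyclically in a seed-determined random permutation — the only
#' stochastic element, so the same seed reproduces the same model. Each
#' visit takes a safeguarded one-dimensional Newton step against the
#' penalty (trust region 1 on the standardized scale, step halving if
#' the penalized objective would decrease): a coefficient at zero
#' enters only if the magnitude of its log-likelihood gradient exceeds
#' the penalty derivative at 0+, and a nonzero coefficient whose update
#' crosses zero is set to zero. Convergence: maximum absolute update
#' below `tol` over a full cycle, capped at `max_cycles` cycles.
#'
#' @param x A [dosage_data()] object (QC already applied).
#' @param penalty A [neg_penalty_spec()]; if its `scale` is `NA` it is
#'   calibrated via [calibrate_scale()] with [null_score_sd()].
#' @param seed Integer seed determining the coordinate visit order.
#' @param adjust_region Include region indicators (default `TRUE`).
#' @param tol,max_cycles Convergence controls (1e-6, 200).
#' @return An object of class `neg_fit`: `selected` (variant ids with
#'   nonzero coefficients, in position order), `beta` (named, on the
#'   standardized scale), `beta_cov` (unpenalized coefficients),
#'   `converged`, `n_cycles`, `seed`, `scale`, `d0`, `objective`, plus
#'   the standardization parameters.
#' @export
fit_neg_model <- function(x, penalty = neg_penalty_spec(), seed = 1,
                          adjust_region = TRUE, tol = 1e-6,
                          max_cycles = 200) {
  stopifnot(inherits(x, "dosage_data"), inherits(penalty, "neg_penalty_spec"))
  y <- case_indicator(x$samples)
  g <- standardize_dosages(x)
  gmat <- g$mat
  m <- ncol(gmat)
  z <- base_design(x$samples, adjust_region)
  pz <- ncol(z)

  scale <- penalty$scale
  if (is.na(scale)) {
    scale <- calibrate_scale(penalty$shape, penalty$target_alpha,
                             null_score_sd(x, adjust_region))
  }
  shape <- penalty$shape
  d0 <- neg_deriv0(shape, scale)
  pen0 <- neg_penalty(0, shape, scale)
  pen_at <- function(b) {
    if (b == 0) 0 else neg_penalty(abs(b), shape, scale) - pen0
  }
  dpen_at <- function(b) neg_penalty_deriv(abs(b), shape, scale)

  # init at the covariate-only ML fit
  cov_fit <- fit_logistic(z, y)
  beta_cov <- cov_fit$coefficients
  beta <- numeric(m)
  pen_terms <- numeric(m)
  eta <- drop(z %*% beta_cov)

  loglik <- function(eta) sum(y * eta - log1p(exp(eta)))
  obj <- loglik(eta) - 0
  set.seed(seed)
  ord <- sample.int(m)

  n_cycles <- 0
  converged <- FALSE
  mu <- plogis(eta)
  grad_all <- drop(crossprod(gmat, y - mu)) # refreshed after accepted steps

  for (cycle in seq_len(max_cycles)) {
    n_cycles <- cycle
    max_step <- 0

    # unpenalized covariates: one joint Newton step
    w <- pmax(mu * (1 - mu), 1e-10)
    delta_cov <- tryCatch(
      solve(crossprod(z * w, z), crossprod(z, y - mu)),
      error = function(e) NULL
    )
    if (!is.null(delta_cov)) {
      delta_cov <- drop(delta_cov)
      step <- 1
      for (h in 1:30) {
        eta_new <- eta + drop(z %*% (step * delta_cov))
        new_obj <- loglik(eta_new) - sum(pen_terms)
        if (new_obj >= obj - 1e-12) break
        step <- step / 2
      }
      if (new_obj >= obj - 1e-12) {
        beta_cov <- beta_cov + step * delta_cov
        eta <- eta_new
        obj <- new_obj
        mu <- plogis(eta)
        grad_all <- drop(crossprod(gmat, y - mu))
        max_step <- max(max_step, max(abs(step * delta_cov)))
      }
    }

    for (j in ord) {
      bj <- beta[j]
      if (bj == 0) {
        if (abs(grad_all[j]) <= d0) next
      }
      xj <- gmat[, j]
      gj <- sum(xj * (y - mu))
      hj <- sum(xj^2 * pmax(mu * (1 - mu), 1e-10))
      if (bj == 0) {
        if (abs(gj) <= d0) next
        s <- sign(gj)
        delta <- s * (abs(gj) - d0) / hj
      } else {
        s <- sign(bj)
        delta <- (gj - s * dpen_at(bj)) / hj
      }
      delta <- max(min(delta, 1), -1)
      accepted <- FALSE
      for (h in 1:30) {
        bnew <- bj + delta
        if (bj != 0 && sign(bnew) != sign(bj)) bnew <- 0
        if (bnew == bj) break
        pen_new <- pen_at(bnew)
        eta_new <- eta + (bnew - bj) * xj
        new_obj <- loglik(eta_new) - (sum(pen_terms) - pen_terms[j] + pen_new)
        if (new_obj >= obj - 1e-12) {
          accepted <- TRUE
          break
        }
        delta <- delta / 2
      }
      if (accepted) {
        max_step <- max(max_step, abs(bnew - bj))
        beta[j] <- bnew
        pen_terms[j] <- pen_new
        eta <- eta_new
        obj <- new_obj
        mu <- plogis(eta)
        grad_all <- drop(crossprod(gmat, y - mu))
      }
    }
    if (max_step < tol) {
      converged <- TRUE
      break
    }
  }

  nz <- which(beta != 0)
  structure(
    list(selected = g$ids[nz], beta = stats::setNames(beta[nz], g$ids[nz]),
         beta_all = stats::setNames(beta, g$ids),
         beta_cov = beta_cov, converged = converged, n_cycles = n_cycles,
         seed = seed, shape = shape, scale = scale, d0 = d0,
         objective = obj, center = g$center, sd = g$sd,
         adjust_region = adjust_region),
    class = "neg_fit"
  )
}

standardize_dosages <- function(x) {
  d <- dosages(x)
  mat <- t(d)
  center <- colMeans(mat)
  sds <- apply(mat, 2, stats::sd)
  keep <- sds > 0
  mat <- sweep(mat[, keep, drop = FALSE], 2, center[keep], "-")
  mat <- sweep(mat, 2, sds[keep], "/")
  list(mat = mat, ids = x$variants$id[keep], center = center[keep],
       sd = sds[keep])
}

#' @export
print.neg_fit <- function(x, ...) {
  cat("<neg_fit> seed ", x$seed, ", ", length(x$selected),
      " variant(s) selected",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  if (length(x$selected) > 0) {
    print(tibble::tibble(id = x$selected, beta_std = unname(x$beta)))
  }
  invisible(x)
}

#' Tidy a NEG fit into one row per selected variant
#'
#' @param x A `neg_fit` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (standardized scale) and
#'   `estimate_dosage` (per-allele scale).
#' @export
tidy.neg_fit <- function(x, ...) {
  tibble::tibble(term = x$selected,
                 estimate = unname(x$beta),
                 estimate_dosage = unname(x$beta / x$sd[match(x$selected,
                                                              names(x$beta_all))]))
}

#' Stationarity (KKT-style) audit of a NEG fit
#'
#' Checks, at the returned solution, that every nonzero coefficient
#' satisfies |d loglik / d beta_j| = penalty derivative at |beta_j| and
#' every zero coefficient satisfies |d loglik / d beta_j| <= derivative
#' at 0+ (within `tol`).
#'
#' @param fit A `neg_fit` object.
#' @param x The [dosage_data()] it was fitted to.
#' @param tol Audit tolerance (default 1e-4).
#' @return A tibble (`id`, `active`, `gradient`, `bound`, `ok`) with
#'   attribute `pass` (all ok).
#' @export
neg_kkt_audit <- function(fit, x, tol = 1e-4) {
  g <- standardize_dosages(x)
  y <- case_indicator(x$samples)
  z <- base_design(x$samples, fit$adjust_region)
  eta <- drop(z %*% fit$beta_cov) + drop(g$mat %*% fit$beta_all[g$ids])
  mu <- plogis(eta)
  grad <- drop(crossprod(g$mat, y - mu))
  beta <- fit$beta_all[g$ids]
  active <- beta != 0
  bound <- ifelse(active,
                  neg_penalty_deriv(abs(beta), fit$shape, fit$scale),
                  fit$d0)
  ok <- ifelse(active,
               abs(abs(grad) - bound) <= tol * pmax(1, abs(bound)),
               abs(grad) <= bound + tol * pmax(1, abs(bound)))
  out <- tibble::tibble(id = g$ids, active = active,
                        gradient = abs(grad), bound = bound, ok = ok)
  attr(out, "pass") <- all(ok)
  out
}

#' Run repeated stochastic NEG model searches
#'
#' Runs [fit_neg_model()] `n_iter` times; iteration `i` uses seed
#' `base_seed + i - 1`, so the whole set is reproducible from
#' `base_seed` and any single iteration can be re-run in isolation.
#'
#' @param x A [dosage_data()] object.
#' @param penalty A [neg_penalty_spec()]. When its scale needs
#'   calibration this is done once and shared across iterations.
#' @param n_iter Number of iterations (default 100).
#' @param base_seed Seed of the first iteration.
#' @param ... Passed to [fit_neg_model()].
#' @return A list with `fits` (list of `neg_fit`) and `models` (tibble:
#'   `iteration`, `seed`, `converged`, `size`, `variants` comma-joined,
#'   `betas` comma-joined).
#' @export
run_iterations <- function(x, penalty = neg_penalty_spec(), n_iter = 100,
                           base_seed = 1, ...) {
  if (is.na(penalty$scale)) {
    dots <- list(...)
    adj <- if (is.null(dots$adjust_region)) TRUE else dots$adjust_region
    penalty$scale <- calibrate_scale(penalty$shape, penalty$target_alpha,
                                     null_score_sd(x, adj))
  }
  fits <- purrr::map(seq_len(n_iter), function(i) {
    fit_neg_model(x, penalty, seed = base_seed + i - 1, ...)
  })
  models <- purrr::map2_dfr(fits, seq_len(n_iter), function(f, i) {
    tibble::tibble(
      iteration = i, seed = f$seed, converged = f$converged,
      size = length(f$selected),
      variants = paste(f$selected, collapse = ","),
      betas = paste(formatC(unname(f$beta), digits = 6, format = "g"),
                    collapse = ",")
    )
  })
  list(fits = fits, models = models)
}
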