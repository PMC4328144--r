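#' Greedy LD pruning of highly correlated variants
#'
#' Sliding-window greedy pruning on dosage correlation: variants are
#' taken in position order; whenever a pair within `window` retained
#' variants has squared dosage correlation above `r2_threshold`, the
#' member with the lower MAF is removed (ties: the later position).
#' The output contains no pair above the threshold within the window.
#'
#' @param x A [dosage_data()] object.
#' @param r2_threshold Squared-correlation threshold (default 0.95).
#' @param window Number of retained variants to compare against
#'   (default 250).
#' @return A list with `data` (pruned [dosage_data()]) and `removed`
#'   (tibble: `removed_id`, `kept_id`, `r2`).
#' @export
ld_prune <- function(x, r2_threshold = 0.95, window = 250) {
  stopifnot(inherits(x, "dosage_data"))
  d <- dosages(x)
  maf <- allele_freqs(x)$maf
  m <- nrow(x$variants)
  keep <- logical(m)
  survivors <- integer(0)
  removed <- list()
  for (v in seq_len(m)) {
    if (stats::sd(d[v, ]) == 0) next # constant columns carry no signal
    recent <- utils::tail(survivors, window)
    dropped_v <- FALSE
    for (s in recent) {
      r2 <- suppressWarnings(stats::cor(d[v, ], d[s, ])^2)
      if (!is.na(r2) && r2 > r2_threshold) {
        # drop the lower-MAF member; tie -> drop the later position (v)
        if (maf[v] > maf[s]) {
          keep[s] <- FALSE
          survivors <- setdiff(survivors, s)
          removed[[length(removed) + 1]] <-
            tibble::tibble(removed_id = x$variants$id[s],
                           kept_id = x$variants$id[v], r2 = r2)
        } else {
          dropped_v <- TRUE
          removed[[length(removed) + 1]] <-
            tibble::tibble(removed_id = x$variants$id[v],
                           kept_id = x$variants$id[s], r2 = r2)
          break
        }
      }
    }
    if (!dropped_v) {
      keep[v] <- TRUE
      survivors <- c(survivors, v)
    }
  }
  list(data = subset_dosage(x, variants = keep),
       removed = if (length(removed) > 0) dplyr::bind_rows(removed)
       else tibble::tibble(removed_id = character(0),
                           kept_id = character(0), r2 = numeric(0)))
}

#' Elastic-net specification
#'
#' Penalty per genotype term: `lambda * (alpha * |beta| + (1 - alpha) *
#' beta^2)` (note the unhalved quadratic part — implementations that use
#' `beta^2 / 2` put lambda on a different scale). `alpha = 1` is the
#' lasso, `alpha = 0.5` the elastic net used for comparison runs.
#'
#' @param alpha Mixing weight in (0, 1\].
#' @param lambda_grid Decreasing positive sequence, or `NULL` to use
#'   `n_lambda` log-spaced points from the data-derived `lambda_max`
#'   down to `lambda_min_ratio * lambda_max`.
#' @param n_lambda,lambda_min_ratio Grid size (100) and lower ratio (1e-3).
#' @param n_folds Cross-validation folds (default 10).
#' @param cv_rule `"min"` (default: lambda minimizing mean CV deviance)
#'   or `"1se"`.
#' @param seed Seed for the CV fold assignment.
#' @return A list of class `enet_spec`.
#' @export
enet_spec <- function(alpha = 0.5, lambda_grid = NULL, n_lambda = 100,
                      lambda_min_ratio = 1e-3, n_folds = 10,
                      cv_rule = c("min", "1se"), seed = 1) {
  stopifnot(alpha > 0, alpha <= 1)
  if (!is.null(lambda_grid)) {
    stopifnot(all(lambda_grid > 0), all(diff(lambda_grid) < 0))
  }
  structure(list(alpha = alpha, lambda_grid = lambda_grid,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 n_folds = n_folds, cv_rule = match.arg(cv_rule),
                 seed = seed),
            class = "enet_spec")
}

# the coordinate update shared by the quadratic subproblems: penalized
# weighted least squares min (1/2n) sum w (y - x b)^2 +
# sum_j lambda (alpha |b_j| + (1-alpha) b_j^2), first pz columns
# unpenalized. On an orthonormal design (t(x) %*% x / n = I, w = 1)
# the solution is the soft-thresholded vector of univariate estimates.
penalized_wls_enet <- function(xmat, y, w, pz, alpha, lambda,
                               tol = 1e-10, max_sweeps = 1000) {
  n <- nrow(xmat); p <- ncol(xmat)
  beta <- numeric(p)
  r <- w * y
  for (sweep in seq_len(max_sweeps)) {
    maxd <- 0
    for (j in seq_len(p)) {
      xj <- xmat[, j]
      hj <- sum(w * xj^2) / n
      gj <- sum(xj * r) / n + hj * beta[j]
      bnew <- if (j <= pz) gj / hj else {
        sign(gj) * max(0, abs(gj) - lambda * alpha) /
          (hj + 2 * lambda * (1 - alpha))
      }
      if (bnew != beta[j]) {
        r <- r - (bnew - beta[j]) * w * xj
        maxd <- max(maxd, abs(bnew - beta[j]))
        beta[j] <- bnew
      }
    }
    if (maxd < tol) break
  }
  setNames(beta, colnames(xmat))
}

# penalized-logistic coordinate descent over a lambda path.
# objective: -(1/n) loglik + sum_j lambda (alpha |b_j| + (1-alpha) b_j^2);
# covariates (first pz columns) unpenalized. Warm starts along the
# decreasing path and an active-set strategy (iterate on the nonzero
# set, then sweep all coordinates for violators). Returns p x nlambda.
enet_path_solve <- function(xmat, y, pz, alpha, lambdas, tol = 1e-7,
                            max_outer = 40) {
  n <- nrow(xmat); p <- ncol(xmat)
  betas <- matrix(0, p, length(lambdas))
  beta <- numeric(p)
  cov_fit <- fit_logistic(xmat[, seq_len(pz), drop = FALSE], y)
  beta[seq_len(pz)][match(names(cov_fit$coefficients),
                          colnames(xmat)[seq_len(pz)])] <- cov_fit$coefficients

  sweep_set <- function(idx, beta, r, w, lam) {
    maxd <- 0
    for (j in idx) {
      xj <- xmat[, j]
      hj <- sum(w * xj^2) / n
      gj <- sum(xj * r) / n + hj * beta[j]
      bnew <- if (j <= pz) gj / hj else {
        sign(gj) * max(0, abs(gj) - lam * alpha) /
          (hj + 2 * lam * (1 - alpha))
      }
      if (bnew != beta[j]) {
        r <- r - (bnew - beta[j]) * w * xj
        maxd <- max(maxd, abs(bnew - beta[j]))
        beta[j] <- bnew
      }
    }
    list(beta = beta, r = r, maxd = maxd)
  }

  for (k in seq_along(lambdas)) {
    lam <- lambdas[k]
    for (outer in seq_len(max_outer)) {
      eta <- drop(xmat %*% beta)
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-8)
      r <- y - mu
      # converge on the current active set under this quadratic
      active <- c(seq_len(pz), which(beta[-seq_len(pz)] != 0) + pz)
      for (inner in seq_len(50)) {
        st <- sweep_set(active, beta, r, w, lam)
        beta <- st$beta; r <- st$r
        if (st$maxd < tol * 10) break
      }
      # full sweep: picks up entering coordinates and measures progress
      st <- sweep_set(seq_len(p), beta, r, w, lam)
      beta <- st$beta; r <- st$r
      if (st$maxd < tol) break
    }
    betas[, k] <- beta
  }
  rownames(betas) <- colnames(xmat)
  betas
}

#' Elastic-net / lasso penalized logistic regression path with CV
#'
#' The package's own cyclic coordinate-descent solver for penalized
#' logistic regression with per-term penalty `lambda (alpha |beta| +
#' (1 - alpha) beta^2)`, genotypes standardized and covariates
#' (intercept, region) unpenalized. Solves the whole decreasing lambda
#' path with warm starts, then picks lambda by K-fold cross-validated
#' mean held-out deviance (`"min"` rule by default).
#'
#' @param x A [dosage_data()] object (typically LD-pruned first).
#' @param spec An [enet_spec()].
#' @param adjust_region Include region indicators (default `TRUE`).
#' @return An object of class `enet_fit`: `path` (tibble: `lambda`,
#'   `df`, `deviance`), `cv` (tibble: `lambda`, `cv_deviance`,
#'   `cv_se`), `lambda_max`, `lambda_sel`, `selected` (variant ids
#'   nonzero at `lambda_sel`), `beta` (standardized coefficients at
#'   `lambda_sel`), `beta_cov`, and the design internals needed for
#'   the KKT audit.
#' @export
fit_elastic_net <- function(x, spec = enet_spec(), adjust_region = TRUE) {
  stopifnot(inherits(x, "dosage_data"), inherits(spec, "enet_spec"))
  y <- case_indicator(x$samples)
  g <- standardize_dosages(x)
  z <- base_design(x$samples, adjust_region)
  xmat <- cbind(z, g$mat)
  pz <- ncol(z)
  n <- length(y)

  cov_fit <- fit_logistic(z, y)
  mu0 <- cov_fit$fitted
  lambda_max <- max(abs(crossprod(g$mat, y - mu0)) / n) / spec$alpha
  lambdas <- spec$lambda_grid
  if (is.null(lambdas)) {
    # start a hair above lambda_max so the first path point is exactly
    # empty despite rounding in the gradient accumulation
    top <- lambda_max * (1 + 1e-4)
    lambdas <- exp(seq(log(top), log(top * spec$lambda_min_ratio),
                       length.out = spec$n_lambda))
  }

  betas <- enet_path_solve(xmat, y, pz, spec$alpha, lambdas)
  eta_path <- xmat %*% betas
  dev <- -2 * colSums(y * eta_path - log1p(exp(eta_path)))
  df <- colSums(betas[-seq_len(pz), , drop = FALSE] != 0)
  path <- tibble::tibble(lambda = lambdas, df = df, deviance = dev)

  # K-fold CV on held-out deviance
  set.seed(spec$seed)
  folds <- NULL
  for (attempt in 1:2) {
    cand <- sample(rep(seq_len(spec$n_folds), length.out = n))
    degen <- any(vapply(seq_len(spec$n_folds), function(k) {
      yt <- y[cand != k]
      length(unique(yt)) < 2
    }, logical(1)))
    if (!degen) {
      folds <- cand
      break
    }
  }
  if (is.null(folds)) stop("cross-validation folds degenerate (a fold with one class)")

  cvdev <- matrix(NA_real_, spec$n_folds, length(lambdas))
  for (k in seq_len(spec$n_folds)) {
    tr <- folds != k
    bk <- enet_path_solve(xmat[tr, , drop = FALSE], y[tr], pz, spec$alpha,
                          lambdas)
    eta_te <- xmat[!tr, , drop = FALSE] %*% bk
    yte <- y[!tr]
    cvdev[k, ] <- -2 * colMeans(yte * eta_te - log1p(exp(eta_te)))
  }
  cv_mean <- colMeans(cvdev)
  cv_se <- apply(cvdev, 2, stats::sd) / sqrt(spec$n_folds)
  sel <- which.min(cv_mean)
  if (spec$cv_rule == "1se") {
    sel <- min(which(cv_mean <= cv_mean[sel] + cv_se[sel]))
  }

  beta_sel <- betas[, sel]
  nz <- which(beta_sel[-seq_len(pz)] != 0)
  structure(
    list(path = path,
         cv = tibble::tibble(lambda = lambdas, cv_deviance = cv_mean,
                             cv_se = cv_se),
         lambda_max = lambda_max, lambda_sel = lambdas[sel],
         alpha = spec$alpha,
         selected = g$ids[nz],
         beta = stats::setNames(beta_sel[-seq_len(pz)][nz], g$ids[nz]),
         beta_all = stats::setNames(beta_sel[-seq_len(pz)], g$ids),
         beta_cov = beta_sel[seq_len(pz)],
         betas = betas, pz = pz, ids = g$ids,
         adjust_region = adjust_region),
    class = "enet_fit"
  )
}

#' @export
print.enet_fit <- function(x, ...) {
  cat("<enet_fit> alpha ", x$alpha, ", lambda ", signif(x$lambda_sel, 4),
      " (CV), ", length(x$selected), " variant(s) selected\n", sep = "")
  invisible(x)
}

#' Tidy an elastic-net fit into one row per selected variant
#'
#' @param x An `enet_fit` object.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` (standardized scale).
#' @export
tidy.enet_fit <- function(x, ...) {
  tibble::tibble(term = x$selected, estimate = unname(x$beta))
}

#' Stationarity (KKT) audit of an elastic-net fit
#'
#' At the CV-selected lambda, checks the subgradient conditions of the
#' penalty `lambda (alpha |beta| + (1 - alpha) beta^2)`: for nonzero
#' beta_j, `-(1/n) d loglik/d beta_j + 2 lambda (1 - alpha) beta_j =
#' -lambda alpha sign(beta_j)` (within `tol`); for zero beta_j the
#' magnitude is bounded by `lambda alpha`.
#'
#' @param fit An `enet_fit` object.
#' @param x The [dosage_data()] it was fitted to.
#' @param tol Audit tolerance (default 1e-4).
#' @return Tibble (`id`, `active`, `gradient`, `bound`, `ok`) with
#'   attribute `pass`.
#' @export
enet_kkt_audit <- function(fit, x, tol = 1e-4) {
  g <- standardize_dosages(x)
  y <- case_indicator(x$samples)
  z <- base_design(x$samples, fit$adjust_region)
  n <- length(y)
  eta <- drop(z %*% fit$beta_cov) + drop(g$mat %*% fit$beta_all[g$ids])
  mu <- plogis(eta)
  grad <- -drop(crossprod(g$mat, y - mu)) / n
  beta <- fit$beta_all[g$ids]
  lam <- fit$lambda_sel
  active <- beta != 0
  total <- grad + 2 * lam * (1 - fit$alpha) * beta
  ok <- ifelse(active,
               abs(total + lam * fit$alpha * sign(beta)) <= tol,
               abs(total) <= lam * fit$alpha + tol)
  out <- tibble::tibble(id = g$ids, active = active, gradient = total,
                        bound = lam * fit$alpha, ok = ok)
  attr(out, "pass") <- all(ok)
  out
}
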