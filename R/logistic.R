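#' Maximum-likelihood logistic regression by IRLS
#'
#' The package's own logistic fitter: iteratively reweighted least
#' squares with standard-error estimates from the observed information
#' matrix. Aliased (rank-deficient) columns are dropped before fitting.
#' Convergence: maximum absolute coefficient change below `tol` (default
#' 1e-8), capped at `max_iter` (50) iterations. Quasi-separation (any
#' coefficient diverging beyond `beta_cap`, default 15) flags the fit;
#' Wald statistics are then unreliable and callers fall back to the
#' score test.
#'
#' @param x Numeric design matrix (n x p), including the intercept
#'   column if one is wanted.
#' @param y 0/1 response vector (1 = case).
#' @param tol,max_iter,beta_cap Convergence tolerance, iteration cap and
#'   separation guard.
#' @return An object of class `fm_logistic` with elements
#'   `coefficients`, `se`, `vcov`, `loglik`, `fitted`, `converged`,
#'   `separated`, `n`, `dropped` (aliased column names).
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 50, beta_cap = 15) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))

  qr_x <- qr(x)
  dropped <- character(0)
  if (qr_x$rank < ncol(x)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- colnames(x)[-keep]
    x <- x[, sort(keep), drop = FALSE]
  }
  p <- ncol(x)
  beta <- numeric(p)
  converged <- FALSE
  separated <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    xtwx <- crossprod(x * w, x)
    score <- crossprod(x, y - mu)
    delta <- tryCatch(solve(xtwx, score), error = function(e) NULL)
    if (is.null(delta)) {
      separated <- TRUE
      break
    }
    beta <- beta + drop(delta)
    if (any(abs(beta) > beta_cap)) {
      separated <- TRUE
      break
    }
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  xtwx <- crossprod(x * w, x)
  vcov <- tryCatch(solve(xtwx), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  names(beta) <- names(se) <- colnames(x)
  dimnames(vcov) <- list(colnames(x), colnames(x))
  loglik <- sum(y * eta - log1p(exp(eta)))

  structure(
    list(coefficients = beta, se = se, vcov = vcov, loglik = loglik,
         fitted = mu, converged = converged, separated = separated,
         n = length(y), dropped = dropped),
    class = "fm_logistic"
  )
}

#' Score test for one added term in a logistic model
#'
#' Fits the null model `y ~ x0`, then tests the score of an additional
#' column `z` at zero: `U = z'(y - mu0)`, with variance from the
#' efficient information (the `z` information minus its projection onto
#' the null design). Robust under separation of the full model.
#'
#' @param x0 Null design matrix (with intercept).
#' @param z Candidate column.
#' @param y 0/1 response.
#' @param null_fit Optional pre-computed [fit_logistic()] on `x0`.
#' @return A list with `u` (score), `v` (variance), `z` (signed root
#'   statistic) and `p` (two-sided p-value).
#' @export
score_test <- function(x0, z, y, null_fit = NULL) {
  x0 <- as.matrix(x0)
  if (is.null(null_fit)) null_fit <- fit_logistic(x0, y)
  if (length(null_fit$dropped) > 0) {
    x0 <- x0[, names(null_fit$coefficients), drop = FALSE]
  }
  mu <- null_fit$fitted
  w <- pmax(mu * (1 - mu), 1e-10)
  u <- sum(z * (y - mu))
  xtwz <- crossprod(x0 * w, z)
  v <- sum(w * z^2) - drop(crossprod(xtwz, solve(crossprod(x0 * w, x0), xtwz)))
  if (v <= 0) {
    return(list(u = u, v = v, z = NA_real_, p = NA_real_))
  }
  zs <- u / sqrt(v)
  list(u = u, v = v, z = zs, p = 2 * pnorm(-abs(zs)))
}

#' @export
print.fm_logistic <- function(x, ...) {
  cat("<fm_logistic> n =", x$n, if (x$separated) "(separated)" else "",
      "\n")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a logistic fit into one row per coefficient
#'
#' @param x An `fm_logistic` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `odds.ratio`.
#' @export
tidy.fm_logistic <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    odds.ratio = unname(exp(x$coefficients))
  )
}

#' One-row model summary of a logistic fit
#'
#' @param x An `fm_logistic` object.
#' @param ... Unused.
#' @return Tibble with `logLik`, `deviance`, `nobs`, `converged`,
#'   `separated`.
#' @export
glance.fm_logistic <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, deviance = -2 * x$loglik,
                 nobs = x$n, converged = x$converged,
                 separated = x$separated)
}
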