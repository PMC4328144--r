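#' Normal-exponential-gamma (NEG) penalty specification
#'
#' The NEG prior is the marginal of a normal with exponential-mixed
#' variance whose rate is gamma-distributed: a sharp peak at zero (its
#' negative log-density has a finite positive derivative at 0+, so
#' coordinate-wise maximization can return exact zeros) and heavy
#' polynomial tails (the derivative vanishes as |beta| grows, so strong
#' effects are barely shrunk). `shape` controls tail heaviness; `scale`
#' sets the selection threshold and is usually calibrated to a target
#' per-variant type-I error via [calibrate_scale()] rather than set
#' directly.
#'
#' @param shape Shape parameter lambda (default 0.05).
#' @param scale Scale parameter gamma (> 0), or `NA` to be calibrated
#'   from the data at fit time.
#' @param target_alpha Per-variant type-I error the scale is calibrated
#'   to when `scale` is `NA` (default 1e-4).
#' @return A list of class `neg_penalty_spec`.
#' @export
neg_penalty_spec <- function(shape = 0.05, scale = NA_real_,
                             target_alpha = 1e-4) {
  stopifnot(shape > 0, is.na(scale) || scale > 0,
            target_alpha > 0, target_alpha < 1)
  structure(list(shape = shape, scale = scale, target_alpha = target_alpha),
            class = "neg_penalty_spec")
}

# I(a, z) = integral_0^inf t^(a-1) exp(-t^2/2 - z t) dt, evaluated on
# the log scale by adaptive quadrature. The NEG density is
#   p(beta) = I(2*shape + 1, |beta|/scale) / (2^shape Gamma(shape) scale),
# which is the parabolic-cylinder closed form
#   p(beta) ~ exp(beta^2/(4 scale^2)) D_{-2 shape - 1}(|beta|/scale)
# with D evaluated through its negative-order integral representation.
neg_log_i <- function(a, z) {
  # peak of log integrand (a-1) log t - t^2/2 - z t
  tstar <- if (a > 1) (-z + sqrt(z^2 + 4 * (a - 1))) / 2 else max(1e-3, 1 - z)
  tstar <- max(tstar, 1e-8)
  lmax <- (a - 1) * log(tstar) - tstar^2 / 2 - z * tstar
  f <- function(t) exp((a - 1) * log(t) - t^2 / 2 - z * t - lmax)
  val <- stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  lmax + log(val)
}

# asymptotic branch for large z: I(a,z) = Gamma(a) z^-a E[exp(-T^2/2)],
# T ~ Gamma(a, z); two-term expansion of the expectation
neg_log_i_asym <- function(a, z) {
  lgamma(a) - a * log(z) + log1p(-a * (a + 1) / (2 * z^2))
}

#' NEG penalty (negative log prior density)
#'
#' Evaluates `-log p(beta)` of the NEG prior, either through the
#' parabolic-cylinder closed form (default, via the negative-order
#' integral representation) or by adaptive quadrature of the
#' normal-exponential-gamma scale-mixture (a Laplace density mixed over
#' a Gamma-distributed squared rate). The two routes agree to 1e-6
#' relative and serve as mutual checks. Beyond `|beta|/scale > 30` an
#' asymptotic branch guards against overflow; there the penalty grows
#' like `(2 shape + 1) log |beta|`.
#'
#' @param beta Coefficient value(s); the penalty is symmetric in beta.
#' @param shape,scale NEG parameters (both > 0).
#' @param method `"cylinder"` (default) or `"mixture"`.
#' @return Penalty value(s), same length as `beta`.
#' @export
neg_penalty <- function(beta, shape, scale, method = c("cylinder", "mixture")) {
  method <- match.arg(method)
  stopifnot(shape > 0, scale > 0)
  z <- abs(beta) / scale
  a <- 2 * shape + 1
  if (method == "cylinder") {
    logi <- vapply(z, function(zi) {
      if (zi > 30) neg_log_i_asym(a, zi) else neg_log_i(a, zi)
    }, numeric(1))
    shape * log(2) + lgamma(shape) + log(scale) - logi
  } else {
    # scale mixture: p(beta) = int_0^inf sqrt(eta/2) exp(-sqrt(2 eta) |beta|)
    #   dGamma(eta; shape, rate = scale^2), integrated over log eta
    b <- abs(beta)
    vapply(seq_along(z), function(k) {
      if (z[k] > 30) {
        return(shape * log(2) + lgamma(shape) + log(scale) -
                 neg_log_i_asym(a, z[k]))
      }
      lf <- function(eta) {
        0.5 * log(eta / 2) - sqrt(2 * eta) * b[k] +
          stats::dgamma(eta, shape = shape, rate = scale^2, log = TRUE)
      }
      # peak over log eta, searched around the natural 1/scale^2 range
      lo <- log(1e-12 / scale^2); hi <- log(1e6 / scale^2)
      lstar <- stats::optimize(function(l) -(lf(exp(l)) + l), c(lo, hi))$minimum
      lmax <- lf(exp(lstar)) + lstar
      val <- stats::integrate(function(l) exp(lf(exp(l)) + l - lmax),
                              lstar - 80, lstar + 80,
                              rel.tol = 1e-10, abs.tol = 0)$value
      -(lmax + log(val))
    }, numeric(1))
  }
}

#' Derivative of the NEG penalty
#'
#' For beta > 0 the derivative is `(2 shape + 1) / scale` times the
#' ratio of parabolic-cylinder functions of adjacent order; it is
#' strictly positive, finite at 0+ (the sparsity threshold) and
#' monotone decreasing in beta (weak shrinkage of large effects). The
#' odd extension gives the derivative for negative beta.
#'
#' @inheritParams neg_penalty
#' @return Derivative value(s); at `beta = 0` the right-hand limit
#'   `deriv(0+)` is returned.
#' @export
neg_penalty_deriv <- function(beta, shape, scale) {
  stopifnot(shape > 0, scale > 0)
  a <- 2 * shape + 1
  vapply(beta, function(b) {
    z <- abs(b) / scale
    d <- if (z == 0) {
      neg_deriv0(shape, scale)
    } else if (z > 30) {
      exp(neg_log_i_asym(a + 1, z) - neg_log_i_asym(a, z)) / scale
    } else {
      exp(neg_log_i(a + 1, z) - neg_log_i(a, z)) / scale
    }
    if (b < 0) -d else d
  }, numeric(1))
}

# closed form of deriv(0+): sqrt(2) Gamma(shape + 1) /
#   (scale * Gamma(shape + 1/2))
neg_deriv0 <- function(shape, scale) {
  exp(0.5 * log(2) + lgamma(shape + 1) - lgamma(shape + 0.5)) / scale
}

#' Calibrate the NEG scale to a target per-variant type-I error
#'
#' For a standardized variant, a zero coefficient enters the model only
#' when the magnitude of the score gradient exceeds the penalty
#' derivative at 0+. Setting that threshold equal to the critical value
#' of the two-sided single-variant score test at level `target_alpha`
#' makes "selected" coincide with "score-test significant at
#' target_alpha" in a one-variant model. The scale solving this is
#' found by bisection on the monotone map scale -> deriv(0+).
#'
#' @param shape NEG shape parameter.
#' @param target_alpha Per-variant type-I error (e.g. 1e-4).
#' @param score_sd Null standard deviation of the score gradient for a
#'   standardized variant: `sqrt(sum(w_i))` with `w_i = mu0_i (1 -
#'   mu0_i)` from the covariate-only fit. See [null_score_sd()].
#' @return The calibrated scale (gamma).
#' @export
calibrate_scale <- function(shape, target_alpha, score_sd) {
  stopifnot(shape > 0, target_alpha > 0, target_alpha < 1, score_sd > 0)
  target_d0 <- stats::qnorm(1 - target_alpha / 2) * score_sd
  f <- function(g) neg_deriv0(shape, g) - target_d0
  lo <- 1e-8; hi <- 1e8
  if (f(lo) < 0 || f(hi) > 0) {
    stop("calibration bisection failed: target threshold ", target_d0,
         " outside achievable range")
  }
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi / lo - 1 < 1e-12) break
  }
  sqrt(lo * hi)
}

#' Null score standard deviation for a standardized variant
#'
#' Fits the covariate-only logistic model and returns
#' `sqrt(sum(mu (1 - mu)))`, the null standard deviation of the score
#' gradient of a standardized genotype independent of the covariates.
#' This is the dataset summary [calibrate_scale()] consumes.
#'
#' @param x A [dosage_data()] object.
#' @param adjust_region Include region indicators (default `TRUE`).
#' @return Positive scalar.
#' @export
null_score_sd <- function(x, adjust_region = TRUE) {
  y <- case_indicator(x$samples)
  z <- base_design(x$samples, adjust_region)
  fit <- fit_logistic(z, y)
  sqrt(sum(fit$fitted * (1 - fit$fitted)))
}
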