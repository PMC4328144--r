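test_that("LD pruning removes the lower-MAF member of tight pairs", {
  set.seed(61)
  n <- 300
  base <- rbinom(n, 2, 0.4)
  rare <- rbinom(n, 2, 0.1)
  g <- rbind(base, base, rare, rbinom(n, 2, 0.3))
  dd <- dd_from_genotypes(g)
  pr <- ld_prune(dd)
  # the duplicated column collapses to one survivor
  expect_equal(nrow(pr$data$variants), 3)
  expect_equal(pr$removed$removed_id, "v002") # tie in MAF: later pos goes
  expect_equal(pr$removed$kept_id, "v001")

  # nothing above threshold: identity
  dd2 <- dd_from_genotypes(rbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.2)))
  pr2 <- ld_prune(dd2)
  expect_equal(nrow(pr2$data$variants), 2)
})

test_that("greedy pruning matches the hand-worked 6-variant fixture", {
  set.seed(8)
  n <- 2000
  a <- rbinom(n, 2, 0.5)              # v1: maf 0.5
  b <- a; flip <- sample(n, 20); b[flip] <- 2 - b[flip] # v2 ~ v1, maf ~0.5
  c_ <- rbinom(n, 2, 0.2)             # v3 independent
  d <- c_; flip <- sample(n, 15); d[flip] <- rbinom(15, 2, 0.2) # v4 ~ v3
  e <- rbinom(n, 2, 0.35)             # v5 independent
  f <- rbinom(n, 2, 0.45)             # v6 independent
  g <- rbind(a, b, c_, d, e, f)
  dd <- dd_from_genotypes(g)
  d_mat <- dosages(dd)
  r2_12 <- dosage_r2(d_mat[1, ], d_mat[2, ])
  r2_34 <- dosage_r2(d_mat[3, ], d_mat[4, ])
  expect_gt(r2_12, 0.95)
  expect_gt(r2_34, 0.95)
  pr <- ld_prune(dd)
  maf <- allele_freqs(dd)$maf
  keep_12 <- if (maf[2] > maf[1]) "v002" else "v001"
  keep_34 <- if (maf[4] > maf[3]) "v004" else "v003"
  expect_setequal(pr$data$variants$id, c(keep_12, keep_34, "v005", "v006"))
  # exhaustive check: no surviving pair above threshold
  ds <- dosages(pr$data)
  combs <- utils::combn(nrow(ds), 2)
  r2s <- apply(combs, 2, function(ij) dosage_r2(ds[ij[1], ], ds[ij[2], ]))
  expect_true(all(r2s <= 0.95))
})

test_that("the quadratic core soft-thresholds exactly on orthonormal designs", {
  set.seed(30)
  n <- 64
  x <- qr.Q(qr(matrix(rnorm(n * 5), n, 5))) * sqrt(n) # t(x) x / n = I
  y <- rnorm(n, sd = 2)
  zhat <- drop(crossprod(x, y)) / n
  lam <- 0.3
  # lasso: soft threshold
  b <- finemapr:::penalized_wls_enet(x, y, rep(1, n), 0, 1, lam)
  expect_equal(unname(b), sign(zhat) * pmax(0, abs(zhat) - lam),
               tolerance = 1e-9)
  # elastic net: soft threshold then shrink by 1 + 2 lambda (1 - alpha)
  b2 <- finemapr:::penalized_wls_enet(x, y, rep(1, n), 0, 0.5, lam)
  expect_equal(unname(b2),
               sign(zhat) * pmax(0, abs(zhat) - lam * 0.5) /
                 (1 + 2 * lam * 0.5),
               tolerance = 1e-9)
})

test_that("lambda above lambda_max yields the empty model; KKT holds at
           the CV-selected lambda", {
  sim <- single_causal_sim(seed = 83, n_variants = 25, or = 1.6,
                           scale = 0.5)
  sp <- enet_spec(alpha = 0.5, n_lambda = 25, n_folds = 4, seed = 2)
  fit <- fit_elastic_net(sim$data, sp)
  expect_equal(fit$path$df[1], 0) # at lambda_max nothing enters
  expect_gt(length(fit$selected), 0)
  aud <- enet_kkt_audit(fit, sim$data)
  expect_true(attr(aud, "pass"))

  # explicit grid entirely above lambda_max: empty everywhere
  sp2 <- enet_spec(alpha = 1,
                   lambda_grid = fit$lambda_max * c(4, 2, 1.01),
                   n_folds = 4, seed = 2)
  fit2 <- fit_elastic_net(sim$data, sp2)
  expect_true(all(fit2$path$df == 0))
})

test_that("CV folds and the whole fit are reproducible from the seed", {
  sim <- single_causal_sim(seed = 19, n_variants = 20, scale = 0.4)
  sp <- enet_spec(alpha = 1, n_lambda = 15, n_folds = 4, seed = 7)
  f1 <- fit_elastic_net(sim$data, sp)
  f2 <- fit_elastic_net(sim$data, sp)
  expect_identical(f1$cv, f2$cv)
  expect_identical(f1$beta, f2$beta)
})

test_that("the lasso path approaches the unpenalized fit and matches glmnet", {
  sim <- single_causal_sim(seed = 28, n_variants = 15, or = 1.6,
                           scale = 0.5)
  g <- finemapr:::standardize_dosages(sim$data)
  z <- finemapr:::base_design(sim$data$samples)
  y <- as.numeric(sim$data$samples$status == "case")
  xmat <- cbind(z, g$mat)
  lams <- exp(seq(log(0.05), log(1e-5), length.out = 12))
  betas <- finemapr:::enet_path_solve(xmat, y, ncol(z), 1, lams)

  unpen <- fit_logistic(xmat, y)
  dist <- apply(betas, 2, function(b) max(abs(b - unpen$coefficients)))
  expect_lt(dist[length(lams)], 1e-3)
  expect_true(all(diff(dist) < 1e-8)) # monotone approach along the path

  # independent implementation check at a mid-path lambda (glmnet uses
  # the same objective for alpha = 1 once penalty factors are rescaled)
  lam <- 0.02
  bg <- glmnet::glmnet(
    xmat[, -1], y, family = "binomial", alpha = 1, standardize = FALSE,
    penalty.factor = c(rep(0, ncol(z) - 1), rep(1, ncol(g$mat))),
    lambda = lam * ncol(g$mat) / (ncol(xmat) - 1), thresh = 1e-14
  )
  own <- finemapr:::enet_path_solve(xmat, y, ncol(z), 1, lam)[, 1]
  ref <- c(bg$a0, as.numeric(bg$beta))
  expect_equal(unname(own), unname(ref), tolerance = 1e-4)
})
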