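test_that("dosage r2 is 1 for identical or allele-flipped vectors", {
  set.seed(3)
  a <- rbinom(200, 2, 0.3) + runif(200, -0.01, 0.01)
  expect_equal(dosage_r2(a, a), 1)
  expect_equal(dosage_r2(a, 2 - a), 1)
  expect_error(dosage_r2(a, rep(1, 200)), "constant")
  b <- rbinom(200, 2, 0.4)
  expect_lt(dosage_r2(a, b), 0.1)
})

test_that("null r2 between independent variants is small at large n", {
  set.seed(10)
  hits <- vapply(1:20, function(i) {
    a <- rbinom(5000, 2, 0.3)
    b <- rbinom(5000, 2, 0.4)
    dosage_r2(a, b)
  }, numeric(1))
  expect_true(mean(hits < 0.01) >= 0.95)
})

test_that("D-prime separates coupling from correlation", {
  # perfectly coupled loci
  set.seed(5)
  h <- rbinom(400, 1, 0.3)
  g_a <- h[1:200] + h[201:400]
  expect_equal(dprime(g_a, g_a), 1)

  # repulsion: minor alleles (freqs ~0.09 and ~0.15) never on the same
  # haplotype -> r2 low but D-prime 1
  n_hap <- 4000
  ha <- rep(0L, n_hap); hb <- rep(0L, n_hap)
  ha[1:360] <- 1L          # freq 0.09
  hb[361 + seq_len(600)] <- 1L # freq 0.15, disjoint carriers
  idx <- sample(n_hap)
  ha <- ha[idx]; hb <- hb[idx]
  g_a <- ha[1:2000] + ha[2001:4000]
  g_b <- hb[1:2000] + hb[2001:4000]
  expect_lt(dosage_r2(g_a, g_b), 0.1)
  expect_gt(dprime(g_a, g_b), 0.9)

  # linkage equilibrium: D-prime distribution centred low
  dps <- vapply(1:10, function(i) {
    a <- rbinom(5000, 2, 0.3)
    b <- rbinom(5000, 2, 0.4)
    dprime(a, b)
  }, numeric(1))
  expect_lt(mean(dps), 0.1)
})

test_that("identical models collapse to a single full-frequency class", {
  sim <- single_causal_sim(seed = 71, n_variants = 20, scale = 0.4)
  models <- tibble::tibble(iteration = 1:100, seed = 1:100,
                           converged = TRUE, size = 1L,
                           variants = "v010", betas = "0.2")
  cl <- collapse_models(models, sim$data)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$frequency, 100)
  expect_equal(cl$representative, "v010")
})

test_that("models whose SNPs are near-perfect proxies merge; sizes never mix", {
  set.seed(44)
  n <- 1500
  a <- rbinom(n, 2, 0.4)
  b <- a; fl <- sample(n, 12); b[fl] <- rbinom(12, 2, 0.4) # r2 ~ 0.99
  c_ <- rbinom(n, 2, 0.3)
  g <- rbind(a, b, c_)
  dd <- dd_from_genotypes(g)
  d <- dosages(dd)
  expect_gt(dosage_r2(d[1, ], d[2, ]), 0.95)

  models <- tibble::tibble(
    iteration = 1:4, seed = 1:4, converged = TRUE,
    size = c(1L, 1L, 1L, 2L),
    variants = c("v001", "v002", "v003", "v001,v003"),
    betas = c("0.2", "0.2", "0.1", "0.2,0.1")
  )
  cl <- collapse_models(models, dd, r2_equiv = 0.9)
  expect_equal(nrow(cl), 3)
  merged <- cl[cl$size == 1 & cl$frequency == 2, ]
  expect_equal(nrow(merged), 1) # v001 and v002 merged
  expect_equal(sum(cl$frequency), 4)
  # the 2-SNP model never merges with 1-SNP models
  expect_true(any(cl$size == 2 & cl$frequency == 1))
})

test_that("collapsing is order-invariant and monotone in the threshold", {
  set.seed(12)
  n <- 1000
  a <- rbinom(n, 2, 0.4)
  b <- a; fl <- sample(n, 150); b[fl] <- rbinom(150, 2, 0.4) # moderate r2
  dd <- dd_from_genotypes(rbind(a, b))
  r2_ab <- dosage_r2(dosages(dd)[1, ], dosages(dd)[2, ])
  expect_true(r2_ab > 0.5 && r2_ab < 0.95)

  models <- tibble::tibble(iteration = 1:3, seed = 1:3, converged = TRUE,
                           size = 1L,
                           variants = c("v001", "v002", "v001"),
                           betas = "0.1")
  cl_fwd <- collapse_models(models, dd, r2_equiv = 0.5)
  cl_rev <- collapse_models(models[3:1, ], dd, r2_equiv = 0.5)
  expect_equal(cl_fwd$frequency, cl_rev$frequency)
  expect_equal(cl_fwd$representative, cl_rev$representative)

  n_low <- nrow(collapse_models(models, dd, r2_equiv = 0.5))
  n_high <- nrow(collapse_models(models, dd, r2_equiv = 0.99))
  expect_lte(n_low, n_high)
})

test_that("refits reproduce the scan for singletons and recover planted
           multi-SNP effects", {
  sim <- single_causal_sim(seed = 91, n_variants = 30, or = 1.5)
  sc <- single_snp_scan(sim$data)
  ts <- top_snp(sc)
  rf <- refit_model(sim$data, ts)
  rec <- sc[sc$id == ts, ]
  expect_equal(rf$beta, rec$beta, tolerance = 1e-8)
  expect_equal(rf$p, rec$p, tolerance = 1e-8)

  # three independent planted effects recovered jointly within 3 SEs
  set.seed(2)
  n <- 3000
  g <- rbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.4), rbinom(n, 2, 0.25))
  betas <- log(c(1.4, 1.3, 1.5))
  eta <- -0.8 + drop(t(g) %*% betas)
  y <- rbinom(n, 1, plogis(eta))
  dd <- dd_from_genotypes(g, status = ifelse(y == 1, "case", "control"))
  rf3 <- refit_model(dd, c("v001", "v002", "v003"))
  expect_true(all(abs(rf3$beta - betas) < 3 * rf3$se))
})

test_that("collinear refit sets are refused with the offending pair named", {
  n <- 500
  a <- rbinom(n, 2, 0.4)
  dd <- dd_from_genotypes(rbind(a, a))
  expect_error(refit_model(dd, c("v001", "v002")), "v001 and v002")
})
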