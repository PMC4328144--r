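test_that("constant dosages and conditioning variants are flagged", {
  g <- rbind(rep(1L, 40), rbinom(40, 2, 0.4), rbinom(40, 2, 0.3))
  dd <- dd_from_genotypes(g)
  sc <- single_snp_scan(dd)
  expect_equal(sc$note[1], "constant_dosage")
  expect_true(is.na(sc$p[1]))

  sc2 <- single_snp_scan(dd, condition_on = "v002")
  expect_equal(sc2$note[sc2$id == "v002"], "in_conditioning_set")
  expect_true(is.na(sc2$p[sc2$id == "v002"]))
})

test_that("top_snp uses minimum p with position then id tie-breaks", {
  rec <- tibble::tibble(id = c("a", "b", "c"), chrom = "1",
                        pos = c(100L, 200L, 300L),
                        p = c(0.1, 1e-8, 0.5))
  expect_equal(top_snp(rec), "b")
  tie <- tibble::tibble(id = c("z", "a"), chrom = "1",
                        pos = c(500L, 200L), p = c(1e-6, 1e-6))
  expect_equal(top_snp(tie), "a") # lower position wins
  tie2 <- tibble::tibble(id = c("z", "a"), chrom = "1",
                         pos = c(200L, 200L), p = c(1e-6, 1e-6))
  expect_equal(top_snp(tie2), "a") # then lexicographic id
})

test_that("the significance gate is strict", {
  rec <- tibble::tibble(id = "a", chrom = "1", pos = 1L, p = 2e-6)
  expect_true(gate_region(rec))
  rec$p <- 1e-5
  expect_false(gate_region(rec)) # boundary is excluded
  rec$p <- NA_real_
  expect_false(gate_region(rec))
})

test_that("region narrowing covers 500 kb around core SNPs, clipped at 1", {
  rec <- tibble::tibble(id = c("a", "b", "c"), chrom = "1",
                        pos = c(1000000L, 1400000L, 2000000L),
                        p = c(1e-8, 1e-7, 1e-3))
  w <- narrow_region(rec)
  expect_equal(w$start, 500000)
  expect_equal(w$end, 1900000)

  rec1 <- tibble::tibble(id = "a", chrom = "1", pos = 200000L, p = 1e-8)
  w1 <- narrow_region(rec1)
  expect_equal(w1$start, 1)
  expect_equal(w1$end, 700000)

  # fallback: nothing under p_core, window around the top SNP
  rec2 <- tibble::tibble(id = c("a", "b"), chrom = "1",
                         pos = c(1000000L, 3000000L), p = c(3e-6, 0.2))
  w2 <- narrow_region(rec2)
  expect_equal(w2$start, 500000)
  expect_equal(w2$end, 1500000)
})

test_that("the secondary-signal rule is strict and ignores conditioned SNPs", {
  rec <- tibble::tibble(id = c("a", "b"), chrom = "1",
                        pos = c(1L, 2L), p = c(NA, 2e-6),
                        note = c("in_conditioning_set", NA))
  s <- secondary_signal(rec)
  expect_true(s$found)
  expect_equal(s$id, "b")
  rec$p[2] <- 1e-5
  expect_false(secondary_signal(rec)$found) # boundary excluded
})

test_that("conditioning on the causal variant removes its tags' signal", {
  sim <- single_causal_sim(seed = 31, n_variants = 40, or = 1.6, scale = 1)
  sc <- single_snp_scan(sim$data)
  expect_true(gate_region(sc))
  cond <- single_snp_scan(sim$data, condition_on = sim$truth$id)
  expect_false(secondary_signal(cond)$found)
})

test_that("Wald and score tests agree for moderate signals", {
  sim <- single_causal_sim(seed = 12, n_variants = 20, or = 1.2,
                           scale = 0.5)
  wald <- single_snp_scan(sim$data, test = "wald")
  score <- single_snp_scan(sim$data, test = "score")
  z <- abs(wald$beta / wald$se)
  keep <- !is.na(z) & z < 4 & z > 0.3
  rel <- abs(log10(wald$p[keep]) - log10(score$p[keep])) /
    abs(log10(wald$p[keep]))
  expect_true(all(rel < 0.2))
})

test_that("scan is invariant to sample permutation and region relabeling", {
  sim <- single_causal_sim(seed = 77, n_variants = 15, scale = 0.3)
  sc <- single_snp_scan(sim$data)
  set.seed(1)
  perm <- sample(nrow(sim$data$samples))
  xp <- subset_dosage(sim$data, samples = perm)
  scp <- single_snp_scan(xp)
  expect_equal(sc$p, scp$p, tolerance = 1e-9)

  xr <- sim$data
  xr$samples$region <- paste0("zone_", xr$samples$region)
  scr <- single_snp_scan(xr)
  expect_equal(sc$p, scr$p, tolerance = 1e-9)
})

test_that("region adjustment calibrates type-I error under stratification", {
  # drifted null region with unequal case/control quotas by region
  cfg <- sim_config(n_variants = 250, regions = default_sim_regions(0.3),
                    f_st = 0.1, switch_rate = 1e-3, seed = 55)
  sim <- simulate_case_control(cfg)
  adj <- single_snp_scan(sim$data)
  unadj <- single_snp_scan(sim$data, adjust_region = FALSE)
  rate_adj <- mean(adj$p < 0.05, na.rm = TRUE)
  rate_unadj <- mean(unadj$p < 0.05, na.rm = TRUE)
  m <- sum(!is.na(adj$p))
  band <- 3 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(rate_adj - 0.05), band + 0.01)
  expect_gt(rate_unadj, 0.05 + band)
})

test_that("null p-values are approximately uniform without stratification", {
  cfg <- sim_config(n_variants = 300, regions = default_sim_regions(0.3),
                    f_st = 0, switch_rate = 1e-3, seed = 66)
  sim <- simulate_case_control(cfg)
  sc <- single_snp_scan(sim$data)
  ks <- suppressWarnings(ks.test(sc$p[!is.na(sc$p)], "punif"))
  expect_gt(ks$p.value, 0.01)
})
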