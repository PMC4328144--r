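test_that("Balding-Nichols drift has the right moments", {
  expect_equal(drift_frequencies(0.3, 0, 7), rep(0.3, 7))
  expect_error(drift_frequencies(0, 0.01, 7), "in \\(0, 1\\)")

  set.seed(101)
  f <- 0.01; p <- 0.3; n <- 1e4
  draws <- drift_frequencies(p, f, n)
  se_mean <- sqrt(f * p * (1 - p) / n)
  expect_lt(abs(mean(draws) - p), 3 * se_mean)
  target_var <- f * p * (1 - p)
  # MC error of a variance estimate: var ~ 2 sigma^4 / n for near-normal
  expect_lt(abs(var(draws) - target_var), 4 * target_var / sqrt(n) * 2)
})

test_that("mosaic haplotypes interpolate between founder copies and LE", {
  set.seed(33)
  m <- 30
  positions <- seq(1000, by = 10000, length.out = m)
  founders2 <- matrix(rbinom(2 * m, 1, 0.5), nrow = 2)
  # no switching: every haplotype is an exact founder copy
  h0 <- simulate_haplotypes(founders2, positions, 50, switch_rate = 0)
  match_f <- apply(h0, 1, function(h) {
    any(apply(founders2, 1, function(f) all(f == h)))
  })
  expect_true(all(match_f))

  # adjacent-variant r2: maximal at rate 0, near 0 at huge rate,
  # monotone decreasing in between
  adj_r2 <- function(rate) {
    h <- simulate_haplotypes(founders2, positions, 600, rate)
    hk <- h[, apply(h, 2, sd) > 0, drop = FALSE]
    r2 <- vapply(seq_len(ncol(hk) - 1), function(i) {
      cor(hk[, i], hk[, i + 1])^2
    }, numeric(1))
    mean(r2, na.rm = TRUE)
  }
  rates <- c(0, 1e-6, 1e-5, 1e-4, 1)
  r2s <- vapply(rates, adj_r2, numeric(1))
  expect_equal(r2s[1], 1) # exact founder copies, K = 2
  expect_lt(r2s[5], 0.05)
  expect_true(all(diff(r2s) < 0.05)) # decreasing up to MC noise
  expect_true(r2s[3] < r2s[1] - 0.1 && r2s[3] > r2s[5] + 0.1)
})

test_that("imputation degradation hits the target INFO", {
  set.seed(17)
  g <- rbinom(2000, 2, 0.3)
  full <- degrade_to_dosage(g, 1, 0.3)
  expect_equal(full$p_ab, as.numeric(g == 1))
  expect_equal(full$realized_info, 1)

  deg <- degrade_to_dosage(g, 0.6, mean(g) / 2)
  expect_gte(deg$realized_info, 0.58)
  expect_lte(deg$realized_info, 0.62)
  # w = 0 is the pure prior: no information
  prior_only <- finemapr:::info_score(
    rep((1 - 0.3)^2, 10), rep(2 * 0.3 * 0.7, 10), rep(0.09, 10))
  expect_equal(as.numeric(prior_only), 0, tolerance = 1e-12)

  expect_error(degrade_to_dosage(rep(0L, 50), 0.8, 0), "monomorphic")
})

test_that("null regions show equal case/control frequencies", {
  # large founder pool and fast switching: individuals are effectively
  # independent draws, so the binomial standard error applies
  cfg <- sim_config(n_variants = 25, regions = default_sim_regions(0.4),
                    founder_pool = 200, switch_rate = 1e-3, f_st = 0,
                    seed = 5)
  sim <- simulate_case_control(cfg)
  d <- dosages(sim$data)
  is_case <- sim$data$samples$status == "case"
  f_case <- rowMeans(d[, is_case]) / 2
  f_ctrl <- rowMeans(d[, !is_case]) / 2
  n <- ncol(d) / 2
  se <- sqrt(f_ctrl * (1 - f_ctrl) * (1 / (2 * sum(is_case)) +
                                        1 / (2 * sum(!is_case))))
  expect_true(all(abs(f_case - f_ctrl) < 4 * se + 1e-6))
})

test_that("a planted effect is recovered by the marginal fit", {
  sim <- single_causal_sim(seed = 9, n_variants = 30, or = 1.5, scale = 1)
  sc <- single_snp_scan(sim$data)
  rec <- sc[sc$id == sim$truth$id, ]
  expect_lt(abs(rec$beta - log(1.5)), 3 * rec$se)
})

test_that("truth records round-trip causal identity, including untyped", {
  cfg <- sim_config(n_variants = 20, regions = default_sim_regions(0.2),
                    causal_spec = tibble::tibble(variant = c(5, 12),
                                                 or = c(1.4, 1.2),
                                                 typed = c(TRUE, FALSE)),
                    seed = 2)
  sim <- simulate_case_control(cfg)
  expect_equal(sim$truth$variant, c(5, 12))
  expect_equal(sim$truth$or, c(1.4, 1.2))
  expect_true("v0005" %in% sim$data$variants$id)
  expect_false("v0012" %in% sim$data$variants$id) # untyped: dropped
  expect_equal(nrow(sim$data$variants), 19)
})

test_that("per-array imputation targets drive the retention classes", {
  imp <- tibble::tibble(variant = c(2, 2, 3, 3, 4, 4),
                        array = rep(c("a1", "a2"), 3),
                        target_info = c(0.9, 0.85, 0.65, 0.7, 0.9, 0.45))
  cfg <- sim_config(n_variants = 5, regions = default_sim_regions(0.5),
                    arrays = c("a1", "a2"), imputation_spec = imp,
                    seed = 8, f_st = 0)
  sim <- simulate_case_control(cfg)
  qc <- run_snp_qc(sim$data)
  ret <- setNames(qc$report$retention, qc$report$id)
  expect_equal(unname(ret["v0001"]), "A") # genotyped on both arrays
  expect_equal(unname(ret["v0002"]), "B") # min INFO >= 0.8
  expect_equal(unname(ret["v0003"]), "C") # min INFO in [0.5, 0.8)
  expect_equal(unname(ret["v0004"]), "excluded") # min INFO < 0.5
})

test_that("unattainable quotas error out", {
  cfg <- sim_config(n_variants = 5,
                    regions = tibble::tibble(region = "X", n_cases = 50,
                                             n_controls = 0),
                    baseline_intercept = -30, seed = 1)
  expect_error(simulate_case_control(cfg, max_batches = 3),
               "unattainable")
})
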