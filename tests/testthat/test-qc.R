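test_that("exact HWE test matches full enumeration for small tables", {
  expect_equal(hwe_exact_test(25, 50, 25), hwe_brute(25, 50, 25))
  expect_gt(hwe_exact_test(25, 50, 25), 0.9) # modal outcome
  expect_lt(hwe_exact_test(0, 20, 0), 1e-4)  # all-heterozygote excess
  expect_equal(hwe_exact_test(10, 0, 0), 1)  # monomorphic convention

  set.seed(42)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    parts <- as.vector(stats::rmultinom(1, n, c(1, 1, 1)))
    p1 <- hwe_exact_test(parts[1], parts[2], parts[3])
    p2 <- hwe_brute(parts[1], parts[2], parts[3])
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_gt(p1, 0)
    expect_lte(p1, 1)
  }
})

# independently coded INFO: ratio of mean posterior dosage variance to
# the binomial variance at the empirical allele frequency
info_oracle <- function(p_aa, p_ab, p_bb) {
  e <- p_ab + 2 * p_bb
  e2 <- p_ab + 4 * p_bb
  theta <- sum(e) / (2 * length(e))
  1 - mean(e2 - e^2) / (2 * theta * (1 - theta))
}

test_that("INFO score has the right limits and matches a reimplementation", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  one_hot <- list(p_aa = as.numeric(g == 0), p_ab = as.numeric(g == 1),
                  p_bb = as.numeric(g == 2))
  expect_equal(as.numeric(info_score(one_hot$p_aa, one_hot$p_ab,
                                     one_hot$p_bb)), 1)

  theta <- 0.3
  n <- 50
  prior <- list(p_aa = rep((1 - theta)^2, n),
                p_ab = rep(2 * theta * (1 - theta), n),
                p_bb = rep(theta^2, n))
  expect_equal(as.numeric(info_score(prior$p_aa, prior$p_ab, prior$p_bb)),
               0, tolerance = 1e-12)

  set.seed(7)
  raw <- matrix(runif(3 * 40), ncol = 3)
  raw <- raw / rowSums(raw)
  got <- as.numeric(info_score(raw[, 1], raw[, 2], raw[, 3]))
  expect_equal(got, min(1, max(0, info_oracle(raw[, 1], raw[, 2], raw[, 3]))),
               tolerance = 1e-12)
  # on realistic (informative) posteriors the clip never engages
  g <- rbinom(60, 2, 0.3)
  noisy <- degrade_to_dosage(g, 0.7, mean(g) / 2)
  expect_equal(as.numeric(info_score(noisy$p_aa, noisy$p_ab, noisy$p_bb)),
               info_oracle(noisy$p_aa, noisy$p_ab, noisy$p_bb),
               tolerance = 1e-12)

  # invariant to sample order and to duplicating the sample set
  perm <- sample(40)
  expect_equal(as.numeric(info_score(raw[perm, 1], raw[perm, 2],
                                     raw[perm, 3])), got)
  dup <- rbind(raw, raw)
  expect_equal(as.numeric(info_score(dup[, 1], dup[, 2], dup[, 3])), got)
})

test_that("SNP QC exclusions follow the priority order on a crafted fixture", {
  set.seed(5)
  n <- 400
  # well-behaved genotype generator at HWE
  hwe_g <- function(p) rbinom(n, 2, p)
  g <- rbind(
    hwe_g(0.3),                         # clean -> kept
    hwe_g(0.031),                       # MAF just above threshold -> kept
    hwe_g(0.01),                        # rare -> MAF exclusion
    c(rep(1L, n)),                      # all hets -> HWE exclusion
    hwe_g(0.4)                          # will get missing calls -> call rate
  )
  dd <- dd_from_genotypes(g)
  # knock 5% of calls out of variant 5
  miss <- sample(n, 20)
  dd$p_aa[5, miss] <- NA; dd$p_ab[5, miss] <- NA; dd$p_bb[5, miss] <- NA
  rep_ <- snp_qc_filter(dd)
  expect_true(rep_$kept[1])
  expect_true(rep_$kept[2])
  expect_equal(rep_$reason[3], "MAF")
  expect_equal(rep_$reason[4], "HWE")
  expect_equal(rep_$reason[5], "call_rate")
})

test_that("HWE p threshold is strict at the boundary", {
  th <- qc_thresholds()
  # a variant fails only if p < 1e-4; craft via direct check on values
  expect_true(5e-5 < th$hwe_p_min)
  g <- matrix(rep(1L, 60), nrow = 1) # all heterozygotes
  dd <- dd_from_genotypes(g)
  expect_false(snp_qc_filter(dd)$kept[1])
})

test_that("retention typing implements the A/B/C rules", {
  arrays <- c("a1", "a2", "a3", "a4")
  expect_equal(classify_retention(arrays, numeric(0), 0.2, arrays), "A")
  expect_equal(classify_retention(character(0),
                                  c(a1 = 0.82, a2 = 0.9, a3 = 0.85, a4 = 0.99),
                                  0.2, arrays), "B")
  expect_equal(classify_retention("a1",
                                  c(a2 = 0.6, a3 = 0.7, a4 = 0.9),
                                  0.05, arrays), "C")
  expect_equal(classify_retention(character(0),
                                  c(a1 = 0.6, a2 = 0.9, a3 = 0.9, a4 = 0.9),
                                  0.02, arrays), "excluded")
  expect_equal(classify_retention(character(0),
                                  c(a1 = 0.4, a2 = 0.9, a3 = 0.9, a4 = 0.9),
                                  0.2, arrays), "excluded")
  expect_error(classify_retention(character(0), c(a1 = 0.9), 0.2, arrays),
               "no INFO entry")
})

test_that("retention partition is exhaustive and exclusive", {
  arrays <- c("a1", "a2")
  set.seed(13)
  for (i in 1:50) {
    gen <- sample(c(list(character(0)), list("a1"), list(arrays)), 1)[[1]]
    info <- setNames(runif(2), arrays)
    maf <- runif(1, 0, 0.5)
    r <- classify_retention(gen, info, maf, arrays)
    expect_true(r %in% c("A", "B", "C", "excluded"))
  }
})
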