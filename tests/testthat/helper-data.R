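# Build a dosage_data object from a hard-genotype matrix (variants x
# samples), one-hot posteriors. Defaults give a single region so tests
# that do not exercise stratification stay small.
dd_from_genotypes <- function(g, status = NULL, region = NULL,
                              pos = NULL, genotyped = TRUE) {
  m <- nrow(g); n <- ncol(g)
  if (is.null(status)) status <- rep(c("case", "control"), length.out = n)
  if (is.null(region)) region <- rep("all", n)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  variants <- tibble::tibble(
    id = sprintf("v%03d", seq_len(m)), chrom = "1", pos = pos,
    a0 = "A", a1 = "G",
    genotyped_on = replicate(m, if (genotyped) "array1" else character(0),
                             simplify = FALSE),
    info_by_array = replicate(m, numeric(0), simplify = FALSE)
  )
  samples <- tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)),
                            status = status, region = region)
  dosage_data(variants,
              p_aa = (g == 0) * 1, p_ab = (g == 1) * 1, p_bb = (g == 2) * 1,
              samples = samples)
}

# Independent-variant null case-control dataset: binomial genotypes at
# random allele frequencies, status assigned independently of genotype.
null_dd <- function(m, n, maf_range = c(0.1, 0.5), seed = 1) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  g <- matrix(rbinom(m * n, 2, rep(p, n)), nrow = m)
  status <- rep(c("case", "control"), length.out = n)
  dd_from_genotypes(g, status = status)
}

# Small LD region with one planted causal variant, via the simulator.
single_causal_sim <- function(seed, n_variants = 60, or = 1.5,
                              causal = NULL, scale = 1, f_st = 0.01,
                              switch_rate = 1e-5,
                              maf_range = c(0.2, 0.5)) {
  if (is.null(causal)) causal <- ceiling(n_variants / 2)
  cfg <- sim_config(
    n_variants = n_variants,
    regions = default_sim_regions(scale),
    causal_spec = tibble::tibble(variant = causal, or = or, typed = TRUE),
    f_st = f_st, switch_rate = switch_rate, maf_range = maf_range,
    seed = seed
  )
  simulate_case_control(cfg)
}

# independent oracle: direct enumeration of the conditional genotype
# distribution given allele counts, P(n_ab) proportional to
# n! 2^n_ab / (n_aa! n_ab! n_bb!), summed over outcomes no more
# probable than the observed one
hwe_brute <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  if (min(n_a, 2 * n - n_a) == 0) return(1)
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (n_a - h) / 2
    bb <- n - aa - h
    lfactorial(n) + h * log(2) -
      lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

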