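test_that("single population with vanishing theta yields no variation", {
  cfg <- demography_config(
    populations = data.frame(name = "A", theta = 1e-12),
    splits = data.frame(parent = character(0), child1 = character(0),
                        child2 = character(0), time = numeric(0)),
    samples = data.frame(sample = c("s1", "s2", "s3"), population = "A",
                         age = 0, ploidy = 2))
  p <- simulate_genotypes(cfg, 500, seed = 1)
  expect_true(all(p$geno == p$geno[, 1]))
  expect_true(all(p$geno == 0))
})

test_that("two-population divergence matches the closed-form expectation", {
  tau <- 0.002; th <- 0.01
  p <- simulate_genotypes(two_pop_config(tau, th), 1e5, seed = 42)
  frac <- mean(p$geno[, 1] != p$geno[, 2])
  expected <- two_pop_diff_prob(tau, th)
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("closer split shares more exclusive derived alleles (tree oracle)", {
  # EUR and IND split below the Asian split, so EUR+IND exclusive sharing
  # must exceed EUR+ASIA exclusive sharing
  cfg <- demography_config(
    populations = data.frame(
      name = c("EUR", "IND", "ASIA", "OUT", "EI", "EIA", "ROOT"),
      theta = c(rep(1e-8, 4), rep(0.01, 3))),
    splits = data.frame(parent = c("EI", "EIA", "ROOT"),
                        child1 = c("EUR", "EI", "EIA"),
                        child2 = c("IND", "ASIA", "OUT"),
                        time = c(0.002, 0.003, 0.01)),
    samples = data.frame(sample = c("e", "i", "s", "o"),
                         population = c("EUR", "IND", "ASIA", "OUT"),
                         age = 0, ploidy = 1))
  p <- simulate_genotypes(cfg, 1e5, seed = 7)
  g <- p$geno
  ei <- sum(g[, "e"] == 1 & g[, "i"] == 1 & g[, "s"] == 0 & g[, "o"] == 0)
  es <- sum(g[, "e"] == 1 & g[, "s"] == 1 & g[, "i"] == 0 & g[, "o"] == 0)
  expect_gt(ei, es)
})

test_that("seed determinism gives bit-identical panels and stacks", {
  cfg <- two_pop_config()
  expect_identical(simulate_genotypes(cfg, 200, seed = 9)$geno,
                   simulate_genotypes(cfg, 200, seed = 9)$geno)
  dm <- damage_model(weibull_decay(0.3, 0.3, 1))
  truth <- data.frame(chrom = "chr1", pos = 1:50, ref = "C",
                      genotype = "CC")
  expect_identical(simulate_reads(truth, 9, dm, seed = 3)$reads,
                   simulate_reads(truth, 9, dm, seed = 3)$reads)
  segs <- data.frame(start = 100, end = 200, cn = 4L)
  gc <- runif(500, 0.3, 0.6)
  expect_identical(simulate_depth(segs, gc, seed = 5)$depth,
                   simulate_depth(segs, gc, seed = 5)$depth)
})

test_that("ascertainment keeps only sites variable in the panel", {
  cfg <- demography_config(
    populations = data.frame(name = c("A", "B", "AB"),
                             theta = c(0.005, 0.005, 0.01)),
    splits = data.frame(parent = "AB", child1 = "A", child2 = "B",
                        time = 0.002),
    samples = data.frame(sample = c("a1", "a2", "b1"),
                         population = c("A", "A", "B"),
                         age = 0, ploidy = 2),
    ascertainment = "A")
  p <- simulate_genotypes(cfg, 300, seed = 2)
  dos <- p$geno[, c("a1", "a2")]
  expect_true(all(rowSums(dos) > 0 & rowSums(dos) < 4))
})

test_that("folded SFS in one panmictic population fits neutral expectations", {
  cfg <- demography_config(
    populations = data.frame(name = "A", theta = 0.01),
    splits = data.frame(parent = character(0), child1 = character(0),
                        child2 = character(0), time = numeric(0)),
    samples = data.frame(sample = paste0("s", 1:5), population = "A",
                         age = 0, ploidy = 2))
  p <- simulate_genotypes(cfg, 1e5, seed = 11)
  dac <- rowSums(p$geno)
  seg <- dac > 0 & dac < 10
  counts <- tabulate(dac[seg], nbins = 9)
  # neutral SFS: E[xi_i] proportional to 1/i; fold over i and n-i
  exp_unfolded <- 1 / (1:9)
  folded_obs <- counts[1:4] + counts[9:6]
  folded_obs <- c(folded_obs, counts[5])
  folded_exp <- exp_unfolded[1:4] + exp_unfolded[9:6]
  folded_exp <- c(folded_exp, exp_unfolded[5])
  pval <- stats::chisq.test(folded_obs,
                            p = folded_exp / sum(folded_exp))$p.value
  expect_gt(pval, 0.01)
})

test_that("read simulator hits requested coverage and damage rates", {
  dm <- damage_model(weibull_decay(0.3, 0.3, 1), weibull_decay(0, 1, 1))
  truth <- data.frame(chrom = "chr1", pos = seq_len(2e4), ref = "C",
                      genotype = "CC")
  st <- simulate_reads(truth, coverage_mean = 9, dm, qual_profile = 30,
                       seed = 8)
  cov <- nrow(st$reads) / nrow(st$sites)
  expect_lt(abs(cov - 9) / 9, 0.01)
  # forward reads with the C template at 5' position 1: damage then error
  r <- st$reads[st$reads$strand == "+" & st$reads$pos5 == 1, ]
  d <- 0.3 * exp(-0.3)
  eps <- 1e-3
  p_t <- d * (1 - eps) + (1 - d) * eps / 3
  obs <- mean(r$base == "T")
  se <- sqrt(p_t * (1 - p_t) / nrow(r))
  expect_lt(abs(obs - p_t), 3 * se)
})

test_that("zero-amplitude damage leaves only sequencing error at termini", {
  dm <- damage_model(weibull_decay(0, 1, 1, degenerate = TRUE))
  truth <- data.frame(chrom = "chr1", pos = seq_len(5000), ref = "C",
                      genotype = "CC")
  st <- simulate_reads(truth, 9, dm, qual_profile = 30, seed = 4)
  r <- st$reads[st$reads$pos5 <= 2, ]
  mismatch <- mean(r$base != "C")
  eps <- 1e-3
  se <- sqrt(eps * (1 - eps) / nrow(r))
  expect_lt(abs(mismatch - eps), 3 * se)
})

test_that("depth simulator reproduces copy-number ratios and GC bias", {
  gc <- rep(0.45, 3e4)
  segs <- data.frame(start = 10000, end = 20000, cn = 6L)
  tr <- simulate_depth(segs, gc, base_depth = 9, seed = 6)
  bg <- mean(tr$depth[tr$true_cn == 2])
  seg <- mean(tr$depth[tr$true_cn == 6])
  se_ratio <- (seg / bg) * sqrt(1 / sum(tr$depth[tr$true_cn == 6]) +
                                  1 / sum(tr$depth[tr$true_cn == 2]))
  expect_lt(abs(seg / bg - 3), 3 * se_ratio)
  expect_lt(abs(bg - 9), 0.15)
  # injected U-shaped bias is recovered by a loess of depth on GC
  set.seed(31)
  gc2 <- runif(1e4, 0.25, 0.65)
  bias <- function(g) 1 + 2 * (g - 0.45)^2
  tr2 <- simulate_depth(NULL, gc2, bias = bias, base_depth = 200,
                        seed = 12)
  fit <- stats::loess(depth ~ gc, data = tr2, span = 0.3)
  pred <- predict(fit)
  truthv <- 200 * bias(tr2$gc)
  r2 <- 1 - sum((pred - truthv)^2) / sum((truthv - mean(truthv))^2)
  expect_gt(r2, 0.9)
})

test_that("overlapping copy-number segments are rejected", {
  gc <- rep(0.4, 100)
  segs <- data.frame(start = c(10, 40), end = c(50, 80), cn = c(3L, 4L))
  expect_error(simulate_depth(segs, gc, seed = 1), "overlap")
})

test_that("panel writers round-trip through TSV and EIGENSTRAT", {
  p <- simulate_genotypes(two_pop_config(), 100, seed = 3)
  p$geno[5, 1] <- NA
  tsv <- tempfile(fileext = ".tsv")
  write_panel_tsv(p, tsv)
  q <- read_panel_tsv(tsv)
  expect_identical(unname(q$geno), unname(p$geno))
  expect_identical(q$samples$population, p$samples$population)
  pre <- tempfile()
  write_panel_eigenstrat(p, pre)
  r <- read_panel_eigenstrat(pre, block_size = 500)
  expect_identical(unname(r$geno), unname(p$geno))
})

test_that("invalid demographies are rejected with configuration errors", {
  pops <- data.frame(name = c("A", "B", "AB"), theta = 0.01)
  smp <- data.frame(sample = c("a", "b"), population = c("A", "B"),
                    age = 0, ploidy = 1)
  expect_error(demography_config(
    pops, data.frame(parent = "AB", child1 = "A", child2 = "B",
                     time = -1), smp), "positive")
  expect_error(demography_config(
    pops, data.frame(parent = "AB", child1 = "A", child2 = "C",
                     time = 1), smp), "unknown")
  expect_error(demography_config(
    pops, data.frame(parent = "AB", child1 = "A", child2 = "B", time = 1),
    data.frame(sample = "a", population = "A", age = 2, ploidy = 1)),
    "older")
  # parent merging below its children is not a valid tree
  pops4 <- data.frame(name = c("A", "B", "C", "AB", "R"), theta = 0.01)
  expect_error(demography_config(
    pops4,
    data.frame(parent = c("AB", "R"), child1 = c("A", "AB"),
               child2 = c("B", "C"), time = c(2, 1)),
    smp), "ordered")
})
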