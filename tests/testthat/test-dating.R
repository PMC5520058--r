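base_params <- function(...) {
  args <- list(theta1 = 1e-4, theta2 = 1e-4, P0 = 1e-5, P2 = 2e-5,
               P3 = 3e-5, alpha = 0.2, tau1 = 1.5e-5)
  args[names(list(...))] <- list(...)
  do.call(coal_params, args)
}

test_that("haploidization halves homozygotes and flips fair coins on hets", {
  g <- cbind(s1 = c(0L, 2L, 2L, 0L), s2 = c(2L, 2L, 0L, 0L))
  p <- genotype_panel(g, populations = c("X", "Y"))
  h1 <- haploidize(p, c(X = "s1", Y = "s2"), seed = 1)
  h2 <- haploidize(p, c(X = "s1", Y = "s2"), seed = 99)
  expect_identical(h1$hap, h2$hap)  # no hets: seed-independent
  expect_equal(unname(h1$hap[, "X"]), c(0, 1, 1, 0))
  # dosage-1 sites draw the derived allele with probability one half
  ph <- genotype_panel(matrix(1L, 10000, 1, dimnames = list(NULL, "q")),
                       populations = "Q")
  hh <- haploidize(ph, c(Q = "q"), seed = 5)
  expect_lt(abs(mean(hh$hap) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("sharing patterns count exactly the exclusive configurations", {
  hap <- rbind(c(1, 1, 0, 0),  # anc+eur exclusive
               c(0, 1, 1, 0),  # eur+ind exclusive
               c(1, 1, 1, 1),  # all derived: neither
               c(1, 1, 1, 0),  # not exclusive
               c(1, 1, 0, 1))  # asia derived: strict excludes
  colnames(hap) <- c("ANC", "EUR", "IND", "ASIA")
  hp <- structure(list(hap = hap, block = rep(1L, 5), polarized = TRUE),
                  class = "haploid_panel")
  cnt <- count_sharing_patterns(hp)
  expect_equal(cnt$n_anc_eur, 1)
  expect_equal(cnt$n_eur_ind, 1)
  lenient <- count_sharing_patterns(hp, strict = FALSE)
  expect_equal(lenient$n_anc_eur, 2)
  hp$polarized <- FALSE
  expect_error(count_sharing_patterns(hp), "polarized")
})

test_that("sharing ratio arithmetic and degenerate cases", {
  pb <- data.frame(block = 1L, n_anc_eur = 119, n_eur_ind = 100,
                   n_sites = 1000)
  cnt <- structure(list(per_block = pb, n_anc_eur = 119, n_eur_ind = 100,
                        n_sites = 1000, strict = TRUE),
                   class = "sharing_counts")
  r <- sharing_ratio(cnt)
  expect_equal(r$R, 1.19)
  expect_true(is.na(r$se))
  # equal per-block counts give zero-width CI
  pb2 <- data.frame(block = 1:10, n_anc_eur = 12, n_eur_ind = 10,
                    n_sites = 100)
  cnt2 <- structure(list(per_block = pb2, n_anc_eur = 120,
                         n_eur_ind = 100, n_sites = 1000, strict = TRUE),
                    class = "sharing_counts")
  r2 <- sharing_ratio(cnt2)
  expect_equal(r2$R, 1.2)
  expect_equal(r2$se, 0)
  cnt0 <- cnt; cnt0$n_eur_ind <- 0
  expect_error(sharing_ratio(cnt0), "zero")
})

test_that("jackknife CI covers the truth across seeded Poisson replicates", {
  hits <- 0
  for (k in 1:60) {
    set.seed(k)
    lam_ae <- 12; lam_ei <- 10
    pb <- data.frame(block = 1:50, n_anc_eur = rpois(50, lam_ae),
                     n_eur_ind = rpois(50, lam_ei), n_sites = 100)
    cnt <- structure(list(per_block = pb,
                          n_anc_eur = sum(pb$n_anc_eur),
                          n_eur_ind = sum(pb$n_eur_ind),
                          n_sites = 5000, strict = TRUE),
                     class = "sharing_counts")
    r <- sharing_ratio(cnt)
    if (r$ci[1] <= 1.2 && 1.2 <= r$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 54)  # >= 90% coverage
})

test_that("expectation is exactly one at the exchangeability point", {
  p <- base_params(alpha = 0, tau1 = 2e-5)  # tau1 = P2
  expect_equal(as.numeric(expected_ratio(p)), 1, tolerance = 1e-9)
  expect_equal(as.numeric(expected_ratio(p, strict = FALSE)), 1,
               tolerance = 1e-9)
})

test_that("expectation is strictly decreasing in tau1 and in alpha", {
  taus <- seq(1.05e-5, 1.95e-5, length.out = 20)
  r_tau <- vapply(taus, function(t1)
    as.numeric(expected_ratio(base_params(tau1 = t1))), 0)
  expect_true(all(diff(r_tau) < 0))
  alphas <- seq(0, 0.9, length.out = 10)
  r_a <- vapply(alphas, function(a)
    as.numeric(expected_ratio(base_params(alpha = a))), 0)
  expect_true(all(diff(r_a) < 0))
})

test_that("expectation matches the Monte-Carlo oracle, both modes", {
  p <- base_params()
  for (strict in c(TRUE, FALSE)) {
    er <- as.numeric(expected_ratio(p, strict = strict))
    mc <- mc_expected_ratio(p, n_rep = 1.5e5, strict = strict, seed = 77)
    expect_lt(abs(er - mc$ratio), 3 * mc$se)
  }
})

test_that("expectation is invariant under joint rescaling of parameters", {
  p1 <- base_params()
  p2 <- coal_params(1e-2, 1e-2, 1e-3, 2e-3, 3e-3, alpha = 0.2,
                    tau1 = 1.5e-3)
  expect_equal(as.numeric(expected_ratio(p1)),
               as.numeric(expected_ratio(p2)), tolerance = 1e-9)
})

test_that("solver inverts the expectation and flags unreachable targets", {
  p <- base_params(tau1 = 1.35e-5)
  r_true <- as.numeric(expected_ratio(p))
  sol <- solve_tau1(r_true, p)
  expect_lt(abs(sol$tau1 - 1.35e-5), 1e-8)
  # R = 1 with alpha = 0 solves to tau1 = P2 exactly
  p0 <- base_params(alpha = 0)
  sol1 <- solve_tau1(1, p0)
  expect_lt(abs(sol1$tau1 - p0$P2), 1e-8)
  expect_error(solve_tau1(10, p), "attainable")
  expect_error(solve_tau1(0.1, p), "attainable")
})

test_that("posterior-draw CI brackets the point solve", {
  p <- base_params(tau1 = 1.4e-5)
  r_true <- as.numeric(expected_ratio(p))
  R <- structure(list(R = r_true, ci = c(r_true - 0.03, r_true + 0.03),
                      se = 0.015, n_blocks = 50, conf = 0.95),
                 class = "ratio_estimate")
  draws <- sample_coal_posterior(p, 20, sd_rel = 0.03, seed = 8)
  sol <- solve_tau1(R, p, posterior_draws = draws)
  expect_true(sol$ci[1] <= sol$tau1 && sol$tau1 <= sol$ci[2])
  expect_equal(sol$n_draws, 20L)
})

test_that("corrupting the ancient sample off-panel leaves R unchanged", {
  demo <- study_demography()
  panel <- simulate_genotypes(demo, 5e4, seed = 31)
  keep <- modern_variable_sites(panel, c("EUR", "IND", "ASIA"))
  # damage-driven errors hit sites NOT variable among moderns
  corrupt <- panel
  j <- which(panel$samples$sample == "anc1")
  bad <- which(!keep)
  corrupt$geno[bad, j] <- (corrupt$geno[bad, j] + 1L) %% 3L
  h1 <- haploidize(panel, c(ANC = "anc1", EUR = "eur1", IND = "ind1",
                            ASIA = "asia1"), seed = 7)
  h2 <- haploidize(corrupt, c(ANC = "anc1", EUR = "eur1", IND = "ind1",
                              ASIA = "asia1"), seed = 7)
  r1 <- sharing_ratio(count_sharing_patterns(h1, sites_keep = keep))
  r2 <- sharing_ratio(count_sharing_patterns(h2, sites_keep = keep))
  expect_identical(r1$R, r2$R)
})

test_that("calibration arithmetic identities hold exactly", {
  expect_equal(calibrate_time(0, 4e-9, 3), 0)
  expect_equal(calibrate_time(2 * 0.5247e-4, 4e-9, 3),
               2 * calibrate_time(0.5247e-4, 4e-9, 3))
  # doubling the sample age halves the mutation-rate bound
  expect_equal(mu_upper(1e-5, 14000, 3), mu_upper(1e-5, 7000, 3) / 2)
  # full-chain identity: calibrating with the age-derived bound returns
  # the age exactly
  tau <- 1.30667e-5
  expect_equal(calibrate_time(tau, mu_upper(tau, 7000, 3), 3), 7000)
})
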