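test_that("undamaged error-free reads tabulate to zero proportions", {
  truth <- data.frame(chrom = "chr1", pos = 1:500, ref = "C",
                      genotype = "CC")
  dm0 <- damage_model(weibull_decay(0, 1, 1, degenerate = TRUE))
  st <- simulate_reads(truth, 9, dm0, qual_profile = 93, seed = 1)
  tabs <- tabulate_mismatches(st)
  expect_true(all(tabs$five_prime$mismatches == 0))
  expect_true(all(tabs$three_prime$mismatches == 0))
  # zero-opportunity rows report NA, not 0
  empty <- tabs$five_prime$opportunities == 0
  if (any(empty))
    expect_true(all(is.na(tabs$five_prime$proportion[empty])))
})

test_that("tabulated proportions track the injected Weibull decay", {
  truth <- data.frame(chrom = "chr1", pos = seq_len(2e4), ref = "C",
                      genotype = "CC")
  dm <- damage_model(weibull_decay(0.3, 0.3, 1), weibull_decay(0, 1, 1))
  st <- simulate_reads(truth, 9, dm, qual_profile = 40, seed = 2)
  tab <- tabulate_mismatches(st)$five_prime
  eps <- 1e-4
  for (x in c(1, 2, 4, 8)) {
    d <- 0.3 * exp(-0.3 * x)
    expected <- d * (1 - eps) + (1 - d) * eps / 3
    se <- sqrt(expected * (1 - expected) / tab$opportunities[x])
    expect_lt(abs(tab$proportion[x] - expected), 3 * se)
  }
})

test_that("reverse-strand reads show the complement-relabelled pattern", {
  # same chemistry read on opposite strands must tabulate identically
  truth_c <- data.frame(chrom = "chr1", pos = seq_len(8000), ref = "C",
                        genotype = "CC")
  truth_g <- data.frame(chrom = "chr1", pos = seq_len(8000), ref = "G",
                        genotype = "GG")
  dm <- damage_model(weibull_decay(0.3, 0.3, 1), weibull_decay(0, 1, 1))
  st_c <- simulate_reads(truth_c, 9, dm, qual_profile = 93, seed = 3)
  st_g <- simulate_reads(truth_g, 9, dm, qual_profile = 93, seed = 3)
  fwd_c <- st_c$reads$strand == "+"
  rev_g <- st_g$reads$strand == "-"
  # forward C>T at 5' position x and reverse G>A at 5' position x are the
  # same event; compare pooled rates at the first positions
  for (x in 1:3) {
    a <- st_c$reads[fwd_c & st_c$reads$pos5 == x, ]
    b <- st_g$reads[rev_g & st_g$reads$pos5 == x, ]
    pa <- mean(a$base == "T"); pb <- mean(b$base == "A")
    se <- sqrt(pa * (1 - pa) / nrow(a) + pb * (1 - pb) / nrow(b))
    expect_lt(abs(pa - pb), 4 * max(se, 0.01))
  }
  # and the tabulation itself aggregates both strands consistently
  tabs <- tabulate_mismatches(st_c)
  both <- tabulate_mismatches(
    list(sites = rbind(st_c$sites, st_g$sites),
         reads = rbind(st_c$reads,
                       transform(st_g$reads,
                                 site = site + nrow(st_c$sites)))))
  expect_gt(stats::cor(tabs$five_prime$proportion[1:10],
                       both$five_prime$proportion[1:10]), 0.98)
})

test_that("noiseless Weibull tables are recovered to 1e-4", {
  a <- 0.25; b <- 0.4; cc <- 1.2
  pos <- 1:25
  tab <- structure(data.frame(
    end = "5prime", pos = pos, opportunities = 1e6,
    mismatches = round(1e6 * a * exp(-(pos^cc) * b)),
    proportion = a * exp(-(pos^cc) * b)),
    class = c("damage_table", "data.frame"))
  fit <- fit_weibull(tab, error_floor = FALSE)
  expect_lt(abs(fit$a - a), 1e-4)
  expect_lt(abs(fit$b - b), 1e-4)
  expect_lt(abs(fit$c - cc), 1e-4)
})

test_that("all-zero tables return a degenerate zero-amplitude model", {
  tab <- structure(data.frame(end = "5prime", pos = 1:30,
                              opportunities = 1000, mismatches = 0,
                              proportion = 0),
                   class = c("damage_table", "data.frame"))
  fit <- fit_weibull(tab)
  expect_equal(fit$a, 0)
  expect_true(fit$degenerate)
  expect_equal(damage_probability(damage_model(fit), "5prime", 1:10),
               rep(0, 10))
})

test_that("binomial-noise tables recover the amplitude within 0.03", {
  a <- 0.3; b <- 0.3
  pos <- 1:25
  truthp <- a * exp(-pos * b)
  err <- replicate(40, {
    m <- rbinom(length(pos), 1e4, truthp)
    tab <- structure(data.frame(end = "5prime", pos = pos,
                                opportunities = 1e4, mismatches = m,
                                proportion = m / 1e4),
                     class = c("damage_table", "data.frame"))
    fit_weibull(tab, error_floor = FALSE)$a - a
  })
  expect_lt(mean(abs(err)), 0.03)
})

test_that("free-shape Weibull never fits worse than exponential decay", {
  set.seed(17)
  pos <- 1:25
  truthp <- 0.3 * exp(-(pos^1.3) * 0.25)
  m <- rbinom(length(pos), 1e4, truthp)
  tab <- structure(data.frame(end = "5prime", pos = pos,
                              opportunities = 1e4, mismatches = m,
                              proportion = m / 1e4),
                   class = c("damage_table", "data.frame"))
  rss_w <- attr(fit_weibull(tab, error_floor = FALSE), "rss")
  rss_e <- attr(fit_weibull(tab, error_floor = FALSE, fix_c = TRUE),
                "rss")
  expect_lte(rss_w, rss_e + 1e-12)
})

test_that("damage probability evaluates the decay and rejects bad input", {
  w <- weibull_decay(0.3, 0.3, 1)
  expect_equal(damage_probability(damage_model(w), "5prime", 1),
               0.3 * exp(-0.3))
  expect_error(damage_probability(damage_model(w), "5prime", 0), ">= 1")
  d <- damage_probability(damage_model(w), "5prime", 1:30)
  expect_true(all(diff(d) <= 0))
})

test_that("round-trip: simulate -> tabulate -> fit recovers the model", {
  truth <- data.frame(chrom = "chr1", pos = seq_len(3e4), ref = "C",
                      genotype = "CC")
  dm <- damage_model(weibull_decay(0.3, 0.3, 1), weibull_decay(0, 1, 1))
  st <- simulate_reads(truth, 9, dm, qual_profile = 93, seed = 5)
  fit <- fit_weibull(tabulate_mismatches(st)$five_prime,
                     error_floor = FALSE)
  expect_lt(abs(fit$a - 0.3), 0.03)
  d_true <- damage_probability(dm, "5prime", 1:10)
  d_fit <- damage_probability(damage_model(fit), "5prime", 1:10)
  expect_lt(max(abs(d_true - d_fit)), 0.02)
})

test_that("damage tables and models round-trip through disk", {
  tab <- structure(data.frame(end = "5prime", pos = 1:10,
                              opportunities = 100,
                              mismatches = c(30, 22, 16, 12, 9, 7, 5, 4,
                                             3, 2),
                              proportion = NA_real_),
                   class = c("damage_table", "data.frame"))
  tab$proportion <- tab$mismatches / tab$opportunities
  f <- tempfile(fileext = ".tsv")
  write_damage_table(tab, f)
  expect_equal(read_damage_table(f)$mismatches, tab$mismatches)
  dm <- damage_model(weibull_decay(0.3, 0.31, 1.1),
                     weibull_decay(0.2, 0.4, 0.9))
  j <- tempfile(fileext = ".json")
  write_damage_model(dm, j)
  dm2 <- read_damage_model(j)
  expect_equal(dm2$five_prime$a, 0.3)
  expect_equal(dm2$three_prime$c, 0.9)
  # MapDamage-style misincorporation text is accepted
  md <- tempfile()
  writeLines(c("Pos\tC\tC>T", paste(1:10, 100, tab$mismatches,
                                    sep = "\t")), md)
  expect_equal(read_damage_table(md, end = "5prime")$proportion,
               tab$proportion)
})
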