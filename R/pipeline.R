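#' Default synthetic-study demography
#'
#' A four-population dog world (ancient sample ANC, European EUR, Indian
#' IND, Asian ASIA) plus an outgroup OUT, in mutation-scaled units. The
#' divergence-time ratios mirror the modern-dog point estimates the dating
#' model conditions on (tau1 : P2 : P3 = 0.75 : 1 : 1.5 with an Asian
#' admixture fraction of 0.2 into the ancient lineage), rescaled so that
#' panels of 1e5-2e5 unlinked sites carry informative pattern counts. The
#' Asian-derived fraction of the ancient lineage travels through an inert
#' ghost population that only rejoins at the (Europe,India)/Asia split, so
#' the simulator matches the dating expectation's admixture convention.
#'
#' @param tau1 ancient-European divergence
#' @param P2 Europe/India divergence
#' @param P3 (Europe,India)/Asia divergence
#' @param alpha Asian admixture proportion of the ancient lineage
#' @param theta shared population size (leaf and ancestral)
#' @param anc_age ancient sample age (mutation-scaled, < tau1)
#' @param n_modern diploid samples per modern population
#' @param ascertainment ascertainment panel label(s) or "none"
#' @return a [demography_config()]
#' @export
study_demography <- function(tau1 = 0.0015, P2 = 0.002, P3 = 0.003,
                             alpha = 0.2, theta = 0.01, anc_age = 0.001,
                             n_modern = 2, ascertainment = "none") {
  delta <- P3 * 1e-6
  pops <- data.frame(
    name = c("ANC", "EUR", "IND", "ASIA", "OUT", "GHOST", "ANCEUR",
             "WEST", "ASIAG", "DOG", "ROOT"),
    theta = theta)
  splits <- data.frame(
    parent = c("ANCEUR", "WEST", "ASIAG", "DOG", "ROOT"),
    child1 = c("ANC", "ANCEUR", "ASIA", "WEST", "DOG"),
    child2 = c("EUR", "IND", "GHOST", "ASIAG", "OUT"),
    time = c(tau1, P2, P3 - delta, P3, 4 * P3))
  admix <- if (alpha > 0)
    data.frame(source = "GHOST", dest = "ANC",
               time = anc_age * 1.01, proportion = alpha) else NULL
  mod <- expand.grid(pop = c("EUR", "IND", "ASIA"),
                     k = seq_len(n_modern), stringsAsFactors = FALSE)
  samples <- rbind(
    data.frame(sample = "anc1", population = "ANC", age = anc_age,
               ploidy = 2L),
    data.frame(sample = paste0(tolower(mod$pop), mod$k),
               population = mod$pop, age = 0, ploidy = 2L),
    data.frame(sample = "out1", population = "OUT", age = 0, ploidy = 2L))
  demography_config(pops, splits, samples, admixture = admix,
                    ascertainment = ascertainment)
}

#' Run the synthetic end-to-end study
#'
#' Simulates a four-population world with an admixed ancient lineage, then
#' exercises the whole chain: damage simulation and Weibull refit,
#' damage-aware calling with concordance against truth, outgroup-f3 and
#' f4-ratio admixture estimation, sharing-ratio divergence dating with
#' jackknife CI and calibration, read-depth copy-number calling, and
#' dog/wolf locus classification of a synthetic F1. Every stage receives a
#' seed derived from `seed`; the returned report is fully deterministic.
#'
#' @param seed integer master seed
#' @param n_sites sites for the genotype panel stages
#' @param n_call_sites sites for the calling stage
#' @param n_damage_sites sites for the damage-fitting stage (damage
#'   tabulation uses invariant reference-matching sites, as a genome-scale
#'   misincorporation scan would)
#' @param mu assumed per-generation mutation rate for calibration
#' @param g generation time in years
#' @param verbose print stage banners
#' @return a `study_report` list (JSON-serializable) with one element per
#'   stage, each carrying estimates, uncertainty and the simulated truth
#' @export
run_synthetic_study <- function(seed = 1, n_sites = 1e5,
                                n_call_sites = 2000,
                                n_damage_sites = 2e4, mu = 4e-9, g = 3,
                                verbose = TRUE) {
  say <- function(...) if (verbose) message("[study] ", ...)
  report <- list(version = 1L, seed = seed,
                 params = list(n_sites = n_sites,
                               n_call_sites = n_call_sites,
                               n_damage_sites = n_damage_sites,
                               mu = mu, g = g))

  # --- damage model -------------------------------------------------
  say("damage: simulate reads, tabulate, refit Weibull")
  dm_true <- damage_model(weibull_decay(0.3, 0.3, 1),
                          weibull_decay(0.25, 0.35, 1))
  set.seed(seed)
  dtruth <- data.frame(chrom = "chr1", pos = seq_len(n_damage_sites),
                       ref = sample(c("C", "G"), n_damage_sites,
                                    replace = TRUE))
  dtruth$genotype <- paste0(dtruth$ref, dtruth$ref)
  dstack <- simulate_reads(dtruth, coverage_mean = 9, damage = dm_true,
                           seed = seed + 6)
  dm_fit <- fit_damage_model(dstack)

  # --- calling ------------------------------------------------------
  truth <- data.frame(chrom = "chr1", pos = seq_len(n_call_sites),
                      ref = "C",
                      genotype = sample(c("CC", "CT", "TT", "GG"),
                                        n_call_sites, replace = TRUE,
                                        prob = c(0.85, 0.03, 0.06, 0.06)))
  stack <- simulate_reads(truth, coverage_mean = 9, damage = dm_true,
                          seed = seed + 1)
  report$damage <- list(
    true = list(a5 = 0.3, b5 = 0.3, c5 = 1, a3 = 0.25, b3 = 0.35, c3 = 1),
    fitted = list(a5 = dm_fit$five_prime$a, b5 = dm_fit$five_prime$b,
                  c5 = dm_fit$five_prime$c, a3 = dm_fit$three_prime$a,
                  b3 = dm_fit$three_prime$b, c3 = dm_fit$three_prime$c))

  say("calling: damage-aware vs damage-naive")
  calls <- call_region(stack, dm_fit)
  naive <- call_region(stack, damage_model(
    weibull_decay(0, 1, 1, degenerate = TRUE)))
  called <- !is.na(calls$genotype)
  conc <- mean(calls$genotype[called] ==
                 truth$genotype[called])
  hom_truth <- truth$genotype %in% c("CC", "GG", "TT", "AA")
  is_het <- function(x) !is.na(x) & substr(x, 1, 1) != substr(x, 2, 2)
  report$calling <- list(
    concordance = conc, missing_rate = mean(!called),
    false_het_aware = mean(is_het(calls$genotype[hom_truth])),
    false_het_naive = mean(is_het(naive$genotype[hom_truth])))

  # --- genotype panel, f-statistics ---------------------------------
  say("panel: coalescent simulation (", n_sites, " sites )")
  demo <- study_demography()
  panel <- simulate_genotypes(demo, n_sites, seed = seed + 2)
  fp <- freq_panel(panel)
  f3 <- f3_stat(fp, "OUT", "ANC", "EUR", bias_correct = FALSE)
  # f4(IND,OUT; ANC,ASIA)/f4(IND,OUT; EUR,ASIA) estimates the European
  # fraction of the ancient lineage, so alpha = 1 - ratio
  fr <- f4_ratio(fp, c("IND", "OUT", "ANC", "ASIA"),
                 c("IND", "OUT", "EUR", "ASIA"))
  report$fstats <- list(
    outgroup_f3_anc_eur = f3$estimate, f3_se = f3$se,
    f4_ratio_alpha = 1 - fr$estimate, f4_ratio_se = fr$se,
    alpha_true = 0.2)

  # --- dating --------------------------------------------------------
  say("dating: haploidize, count, solve tau1")
  keep <- modern_variable_sites(panel, c("EUR", "IND", "ASIA"))
  hp <- haploidize(panel, c(ANC = "anc1", EUR = "eur1", IND = "ind1",
                            ASIA = "asia1"), seed = seed + 3)
  counts <- count_sharing_patterns(hp, sites_keep = keep)
  R <- sharing_ratio(counts)
  cp <- coal_params(theta1 = 0.01, theta2 = 0.01, P0 = 0.0005,
                    P2 = 0.002, P3 = 0.003, alpha = 0.2)
  tau <- solve_tau1(R, cp, clamp = TRUE)
  mu_b <- mu_upper(tau$tau1, sample_age_years = 7000, g = g)
  report$dating <- list(
    R = R$R, R_ci = R$ci, tau1 = tau$tau1, tau1_ci = tau$ci,
    tau1_true = 0.0015,
    tau1_in_ci = !anyNA(tau$ci) && tau$ci[1] <= 0.0015 &&
      0.0015 <= tau$ci[2],
    mu_upper_7k = mu_b,
    # calibration identity: calibrating tau1 with its own age-derived
    # upper bound must return the sample age exactly
    calibration_identity_years = calibrate_time(tau$tau1, mu_b, g),
    calibration_identity_ok =
      isTRUE(all.equal(calibrate_time(tau$tau1, mu_b, g), 7000)))

  # --- copy number ---------------------------------------------------
  say("cnv: depth simulation and copy-number calls")
  gc <- rep(rep(seq(0.3, 0.6, length.out = 40), each = 3000), 2)
  segs <- data.frame(start = 120000, end = 150000, cn = 3L)
  tr <- simulate_depth(segs, gc, bias = function(g) 1 + 1.5 * (g - 0.45)^2,
                       base_depth = 9, seed = seed + 4)
  win <- bin_depth(tr)
  ctrl <- data.frame(chrom = "chr1", start = 0, end = 120000)
  corr <- gc_correct(win, ctrl, min_control = 30)
  cnt <- window_copy_number(corr)
  loc <- locus_copy_number(cnt, data.frame(chrom = "chr1",
                                           start = 125000, end = 145000))
  report$cnv <- list(cn_estimate = loc$estimate, cn_call = loc$call,
                     cn_true = 3L)

  # --- locus classification ------------------------------------------
  say("loci: F1 dog x wolf classification")
  lc <- .simulate_f1_classification(seed = seed + 5)
  report$loci <- lc

  class(report) <- "study_report"
  report
}

# two-clade world with an F1 query; returns classification rates
.simulate_f1_classification <- function(seed, n_windows = 30,
                                        sites_per_window = 60) {
  set.seed(seed)
  n_sites <- n_windows * sites_per_window
  p_dog <- rbeta(n_sites, 0.4, 0.4)
  p_wolf <- rbeta(n_sites, 0.4, 0.4)
  gmat <- cbind(
    dog1 = rbinom(n_sites, 2, p_dog), dog2 = rbinom(n_sites, 2, p_dog),
    dog3 = rbinom(n_sites, 2, p_dog),
    wolf1 = rbinom(n_sites, 2, p_wolf), wolf2 = rbinom(n_sites, 2, p_wolf),
    wolf3 = rbinom(n_sites, 2, p_wolf),
    f1 = rbinom(n_sites, 1, p_dog) + rbinom(n_sites, 1, p_wolf))
  panel <- genotype_panel(gmat, block_id =
                            rep(seq_len(n_windows), each = sites_per_window))
  calls <- classify_locus(panel, dog = c("dog1", "dog2", "dog3"),
                          wolf = c("wolf1", "wolf2", "wolf3"),
                          query = "f1")
  cls <- calls$class[!is.na(calls$class)]
  list(n_windows = length(cls),
       het_like_rate = mean(cls == "heterozygous-like"))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic end-to-end study (seed", x$seed, ")\n")
  cat(sprintf("  calling: concordance %.3f, false-het aware %.4f vs naive %.4f\n",
              x$calling$concordance, x$calling$false_het_aware,
              x$calling$false_het_naive))
  cat(sprintf("  f4-ratio alpha %.3f (true %.2f)\n",
              x$fstats$f4_ratio_alpha, x$fstats$alpha_true))
  cat(sprintf("  dating: R %.3f, tau1 %.5g (true %.5g, in CI: %s)\n",
              x$dating$R, x$dating$tau1, x$dating$tau1_true,
              x$dating$tau1_in_ci))
  cat(sprintf("  cnv: locus CN %.2f -> call %d (true %d)\n",
              x$cnv$cn_estimate, x$cnv$cn_call, x$cnv$cn_true))
  cat(sprintf("  loci: F1 heterozygous-like in %.0f%% of windows\n",
              100 * x$loci$het_like_rate))
  invisible(x)
}

#' Write a study report as JSON
#'
#' @param report a `study_report`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
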