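#' Mutation-scaled coalescent parameters for sharing-ratio dating
#'
#' The dating model follows a rooted ((ancient, European) Boxer-ancestral,
#' Indian) Asian topology with an optional Asian admixture pulse into the
#' ancient lineage. All times are in expected mutations per site and sizes
#' are theta = 4*N*mu.
#'
#' @param theta1 size of the European/Boxer ancestral population (the
#'   coalescent environment of the ancient + European pair on
#'   `[tau1, P2)`)
#' @param theta2 size of the European/Indian ancestral population
#'   (`[P2, P3)`)
#' @param P0 Europe/Boxer divergence (lower bound for `tau1`)
#' @param P2 Europe/India divergence
#' @param P3 (Europe, India)/Asia divergence
#' @param alpha Asian admixture proportion of the ancient lineage; the
#'   Asian-derived fraction joins the rest only at/above `P3`
#' @param tau1 ancient-European divergence; may be `NA` when the object
#'   parameterizes a solve
#' @param theta_anc size of the population ancestral to everything above
#'   `P3` (defaults to `theta2`)
#' @return a `coal_params`
#' @export
coal_params <- function(theta1, theta2, P0, P2, P3, alpha, tau1 = NA,
                        theta_anc = theta2) {
  stopifnot(theta1 > 0, theta2 > 0, theta_anc > 0, P0 > 0,
            alpha >= 0, alpha <= 1)
  if (!(P0 <= P2 && P2 <= P3))
    stop("parameter ordering violated: need P0 <= P2 <= P3",
         call. = FALSE)
  if (!is.na(tau1) && !(P0 <= tau1 && tau1 <= P2))
    stop("parameter ordering violated: need P0 <= tau1 <= P2",
         call. = FALSE)
  structure(list(theta1 = theta1, theta2 = theta2, theta_anc = theta_anc,
                 P0 = P0, P2 = P2, P3 = P3, alpha = alpha, tau1 = tau1),
            class = "coal_params")
}

#' @export
print.coal_params <- function(x, ...) {
  cat("Coalescent parameters (mutation-scaled):\n")
  cat(sprintf("  theta1=%.4g theta2=%.4g theta_anc=%.4g\n",
              x$theta1, x$theta2, x$theta_anc))
  cat(sprintf("  P0=%.4g tau1=%.4g P2=%.4g P3=%.4g alpha=%.3f\n",
              x$P0, x$tau1, x$P2, x$P3, x$alpha))
  invisible(x)
}

#' Pseudo-haploidize a genotype panel
#'
#' Retains one sample per requested population and draws a single allele
#' per site (uniformly from the diploid dosage), so downstream counting
#' never relies on heterozygote accuracy. Sites missing in a retained
#' sample are set NA.
#'
#' @param panel a `genotype_panel`
#' @param populations named character vector `population = sample`, or a
#'   character vector of population labels (first sample of each is used)
#' @param seed integer seed for the allele draws
#' @return a `haploid_panel`: list with `hap` (sites x populations 0/1
#'   matrix), `block`, `polarized`
#' @export
haploidize <- function(panel, populations, seed = 1) {
  stopifnot(length(populations) >= 1)
  if (is.null(names(populations))) {
    smp <- vapply(populations, function(p) {
      i <- which(panel$samples$population == p)
      if (!length(i)) stop("no sample in population ", p, call. = FALSE)
      panel$samples$sample[i[1]]
    }, "")
    populations <- setNames(smp, populations)
  }
  set.seed(seed)
  hap <- sapply(names(populations), function(p) {
    s <- populations[[p]]
    j <- which(panel$samples$sample == s)
    g <- panel$geno[, j]
    pl <- panel$samples$ploidy[j]
    ifelse(is.na(g), NA_real_,
           as.numeric(runif(length(g)) * pl < g))
  })
  colnames(hap) <- names(populations)
  structure(list(hap = hap, block = panel$sites$block_id,
                 polarized = panel$polarized),
            class = "haploid_panel")
}

#' Count exclusive derived-allele-sharing patterns
#'
#' Tallies, per jackknife block, sites where the derived allele is carried
#' exclusively by the ancient + European chromosomes (`n_anc_eur`) versus
#' exclusively by the European + Indian chromosomes (`n_eur_ind`). Under
#' `strict = TRUE` (default) the Asian chromosome must be ancestral as
#' well; otherwise it is unconstrained. `sites_keep` restricts counting to
#' an ascertained subset (typically sites variable among the modern
#' populations, see [modern_variable_sites()]).
#'
#' @param hp a `haploid_panel` with (at least) the four populations
#' @param anc,eur,ind,asia column labels in `hp$hap`
#' @param strict condition on the Asian chromosome being ancestral
#' @param sites_keep optional logical vector of sites to count
#' @return a `sharing_counts`: list with per-block data.frame and totals
#' @export
count_sharing_patterns <- function(hp, anc = "ANC", eur = "EUR",
                                   ind = "IND", asia = "ASIA",
                                   strict = TRUE, sites_keep = NULL) {
  if (!isTRUE(hp$polarized))
    stop("panel must be outgroup-polarized", call. = FALSE)
  h <- hp$hap
  keep <- rowSums(is.na(h[, c(anc, eur, ind, asia), drop = FALSE])) == 0
  if (!is.null(sites_keep)) keep <- keep & sites_keep
  a <- h[keep, anc]; e <- h[keep, eur]
  i <- h[keep, ind]; s <- h[keep, asia]
  blk <- hp$block[keep]
  if (strict) {
    ae <- a == 1 & e == 1 & i == 0 & s == 0
    ei <- e == 1 & i == 1 & a == 0 & s == 0
  } else {
    ae <- a == 1 & e == 1 & i == 0
    ei <- e == 1 & i == 1 & a == 0
  }
  per_block <- data.frame(
    block = sort(unique(blk)),
    n_anc_eur = as.vector(rowsum(as.numeric(ae), blk)),
    n_eur_ind = as.vector(rowsum(as.numeric(ei), blk)),
    n_sites = as.vector(rowsum(rep(1, length(blk)), blk)))
  structure(list(per_block = per_block,
                 n_anc_eur = sum(ae), n_eur_ind = sum(ei),
                 n_sites = sum(keep), strict = strict),
            class = "sharing_counts")
}

#' @export
print.sharing_counts <- function(x, ...) {
  cat("Exclusive derived-allele sharing (",
      if (x$strict) "strict" else "lenient", "):\n", sep = "")
  cat("  ancient+European:", x$n_anc_eur,
      "  European+Indian:", x$n_eur_ind,
      "  (", x$n_sites, "sites,", nrow(x$per_block), "blocks )\n")
  invisible(x)
}

#' Sites variable among designated modern populations
#'
#' @param panel a `genotype_panel`
#' @param populations modern population labels
#' @return logical vector, TRUE where the site is polymorphic among the
#'   chromosomes of those populations
#' @export
modern_variable_sites <- function(panel, populations) {
  j <- which(panel$samples$population %in% populations)
  g <- panel$geno[, j, drop = FALSE]
  tot <- rowSums(g, na.rm = TRUE)
  pl <- rowSums((!is.na(g)) *
                  rep(panel$samples$ploidy[j], each = nrow(g)))
  tot > 0 & tot < pl
}

#' Derived-allele-sharing ratio with jackknife confidence interval
#'
#' R = total ancient+European exclusive sharing over total
#' European+Indian exclusive sharing; the 95% CI comes from a weighted
#' delete-one-block jackknife of the ratio (weights proportional to
#' per-block site counts).
#'
#' @param counts a `sharing_counts`
#' @param conf confidence level
#' @return a `ratio_estimate`: list(R, ci, se, n_blocks)
#' @export
sharing_ratio <- function(counts, conf = 0.95) {
  if (counts$n_eur_ind == 0)
    stop("zero European+Indian sharing count: ratio undefined",
         call. = FALSE)
  pb <- counts$per_block
  jk <- .block_jackknife_agg(pb$n_anc_eur, pb$n_eur_ind, pb$n_sites)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (is.na(jk$se)) c(NA_real_, NA_real_)
        else jk$estimate + c(-1, 1) * z * jk$se
  structure(list(R = jk$estimate, ci = ci, se = jk$se,
                 n_blocks = jk$n_blocks, conf = conf),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("Sharing ratio R = %.4f (%.0f%% CI %.4f-%.4f, %d blocks)\n",
              x$R, 100 * x$conf, x$ci[1], x$ci[2], x$n_blocks))
  invisible(x)
}

# --- expectation machinery -------------------------------------------------
# The four haploid lineages a (ancient), e (European), i (Indian),
# s (Asian) are tracked as a continuous-time Markov chain on the 15 set
# partitions of {a,e,i,s}. Within each epoch rates are constant, so state
# probabilities and occupancies are matrix exponentials; the expected count
# of a pattern is the expected total time some lineage subtends exactly
# that sample set (mutations are Poisson with rate 1 per unit of
# mutation-scaled branch length, so expected length = expected count per
# site).

.BITS <- c(a = 1L, e = 2L, i = 4L, s = 8L)

# all set partitions of {a,e,i,s}, each a sorted integer vector of masks
.partitions4 <- function() {
  parts <- list(list(1L))
  for (el in c(2L, 4L, 8L)) {
    out <- list()
    for (p in parts) {
      for (k in seq_along(p)) {
        q <- p
        q[[k]] <- q[[k]] + el
        out[[length(out) + 1L]] <- q
      }
      out[[length(out) + 1L]] <- c(p, list(el))
    }
    parts <- out
  }
  lapply(parts, function(p) sort(unlist(p)))
}

.part_key <- function(p) paste(p, collapse = ".")

# generator for one epoch: `coalescible(mask)` says whether a block may
# coalesce in this epoch; eligible blocks form one population with pairwise
# rate 2/theta
.epoch_generator <- function(parts, coalescible, theta) {
  n <- length(parts)
  keys <- vapply(parts, .part_key, "")
  Q <- matrix(0, n, n, dimnames = list(keys, keys))
  rate <- 2 / theta
  for (si in seq_len(n)) {
    p <- parts[[si]]
    el <- which(vapply(p, coalescible, TRUE))
    if (length(el) < 2) next
    for (x in seq_along(el)) for (y in seq_along(el)) {
      if (x >= y) next
      q <- p[-c(el[x], el[y])]
      q <- sort(c(q, p[el[x]] + p[el[y]]))
      Q[si, .part_key(q)] <- Q[si, .part_key(q)] + rate
    }
    Q[si, si] <- -sum(Q[si, -si])
  }
  Q
}

# occupancy of target states over a finite epoch: returns the updated
# state distribution and the expected time spent in each state
.epoch_step <- function(p0, Q, dt) {
  n <- length(p0)
  M <- rbind(cbind(Q, diag(n)), matrix(0, n, 2 * n))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(M * dt)))
  list(p = as.vector(p0 %*% E[1:n, 1:n, drop = FALSE]),
       occ = as.vector(p0 %*% E[1:n, (n + 1):(2 * n), drop = FALSE]))
}

# expected occupancy per transient state until absorption
.absorbing_occupancy <- function(p0, Q) {
  trans <- which(diag(Q) < 0)
  occ <- numeric(length(p0))
  if (length(trans))
    occ[trans] <- as.vector(solve(t(-Q[trans, trans, drop = FALSE]),
                                  p0[trans]))
  occ
}

# expected exclusive branch length per target mask, one admixture scenario
.scenario_lengths <- function(params, asian, targets) {
  parts <- .partitions4()
  keys <- vapply(parts, .part_key, "")
  n <- length(parts)
  AE <- .BITS[["a"]] + .BITS[["e"]]
  AEI <- AE + .BITS[["i"]]
  coal1 <- if (asian) function(m) FALSE else
    function(m) bitwAnd(m, bitwOr(.BITS[["i"]], .BITS[["s"]])) == 0L
  coal2 <- if (asian)
    function(m) bitwAnd(m, bitwOr(.BITS[["a"]], .BITS[["s"]])) == 0L
  else
    function(m) bitwAnd(m, .BITS[["s"]]) == 0L
  coal3 <- function(m) TRUE
  Q1 <- .epoch_generator(parts, coal1, params$theta1)
  Q2 <- .epoch_generator(parts, coal2, params$theta2)
  Q3 <- .epoch_generator(parts, coal3, params$theta_anc)
  p0 <- setNames(numeric(n), keys)
  p0[.part_key(sort(unname(.BITS)))] <- 1
  occ_total <- numeric(n)
  s1 <- .epoch_step(p0, Q1, params$P2 - params$tau1)
  occ_total <- occ_total + s1$occ
  s2 <- .epoch_step(s1$p, Q2, params$P3 - params$P2)
  occ_total <- occ_total + s2$occ
  occ_total <- occ_total + .absorbing_occupancy(s2$p, Q3)
  # occupancy of a target mask: time in states containing a block == mask
  vapply(targets, function(m) {
    has <- vapply(parts, function(p) m %in% p, TRUE)
    sum(occ_total[has])
  }, 0)
}

#' Coalescent expectation of the derived-allele-sharing ratio
#'
#' E(n_anc_eur)/E(n_eur_ind), each expectation the expected branch length
#' subtending exactly that sample pair under the structured model: single
#' haploid lineages from the ancient sample, Europe, India and Asia; the
#' ancient lineage is Asian-derived with probability `alpha` (joining only
#' at/above `P3`) and European-derived otherwise; European-side ancient and
#' European lineages may coalesce on `[tau1, P2)` at rate `2/theta1`;
#' survivors plus the Indian lineage interact on `[P2, P3)` at pairwise
#' rate `2/theta2`; all remaining coalescences happen above `P3` in a
#' population of size `theta_anc`. Computed exactly by piecewise matrix
#' exponentials on the partition Markov chain of the four lineages.
#'
#' @param params a [coal_params()] with `tau1` set
#' @param strict condition patterns on the Asian lineage being ancestral
#'   (matching [count_sharing_patterns()]'s default)
#' @return the expected ratio (numeric scalar); the expected per-site
#'   pattern lengths are attached as attribute `lengths`
#' @export
expected_ratio <- function(params, strict = TRUE) {
  stopifnot(inherits(params, "coal_params"))
  if (is.na(params$tau1))
    stop("tau1 must be set (use solve_tau1 to estimate it)", call. = FALSE)
  AE <- .BITS[["a"]] + .BITS[["e"]]
  EI <- .BITS[["e"]] + .BITS[["i"]]
  S <- .BITS[["s"]]
  targets <- if (strict) c(ae = AE, ei = EI)
             else c(ae = AE, aes = AE + S, ei = EI, eis = EI + S)
  le <- .scenario_lengths(params, asian = FALSE, targets)
  la <- if (params$alpha > 0)
    .scenario_lengths(params, asian = TRUE, targets) else le * 0
  len <- (1 - params$alpha) * le + params$alpha * la
  num <- if (strict) len[["ae"]] else len[["ae"]] + len[["aes"]]
  den <- if (strict) len[["ei"]] else len[["ei"]] + len[["eis"]]
  structure(num / den, lengths = len)
}

#' Monte-Carlo oracle for the sharing-ratio expectation
#'
#' Simulates the four-lineage structured coalescent directly (independent
#' of the analytic Markov-chain code path) and returns the ratio of mean
#' exclusive branch lengths with a delta-method Monte-Carlo SE.
#'
#' @param params a [coal_params()] with `tau1` set
#' @param n_rep number of simulated genealogies
#' @param strict as in [expected_ratio()]
#' @param seed integer seed
#' @return list(ratio, se, n_rep)
#' @export
mc_expected_ratio <- function(params, n_rep = 2e5, strict = TRUE,
                              seed = 1) {
  stopifnot(inherits(params, "coal_params"), !is.na(params$tau1))
  set.seed(seed)
  m <- mc_sharing_cpp(as.integer(n_rep), params$tau1, params$P2,
                      params$P3, params$theta1, params$theta2,
                      params$theta_anc, params$alpha)
  num <- if (strict) m[, 1] else m[, 1] + m[, 2]
  den <- if (strict) m[, 3] else m[, 3] + m[, 4]
  r <- mean(num) / mean(den)
  # delta method for a ratio of means
  v <- stats::var(cbind(num, den)) / n_rep
  se <- sqrt(max(0, v[1, 1] / mean(den)^2 +
                   v[2, 2] * mean(num)^2 / mean(den)^4 -
                   2 * v[1, 2] * mean(num) / mean(den)^3))
  list(ratio = r, se = se, n_rep = n_rep)
}

#' Solve for the ancient-European divergence time from an observed ratio
#'
#' Bisects the monotone map tau1 -> expected ratio on `[P0, P2]` until the
#' expectation matches the observed ratio. When a `ratio_estimate` with a
#' CI (and optionally posterior parameter draws) is supplied, the CI on
#' tau1 is the range of solutions over (parameter draw, ratio-CI endpoint)
#' pairs; endpoint solutions falling outside the attainable ratio range are
#' clamped to `[P0, P2]`.
#'
#' @param R_target observed ratio: a `ratio_estimate` or a plain number
#' @param params a [coal_params()] (its `tau1` is ignored)
#' @param posterior_draws optional data.frame of parameter draws (columns
#'   among theta1, theta2, theta_anc, P0, P2, P3, alpha) for the CI
#' @param strict as in [expected_ratio()]
#' @param tol bisection tolerance on tau1
#' @param clamp clamp an out-of-range point target to the nearest boundary
#'   (`[P0, P2]`) instead of raising an error
#' @return a `tau1_estimate`: list(tau1, ci, R, n_draws)
#' @export
solve_tau1 <- function(R_target, params, posterior_draws = NULL,
                       strict = TRUE, tol = 1e-12, clamp = FALSE) {
  R <- if (inherits(R_target, "ratio_estimate")) R_target$R else R_target
  solve_one <- function(p, r, clamp = FALSE) {
    f <- function(t1) {
      p$tau1 <- t1
      as.numeric(expected_ratio(p, strict = strict)) - r
    }
    f_lo <- f(p$P0)   # ratio is largest at tau1 = P0
    f_hi <- f(p$P2)   # and smallest at tau1 = P2
    if (f_lo < 0) {  # r above attainable range
      if (clamp) return(p$P0)
      stop(sprintf(
        "target ratio %.4f outside attainable range [%.4f, %.4f]",
        r, f_hi + r, f_lo + r), call. = FALSE)
    }
    if (f_hi > 0) {  # r below attainable range
      if (clamp) return(p$P2)
      stop(sprintf(
        "target ratio %.4f outside attainable range [%.4f, %.4f]",
        r, f_hi + r, f_lo + r), call. = FALSE)
    }
    uniroot(f, c(p$P0, p$P2), tol = tol)$root
  }
  tau1 <- solve_one(params, R, clamp = clamp)
  ci <- c(NA_real_, NA_real_)
  n_draws <- 0L
  if (inherits(R_target, "ratio_estimate") && all(is.finite(R_target$ci))) {
    draws <- if (is.null(posterior_draws)) list(params) else
      lapply(seq_len(nrow(posterior_draws)), function(k) {
        d <- posterior_draws[k, ]
        p <- params
        for (nm in intersect(names(d), names(p))) p[[nm]] <- d[[nm]]
        p$tau1 <- NA
        tryCatch(do.call(coal_params, p[c("theta1", "theta2", "P0", "P2",
                                          "P3", "alpha", "tau1",
                                          "theta_anc")]),
                 error = function(e) NULL)
      })
    draws <- draws[!vapply(draws, is.null, TRUE)]
    n_draws <- length(draws)
    sols <- unlist(lapply(draws, function(p)
      c(solve_one(p, R_target$ci[1], clamp = TRUE),
        solve_one(p, R_target$ci[2], clamp = TRUE))))
    ci <- range(sols)
  }
  structure(list(tau1 = tau1, ci = ci, R = R, n_draws = n_draws),
            class = "tau1_estimate")
}

#' @export
print.tau1_estimate <- function(x, ...) {
  cat(sprintf("tau1 = %.6g mutations/site (CI %.6g-%.6g) from R = %.4f\n",
              x$tau1, x$ci[1], x$ci[2], x$R))
  invisible(x)
}

#' Synthetic posterior draws around a parameter point
#'
#' Independent normals (relative sd `sd_rel`) truncated to parameter
#' validity by resampling; a stand-in for resampled demographic-sampler
#' posteriors when real draws are unavailable.
#'
#' @param params a [coal_params()]
#' @param n number of draws
#' @param sd_rel relative standard deviation per parameter
#' @param seed integer seed
#' @return data.frame of draws (theta1, theta2, theta_anc, P0, P2, P3,
#'   alpha)
#' @export
sample_coal_posterior <- function(params, n, sd_rel = 0.05, seed = 1) {
  set.seed(seed)
  fields <- c("theta1", "theta2", "theta_anc", "P0", "P2", "P3", "alpha")
  out <- matrix(NA_real_, n, length(fields),
                dimnames = list(NULL, fields))
  for (k in seq_len(n)) {
    repeat {
      v <- vapply(fields, function(f)
        rnorm(1, params[[f]], abs(params[[f]]) * sd_rel), 0)
      ok <- tryCatch({
        do.call(coal_params, c(as.list(v), list(tau1 = NA)))
        TRUE
      }, error = function(e) FALSE)
      if (ok && v[["alpha"]] >= 0 && v[["alpha"]] <= 1) break
    }
    out[k, ] <- v
  }
  as.data.frame(out)
}

#' Upper bound on the per-generation mutation rate from sample age
#'
#' A dated ancient sample must be younger than the calendar time since its
#' divergence from the modern lineage, so mu <= g * tau1 / age.
#'
#' @param tau1 divergence in expected mutations per site
#' @param sample_age_years age of the ancient sample in years
#' @param g generation time in years
#' @return mutation rate bound per generation
#' @export
mu_upper <- function(tau1, sample_age_years, g = 3) {
  stopifnot(tau1 > 0, sample_age_years > 0, g > 0)
  g * tau1 / sample_age_years
}

#' Calibrate a mutation-scaled divergence time to years
#'
#' years = g * tau / mu.
#'
#' @param tau divergence in expected mutations per site
#' @param mu mutation rate per generation
#' @param g generation time in years
#' @return calendar years
#' @export
calibrate_time <- function(tau, mu, g = 3) {
  stopifnot(mu > 0, g > 0)
  g * tau / mu
}
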