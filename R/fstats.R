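#' Per-population derived-allele frequencies from a genotype panel
#'
#' Aggregates sample dosages into per-site population frequencies and
#' haploid sample sizes, the substrate for the f-statistics.
#'
#' @param panel a `genotype_panel`
#' @param populations populations to keep (default all)
#' @return a `freq_panel`: list with `freq` and `count` matrices (sites x
#'   populations; `freq` NA where a population has no called chromosomes)
#'   and `block` (block id per site)
#' @export
freq_panel <- function(panel, populations = NULL) {
  pops <- unique(panel$samples$population)
  if (!is.null(populations)) {
    stopifnot(all(populations %in% pops))
    pops <- populations
  }
  n_site <- nrow(panel$geno)
  fr <- cnt <- matrix(NA_real_, n_site, length(pops),
                      dimnames = list(NULL, pops))
  for (p in pops) {
    j <- which(panel$samples$population == p)
    g <- panel$geno[, j, drop = FALSE]
    pl <- matrix(rep(panel$samples$ploidy[j], each = n_site), n_site)
    pl[is.na(g)] <- 0
    g[is.na(g)] <- 0
    tot <- rowSums(pl)
    cnt[, p] <- tot
    fr[, p] <- ifelse(tot > 0, rowSums(g) / tot, NA_real_)
  }
  structure(list(freq = fr, count = cnt, block = panel$sites$block_id),
            class = "freq_panel")
}

# Busing-style weighted delete-one-block jackknife for a ratio estimator
# sum(num)/sum(den), from per-block aggregates; jackknife weights are the
# per-block site counts m.
.block_jackknife_agg <- function(bn, bd, m) {
  tot_n <- sum(bn)
  tot_d <- sum(bd)
  est <- tot_n / tot_d
  g <- length(bn)
  ok <- (tot_d - bd) != 0 & m > 0 & m < sum(m)
  if (g < 2 || sum(ok) < 2)
    return(list(estimate = est, se = NA_real_, n_blocks = g))
  bn <- bn[ok]; bd <- bd[ok]; m <- m[ok]
  g <- length(bn)
  loo <- (tot_n - bn) / (tot_d - bd)
  n <- sum(m)
  h <- n / m
  theta_J <- g * est - sum((1 - m / n) * loo)
  tau <- h * est - (h - 1) * loo
  var <- sum((tau - theta_J)^2 / (h - 1)) / g
  list(estimate = est, se = sqrt(var), n_blocks = g)
}

# per-site interface: aggregates to blocks, jackknife weights = site counts
.block_jackknife <- function(num, den, block) {
  bn <- as.vector(rowsum(num, block))
  bd <- as.vector(rowsum(den, block))
  m <- as.vector(rowsum(rep(1, length(num)), block))
  .block_jackknife_agg(bn, bd, m)
}

.fstat_result <- function(stat, pops, jk, n_sites) {
  structure(list(stat = stat, pops = pops, estimate = jk$estimate,
                 se = jk$se,
                 Z = if (is.na(jk$se) || jk$se == 0) NA_real_
                     else jk$estimate / jk$se,
                 n_blocks = jk$n_blocks, n_sites = n_sites),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE %.3g  Z %.3f  (%d sites, %d blocks)\n",
              x$stat, paste(x$pops, collapse = ","), x$estimate,
              x$se, x$Z, x$n_sites, x$n_blocks))
  invisible(x)
}

.complete_case <- function(fp, pops) {
  keep <- rowSums(is.na(fp$freq[, pops, drop = FALSE])) == 0
  if (!any(keep)) stop("no complete-case sites", call. = FALSE)
  keep
}

# finite-sample heterozygosity correction term p(1-p)/(n-1)
.hterm <- function(p, n) ifelse(n > 1, p * (1 - p) / (n - 1), NA_real_)

#' Patterson f-statistics and the D-statistic with block-jackknife errors
#'
#' Per-site estimators: f2 = (a-b)^2, f3(C; A, B) = (c-a)(c-b),
#' f4(A,B; C,D) = (a-b)(c-d) and D = sum (a-b)(c-d) / sum
#' (a+b-2ab)(c+d-2cd), averaged (D: ratio-of-sums) over complete-case
#' sites. With `bias_correct = TRUE` the finite-sample heterozygosity terms
#' p(1-p)/(n-1) are subtracted for f2 (both populations) and f3 (the target
#' C). Standard errors come from a weighted delete-one-block jackknife
#' (weights proportional to per-block site counts).
#'
#' @param fp a [freq_panel()]
#' @param A,B,C,D population labels
#' @param bias_correct apply the finite-sample correction (f2/f3)
#' @return an `fstat_result`: estimate, jackknife SE, Z, block count
#' @export
f2_stat <- function(fp, A, B, bias_correct = TRUE) {
  keep <- .complete_case(fp, c(A, B))
  a <- fp$freq[keep, A]; b <- fp$freq[keep, B]
  term <- (a - b)^2
  if (bias_correct)
    term <- term - .hterm(a, fp$count[keep, A]) -
      .hterm(b, fp$count[keep, B])
  jk <- .block_jackknife(term, rep(1, length(term)), fp$block[keep])
  .fstat_result("f2", c(A, B), jk, sum(keep))
}

#' @rdname f2_stat
#' @export
f3_stat <- function(fp, C, A, B, bias_correct = TRUE) {
  keep <- .complete_case(fp, c(A, B, C))
  a <- fp$freq[keep, A]; b <- fp$freq[keep, B]; c_ <- fp$freq[keep, C]
  term <- (c_ - a) * (c_ - b)
  if (bias_correct) term <- term - .hterm(c_, fp$count[keep, C])
  jk <- .block_jackknife(term, rep(1, length(term)), fp$block[keep])
  .fstat_result("f3", c(C, A, B), jk, sum(keep))
}

#' @rdname f2_stat
#' @export
f4_stat <- function(fp, A, B, C, D) {
  keep <- .complete_case(fp, c(A, B, C, D))
  term <- (fp$freq[keep, A] - fp$freq[keep, B]) *
    (fp$freq[keep, C] - fp$freq[keep, D])
  jk <- .block_jackknife(term, rep(1, length(term)), fp$block[keep])
  .fstat_result("f4", c(A, B, C, D), jk, sum(keep))
}

#' @rdname f2_stat
#' @export
d_stat <- function(fp, A, B, C, D) {
  keep <- .complete_case(fp, c(A, B, C, D))
  a <- fp$freq[keep, A]; b <- fp$freq[keep, B]
  c_ <- fp$freq[keep, C]; d <- fp$freq[keep, D]
  num <- (a - b) * (c_ - d)
  den <- (a + b - 2 * a * b) * (c_ + d - 2 * c_ * d)
  ok <- abs(den) > 0 | abs(num) > 0
  jk <- .block_jackknife(num, den, fp$block[keep])
  .fstat_result("D", c(A, B, C, D), jk, sum(keep))
}

#' f4-ratio estimate of an admixture proportion
#'
#' Ratio of two f4 statistics, jackknifed over blocks of the ratio itself
#' (delete-one-block on numerator and denominator jointly).
#'
#' @param fp a [freq_panel()]
#' @param num,den character(4): the numerator / denominator quadruples
#'   (A, B; C, D)
#' @return an `fstat_result` with the ratio estimate; carries an
#'   `unstable` attribute when the denominator f4 is within 2 SE of zero
#' @export
f4_ratio <- function(fp, num, den) {
  stopifnot(length(num) == 4, length(den) == 4)
  keep <- .complete_case(fp, unique(c(num, den)))
  f4term <- function(q)
    (fp$freq[keep, q[1]] - fp$freq[keep, q[2]]) *
    (fp$freq[keep, q[3]] - fp$freq[keep, q[4]])
  jk <- .block_jackknife(f4term(num), f4term(den), fp$block[keep])
  res <- .fstat_result("f4-ratio",
                       paste(c(num[1], den[1]), collapse = "/"), jk,
                       sum(keep))
  res$pops <- list(num = num, den = den)
  dn <- f4_stat(fp, den[1], den[2], den[3], den[4])
  attr(res, "unstable") <- is.na(dn$Z) || abs(dn$Z) < 2
  res
}

#' Build contiguous jackknife blocks from a genetic map
#'
#' Assigns each site to a window of `window_cm` centimorgans using linear
#' interpolation of a two-column (pos, cM) genetic map per chromosome.
#'
#' @param sites data.frame with `chrom` and `pos`
#' @param map data.frame with `chrom`, `pos`, `cM`
#' @param window_cm window size in centimorgans
#' @return integer block id per site
#' @export
genetic_blocks <- function(sites, map, window_cm = 5) {
  block <- integer(nrow(sites))
  offset <- 0L
  for (ch in unique(sites$chrom)) {
    i <- sites$chrom == ch
    m <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(m) < 2)
      stop("genetic map does not cover chromosome ", ch, call. = FALSE)
    cm <- approx(m$pos, m$cM, xout = sites$pos[i], rule = 2)$y
    b <- floor(cm / window_cm)
    block[i] <- offset + as.integer(factor(b))
    offset <- max(block[i])
  }
  block
}
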