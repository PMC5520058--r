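#' Simulate a polarized genotype panel under a structured coalescent
#'
#' Draws one independent single-locus genealogy per site under the
#' piecewise-constant split/admixture demography in `config`, places
#' mutations as a Poisson process on branches (rate 1 per unit of
#' mutation-scaled branch length), and returns diploid derived-allele
#' dosages. Sites are unlinked; the derived state is defined relative to
#' the root (equivalently, an outgroup polarization under infinite sites).
#' If `config$ascertainment` names panel population(s), sites are drawn by
#' rejection until variable among that panel's chromosomes.
#'
#' @param config a [demography_config()]
#' @param n_sites number of sites to simulate
#' @param seed integer seed; identical seeds give identical panels
#' @param block_size sites per jackknife block (contiguous chunks)
#' @param max_tries rejection-sampling cap per site under ascertainment
#' @return A `genotype_panel`: list with `sites` (chrom, pos, block_id),
#'   `samples` (sample, population, ploidy), `geno` (sites x samples
#'   integer dosage matrix, entries 0..ploidy or NA) and `polarized = TRUE`.
#' @export
simulate_genotypes <- function(config, n_sites, seed,
                               block_size = 500, max_tries = 1e6) {
  stopifnot(inherits(config, "demography_config"), n_sites >= 1)
  pops <- config$populations
  pop_idx <- setNames(seq_len(nrow(pops)) - 1L, pops$name)
  smp <- config$samples
  lin_sample <- rep(seq_len(nrow(smp)), smp$ploidy)
  lin_pop <- pop_idx[smp$population][lin_sample]
  lin_age <- smp$age[lin_sample]

  ev <- data.frame(time = numeric(0), type = integer(0), a = integer(0),
                   b = integer(0), p = numeric(0))
  for (i in seq_len(nrow(config$splits))) {
    s <- config$splits[i, ]
    ev <- rbind(ev,
                data.frame(time = s$time, type = 0L,
                           a = pop_idx[[s$child1]], b = pop_idx[[s$parent]],
                           p = 0),
                data.frame(time = s$time, type = 0L,
                           a = pop_idx[[s$child2]], b = pop_idx[[s$parent]],
                           p = 0))
  }
  if (!is.null(config$admixture)) {
    for (i in seq_len(nrow(config$admixture))) {
      a <- config$admixture[i, ]
      ev <- rbind(ev, data.frame(time = a$time, type = 1L,
                                 a = pop_idx[[a$dest]],
                                 b = pop_idx[[a$source]],
                                 p = a$proportion))
    }
  }
  # admixture pulses apply before merges at the same instant
  ev <- ev[order(ev$time, -ev$type), , drop = FALSE]

  asc_idx <- integer(0)
  if (!identical(config$ascertainment, "none")) {
    keep <- smp$population[lin_sample] %in% config$ascertainment
    asc_idx <- which(keep) - 1L
  }

  set.seed(seed)
  hap <- sim_sites_cpp(as.integer(n_sites), pops$theta,
                       as.integer(lin_pop), as.numeric(lin_age),
                       ev$time, ev$type, ev$a, ev$b, ev$p,
                       as.integer(asc_idx), as.integer(max_tries))
  geno <- t(rowsum(t(hap), group = lin_sample))
  colnames(geno) <- smp$sample
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites),
                      block_id = ((seq_len(n_sites) - 1L) %/% block_size) + 1L)
  structure(list(sites = sites,
                 samples = smp[, c("sample", "population", "ploidy")],
                 geno = geno, polarized = TRUE),
            class = "genotype_panel")
}

#' Construct a genotype panel from components
#'
#' @param geno integer matrix, sites x samples, derived-allele dosages
#' @param populations population label per sample (defaults to sample name)
#' @param chrom,pos site coordinates (1-based)
#' @param block_id jackknife block per site
#' @param ploidy per-sample ploidy (default 2)
#' @param polarized whether derived state is outgroup-polarized
#' @return a `genotype_panel`
#' @export
genotype_panel <- function(geno, populations = colnames(geno),
                           chrom = "chr1", pos = seq_len(nrow(geno)),
                           block_id = 1L, ploidy = 2L, polarized = TRUE) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("s", seq_len(ncol(geno)))
  ploidy <- rep_len(ploidy, ncol(geno))
  bad <- !is.na(geno) & (geno < 0 | geno > rep(ploidy, each = nrow(geno)))
  if (any(bad)) stop("dosages must lie in 0..ploidy or NA", call. = FALSE)
  structure(list(
    sites = data.frame(chrom = rep_len(chrom, nrow(geno)), pos = pos,
                       block_id = rep_len(block_id, nrow(geno))),
    samples = data.frame(sample = colnames(geno),
                         population = populations, ploidy = ploidy),
    geno = geno, polarized = polarized), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$geno), "sites x", ncol(x$geno), "samples (",
      length(unique(x$samples$population)), "populations,",
      length(unique(x$sites$block_id)), "blocks )\n")
  cat("  polarized:", x$polarized,
      " missing:", sum(is.na(x$geno)), "\n")
  invisible(x)
}

#' Write / read a genotype panel as TSV (site rows, sample columns)
#'
#' Columns: chrom, pos, block_id, then one dosage column per sample;
#' missing dosages written as `NA`. Population assignments are stored in a
#' `#pop:` comment line.
#' @param panel a `genotype_panel`
#' @param path file path
#' @return `read_panel_tsv` returns a `genotype_panel`.
#' @export
write_panel_tsv <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#pop: ", paste(panel$samples$sample,
                                    panel$samples$population,
                                    sep = "=", collapse = ",")), con)
  df <- cbind(panel$sites, as.data.frame(panel$geno))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  popmap <- NULL
  if (startsWith(hdr, "#pop: ")) {
    kv <- strsplit(strsplit(sub("^#pop: ", "", hdr), ",")[[1]], "=")
    popmap <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  geno <- as.matrix(df[, -(1:3), drop = FALSE])
  pops <- if (is.null(popmap)) colnames(geno) else
    unname(popmap[colnames(geno)])
  genotype_panel(geno, populations = pops, chrom = df$chrom, pos = df$pos,
                 block_id = df$block_id)
}

#' Write a genotype panel as an EIGENSTRAT-like triple
#'
#' Produces `<prefix>.geno` (one row per site, one digit per sample, 9 for
#' missing), `<prefix>.snp` (site id, chrom, genetic position 0, physical
#' position) and `<prefix>.ind` (sample, sex U, population).
#' @param panel a `genotype_panel`
#' @param prefix output path prefix
#' @return `read_panel_eigenstrat` returns a `genotype_panel` (block ids
#'   rebuilt as contiguous chunks of `block_size` sites).
#' @export
write_panel_eigenstrat <- function(panel, prefix) {
  g <- panel$geno
  g[is.na(g)] <- 9L
  writeLines(apply(g, 1, paste, collapse = ""), paste0(prefix, ".geno"))
  snp <- data.frame(id = paste0(panel$sites$chrom, "_", panel$sites$pos),
                    chrom = panel$sites$chrom, gpos = 0,
                    pos = panel$sites$pos)
  write.table(snp, paste0(prefix, ".snp"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ind <- data.frame(sample = panel$samples$sample, sex = "U",
                    population = panel$samples$population)
  write.table(ind, paste0(prefix, ".ind"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_panel_eigenstrat
#' @param block_size sites per rebuilt jackknife block
#' @export
read_panel_eigenstrat <- function(prefix, block_size = 500) {
  rows <- readLines(paste0(prefix, ".geno"))
  geno <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  geno[geno == 9L] <- NA_integer_
  snp <- read.table(paste0(prefix, ".snp"), sep = "\t")
  ind <- read.table(paste0(prefix, ".ind"), sep = "\t")
  colnames(geno) <- ind[[1]]
  genotype_panel(geno, populations = ind[[3]], chrom = snp[[2]],
                 pos = snp[[4]],
                 block_id = ((seq_len(nrow(geno)) - 1L) %/% block_size) + 1L)
}

#' Weibull decay model of terminal deamination damage
#'
#' Damage probability at 1-based position `x` from the relevant read end is
#' `a * exp(-(x^c) * b)`: `a` is the amplitude at position 0 (in [0, 1]),
#' `b > 0` the decay rate and `c > 0` the shape (c = 1 is exponential
#' decay).
#'
#' @param a,b,c decay parameters
#' @param end which terminus the decay models: `"5prime"` (C>T) or
#'   `"3prime"` (G>A)
#' @param degenerate flag set by [fit_weibull()] when the table carried no
#'   damage signal (then `a = 0`)
#' @return an object of class `weibull_decay`
#' @export
weibull_decay <- function(a, b, c, end = c("5prime", "3prime"),
                          degenerate = FALSE) {
  end <- match.arg(end)
  stopifnot(a >= 0, a <= 1, b > 0, c > 0)
  structure(list(a = a, b = b, c = c, end = end, degenerate = degenerate),
            class = "weibull_decay")
}

#' @export
print.weibull_decay <- function(x, ...) {
  cat(sprintf("Weibull decay (%s): a=%.4g b=%.4g c=%.4g%s\n", x$end,
              x$a, x$b, x$c, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Two-ended post-mortem damage model
#'
#' @param five_prime a [weibull_decay()] for 5' C>T damage
#' @param three_prime a [weibull_decay()] for 3' G>A damage
#' @return an object of class `damage_model`
#' @export
damage_model <- function(five_prime, three_prime = five_prime) {
  stopifnot(inherits(five_prime, "weibull_decay"),
            inherits(three_prime, "weibull_decay"))
  five_prime$end <- "5prime"
  three_prime$end <- "3prime"
  structure(list(five_prime = five_prime, three_prime = three_prime),
            class = "damage_model")
}

#' @export
print.damage_model <- function(x, ...) {
  cat("Post-mortem damage model\n  5' C>T: ")
  print(x$five_prime)
  cat("  3' G>A: ")
  print(x$three_prime)
  invisible(x)
}

#' Simulate an ancient-DNA read stack over known genotypes
#'
#' Per site, a Poisson(`coverage_mean`) number of reads is drawn. Each read
#' receives a uniform orientation, a length from `len_range` (uniform,
#' default 50-90 bp, mean ~70 bp as typical of ancient libraries), and a
#' uniform position of the site within the read. The template allele is
#' drawn from the true genotype, deamination damage is applied first
#' (C>T with probability d5(position from the read's 5' end), G>A with
#' d3(position from the 3' end), strand-resolved: on reverse-orientation
#' reads the same chemistry presents as G>A near the read 5' end and C>T
#' near the 3' end in reference-forward coordinates), then sequencing error
#' per the Phred quality.
#'
#' @param truth data.frame with columns `chrom`, `pos`, `ref` and
#'   `genotype` (two-character string such as "CC" or "CT")
#' @param coverage_mean mean per-site coverage (> 0)
#' @param damage a [damage_model()]
#' @param qual_profile Phred qualities to sample from (numeric vector)
#' @param seed integer seed
#' @param len_range integer read-length range (uniform)
#' @param mapq mapping quality assigned to all reads
#' @return a `read_stack`: list with `sites` (the truth table) and `reads`
#'   (data.frame: site, base, qual, mapq, strand, pos5, pos3, len)
#' @export
simulate_reads <- function(truth, coverage_mean, damage,
                           qual_profile = 30, seed = 1,
                           len_range = c(50, 90), mapq = 37) {
  stopifnot(coverage_mean > 0, inherits(damage, "damage_model"))
  set.seed(seed)
  n_site <- nrow(truth)
  n_reads <- rpois(n_site, coverage_mean)
  site <- rep(seq_len(n_site), n_reads)
  n <- length(site)
  g <- truth$genotype[site]
  pick <- ifelse(runif(n) < 0.5, 1L, 2L)
  allele <- substr(g, pick, pick)
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  pos5 <- floor(runif(n) * len) + 1L
  pos3 <- len - pos5 + 1L
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  d5 <- damage_probability(damage, "5prime", pos5)
  d3 <- damage_probability(damage, "3prime", pos3)
  base <- allele
  u <- runif(n)
  fwd <- strand == "+"
  hit <- (fwd & allele == "C" & u < d5) | (!fwd & allele == "C" & u < d3)
  base[hit] <- "T"
  hit <- (fwd & allele == "G" & u < d3) | (!fwd & allele == "G" & u < d5)
  base[hit] <- "A"
  qual <- if (length(qual_profile) == 1L) rep(qual_profile, n)
          else sample(qual_profile, n, replace = TRUE)
  eps <- 10^(-qual / 10)
  err <- runif(n) < eps
  if (any(err)) {
    nts <- c("A", "C", "G", "T")
    base[err] <- vapply(base[err], function(b)
      sample(setdiff(nts, b), 1), "")
  }
  structure(list(sites = truth,
                 reads = data.frame(site = site, base = base, qual = qual,
                                    mapq = mapq, strand = strand,
                                    pos5 = pos5, pos3 = pos3, len = len,
                                    stringsAsFactors = FALSE)),
            class = "read_stack")
}

#' @export
print.read_stack <- function(x, ...) {
  cat("Read stack:", nrow(x$sites), "sites,", nrow(x$reads), "reads (mean",
      round(nrow(x$reads) / max(1, nrow(x$sites)), 2), "x )\n")
  invisible(x)
}

#' Simulate a per-position depth track with known copy number and GC bias
#'
#' Depth at each position is Poisson with mean
#' `base_depth * (CN/2) * bias(GC)`.
#'
#' @param cn_segments data.frame with columns `start`, `end` (0-based
#'   half-open) and `cn` (integer copy number) for regions deviating from
#'   the diploid background; must not overlap
#' @param gc per-position GC fraction in `[0, 1]` (its length sets the
#'   track length)
#' @param bias function mapping GC fraction to a positive depth multiplier
#'   (default flat)
#' @param base_depth diploid mean depth
#' @param seed integer seed
#' @param chrom chromosome label
#' @return a `depth_track` data.frame: chrom, start, end (0-based
#'   half-open, unit intervals), depth, gc, true_cn
#' @export
simulate_depth <- function(cn_segments, gc, bias = function(g) 1,
                           base_depth = 9, seed = 1, chrom = "chr1") {
  stopifnot(all(gc >= 0 & gc <= 1), base_depth > 0)
  L <- length(gc)
  cn <- rep(2L, L)
  if (!is.null(cn_segments) && nrow(cn_segments) > 0) {
    seg <- cn_segments[order(cn_segments$start), , drop = FALSE]
    if (any(seg$cn < 0)) stop("copy number must be >= 0", call. = FALSE)
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)]))
      stop("overlapping copy-number segments", call. = FALSE)
    for (i in seq_len(nrow(seg))) {
      idx <- seq(seg$start[i] + 1L, min(seg$end[i], L))
      cn[idx] <- seg$cn[i]
    }
  }
  set.seed(seed)
  mu <- base_depth * (cn / 2) * vapply(gc, bias, 0)
  structure(data.frame(chrom = chrom, start = 0:(L - 1), end = 1:L,
                       depth = rpois(L, mu), gc = gc, true_cn = cn),
            class = c("depth_track", "data.frame"))
}
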