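#' @rdname site_likelihoods
#' @format NULL
#' @export
GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

.NTS <- c("A", "C", "G", "T")

# P(damaged base | template base) for one read: deamination acts before
# sequencing error. Strand conversion table (reference-forward alleles):
#   forward read:  C -> T with d5(pos5),  G -> A with d3(pos3)
#   reverse read:  G -> A with d5(pos5),  C -> T with d3(pos3)
# because the chemical C>T event on a reverse-orientation read's own 5' end
# presents as G>A in reference-forward coordinates.
.damage_matrix <- function(damage, strand, pos5, pos3) {
  if (strand == "+") {
    dct <- damage_probability(damage, "5prime", pos5)
    dga <- damage_probability(damage, "3prime", pos3)
  } else {
    dga <- damage_probability(damage, "5prime", pos5)
    dct <- damage_probability(damage, "3prime", pos3)
  }
  m <- diag(4)
  dimnames(m) <- list(.NTS, .NTS)  # [template, damaged]
  m["C", "C"] <- 1 - dct; m["C", "T"] <- dct
  m["G", "G"] <- 1 - dga; m["G", "A"] <- dga
  m
}

#' Damage-aware genotype likelihoods at one site
#'
#' Computes log-likelihoods for the 10 unordered diploid genotypes from a
#' read stack, modelling post-mortem deamination before sequencing error.
#' Reads with mapping quality < `min_mq` and bases with quality < `min_bq`
#' are excluded; base qualities are capped at `cap_bq` before conversion to
#' error probability. Per read, P(observed | true allele) =
#' sum over damaged bases of P_err(observed | damaged) * P_dam(damaged |
#' true; position, orientation), with P_err(o | b) = 1 - eps if o == b else
#' eps/3; a diploid genotype averages its two alleles and the site
#' log-likelihood sums over retained reads.
#'
#' @param site list or one-row pileup with `ref` and `reads` (data.frame:
#'   base, qual, mapq, strand, pos5, pos3)
#' @param damage a [damage_model()] (use amplitude 0 for a damage-naive
#'   caller)
#' @param min_bq,min_mq base/mapping quality floors (exclusive)
#' @param cap_bq base-quality cap applied before eps conversion
#' @return a `genotype_likelihoods`: list with `loglik` (named over the 10
#'   genotypes) and `depth` (reads retained after filters)
#' @export
site_likelihoods <- function(site, damage, min_bq = 15, min_mq = 15,
                             cap_bq = 40) {
  stopifnot(inherits(damage, "damage_model"))
  r <- site$reads
  keep <- r$mapq >= min_mq & r$qual >= min_bq & r$base %in% .NTS
  r <- r[keep, , drop = FALSE]
  n <- nrow(r)
  if (n == 0) {
    return(structure(list(loglik = setNames(rep(0, 10), GENOTYPES),
                          depth = 0L), class = "genotype_likelihoods"))
  }
  eps <- 10^(-pmin(r$qual, cap_bq) / 10)
  # per-read P(observed | true allele) for each of the four alleles
  pa <- matrix(0, n, 4, dimnames = list(NULL, .NTS))
  for (i in seq_len(n)) {
    dm <- .damage_matrix(damage, r$strand[i], r$pos5[i], r$pos3[i])
    perr <- ifelse(.NTS == r$base[i], 1 - eps[i], eps[i] / 3)
    pa[i, ] <- as.vector(dm %*% perr)
  }
  ll <- setNames(numeric(10), GENOTYPES)
  for (g in GENOTYPES) {
    a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
    ll[g] <- sum(log((pa[, a1] + pa[, a2]) / 2))
  }
  structure(list(loglik = ll, depth = n), class = "genotype_likelihoods")
}

#' @export
print.genotype_likelihoods <- function(x, ...) {
  cat("Genotype log-likelihoods (depth", x$depth, ")\n")
  print(round(sort(x$loglik, decreasing = TRUE), 3))
  invisible(x)
}

#' Genotype call from likelihoods: depth filter and het demotion
#'
#' Sites with effective depth < `min_depth` are reported missing. The
#' maximum-likelihood genotype under a flat prior is called with
#' GQ = Phred-scaled log-likelihood difference to the runner-up. When the
#' best genotype is heterozygous with GQ < `het_gq`, the best homozygote is
#' emitted instead (annotated `het-demoted`) with GQ recomputed against the
#' next-best remaining genotype. Ties break by fixed genotype order
#' (AA, AC, ..., TT).
#'
#' @param lik a `genotype_likelihoods`
#' @param min_depth minimum effective depth for a call
#' @param het_gq minimum GQ for a heterozygous call (inclusive)
#' @return a `genotype_call`: list(genotype, gq, depth, missing, filters)
#' @export
call_site <- function(lik, min_depth = 7, het_gq = 30) {
  if (lik$depth < min_depth) {
    return(structure(list(genotype = NA_character_, gq = 0,
                          depth = lik$depth, missing = TRUE,
                          filters = "low-depth"),
                     class = "genotype_call"))
  }
  ll <- lik$loglik
  ord <- order(-ll, seq_along(ll))  # ties: fixed genotype order
  phred <- function(d) d * 10 / log(10)
  best <- GENOTYPES[ord[1]]
  gq <- phred(ll[ord[1]] - ll[ord[2]])
  filters <- character(0)
  is_het <- substr(best, 1, 1) != substr(best, 2, 2)
  if (is_het && gq < het_gq) {
    hom <- GENOTYPES[substr(GENOTYPES, 1, 1) == substr(GENOTYPES, 2, 2)]
    hom_ll <- ll[hom]
    best <- hom[order(-hom_ll, seq_along(hom_ll))[1]]
    rest <- ll[setdiff(GENOTYPES, best)]
    gq <- phred(ll[best] - max(rest))
    filters <- "het-demoted"
  }
  structure(list(genotype = unname(best), gq = max(unname(gq), 0),
                 depth = lik$depth, missing = FALSE, filters = filters),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  if (x$missing) cat("call: missing (depth", x$depth, ")\n")
  else cat("call:", x$genotype, " GQ", round(x$gq, 1), " depth", x$depth,
           if (length(x$filters)) paste0(" [", x$filters, "]") else "",
           "\n")
  invisible(x)
}

#' Call genotypes across a region and emit VCF records
#'
#' Runs [site_likelihoods()] and [call_site()] over every site of a pileup
#' or simulated read stack, deterministically, one VCF record per site.
#'
#' @param stack a `read_stack` or object from [read_pileup()]
#' @param damage a [damage_model()]
#' @param min_depth,het_gq calling thresholds (see [call_site()])
#' @param sample sample name for the VCF column
#' @param ... passed to [site_likelihoods()]
#' @return a `vcf_calls` data.frame: chrom, pos, ref, alt, genotype, gq,
#'   depth, filter
#' @export
call_region <- function(stack, damage, min_depth = 7, het_gq = 30,
                        sample = "sample", ...) {
  sites <- stack$sites
  reads <- stack$reads
  n <- nrow(sites)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                    alt = rep(".", n), genotype = rep(NA_character_, n),
                    gq = rep(0, n), depth = rep(0L, n),
                    filter = rep("PASS", n), stringsAsFactors = FALSE)
  idx <- split(seq_len(nrow(reads)), factor(reads$site, levels = seq_len(n)))
  for (i in seq_len(n)) {
    site <- list(ref = sites$ref[i],
                 reads = reads[idx[[i]], , drop = FALSE])
    cl <- call_site(site_likelihoods(site, damage, ...),
                    min_depth = min_depth, het_gq = het_gq)
    out$depth[i] <- cl$depth
    if (cl$missing) {
      out$filter[i] <- "LowDepth"
      next
    }
    out$genotype[i] <- cl$genotype
    out$gq[i] <- cl$gq
    alts <- setdiff(unique(strsplit(cl$genotype, "")[[1]]), sites$ref[i])
    out$alt[i] <- if (length(alts)) paste(sort(alts), collapse = ",") else "."
    if ("het-demoted" %in% cl$filters) out$filter[i] <- "HetDemoted"
  }
  attr(out, "sample") <- sample
  class(out) <- c("vcf_calls", "data.frame")
  out
}

#' Write calls as VCF v4.2
#'
#' @param calls a `vcf_calls` data.frame from [call_region()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vcf <- function(calls, path) {
  sample <- attr(calls, "sample")
  if (is.null(sample)) sample <- "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=paleocanid",
    "##FILTER=<ID=LowDepth,Description=\"Effective depth below minimum; genotype reported missing\">",
    "##FILTER=<ID=HetDemoted,Description=\"Best heterozygote below GQ threshold; homozygote emitted\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Phred-scaled genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Effective depth after quality filters\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  body <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (is.na(calls$genotype[i])) {
      gt <- "./."
    } else {
      alleles <- c(calls$ref[i],
                   if (calls$alt[i] != ".")
                     strsplit(calls$alt[i], ",")[[1]] else character(0))
      g <- strsplit(calls$genotype[i], "")[[1]]
      gt <- paste(match(g, alleles) - 1L, collapse = "/")
    }
    body[i] <- paste(calls$chrom[i], calls$pos[i], ".", calls$ref[i],
                     calls$alt[i], ".", calls$filter[i], ".", "GT:GQ:DP",
                     paste(gt, round(calls$gq[i]), calls$depth[i],
                           sep = ":"),
                     sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a single-sample VCF written by [write_vcf()]
#'
#' @param path VCF path
#' @return a `vcf_calls` data.frame
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  sample <- utils::tail(strsplit(hdr[length(hdr)], "\t")[[1]], 1)
  if (!length(body)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      genotype = character(0), gq = numeric(0),
                      depth = integer(0), filter = character(0))
  } else {
    f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    gfield <- strsplit(f[, 10], ":", fixed = TRUE)
    gt <- vapply(gfield, `[`, "", 1)
    geno <- vapply(seq_along(gt), function(i) {
      if (gt[i] == "./.") return(NA_character_)
      alleles <- c(f[i, 4],
                   if (f[i, 5] != ".") strsplit(f[i, 5], ",")[[1]]
                   else character(0))
      idx <- as.integer(strsplit(gt[i], "/", fixed = TRUE)[[1]]) + 1L
      paste(sort(alleles[idx]), collapse = "")
    }, "")
    out <- data.frame(chrom = f[, 1], pos = as.integer(f[, 2]),
                      ref = f[, 4], alt = f[, 5], genotype = geno,
                      gq = as.numeric(vapply(gfield, `[`, "", 2)),
                      depth = as.integer(vapply(gfield, `[`, "", 3)),
                      filter = f[, 7], stringsAsFactors = FALSE)
  }
  attr(out, "sample") <- sample
  class(out) <- c("vcf_calls", "data.frame")
  out
}

#' Write / read the package pileup dialect
#'
#' Tab-separated: chrom, pos (1-based), ref, then one
#' `base:qual:mapq:orient:pos5:pos3` tuple per read. A site with no reads
#' has no tuples. Truth genotypes, when present, are carried in a
#' `#truth:` comment line so simulated stacks round-trip.
#'
#' @param stack a `read_stack`
#' @param path file path
#' @return `read_pileup` returns a `read_stack`
#' @export
write_pileup <- function(stack, path) {
  s <- stack$sites
  r <- stack$reads
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(s$genotype))
    writeLines(paste0("#truth: ", paste(s$genotype, collapse = ",")), con)
  tuples <- paste(r$base, r$qual, r$mapq, r$strand, r$pos5, r$pos3,
                  sep = ":")
  by_site <- split(tuples, factor(r$site, levels = seq_len(nrow(s))))
  lines <- vapply(seq_len(nrow(s)), function(i) {
    paste(c(s$chrom[i], s$pos[i], s$ref[i], by_site[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  truth <- NULL
  if (length(lines) && startsWith(lines[1], "#truth: ")) {
    truth <- strsplit(sub("^#truth: ", "", lines[1]), ",")[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  sites <- data.frame(chrom = character(n), pos = integer(n),
                      ref = character(n), stringsAsFactors = FALSE)
  reads <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed pileup line ", i, ": fewer than 3 columns",
           call. = FALSE)
    sites$chrom[i] <- f[1]
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("malformed pileup line ", i, ": bad position",
                         call. = FALSE)
    sites$pos[i] <- pos
    sites$ref[i] <- f[3]
    if (length(f) > 3) {
      parts <- strsplit(f[-(1:3)], ":", fixed = TRUE)
      if (any(lengths(parts) != 6))
        stop("malformed pileup line ", i, ": bad read tuple", call. = FALSE)
      m <- do.call(rbind, parts)
      reads[[i]] <- data.frame(site = i, base = m[, 1],
                               qual = as.numeric(m[, 2]),
                               mapq = as.numeric(m[, 3]), strand = m[, 4],
                               pos5 = as.integer(m[, 5]),
                               pos3 = as.integer(m[, 6]),
                               stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, reads[!vapply(reads, is.null, TRUE)])
  if (is.null(reads))
    reads <- data.frame(site = integer(0), base = character(0),
                        qual = numeric(0), mapq = numeric(0),
                        strand = character(0), pos5 = integer(0),
                        pos3 = integer(0))
  if (!is.null(truth)) sites$genotype <- truth
  structure(list(sites = sites, reads = reads), class = "read_stack")
}
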