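#' Pairwise sequence divergence between samples
#'
#' d(x, y) = mean over shared sites of p_x (1 - p_y) + p_y (1 - p_x) with
#' p = dosage / ploidy: the probability that alleles drawn at random from
#' the two samples differ. Sites missing in either member of a pair are
#' dropped pairwise.
#'
#' @param panel a `genotype_panel`
#' @return a symmetric `dist`-like matrix with zero diagonal; pairs with
#'   no shared sites are NA (flagged by a warning)
#' @export
pairwise_divergence <- function(panel) {
  g <- panel$geno
  n <- ncol(g)
  stopifnot(n >= 2)
  p <- sweep(g, 2, panel$samples$ploidy, "/")
  d <- matrix(0, n, n, dimnames = list(colnames(g), colnames(g)))
  for (x in seq_len(n - 1)) {
    for (y in (x + 1):n) {
      ok <- !is.na(p[, x]) & !is.na(p[, y])
      if (!any(ok)) {
        d[x, y] <- d[y, x] <- NA_real_
        next
      }
      v <- mean(p[ok, x] * (1 - p[ok, y]) + p[ok, y] * (1 - p[ok, x]))
      d[x, y] <- d[y, x] <- v
    }
  }
  if (anyNA(d)) warning("some pairs share no called sites", call. = FALSE)
  d
}

#' Neighbour-joining tree from a divergence matrix
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}); label order is fixed
#' before joining so tie-breaking is deterministic across runs.
#'
#' @param d complete symmetric distance matrix, >= 3 taxa
#' @return an unrooted `phylo` tree
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix has missing entries", call. = FALSE)
  if (nrow(d) < 3) stop("need >= 3 taxa", call. = FALSE)
  ord <- order(rownames(d))
  ape::nj(d[ord, ord])
}

#' Genomic-window bootstrap support for tree bipartitions
#'
#' Splits the genome into windows of `window_cm` centimorgans (via a
#' genetic map; falls back to the panel's jackknife blocks when `map` is
#' NULL), resamples windows with replacement `B` times, rebuilds the NJ
#' tree from each pseudo-panel and reports the fraction of replicates
#' containing each internal edge (bipartition) of the original tree.
#'
#' @param panel a `genotype_panel`
#' @param map optional genetic map (chrom, pos, cM) for
#'   [genetic_blocks()]
#' @param window_cm window size in centimorgans
#' @param B bootstrap replicates; `B = 0` returns the original tree with
#'   an empty support table
#' @param seed integer seed
#' @return list(tree = original `phylo`, support = numeric per internal
#'   node in `tree$node.label` order, B)
#' @export
window_bootstrap_support <- function(panel, map = NULL, window_cm = 5,
                                     B = 100, seed = 1) {
  win <- if (is.null(map)) panel$sites$block_id
         else genetic_blocks(panel$sites, map, window_cm)
  uw <- unique(win)
  if (length(uw) < 10)
    warning("fewer than 10 windows: bootstrap support unreliable",
            call. = FALSE)
  tree <- nj_tree(pairwise_divergence(panel))
  if (B == 0)
    return(list(tree = tree, support = numeric(0), B = 0L))
  idx_by_win <- split(seq_along(win), win)
  set.seed(seed)
  boot <- vector("list", B)
  for (b in seq_len(B)) {
    take <- unlist(idx_by_win[sample(length(uw), replace = TRUE)],
                   use.names = FALSE)
    sub <- panel
    sub$geno <- panel$geno[take, , drop = FALSE]
    sub$sites <- panel$sites[take, , drop = FALSE]
    boot[[b]] <- nj_tree(pairwise_divergence(sub))
  }
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = tree, support = counts / B, B = B)
}

#' Classify a query haplotype as dog-like, wolf-like or heterozygous-like
#'
#' Per window, sites are filtered to minor allele frequencies (computed
#' across the dog + wolf panels) within `maf_range`; mean dosage centroids
#' of the dog and wolf panels are formed and the query's mean absolute
#' distance to each centroid compared. The window is called `dog-like`
#' when the query is nearer the dog centroid by at least `margin` dosage
#' units, `wolf-like` when nearer the wolf centroid by `margin`, and
#' `heterozygous-like` otherwise. Windows with fewer than `min_sites`
#' usable sites are left unclassified.
#'
#' @param panel a `genotype_panel`
#' @param windows data.frame (chrom, start, end, 1-based inclusive
#'   coordinates by site position) defining candidate loci; or NULL to use
#'   the panel's blocks
#' @param dog,wolf sample names of the reference panels
#' @param query sample name of the haplotype to classify
#' @param maf_range keep sites with MAF in this closed range; NULL
#'   disables the filter
#' @param min_sites minimum usable sites per window
#' @param margin decision margin in mean dosage-distance units
#' @return a `locus_calls` data.frame: window, class, score (wolf distance
#'   minus dog distance), n_sites
#' @export
classify_locus <- function(panel, windows = NULL, dog, wolf, query,
                           maf_range = c(0.05, 0.49), min_sites = 20,
                           margin = 0.25) {
  g <- panel$geno
  di <- match(dog, panel$samples$sample)
  wi <- match(wolf, panel$samples$sample)
  qi <- match(query, panel$samples$sample)
  if (anyNA(c(di, wi, qi))) stop("unknown sample name", call. = FALSE)
  win_of <- if (is.null(windows)) {
    panel$sites$block_id
  } else {
    w <- rep(NA_integer_, nrow(g))
    for (k in seq_len(nrow(windows))) {
      w[panel$sites$chrom == windows$chrom[k] &
          panel$sites$pos >= windows$start[k] &
          panel$sites$pos <= windows$end[k]] <- k
    }
    w
  }
  ref_idx <- c(di, wi)
  tot <- rowSums(g[, ref_idx, drop = FALSE], na.rm = TRUE)
  nn <- rowSums((!is.na(g[, ref_idx, drop = FALSE])) *
                  rep(panel$samples$ploidy[ref_idx], each = nrow(g)))
  maf <- pmin(tot / nn, 1 - tot / nn)
  usable <- !is.na(win_of) & nn > 0 & !is.na(g[, qi])
  if (!is.null(maf_range))
    usable <- usable & maf >= maf_range[1] & maf <= maf_range[2]
  ids <- sort(unique(win_of[!is.na(win_of)]))
  out <- data.frame(window = ids, class = NA_character_,
                    score = NA_real_, n_sites = 0L)
  for (r in seq_len(nrow(out))) {
    i <- which(usable & win_of == out$window[r])
    out$n_sites[r] <- length(i)
    if (length(i) < min_sites) next
    cd <- rowMeans(g[i, di, drop = FALSE], na.rm = TRUE)
    cw <- rowMeans(g[i, wi, drop = FALSE], na.rm = TRUE)
    q <- g[i, qi]
    dd <- mean(abs(q - cd), na.rm = TRUE)
    dw <- mean(abs(q - cw), na.rm = TRUE)
    out$score[r] <- dw - dd
    out$class[r] <- if (dw - dd >= margin) "dog-like"
                    else if (dd - dw >= margin) "wolf-like"
                    else "heterozygous-like"
  }
  class(out) <- c("locus_calls", "data.frame")
  out
}
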