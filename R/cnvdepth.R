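#' Bin a per-position depth track into fixed windows
#'
#' @param track a `depth_track` (see [simulate_depth()]) or data.frame with
#'   chrom, start, end (0-based half-open), depth and optionally gc
#' @param window window size in bp (terminal remainder kept as a short
#'   window)
#' @return data.frame: chrom, start, end, depth (mean), gc (mean)
#' @export
bin_depth <- function(track, window = 3000) {
  out <- lapply(split(track, track$chrom), function(tr) {
    w <- tr$start %/% window
    agg <- function(v) as.vector(tapply(v, w, mean))
    st <- as.vector(tapply(tr$start, w, min))
    en <- as.vector(tapply(tr$end, w, max))
    data.frame(chrom = tr$chrom[1], start = st, end = en,
               depth = agg(tr$depth),
               gc = if (!is.null(tr$gc)) agg(tr$gc) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.overlaps_bed <- function(windows, bed) {
  hit <- rep(FALSE, nrow(windows))
  for (i in seq_len(nrow(bed))) {
    hit <- hit | (windows$chrom == bed$chrom[i] &
                    windows$start < bed$end[i] &
                    windows$end > bed$start[i])
  }
  hit
}

#' Loess GC-bias correction of a windowed depth track
#'
#' Fits depth against GC fraction by loess within control windows (regions
#' not known to be copy-number variable) and rescales every window by
#' `control mean / loess(GC)`. GC values outside the fitted support use
#' nearest-endpoint extrapolation and are flagged.
#'
#' @param windows windowed track from [bin_depth()] with a `gc` column
#' @param control BED-style data.frame (chrom, start, end, 0-based
#'   half-open) of control regions; must cover at least `min_control`
#'   windows
#' @param span loess span
#' @param min_control minimum control windows required
#' @return a `gc_correction`: list(windows with `corrected` column and
#'   `extrapolated` flag, curve = loess fit, control_mean)
#' @export
gc_correct <- function(windows, control, span = 0.3, min_control = 100) {
  stopifnot(!is.null(windows$gc))
  ctrl <- .overlaps_bed(windows, control)
  if (sum(ctrl) < min_control)
    stop("control regions cover only ", sum(ctrl), " windows (need >= ",
         min_control, ")", call. = FALSE)
  # widen the span when few control windows are available so the local
  # quadratic always has enough support
  span_eff <- max(span, min(1, 10 / sum(ctrl)))
  fit <- loess(depth ~ gc, data = windows[ctrl, ], span = span_eff,
               degree = 2, family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  rng <- range(windows$gc[ctrl])
  gc_eval <- pmin(pmax(windows$gc, rng[1]), rng[2])
  extrap <- windows$gc < rng[1] | windows$gc > rng[2]
  pred <- predict(fit, data.frame(gc = gc_eval))
  control_mean <- mean(windows$depth[ctrl])
  corr <- windows
  corr$corrected <- windows$depth * control_mean / pred
  # rescale so the control-region mean is exactly preserved
  corr$corrected <- corr$corrected *
    control_mean / mean(corr$corrected[ctrl])
  corr$extrapolated <- extrap
  corr$control <- ctrl
  structure(list(windows = corr, curve = fit,
                 control_mean = control_mean),
            class = "gc_correction")
}

#' @export
print.gc_correction <- function(x, ...) {
  cat("GC loess correction:", nrow(x$windows), "windows, control mean",
      round(x$control_mean, 3), "\n")
  if (any(x$windows$extrapolated))
    cat("  NOTE:", sum(x$windows$extrapolated),
        "windows outside fitted GC support (nearest-endpoint)\n")
  invisible(x)
}

#' Convert corrected window depths to copy-number estimates
#'
#' CN(window) = 2 * corrected depth / control mean (diploid baseline 2).
#'
#' @param corrected a `gc_correction` from [gc_correct()], or a windowed
#'   data.frame with a `corrected` column
#' @param control_mean control-region mean depth (taken from the
#'   `gc_correction` when omitted)
#' @return a `cn_track` data.frame: chrom, start, end, corrected, cn
#' @export
window_copy_number <- function(corrected, control_mean = NULL) {
  if (inherits(corrected, "gc_correction")) {
    if (is.null(control_mean)) control_mean <- corrected$control_mean
    corrected <- corrected$windows
  }
  stopifnot(!is.null(control_mean), control_mean > 0)
  out <- corrected[, c("chrom", "start", "end", "corrected")]
  out$cn <- ifelse(is.na(out$corrected), NA_real_,
                   2 * out$corrected / control_mean)
  class(out) <- c("cn_track", "data.frame")
  out
}

#' Copy number at a locus
#'
#' Median copy number over the windows overlapping the locus, with an
#' integer call by rounding half away from zero.
#'
#' @param cn a `cn_track` from [window_copy_number()]
#' @param locus one-row BED-style data.frame (chrom, start, end)
#' @return list(estimate, call, n_windows)
#' @export
locus_copy_number <- function(cn, locus) {
  hit <- .overlaps_bed(cn, locus)
  if (!any(hit))
    stop("locus overlaps no windows", call. = FALSE)
  est <- median(cn$cn[hit], na.rm = TRUE)
  list(estimate = est, call = as.integer(floor(abs(est) + 0.5) * sign(est)),
       n_windows = sum(hit))
}

#' Bimodality summary of per-sample copy-number calls
#'
#' @param calls integer copy-number calls across samples
#' @return list(low = count of calls <= 3, high = count of calls > 6,
#'   mid = the rest)
#' @export
cn_bimodality <- function(calls) {
  list(low = sum(calls <= 3), high = sum(calls > 6),
       mid = sum(calls > 3 & calls <= 6))
}

#' Write / read a depth or copy-number track as bedGraph-style TSV
#'
#' Columns: chrom, start, end (0-based half-open), then the value
#' column(s).
#' @param track data.frame with chrom/start/end plus value columns
#' @param path file path
#' @return `read_bedgraph` returns a data.frame
#' @export
write_bedgraph <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Read a BED file (0-based half-open)
#'
#' @param path file path (3+ tab-separated columns, no header required)
#' @return data.frame: chrom, start, end (+ name if present)
#' @export
read_bed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}
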