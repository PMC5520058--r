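#' Damage probability at a read position
#'
#' Evaluates the fitted decay `a * exp(-(x^c) * b)` for 1-based positions
#' from the relevant read end. Degenerate models return 0.
#'
#' @param model a [damage_model()] or [weibull_decay()]
#' @param end `"5prime"` or `"3prime"` (ignored when `model` is a single
#'   decay)
#' @param x 1-based position(s) from that end
#' @return numeric vector of damage probabilities
#' @export
damage_probability <- function(model, end = c("5prime", "3prime"), x) {
  end <- match.arg(end)
  if (inherits(model, "damage_model"))
    model <- if (end == "5prime") model$five_prime else model$three_prime
  stopifnot(inherits(model, "weibull_decay"))
  if (any(x < 1)) stop("position x must be >= 1", call. = FALSE)
  if (model$degenerate || model$a == 0) return(rep(0, length(x)))
  model$a * exp(-(x^model$c) * model$b)
}

#' Tabulate strand-resolved misincorporation proportions by read position
#'
#' Counts, per 1-based position from the 5' end, the proportion of
#' reference-C opportunities read as T (and, per position from the 3' end,
#' reference-G read as A). Reverse-orientation reads are complement-relabelled
#' first (reference G read as A near their own 5' end is the same chemical
#' C>T event), so both tables aggregate over strands.
#'
#' @param stack a `read_stack` (see [simulate_reads()]) or a pileup read
#'   with [read_pileup()]
#' @param max_pos tabulate positions `1..max_pos` from each end
#' @return list of two `damage_table` data.frames (`five_prime`,
#'   `three_prime`) with columns end, pos, opportunities, mismatches,
#'   proportion (NA where there are no opportunities)
#' @export
tabulate_mismatches <- function(stack, max_pos = 50) {
  r <- stack$reads
  ref <- stack$sites$ref[r$site]
  fwd <- r$strand == "+"
  # 5' C>T: forward reads at ref C; reverse reads at ref G (complement)
  opp5 <- (fwd & ref == "C") | (!fwd & ref == "G")
  mis5 <- opp5 & ((fwd & r$base == "T") | (!fwd & r$base == "A"))
  # 3' G>A: forward reads at ref G; reverse reads at ref C
  opp3 <- (fwd & ref == "G") | (!fwd & ref == "C")
  mis3 <- opp3 & ((fwd & r$base == "A") | (!fwd & r$base == "T"))
  tab <- function(opp, mis, posv, end) {
    pos <- seq_len(max_pos)
    o <- tabulate(posv[opp], nbins = max_pos)
    m <- tabulate(posv[mis], nbins = max_pos)
    structure(data.frame(end = end, pos = pos, opportunities = o,
                         mismatches = m,
                         proportion = ifelse(o > 0, m / o, NA_real_)),
              class = c("damage_table", "data.frame"))
  }
  list(five_prime = tab(opp5, mis5, r$pos5, "5prime"),
       three_prime = tab(opp3, mis3, r$pos3, "3prime"))
}

#' Fit the Weibull decay model to a misincorporation table
#'
#' Weighted (by opportunities) bounded nonlinear least squares of
#' `a * exp(-(x^c) * b)` against the tabulated proportions. By default a
#' sequencing-error baseline estimated from interior positions
#' (`>= floor_from`) is subtracted before fitting. Initial values: `a` from
#' the proportion at position 1, `b` from the log-linear slope over the
#' first 10 positions, `c = 1`; bounds `a` in [0,1], `b` in (0,50],
#' `c` in (0,5].
#'
#' @param table a `damage_table` from [tabulate_mismatches()]
#' @param fit_range number of terminal positions used for the fit
#' @param error_floor subtract the interior-position error baseline?
#' @param floor_from first position treated as interior
#' @param fix_c fix the shape at `c = 1` (plain exponential decay)
#' @return a [weibull_decay()]; degenerate (a = 0) when the table carries
#'   no signal
#' @export
fit_weibull <- function(table, fit_range = 25, error_floor = TRUE,
                        floor_from = 25, fix_c = FALSE) {
  end <- as.character(table$end[1])
  d <- table[table$pos <= fit_range & table$opportunities > 0, , drop = FALSE]
  if (nrow(d) < 4)
    stop("need >= 4 positions with opportunities to fit", call. = FALSE)
  floor_est <- 0
  if (error_floor) {
    interior <- table[table$pos >= floor_from & table$opportunities > 0, ]
    if (nrow(interior) > 0)
      floor_est <- weighted.mean(interior$proportion,
                                 interior$opportunities)
  }
  y <- pmax(d$proportion - floor_est, 0)
  x <- d$pos
  w <- d$opportunities
  if (all(y == 0))
    return(weibull_decay(0, 0.3, 1, end = end, degenerate = TRUE))
  a0 <- max(min(y[which.min(x)], 1), 1e-4)
  head_idx <- x <= 10 & y > 0
  b0 <- 0.3
  if (sum(head_idx) >= 2) {
    sl <- stats::coef(stats::lm(log(y[head_idx]) ~ x[head_idx]))[2]
    if (is.finite(sl) && sl < 0) b0 <- min(max(-sl, 1e-3), 50)
  }
  df <- data.frame(x = x, y = y, w = w)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14)
  try_fit <- function(start) {
    tryCatch({
      if (fix_c)
        minpack.lm::nlsLM(y ~ a * exp(-x * b), data = df, start = start,
                          weights = df$w, lower = c(0, 1e-8),
                          upper = c(1, 50), control = ctrl)
      else
        minpack.lm::nlsLM(y ~ a * exp(-(x^c) * b), data = df,
                          start = start, weights = df$w,
                          lower = c(0, 1e-8, 1e-8), upper = c(1, 50, 5),
                          control = ctrl)
    }, error = function(e) NULL)
  }
  starts <- list(
    if (fix_c) list(a = a0, b = b0) else list(a = a0, b = b0, c = 1),
    if (fix_c) list(a = max(y), b = 0.3)
    else list(a = max(y), b = 0.3, c = 1),
    if (fix_c) list(a = 0.5, b = 1) else list(a = 0.5, b = 1, c = 0.8))
  fit <- NULL
  for (s in starts) {
    fit <- try_fit(s)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    return(weibull_decay(max(y), b0, 1, end = end, degenerate = TRUE))
  cf <- stats::coef(fit)
  out <- weibull_decay(unname(cf["a"]), unname(cf["b"]),
                       if (fix_c) 1 else unname(cf["c"]), end = end)
  attr(out, "rss") <- sum(df$w * stats::residuals(fit)^2)
  attr(out, "error_floor") <- floor_est
  out
}

#' Fit a full damage model from a read stack
#'
#' Convenience wrapper: tabulates both ends with [tabulate_mismatches()]
#' and fits each with [fit_weibull()].
#' @param stack a `read_stack`
#' @param ... passed to [fit_weibull()]
#' @return a [damage_model()]
#' @export
fit_damage_model <- function(stack, ...) {
  tabs <- tabulate_mismatches(stack)
  damage_model(fit_weibull(tabs$five_prime, ...),
               fit_weibull(tabs$three_prime, ...))
}

#' Write / read a damage table as TSV
#'
#' Columns: end, pos, opportunities, mismatches, proportion. The reader
#' also tolerates MapDamage-style misincorporation text: any
#' tab/space-separated file with a position column (`Pos` or `pos`), an
#' occurrence column (`C` for 5' tables / `G` for 3') and a mismatch count
#' column (`C>T` / `G>A`).
#' @param table a `damage_table`
#' @param path file path
#' @param end which end a MapDamage-style file describes
#' @return `read_damage_table` returns a `damage_table`
#' @export
write_damage_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_damage_table
#' @export
read_damage_table <- function(path, end = c("5prime", "3prime")) {
  end <- match.arg(end)
  df <- read.table(path, header = TRUE, sep = "", check.names = FALSE,
                   comment.char = "#")
  if (all(c("end", "pos", "opportunities", "mismatches") %in% names(df))) {
    df$proportion <- ifelse(df$opportunities > 0,
                            df$mismatches / df$opportunities, NA_real_)
    return(structure(df[, c("end", "pos", "opportunities", "mismatches",
                            "proportion")],
                     class = c("damage_table", "data.frame")))
  }
  nm <- names(df)
  poscol <- nm[tolower(nm) == "pos"][1]
  oppcol <- if (end == "5prime") "C" else "G"
  miscol <- if (end == "5prime") "C>T" else "G>A"
  if (is.na(poscol) || !(oppcol %in% nm) || !(miscol %in% nm))
    stop("unrecognized damage-table format", call. = FALSE)
  o <- df[[oppcol]]
  m <- df[[miscol]]
  structure(data.frame(end = end, pos = df[[poscol]], opportunities = o,
                       mismatches = m,
                       proportion = ifelse(o > 0, m / o, NA_real_)),
            class = c("damage_table", "data.frame"))
}

#' Write / read a damage model as JSON
#'
#' @param model a [damage_model()]
#' @param path file path
#' @return `read_damage_model` returns a [damage_model()]
#' @export
write_damage_model <- function(model, path) {
  jsonlite::write_json(lapply(unclass(model), unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_damage_model
#' @export
read_damage_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  damage_model(
    weibull_decay(x$five_prime$a, x$five_prime$b, x$five_prime$c,
                  end = "5prime",
                  degenerate = isTRUE(x$five_prime$degenerate)),
    weibull_decay(x$three_prime$a, x$three_prime$b, x$three_prime$c,
                  end = "3prime",
                  degenerate = isTRUE(x$three_prime$degenerate)))
}
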