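#' Demographic model for coalescent simulation
#'
#' Describes a population tree with optional admixture pulses in
#' mutation-scaled units: divergence times are expected mutations per site
#' (tau) and population sizes are theta = 4*N*mu, so the pairwise
#' coalescence rate within a population of size theta is 2/theta.
#'
#' @param populations data.frame with columns `name` and `theta`, one row
#'   per population. Must include every internal (ancestral) population
#'   named in `splits$parent` as well as every leaf.
#' @param splits data.frame with columns `parent`, `child1`, `child2`,
#'   `time`: viewed backwards in time, the two child populations merge into
#'   the parent at `time`. Times must be strictly positive and children
#'   must split more recently than their parent.
#' @param samples data.frame with columns `sample`, `population` and
#'   optionally `age` (mutation-scaled time before present, default 0) and
#'   `ploidy` (default 2).
#' @param admixture optional data.frame with columns `source`, `dest`,
#'   `time`, `proportion`: looking backwards, a lineage in `dest` at `time`
#'   jumps to `source` with probability `proportion`.
#' @param ascertainment label(s) of the population(s) whose samples define
#'   the ascertainment panel (simulated sites are rejected unless variable
#'   among their chromosomes), or `"none"`.
#'
#' @return An object of class `demography_config`.
#' @export
demography_config <- function(populations, splits, samples,
                              admixture = NULL, ascertainment = "none") {
  populations <- as.data.frame(populations)
  splits <- as.data.frame(splits)
  samples <- as.data.frame(samples)
  stopifnot(all(c("name", "theta") %in% names(populations)),
            all(c("parent", "child1", "child2", "time") %in% names(splits)),
            all(c("sample", "population") %in% names(samples)))
  if (is.null(samples$age)) samples$age <- 0
  if (is.null(samples$ploidy)) samples$ploidy <- 2L
  if (anyDuplicated(populations$name))
    stop("duplicate population names", call. = FALSE)
  if (any(populations$theta <= 0))
    stop("all theta must be > 0", call. = FALSE)
  if (nrow(splits) > 0 && any(splits$time <= 0))
    stop("split times must be strictly positive", call. = FALSE)
  allpop <- populations$name
  ref <- unique(c(splits$parent, splits$child1, splits$child2,
                  samples$population))
  if (!all(ref %in% allpop))
    stop("unknown population(s): ",
         paste(setdiff(ref, allpop), collapse = ", "), call. = FALSE)
  children <- c(splits$child1, splits$child2)
  if (anyDuplicated(children))
    stop("a population merges into more than one parent", call. = FALSE)
  # child must split (merge upward) strictly before its own parent does
  merge_time <- setNames(rep(Inf, length(allpop)), allpop)
  for (i in seq_len(nrow(splits))) {
    merge_time[splits$child1[i]] <- splits$time[i]
    merge_time[splits$child2[i]] <- splits$time[i]
  }
  for (i in seq_len(nrow(splits))) {
    kids <- c(splits$child1[i], splits$child2[i])
    for (k in kids) {
      # nothing to check: k's merge IS this split
    }
    if (merge_time[splits$parent[i]] <= splits$time[i])
      stop("split times not topologically ordered: parent '",
           splits$parent[i], "' merges at or below its children",
           call. = FALSE)
  }
  n_root <- sum(!(allpop %in% children))
  if (nrow(splits) > 0 && n_root != 1)
    stop("population tree must have a single root (found ", n_root, ")",
         call. = FALSE)
  if (!is.null(admixture)) {
    admixture <- as.data.frame(admixture)
    stopifnot(all(c("source", "dest", "time", "proportion")
                  %in% names(admixture)))
    if (any(admixture$proportion < 0 | admixture$proportion > 1))
      stop("admixture proportions must lie in [0, 1]", call. = FALSE)
    if (!all(c(admixture$source, admixture$dest) %in% allpop))
      stop("admixture references unknown population", call. = FALSE)
  }
  for (i in seq_len(nrow(samples))) {
    mt <- merge_time[samples$population[i]]
    if (is.finite(mt) && samples$age[i] >= mt)
      stop("sample '", samples$sample[i],
           "' is older than its population's first split", call. = FALSE)
  }
  if (!identical(ascertainment, "none") &&
      !all(ascertainment %in% samples$population))
    stop("ascertainment panel has no samples", call. = FALSE)
  structure(list(populations = populations, splits = splits,
                 samples = samples, admixture = admixture,
                 ascertainment = ascertainment),
            class = "demography_config")
}

#' @export
print.demography_config <- function(x, ...) {
  cat("Demographic model (mutation-scaled units)\n")
  cat("  populations:", nrow(x$populations),
      " splits:", nrow(x$splits),
      " samples:", nrow(x$samples), "\n")
  if (!is.null(x$admixture) && nrow(x$admixture) > 0)
    cat("  admixture pulses:", nrow(x$admixture), "\n")
  cat("  ascertainment:",
      paste(x$ascertainment, collapse = "+"), "\n")
  invisible(x)
}

#' Read or write a demographic model as JSON
#'
#' @param config a `demography_config`
#' @param path file path
#' @return `read_demography` returns a `demography_config`;
#'   `write_demography` returns `path` invisibly.
#' @export
write_demography <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_demography
#' @export
read_demography <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  demography_config(x$populations, x$splits, x$samples,
                    admixture = x$admixture,
                    ascertainment = x$ascertainment)
}
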