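#' Admixture graph with drift edges in f2 units
#'
#' A rooted DAG: `edges` are drift edges (`from` = parent) with lengths in
#' f2 units; `admix` rows give an admixture node two parents, the lineage
#' taking `parent1` with probability `prop` (admixture connections carry no
#' drift). Leaves map one-to-one to populations.
#'
#' @param edges data.frame with columns `from`, `to`, `length`
#' @param admix optional data.frame with columns `child`, `parent1`,
#'   `parent2`, `prop`
#' @return an `admixture_graph`
#' @export
admixture_graph <- function(edges, admix = NULL) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to", "length") %in% names(edges)))
  if (any(edges$length < 0))
    stop("drift edge lengths must be >= 0", call. = FALSE)
  if (!is.null(admix)) {
    admix <- as.data.frame(admix)
    stopifnot(all(c("child", "parent1", "parent2", "prop") %in% names(admix)))
    if (any(admix$prop < 0 | admix$prop > 1))
      stop("admixture proportions must lie in [0, 1]", call. = FALSE)
  }
  nodes <- unique(c(edges$from, edges$to,
                    if (!is.null(admix))
                      c(admix$child, admix$parent1, admix$parent2)))
  has_parent <- nodes %in% c(edges$to,
                             if (!is.null(admix)) admix$child)
  root <- nodes[!has_parent]
  if (length(root) != 1)
    stop("graph must have a unique root (found ",
         length(root), ")", call. = FALSE)
  is_parent <- nodes %in% c(edges$from,
                            if (!is.null(admix))
                              c(admix$parent1, admix$parent2))
  leaves <- nodes[!is_parent]
  g <- structure(list(edges = edges, admix = admix, nodes = nodes,
                      root = root, leaves = leaves),
                 class = "admixture_graph")
  .topo_order(g)  # errors on cycles
  g
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat("Admixture graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "drift edges,",
      if (is.null(x$admix)) 0 else nrow(x$admix), "admixture nodes\n")
  cat("  root:", x$root, "  leaves:", paste(x$leaves, collapse = ", "),
      "\n")
  invisible(x)
}

# children-before-parents order; errors if the graph has a cycle
.topo_order <- function(g) {
  parents <- function(v) {
    p <- g$edges$from[g$edges$to == v]
    if (!is.null(g$admix)) {
      i <- which(g$admix$child == v)
      if (length(i)) p <- c(p, g$admix$parent1[i], g$admix$parent2[i])
    }
    p
  }
  order <- character(0)
  mark <- setNames(integer(length(g$nodes)), g$nodes)
  visit <- function(v) {
    if (mark[[v]] == 2L) return()
    if (mark[[v]] == 1L) stop("graph contains a cycle", call. = FALSE)
    mark[[v]] <<- 1L
    for (p in parents(v)) visit(p)
    mark[[v]] <<- 2L
    order <<- c(order, v)
  }
  for (v in g$nodes) visit(v)
  rev(order)  # children before parents
}

# probability each drift edge lies on the lineage route leaf -> root
.edge_usage <- function(g, leaf) {
  if (!(leaf %in% g$leaves))
    stop("population '", leaf, "' is not a leaf of the graph",
         call. = FALSE)
  mass <- setNames(numeric(length(g$nodes)), g$nodes)
  mass[leaf] <- 1
  u <- numeric(nrow(g$edges))
  ord <- .topo_order(g)  # children before parents
  for (v in ord) {
    if (mass[[v]] == 0 || v == g$root) next
    ai <- if (!is.null(g$admix)) which(g$admix$child == v) else integer(0)
    if (length(ai)) {
      mass[[g$admix$parent1[ai]]] <- mass[[g$admix$parent1[ai]]] +
        g$admix$prop[ai] * mass[[v]]
      mass[[g$admix$parent2[ai]]] <- mass[[g$admix$parent2[ai]]] +
        (1 - g$admix$prop[ai]) * mass[[v]]
    } else {
      ei <- which(g$edges$to == v)
      u[ei] <- mass[[v]]
      mass[[g$edges$from[ei]]] <- mass[[g$edges$from[ei]]] + mass[[v]]
    }
  }
  u
}

#' Expected f-statistics on an admixture graph
#'
#' Admixture-weighted overlapping-path summation over the DAG: with
#' u_e(X) the probability that edge e lies on the lineage route from leaf
#' X to the root, E f4(A,B; C,D) = sum_e len_e (u_e(A) - u_e(B)) *
#' (u_e(C) - u_e(D)); f2(A,B) = E f4(A,B; A,B) and f3(C; A,B) =
#' E f4(C,A; C,B).
#'
#' @param graph an [admixture_graph()]
#' @param type one of `"f2"`, `"f3"`, `"f4"`
#' @param pops population (leaf) labels: 2 for f2, 3 for f3 (target first),
#'   4 for f4
#' @return expected value (numeric scalar)
#' @export
expected_f <- function(graph, type = c("f2", "f3", "f4"), pops) {
  type <- match.arg(type)
  quad <- switch(type,
                 f2 = c(pops[1], pops[2], pops[1], pops[2]),
                 f3 = c(pops[1], pops[2], pops[1], pops[3]),
                 f4 = pops)
  stopifnot(length(quad) == 4)
  u <- vapply(unique(quad), function(p) .edge_usage(graph, p),
              numeric(nrow(graph$edges)))
  u <- matrix(u, ncol = length(unique(quad)),
              dimnames = list(NULL, unique(quad)))
  sum(graph$edges$length *
        (u[, quad[1]] - u[, quad[2]]) * (u[, quad[3]] - u[, quad[4]]))
}

# design row over edges for one statistic at given admixture proportions
.stat_row <- function(graph, type, pops) {
  quad <- switch(type,
                 f2 = c(pops[1], pops[2], pops[1], pops[2]),
                 f3 = c(pops[1], pops[2], pops[1], pops[3]),
                 f4 = pops)
  us <- lapply(unique(quad), function(p) .edge_usage(graph, p))
  names(us) <- unique(quad)
  (us[[quad[1]]] - us[[quad[2]]]) * (us[[quad[3]]] - us[[quad[4]]])
}

#' Fit an admixture graph to observed f-statistics
#'
#' Bounded weighted least squares: minimizes sum(((obs - expected)/SE)^2)
#' over drift edge lengths (>= 0) and, when present, admixture proportions
#' in [0, 1]. For fixed proportions the expectations are linear in the
#' lengths, so lengths are profiled out by weighted linear least squares
#' and only the proportions are optimized numerically. Statistics with
#' absolute standardized residual >= `z_cut` are reported as outliers.
#'
#' @param graph an [admixture_graph()] giving the topology (its lengths
#'   and proportions are used as starting values)
#' @param obs data.frame with columns `type` ("f2"/"f3"/"f4"), `pops`
#'   (list-column or comma-separated string of populations), `est`, `se`
#' @param z_cut outlier threshold on |Z residual|
#' @return a `graph_fit`: list(graph with fitted values, fitted, residual
#'   data.frame, outliers, sse, identifiable, null_space)
#' @export
fit_graph <- function(graph, obs, z_cut = 3) {
  obs <- as.data.frame(obs)
  pops_list <- if (is.list(obs$pops)) obs$pops else
    strsplit(as.character(obs$pops), ",")
  n_stat <- nrow(obs)
  n_edge <- nrow(graph$edges)
  has_admix <- !is.null(graph$admix) && nrow(graph$admix) > 0
  n_prop <- if (has_admix) nrow(graph$admix) else 0L
  w <- 1 / obs$se
  design <- function(g) {
    X <- t(vapply(seq_len(n_stat), function(i)
      .stat_row(g, obs$type[i], pops_list[[i]]), numeric(n_edge)))
    matrix(X, nrow = n_stat)
  }
  solve_lengths <- function(props) {
    g <- graph
    if (has_admix) g$admix$prop <- props
    X <- design(g)
    Xw <- X * w
    yw <- obs$est * w
    fit <- tryCatch(stats::lm.fit(Xw, yw), error = function(e) NULL)
    len <- if (is.null(fit)) rep(0, n_edge) else {
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      cf
    }
    if (any(len < 0)) {  # refit under the bound
      f <- function(l) sum((yw - Xw %*% l)^2)
      gr <- function(l) as.vector(-2 * t(Xw) %*% (yw - Xw %*% l))
      len <- nlminb(pmax(len, 0), f, gr, lower = rep(0, n_edge))$par
    }
    g$edges$length <- as.vector(len)
    list(g = g, X = X, sse = sum((yw - (X %*% len) * w)^2))
  }
  if (has_admix) {
    obj <- function(pr) solve_lengths(pr)$sse
    start <- pmin(pmax(graph$admix$prop, 1e-3), 1 - 1e-3)
    opt <- nlminb(start, obj, lower = rep(1e-6, n_prop),
                  upper = rep(1 - 1e-6, n_prop),
                  control = list(abs.tol = 1e-18, rel.tol = 1e-14))
    # polish from a few extra starts to dodge local minima
    for (s0 in list(rep(0.25, n_prop), rep(0.5, n_prop),
                    rep(0.75, n_prop))) {
      o2 <- nlminb(s0, obj, lower = rep(1e-6, n_prop),
                   upper = rep(1 - 1e-6, n_prop),
                   control = list(abs.tol = 1e-18, rel.tol = 1e-14))
      if (o2$objective < opt$objective) opt <- o2
    }
    sol <- solve_lengths(opt$par)
  } else {
    sol <- solve_lengths(NULL)
  }
  X <- sol$X
  expd <- as.vector(X %*% sol$g$edges$length)
  z <- (obs$est - expd) / obs$se
  sv <- svd(X * w, nu = 0, nv = n_edge)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  identifiable <- rank >= n_edge
  null_space <- if (!identifiable)
    sv$v[, (rank + 1):n_edge, drop = FALSE] else NULL
  res <- data.frame(type = obs$type,
                    pops = vapply(pops_list, paste, "", collapse = ","),
                    observed = obs$est, expected = expd, se = obs$se,
                    Z = z)
  structure(list(graph = sol$g, residuals = res,
                 outliers = res[abs(res$Z) >= z_cut, , drop = FALSE],
                 sse = sum(z^2), identifiable = identifiable,
                 null_space = null_space),
            class = "graph_fit")
}

#' @export
print.graph_fit <- function(x, ...) {
  cat("Admixture-graph fit: weighted SSE", format(x$sse, digits = 4),
      "over", nrow(x$residuals), "statistics\n")
  if (!x$identifiable)
    cat("  WARNING: parameters not identifiable (see $null_space)\n")
  if (nrow(x$outliers)) {
    cat("  outliers (|Z| >=", 3, "):\n")
    print(x$outliers, row.names = FALSE)
  } else cat("  no outliers\n")
  invisible(x)
}

#' Read / write an admixture graph as JSON
#'
#' @param graph an [admixture_graph()]
#' @param path file path
#' @return `read_graph` returns an [admixture_graph()]
#' @export
write_graph <- function(graph, path) {
  jsonlite::write_json(list(edges = graph$edges, admix = graph$admix),
                       path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  admix <- x$admix
  if (!is.null(admix) && (is.null(nrow(admix)) || nrow(admix) == 0))
    admix <- NULL
  admixture_graph(x$edges, admix)
}
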