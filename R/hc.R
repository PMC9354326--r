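#' Search configuration
#'
#' @param max_steps maximum number of accepted moves (default 1000, the
#'   cap used throughout the package's experiments).
#' @param tol minimum score improvement required to accept a move
#'   (default 0: any strict improvement is accepted).
#' @param seed integer seed recorded with the run (the search itself is
#'   deterministic; the seed matters for bootstrap resampling).
#' @param form continuous fit term, `"deviance"` or `"literal"`; see
#'   [score_continuous_node()].
#' @param max_parents largest allowed parent-set size. The default `NULL`
#'   resolves to `ceiling(log(n))` at search time: per-node regressions
#'   must stay well-conditioned relative to the sample size (a bootstrap
#'   resample carries only about 0.63 n distinct rows, and an
#'   unconstrained BIC search on such data can grow parent sets toward
#'   interpolation), and a log-n growth preserves the score's consistency
#'   while scaling with the data. Set `Inf` to disable the cap.
#' @export
search_config <- function(max_steps = 1000L, tol = 0, seed = 1L,
                          form = c("deviance", "literal"),
                          max_parents = NULL) {
  stopifnot(max_steps >= 0, tol >= 0, is.null(max_parents) || max_parents >= 0)
  structure(list(max_steps = as.integer(max_steps), tol = tol,
                 seed = as.integer(seed), form = match.arg(form),
                 max_parents = max_parents),
            class = "search_config")
}

#' Prior edge constraints
#'
#' Whitelist edges are always kept in the graph (never deleted or
#' reversed); blacklist edges are never allowed. The whitelist must be
#' acyclic as a graph and disjoint from the blacklist.
#'
#' @param whitelist,blacklist two-column data frames / matrices of
#'   (parent, child) node names, or `NULL`.
#' @export
prior_lists <- function(whitelist = NULL, blacklist = NULL) {
  norm <- function(x) {
    if (is.null(x) || NROW(x) == 0) {
      return(data.frame(parent = character(0), child = character(0)))
    }
    x <- as.data.frame(as.matrix(x), stringsAsFactors = FALSE)
    names(x)[1:2] <- c("parent", "child")
    x[, 1:2]
  }
  wl <- norm(whitelist)
  bl <- norm(blacklist)
  if (nrow(wl) > 0 && nrow(bl) > 0) {
    key <- function(d) paste(d$parent, d$child, sep = "\r")
    if (any(key(wl) %in% key(bl))) {
      stop("whitelist and blacklist overlap")
    }
  }
  structure(list(whitelist = wl, blacklist = bl), class = "prior_lists")
}

prior_masks <- function(priors, nodes) {
  p <- length(nodes)
  W <- matrix(FALSE, p, p)
  B <- matrix(FALSE, p, p)
  if (!is.null(priors)) {
    wl <- priors$whitelist
    bl <- priors$blacklist
    if (nrow(wl) > 0) {
      W[cbind(node_index(wl$parent, nodes), node_index(wl$child, nodes))] <- TRUE
    }
    if (nrow(bl) > 0) {
      B[cbind(node_index(bl$parent, nodes), node_index(bl$child, nodes))] <- TRUE
    }
  }
  list(white = W, black = B)
}

#' Hill-climbing structure search
#'
#' Greedy minimization of the decomposable BIC-type graph score. At each
#' step the search enumerates every eligible operation — additions of
#' absent, non-blacklisted, acyclic-safe edges; deletions of present
#' non-whitelisted edges; reversals of present non-whitelisted edges whose
#' reversed edge is non-blacklisted and acyclic-safe — and applies the one
#' with the most negative score change, stopping when no operation improves
#' the score by more than `tol` or when `max_steps` is reached. Ties are
#' broken deterministically (add < delete < reverse, then source, then
#' target position). Incremental bookkeeping re-scores only the children
#' whose parent set changed, and a transitive-closure index makes the
#' acyclicity check of a candidate cheap.
#'
#' @param data a [make_dataset()] object.
#' @param init initial `dag` (default: the whitelist-only graph, i.e. the
#'   empty graph when there are no priors). Must contain every whitelist
#'   edge, no blacklist edge, and be acyclic.
#' @param priors a [prior_lists()] or `NULL`.
#' @param config a [search_config()].
#' @return An object of class `hc_fit`: list with `dag` (the learned
#'   graph), `score` (its total score), `node_scores`, `trace` (one row per
#'   accepted move: kind, from, to, delta, running total), `local_min`
#'   (`TRUE` when the search stopped because no move improves), `warnings`
#'   (bitmask of scoring degeneracies seen).
#' @export
hc_search <- function(data, init = NULL, priors = NULL,
                      config = search_config()) {
  nodes <- data$nodes
  masks <- prior_masks(priors, nodes)
  if (is.null(init)) {
    wl <- if (is.null(priors)) NULL else priors$whitelist
    init <- dag(nodes, wl)
  }
  if (!identical(init$nodes, nodes)) stop("init nodes must match dataset")
  if (any(masks$white & !init$A)) {
    stop("init must contain every whitelist edge")
  }
  if (any(masks$black & init$A)) {
    stop("init contains a blacklisted edge")
  }
  maxpa <- config$max_parents %||% ceiling(log(data$n))
  maxpa <- if (is.finite(maxpa)) as.integer(maxpa) else length(nodes)
  res <- cpp_hc(data$values, kinds_int(data), init$A * 1L,
                masks$white * 1L, masks$black * 1L,
                config$max_steps, config$tol, form_int(config$form),
                maxpa)
  A <- res$A == 1L
  dimnames(A) <- list(nodes, nodes)
  g <- new_dag(nodes, A)
  trace <- data.frame(
    kind = c("add", "delete", "reverse")[res$kind + 1L],
    from = nodes[res$from], to = nodes[res$to],
    delta = res$delta, total = res$running_total,
    stringsAsFactors = FALSE)
  if (res$warn > 0) raise_score_warnings(res$warn, "hc_search")
  ns <- stats::setNames(res$node_scores, nodes)
  structure(list(dag = g, score = res$total, node_scores = ns,
                 trace = trace, local_min = res$local_min,
                 warnings = res$warn, config = config),
            class = "hc_fit")
}

#' @export
print.hc_fit <- function(x, ...) {
  cat("hc_fit: ", n_edges(x$dag), " edges, score ", format(x$score),
      ", ", nrow(x$trace), " steps",
      if (x$local_min) " (local minimum)" else " (step cap reached)",
      "\n", sep = "")
  invisible(x)
}

#' Enumerate eligible operations
#'
#' The exact candidate set scanned by one hill-climbing step, in the
#' deterministic tie-break order (add < delete < reverse, then source,
#' then target position).
#'
#' @param dag a `dag`.
#' @param index reachability index of `dag` (computed if missing).
#' @param priors a [prior_lists()] or `NULL`.
#' @return List of [operation()] objects.
#' @export
enumerate_eligible <- function(dag, index = reachability(dag),
                               priors = NULL) {
  nodes <- dag$nodes
  p <- length(nodes)
  masks <- prior_masks(priors, nodes)
  A <- dag$A
  ops <- list()
  for (u in seq_len(p)) for (v in seq_len(p)) {
    if (u != v && !A[u, v] && !A[v, u] && !masks$black[u, v] &&
        !index[v, u]) {
      ops[[length(ops) + 1L]] <- operation("add", nodes[u], nodes[v])
    }
  }
  for (u in seq_len(p)) for (v in seq_len(p)) {
    if (A[u, v] && !masks$white[u, v]) {
      ops[[length(ops) + 1L]] <- operation("delete", nodes[u], nodes[v])
    }
  }
  for (u in seq_len(p)) for (v in seq_len(p)) {
    if (A[u, v] && !masks$white[u, v] && !masks$black[v, u] &&
        !any(A[u, ] & index[, v] & seq_len(p) != v)) {
      ops[[length(ops) + 1L]] <- operation("reverse", nodes[u], nodes[v])
    }
  }
  ops
}
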