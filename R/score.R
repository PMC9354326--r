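#' BIC-type node and graph scores
#'
#' The graph score is decomposable: each node contributes a score that
#' depends only on its own parent set, and the graph score is the sum over
#' nodes. Lower is better; the hill-climbing search minimizes it.
#'
#' For a continuous node the score is the Gaussian regression deviance plus
#' a BIC penalty, `n * log(RSS/n) + |pa| * log(n)`, where RSS is the
#' residual sum of squares of an ordinary least-squares fit of the node on
#' its parents plus an intercept (binary parents enter as 0/1 regressors).
#' The intercept is never counted in `|pa|`. `form = "literal"` replaces
#' the fit term by the raw `RSS/n`.
#'
#' For a binary node the score is the logistic-regression deviance
#' `-2 * loglik` at the maximum-likelihood fit plus the same `|pa| * log(n)`
#' penalty. The likelihood is maximized by iteratively reweighted least
#' squares (at most 25 iterations, convergence when the largest coefficient
#' change falls below 1e-8); under separation or non-convergence the fit is
#' repeated with a small ridge penalty (1e-4) on the non-intercept
#' coefficients and a warning is recorded. Fitted probabilities are clipped
#' to `[1e-10, 1 - 1e-10]` before taking logs; a single-class column is
#' scored as the constant model.
#'
#' @param data a [make_dataset()] object.
#' @param node node name or position of the child.
#' @param parents node names or positions of the parent set (may be empty).
#' @param form `"deviance"` (default) or `"literal"` continuous fit term.
#' @return A single numeric score. Degeneracies (floored RSS, singular
#'   design, separation, single-class column) are raised as R warnings.
#' @examples
#' d <- make_dataset(cbind(x = c(1, 2, 3)))
#' score_continuous_node(d, "x", character(0))  # 3 * log(2/3)
#' @export
score_continuous_node <- function(data, node, parents,
                                  form = c("deviance", "literal")) {
  form <- match.arg(form)
  v <- node_index(node, data$nodes)
  if (data$kinds[v] != "continuous") stop("node '", data$nodes[v],
                                          "' is not continuous")
  score_node_checked(data, v, parents, form)
}

#' @rdname score_continuous_node
#' @export
score_binary_node <- function(data, node, parents) {
  v <- node_index(node, data$nodes)
  if (data$kinds[v] != "binary") stop("node '", data$nodes[v],
                                      "' is not binary")
  score_node_checked(data, v, parents, "deviance")
}

score_node_checked <- function(data, v, parents, form) {
  P <- if (length(parents) == 0) integer(0) else node_index(parents, data$nodes)
  if (v %in% P) stop("a node cannot be its own parent")
  res <- cpp_score_node(data$values, kinds_int(data), v, as.integer(P),
                        form_int(form))
  raise_score_warnings(res$warn, data$nodes[v])
  res$score
}

kinds_int <- function(data) as.integer(data$kinds == "binary")
form_int <- function(form) if (identical(form, "literal")) 1L else 0L

raise_score_warnings <- function(warn, label) {
  if (bitwAnd(warn, 1L)) warning("RSS floored (near-perfect fit) for ", label)
  if (bitwAnd(warn, 2L)) warning("singular design for ", label,
                                 "; pseudo-inverse used")
  if (bitwAnd(warn, 4L)) warning("separation / non-convergence for ", label,
                                 "; ridge-stabilized logistic fit used")
  if (bitwAnd(warn, 8L)) warning("single-class binary column ", label,
                                 "; scored as constant model")
  invisible(NULL)
}

#' Score a whole graph
#'
#' Returns the decomposed score: one entry per node (given its parents in
#' `dag`) and the total, their sum.
#'
#' @inheritParams score_continuous_node
#' @param dag a [dag()] whose nodes match the dataset columns.
#' @return A `score_cache`: list with `node_scores` (named numeric vector)
#'   and `total`.
#' @export
score_graph <- function(data, dag, form = c("deviance", "literal")) {
  form <- match.arg(form)
  if (!identical(dag$nodes, data$nodes)) {
    stop("dag nodes must match dataset columns")
  }
  p <- length(data$nodes)
  s <- numeric(p)
  warn <- 0L
  for (v in seq_len(p)) {
    res <- cpp_score_node(data$values, kinds_int(data), v,
                          which(dag$A[, v]), form_int(form))
    s[v] <- res$score
    warn <- bitwOr(warn, res$warn)
  }
  raise_score_warnings(warn, "graph scoring")
  names(s) <- data$nodes
  structure(list(node_scores = s, total = sum(s), form = form),
            class = "score_cache")
}

#' @export
print.score_cache <- function(x, ...) {
  cat("score_cache: total =", format(x$total), "over",
      length(x$node_scores), "nodes\n")
  invisible(x)
}

#' Score change of a single edit operation
#'
#' Computes `score(after) - score(before)` by re-scoring only the affected
#' children: `add`/`delete` touch the target node, `reverse` touches both
#' endpoints. A negative delta is an improvement (the score is minimized).
#'
#' @inheritParams score_graph
#' @param cache the `score_cache` for `dag` from [score_graph()].
#' @param op a [operation()] applicable to `dag`.
#' @return Numeric delta, with attribute `"cache"` holding the updated
#'   `score_cache` for the post-operation graph.
#' @export
score_delta <- function(data, dag, cache, op) {
  i <- node_index(op$from, dag$nodes)
  j <- node_index(op$to, dag$nodes)
  form <- cache$form %||% "deviance"
  pa_j <- which(dag$A[, j])
  new_scores <- cache$node_scores
  if (op$kind == "add") {
    if (dag$A[i, j] || dag$A[j, i]) stop("edge already present")
    new_scores[j] <- score_node_checked(data, j, c(pa_j, i), form)
  } else if (op$kind == "delete") {
    if (!dag$A[i, j]) stop("edge not present")
    new_scores[j] <- score_node_checked(data, j, setdiff(pa_j, i), form)
  } else if (op$kind == "reverse") {
    if (!dag$A[i, j]) stop("edge not present")
    pa_i <- which(dag$A[, i])
    new_scores[i] <- score_node_checked(data, i, c(pa_i, j), form)
    new_scores[j] <- score_node_checked(data, j, setdiff(pa_j, i), form)
  } else {
    stop("unknown operation kind")
  }
  delta <- sum(new_scores) - cache$total
  newcache <- structure(list(node_scores = new_scores,
                             total = sum(new_scores), form = form),
                        class = "score_cache")
  attr(delta, "cache") <- newcache
  delta
}

`%||%` <- function(a, b) if (is.null(a)) b else a
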