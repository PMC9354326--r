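#' Directed acyclic graphs
#'
#' A `dag` object holds an ordered node set and a logical adjacency matrix
#' `A` with `A[i, j] == TRUE` meaning a directed edge from node `i` to node
#' `j`. Objects are validated on construction: no self loops and no directed
#' cycles (checked by topological sort). All matrix indexing inside the
#' package is positional; node names are used only at I/O boundaries.
#'
#' @param nodes character vector of unique node names.
#' @param edges optional two-column matrix or data frame (parent, child),
#'   given by name or by position.
#' @return A `dag` object.
#' @examples
#' g <- dag(c("A", "B", "C"), data.frame(parent = "A", child = "B"))
#' dag_edges(g)
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  p <- length(nodes)
  A <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    i <- node_index(edges[, 1], nodes)
    j <- node_index(edges[, 2], nodes)
    A[cbind(i, j)] <- TRUE
  }
  new_dag(nodes, A)
}

#' @rdname dag
#' @export
empty_dag <- function(nodes) dag(nodes)

new_dag <- function(nodes, A) {
  g <- structure(list(nodes = nodes, A = A), class = "dag")
  validate_dag(g)
  g
}

validate_dag <- function(g) {
  A <- g$A
  p <- length(g$nodes)
  stopifnot(is.matrix(A), nrow(A) == p, ncol(A) == p, is.logical(A))
  if (any(diag(A))) stop("self-loops are not allowed")
  if (is.null(topological_order(A))) stop("graph contains a directed cycle")
  invisible(g)
}

node_index <- function(x, nodes) {
  if (is.numeric(x)) {
    i <- as.integer(x)
    if (any(i < 1L | i > length(nodes))) stop("node index out of range")
    return(i)
  }
  i <- match(as.character(x), nodes)
  if (anyNA(i)) stop("unknown node id: ", paste(x[is.na(i)], collapse = ", "))
  i
}

#' Topological order of an adjacency matrix
#'
#' Kahn's algorithm; returns the order as an integer vector, or `NULL` when
#' the graph has a directed cycle (this is the package's acyclicity check).
#'
#' @param A logical adjacency matrix.
#' @return Integer vector of node positions in topological order, or `NULL`.
#' @export
topological_order <- function(A) {
  p <- nrow(A)
  if (p == 0L) return(integer(0))
  indeg <- colSums(A)
  ord <- integer(0)
  avail <- which(indeg == 0)
  alive <- rep(TRUE, p)
  while (length(avail) > 0) {
    v <- avail[1L]
    avail <- avail[-1L]
    alive[v] <- FALSE
    ord <- c(ord, v)
    ch <- which(A[v, ])
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L && alive[w]) avail <- c(avail, w)
    }
  }
  if (length(ord) < p) NULL else ord
}

#' @export
print.dag <- function(x, ...) {
  e <- dag_edges(x)
  cat("dag: ", length(x$nodes), " nodes, ", nrow(e), " edges\n", sep = "")
  if (nrow(e) > 0 && nrow(e) <= 20) {
    cat(paste0("  ", e$parent, " -> ", e$child, collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

#' Edge list of a dag
#'
#' @param g a `dag`.
#' @return Data frame with columns `parent`, `child` (node names), sorted by
#'   parent then child position (the package's canonical edge order).
#' @export
dag_edges <- function(g) {
  idx <- which(t(g$A))  # row-major: parent-major order
  p <- length(g$nodes)
  child <- (idx - 1L) %% p + 1L
  parent <- (idx - 1L) %/% p + 1L
  data.frame(parent = g$nodes[parent], child = g$nodes[child],
             stringsAsFactors = FALSE)
}

#' Number of edges
#' @param g a `dag`.
#' @export
n_edges <- function(g) sum(g$A)

parents_of <- function(A, v) which(A[, v])

## ---- reachability -------------------------------------------------------

#' Reachability (transitive closure) index
#'
#' `reachability(g)` computes the transitive closure of the adjacency
#' matrix: `reach[u, v]` is `TRUE` iff a directed path of length >= 1 runs
#' from `u` to `v`. The index supports constant-time cycle checks during
#' search: adding u -> v is acyclic-safe iff `has_path(index, v, u)` is
#' `FALSE`.
#'
#' @param g a `dag` (or a logical adjacency matrix).
#' @return Logical p x p matrix with node-name dimnames.
#' @export
reachability <- function(g) {
  A <- if (inherits(g, "dag")) g$A else g
  transitive_closure(A)
}

transitive_closure <- function(A) {
  ## boolean matrix squaring: closure in O(log p) multiplications
  R <- A
  storage.mode(R) <- "numeric"
  repeat {
    R2 <- (R + R %*% R) > 0
    if (identical(R2, R > 0)) break
    R <- R2
    storage.mode(R) <- "numeric"
  }
  R <- R > 0
  dimnames(R) <- dimnames(A)
  R
}

#' Is there a directed path from u to v?
#'
#' @param index reachability matrix from [reachability()].
#' @param u,v node names or positions.
#' @return `TRUE` iff a directed path of length >= 1 exists.
#' @export
has_path <- function(index, u, v) {
  nodes <- rownames(index)
  i <- node_index(u, nodes)
  j <- node_index(v, nodes)
  index[i, j]
}

## ---- edit operations ----------------------------------------------------

#' Graph edit operations
#'
#' The three elementary moves of the hill-climbing search: `add` a directed
#' edge, `delete` one, or `reverse` one. Preconditions: `add` requires the
#' edge absent in both directions; `delete`/`reverse` require the edge
#' present as `from -> to`.
#'
#' @param kind one of `"add"`, `"delete"`, `"reverse"`.
#' @param from,to node names or positions (source and target).
#' @export
operation <- function(kind = c("add", "delete", "reverse"), from, to) {
  kind <- match.arg(kind)
  structure(list(kind = kind, from = from, to = to), class = "dag_operation")
}

#' @export
print.dag_operation <- function(x, ...) {
  cat(x$kind, ": ", x$from, " -> ", x$to, "\n", sep = "")
  invisible(x)
}

#' Apply an edit operation with incremental reachability update
#'
#' Applies an add/delete/reverse move to a dag and updates the reachability
#' index. Additions update the closure incrementally (every ancestor of the
#' source reaches every descendant of the target); deletions and reversals
#' recompute the closure. The returned index always equals the from-scratch
#' transitive closure of the updated graph.
#'
#' @param g a `dag`.
#' @param op a [operation()].
#' @param index reachability index for `g`; computed if missing.
#' @return List with elements `dag` and `index`.
#' @export
apply_operation <- function(g, op, index = reachability(g)) {
  A <- g$A
  i <- node_index(op$from, g$nodes)
  j <- node_index(op$to, g$nodes)
  if (i == j) stop("self-loops are not allowed")
  switch(op$kind,
    add = {
      if (A[i, j] || A[j, i]) stop("edge already present between ",
                                   op$from, " and ", op$to)
      if (index[j, i]) stop("adding ", op$from, " -> ", op$to,
                            " would create a cycle")
      A[i, j] <- TRUE
      index <- close_after_add(index, A, i, j)
    },
    delete = {
      if (!A[i, j]) stop("edge ", op$from, " -> ", op$to, " not present")
      A[i, j] <- FALSE
      index <- transitive_closure(A)
    },
    reverse = {
      if (!A[i, j]) stop("edge ", op$from, " -> ", op$to, " not present")
      A[i, j] <- FALSE
      ## cycle iff a second path i ~> j survives the removal
      index_without <- transitive_closure(A)
      if (index_without[i, j]) {
        stop("reversing ", op$from, " -> ", op$to, " would create a cycle")
      }
      A[j, i] <- TRUE
      index <- close_after_add(index_without, A, j, i)
    },
    stop("unknown operation kind")
  )
  list(dag = new_dag(g$nodes, A), index = index)
}

## incremental closure update for a single added edge i -> j
close_after_add <- function(index, A, i, j) {
  anc <- c(i, which(index[, i]))
  desc <- c(j, which(index[j, ]))
  index[anc, desc] <- TRUE
  index
}

## ---- structural Hamming distance ---------------------------------------

#' Structural Hamming distance between two DAGs
#'
#' For every unordered node pair the contribution is
#' `max(|A(i,j) - B(i,j)|, |A(j,i) - B(j,i)|)`: a missing or extra edge
#' costs 1 and a reversed edge also costs exactly 1 (reversal is one unit
#' of operation). The result is the minimum number of add/delete/reverse
#' moves converting one graph into the other, a valid distance metric on
#' DAGs over a common node set.
#'
#' @param g1,g2 `dag` objects on the same ordered node set.
#' @return Non-negative integer.
#' @examples
#' g1 <- dag(c("A", "B"), data.frame(parent = "A", child = "B"))
#' g2 <- dag(c("A", "B"), data.frame(parent = "B", child = "A"))
#' shd(g1, g2)  # 1: a reversal
#' @export
shd <- function(g1, g2) {
  if (!identical(g1$nodes, g2$nodes)) {
    stop("graphs must share the same ordered node set")
  }
  A <- g1$A
  B <- g2$A
  D <- abs(A - B)
  M <- pmax(D, t(D))
  sum(M[upper.tri(M)])
}
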