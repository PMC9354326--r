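#' Bagging configuration
#'
#' @param B number of bootstrap resamples (ensemble size). Default 100.
#' @param whitelist_fraction fraction of whitelist edges given to each
#'   bootstrap fit. With 1 (default) the whole whitelist constrains every
#'   fit and the aggregation; with less than 1 each bootstrap replicate
#'   receives an independent random subset (re-drawn when cyclic, see
#'   [learn_ensemble()]) and the aggregation is left unconstrained by the
#'   whitelist, so spurious prior edges can be filtered out.
#' @param seed integer seed driving all resampling.
#' @param search a [search_config()] for the per-bootstrap searches.
#' @param resample set `FALSE` to fit every ensemble member on the full
#'   data (diagnostic use).
#' @export
bag_config <- function(B = 100L, whitelist_fraction = 1, seed = 1L,
                       search = search_config(), resample = TRUE) {
  stopifnot(B >= 1, whitelist_fraction >= 0, whitelist_fraction <= 1)
  structure(list(B = as.integer(B),
                 whitelist_fraction = whitelist_fraction,
                 seed = as.integer(seed), search = search,
                 resample = isTRUE(resample)),
            class = "bag_config")
}

#' Learn a bootstrap ensemble of DAGs
#'
#' Draws `B` bootstrap resamples of the rows of `data` (n rows with
#' replacement each) and runs [hc_search()] on each, collecting the learned
#' DAGs. When `whitelist_fraction < 1`, each replicate receives its own
#' random subset of the whitelist; subsets that contain a directed cycle
#' (possible when the prior edges include both directions of a pair, as
#' when direction information comes from time-course data) are re-drawn up
#' to 100 times, after which the offending edges are dropped with a
#' warning. Scoring degeneracies in a replicate (e.g. a single-class binary
#' column after resampling) are warned about and the replicate is kept.
#' Fully reproducible given the seed.
#'
#' @param data a [make_dataset()] object.
#' @param priors a [prior_lists()] or `NULL`.
#' @param config a [bag_config()].
#' @return A `dag_ensemble`: list with `dags` (list of `dag`), `B`, and
#'   the per-replicate whitelists used.
#' @export
learn_ensemble <- function(data, priors = NULL, config = bag_config()) {
  set.seed(config$seed)
  n <- data$n
  wl <- if (is.null(priors)) NULL else priors$whitelist
  bl <- if (is.null(priors)) NULL else priors$blacklist
  dags <- vector("list", config$B)
  wls <- vector("list", config$B)
  n_warn <- 0L
  for (b in seq_len(config$B)) {
    rows <- if (config$resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    data_b <- make_dataset(data$values[rows, , drop = FALSE],
                           kinds = data$kinds)
    wl_b <- subsample_whitelist(wl, config$whitelist_fraction, data$nodes)
    priors_b <- prior_lists(wl_b, bl)
    fit <- withCallingHandlers(
      hc_search(data_b, priors = priors_b, config = config$search),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      })
    dags[[b]] <- fit$dag
    wls[[b]] <- wl_b
  }
  if (n_warn > 0) {
    warning(n_warn, " scoring degeneracy warning(s) across bootstrap fits")
  }
  structure(list(dags = dags, B = config$B, whitelists = wls),
            class = "dag_ensemble")
}

## draw a fraction of whitelist edges, rejecting cyclic subsets
subsample_whitelist <- function(wl, fraction, nodes) {
  if (is.null(wl) || nrow(wl) == 0 || fraction >= 1) return(wl)
  if (fraction <= 0) return(NULL)
  m <- max(1L, round(fraction * nrow(wl)))
  for (try in seq_len(100L)) {
    sub <- wl[sample.int(nrow(wl), m), , drop = FALSE]
    ok <- tryCatch({ dag(nodes, sub); TRUE }, error = function(e) FALSE)
    if (ok) return(sub)
  }
  ## drop edges until acyclic, keeping the earliest-drawn ones
  warning("cyclic whitelist subsets after 100 draws; dropping edges")
  keep <- sub[0, , drop = FALSE]
  for (r in seq_len(nrow(sub))) {
    cand <- rbind(keep, sub[r, , drop = FALSE])
    if (tryCatch({ dag(nodes, cand); TRUE }, error = function(e) FALSE)) {
      keep <- cand
    }
  }
  keep
}

#' @export
print.dag_ensemble <- function(x, ...) {
  cat("dag_ensemble: B =", x$B, "DAGs on",
    length(x$dags[[1]]$nodes), "nodes; mean edges",
    format(mean(vapply(x$dags, n_edges, 0))), "\n")
  invisible(x)
}

#' Ensemble edge frequencies
#'
#' `f[i, j]` is the fraction of ensemble members containing the directed
#' edge i -> j. The generalized selection frequency is
#' `gp[i, j] = f[i, j] + f[j, i] / 2`: the reversed direction counts half,
#' because under the structural Hamming distance a reversal costs one unit
#' while a deletion-plus-nothing also costs one. `pair_mass` is
#' the total edge mass over unordered pairs, the additive constant of the
#' aggregation score.
#'
#' @param ens a `dag_ensemble` (or plain list of `dag`s on a common node
#'   set).
#' @return An `edge_frequency`: list with matrices `f`, `gp`, scalar
#'   `pair_mass`, and `B`.
#' @export
edge_frequencies <- function(ens) {
  dags <- if (inherits(ens, "dag_ensemble")) ens$dags else ens
  if (length(dags) == 0) stop("empty ensemble")
  nodes <- dags[[1]]$nodes
  for (g in dags) {
    if (!identical(g$nodes, nodes)) stop("ensemble members must share nodes")
  }
  f <- Reduce(`+`, lapply(dags, function(g) g$A * 1)) / length(dags)
  gp <- f + t(f) / 2
  structure(list(f = f, gp = gp, pair_mass = sum(f), B = length(dags),
                 nodes = nodes),
            class = "edge_frequency")
}

#' Aggregation score of a candidate DAG against an ensemble
#'
#' The mean structural Hamming distance from `dag` to the ensemble
#' members, computed in closed form from the edge frequencies:
#' `sum over edges e of dag of (1 - 2 gp_e) + C`, where `C = pair_mass`.
#' The closed form equals `mean_b shd(dag, G_b)` exactly, so an edge
#' lowers the score iff its generalized selection frequency exceeds 1/2.
#'
#' @param dag a `dag` on the ensemble's node set.
#' @param freq an [edge_frequencies()] object.
#' @return Numeric score (lower = closer to the ensemble).
#' @export
aggregation_score <- function(dag, freq) {
  if (!identical(dag$nodes, freq$nodes)) {
    stop("dag nodes must match ensemble nodes")
  }
  sum((1 - 2 * freq$gp)[dag$A]) + freq$pair_mass
}

#' Aggregate an ensemble into a consensus DAG
#'
#' Hill-climbs on the aggregation score, starting from the whitelist-only
#' graph (empty without priors), with the same add/delete/reverse moves,
#' constraint rules and deterministic tie-breaking as [hc_search()]. Since
#' the edge term of the score is `1 - 2 gp_e`, an addition improves iff
#' `gp > 1/2`; the search still runs over all three move kinds so that
#' direction conflicts are resolved through reversals under the acyclicity
#' constraint.
#'
#' @param ens a `dag_ensemble` or list of `dag`s.
#' @param priors a [prior_lists()] applied to the consensus search, or
#'   `NULL`.
#' @param config a [search_config()] (only `max_steps` and `tol` are
#'   used).
#' @return A `dag`: a local minimum of the aggregation score containing
#'   every whitelist edge and no blacklist edge.
#' @export
aggregate_dags <- function(ens, priors = NULL, config = search_config()) {
  freq <- edge_frequencies(ens)
  nodes <- freq$nodes
  p <- length(nodes)
  masks <- prior_masks(priors, nodes)
  A <- masks$white
  dimnames(A) <- list(nodes, nodes)
  validate_dag(structure(list(nodes = nodes, A = A), class = "dag"))
  reach <- transitive_closure(A)
  dA <- 1 - 2 * freq$gp          # delta of adding u -> v (static)
  eye <- diag(p) > 0
  steps <- 0L
  while (steps < config$max_steps) {
    addOK <- !A & !t(A) & !masks$black & !t(reach) & !eye
    delOK <- A & !masks$white
    ## a reversal is acyclic-safe iff no second directed path u ~> v
    second <- ((A * 1) %*% (reach * 1)) > 0
    revOK <- delOK & !t(masks$black) & !second
    cand <- list(
      list(kind = "add", D = ifelse(addOK, dA, Inf)),
      list(kind = "delete", D = ifelse(delOK, -dA, Inf)),
      list(kind = "reverse", D = ifelse(revOK, t(dA) - dA, Inf)))
    best <- NULL
    for (cc in cand) {
      m <- suppressWarnings(min(cc$D))
      if (is.finite(m) && (is.null(best) || m < best$delta)) {
        idx <- which(cc$D == m, arr.ind = TRUE)
        idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
        best <- list(kind = cc$kind, delta = m,
                     u = idx[1, 1], v = idx[1, 2])
      }
    }
    if (is.null(best) || !(best$delta < -config$tol)) break
    u <- best$u; v <- best$v
    if (best$kind == "add") {
      A[u, v] <- TRUE
      reach <- close_after_add(reach, A, u, v)
    } else if (best$kind == "delete") {
      A[u, v] <- FALSE
      reach <- transitive_closure(A)
    } else {
      A[u, v] <- FALSE
      A[v, u] <- TRUE
      reach <- transitive_closure(A)
    }
    steps <- steps + 1L
  }
  new_dag(nodes, A)
}

#' Bootstrap-aggregated DAG learning
#'
#' The full pipeline: learn one DAG per bootstrap resample with the
#' BIC-scored hill-climbing search, then aggregate the ensemble into the
#' consensus DAG minimizing the mean structural Hamming distance. When
#' `whitelist_fraction = 1` the whitelist also constrains the aggregation;
#' with partial whitelists the priors only guide the individual bootstrap
#' fits, so prior edges that the data do not support tend to be filtered
#' out at the aggregation step. The blacklist is enforced throughout.
#'
#' @inheritParams learn_ensemble
#' @return A `dag_bag`: list with `dag` (consensus), `freq`
#'   ([edge_frequencies()]), and `ensemble`.
#' @examples
#' mech <- random_mechanism(sim_config(p_continuous = 6, n_edges = 5, seed = 7))
#' d <- simulate_dataset(mech, n = 200, seed = 8)
#' fit <- bagged_dag(d, config = bag_config(B = 10, seed = 9))
#' skeleton_metrics(fit$dag, mech$dag)
#' @export
bagged_dag <- function(data, priors = NULL, config = bag_config()) {
  ens <- learn_ensemble(data, priors, config)
  freq <- edge_frequencies(ens)
  agg_priors <- priors
  if (!is.null(priors) && config$whitelist_fraction < 1) {
    agg_priors <- prior_lists(NULL, priors$blacklist)
  }
  consensus <- aggregate_dags(ens, agg_priors, config$search)
  structure(list(dag = consensus, freq = freq, ensemble = ens,
                 config = config),
            class = "dag_bag")
}

#' @export
print.dag_bag <- function(x, ...) {
  cat("dag_bag: consensus of B =", x$freq$B, "bootstrap DAGs;",
      n_edges(x$dag), "edges\n")
  invisible(x)
}

#' Consensus edge table
#'
#' One row per consensus edge with its ensemble support: forward and
#' reverse selection frequencies and the generalized selection frequency.
#'
#' @param bag a `dag_bag` from [bagged_dag()].
#' @return Data frame with columns `parent`, `child`, `f_forward`,
#'   `f_reverse`, `gp`.
#' @export
consensus_edges <- function(bag) {
  e <- dag_edges(bag$dag)
  i <- node_index(e$parent, bag$dag$nodes)
  j <- node_index(e$child, bag$dag$nodes)
  e$f_forward <- bag$freq$f[cbind(i, j)]
  e$f_reverse <- bag$freq$f[cbind(j, i)]
  e$gp <- bag$freq$gp[cbind(i, j)]
  e
}

#' Write the consensus edge table as TSV
#' @param bag a `dag_bag`.
#' @param path output path.
#' @export
write_consensus <- function(bag, path) {
  utils::write.table(consensus_edges(bag), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
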