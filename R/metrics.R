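#' Edge-recovery metrics
#'
#' Power (true positive rate) is the fraction of true edges recovered,
#' `n_correct / n_true`; FDR is the fraction of estimated edges that are
#' false, `(n_est - n_correct) / n_est`; F1 is the harmonic mean
#' `2 * precision * recall / (precision + recall)` with
#' `precision = 1 - FDR` and `recall = power`. Zero denominators yield 0
#' (no discoveries means no false discoveries; F1 is 0 whenever nothing
#' correct was found).
#'
#' `skeleton_metrics` scores undirected pair recovery: an estimated pair is
#' correct iff the truth has an edge between the two nodes in either
#' direction. `directed_mixed_metrics` restricts both graphs to ordered
#' pairs with one continuous and one binary endpoint and requires the exact
#' directed edge to be present in the truth.
#'
#' @param est,truth `dag` objects on the same ordered node set.
#' @return A `metrics_report`: list with `subset`, `n_true`, `n_est`,
#'   `n_correct`, `power`, `fdr`, `f1`.
#' @examples
#' t <- dag(LETTERS[1:3], data.frame(parent = c("A", "B"), child = c("B", "C")))
#' e <- dag(LETTERS[1:3], data.frame(parent = "B", child = "A"))
#' skeleton_metrics(e, t)  # direction is ignored: power 0.5, fdr 0
#' @export
skeleton_metrics <- function(est, truth) {
  if (!identical(est$nodes, truth$nodes)) {
    stop("graphs must share the same ordered node set")
  }
  ue <- est$A | t(est$A)
  ut <- truth$A | t(truth$A)
  up <- upper.tri(ue)
  metrics_report("skeleton",
                 n_true = sum(ut[up]),
                 n_est = sum(ue[up]),
                 n_correct = sum((ue & ut)[up]))
}

#' @rdname skeleton_metrics
#' @param kinds per-node kind vector (`"continuous"`/`"binary"`), a
#'   `dag_dataset`, or a `dag_mechanism`.
#' @export
directed_mixed_metrics <- function(est, truth, kinds) {
  if (!identical(est$nodes, truth$nodes)) {
    stop("graphs must share the same ordered node set")
  }
  if (inherits(kinds, "dag_dataset") || inherits(kinds, "dag_mechanism")) {
    kinds <- kinds$kinds
  }
  if (length(kinds) != length(est$nodes)) stop("one kind per node required")
  mixed <- outer(kinds, kinds, `!=`)
  metrics_report("directed_mixed",
                 n_true = sum(truth$A & mixed),
                 n_est = sum(est$A & mixed),
                 n_correct = sum(est$A & truth$A & mixed))
}

metrics_report <- function(subset, n_true, n_est, n_correct) {
  power <- if (n_true > 0) n_correct / n_true else 0
  fdr <- if (n_est > 0) (n_est - n_correct) / n_est else 0
  precision <- 1 - fdr
  recall <- power
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(subset = subset, n_true = n_true, n_est = n_est,
                 n_correct = n_correct, power = power, fdr = fdr, f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s: power %.4f, FDR %.4f, F1 %.4f (%d/%d true, %d est)\n",
              x$subset, x$power, x$fdr, x$f1, x$n_correct, x$n_true,
              x$n_est))
  invisible(x)
}

#' Replicate-experiment harness
#'
#' Draws one mechanism from `sim`, then for each replicate simulates a
#' fresh dataset, runs the learner, and computes skeleton (and, when both
#' node kinds are present, directed mixed-pair) metrics. Reports the
#' per-replicate log plus means and standard deviations. Failed replicates
#' are recorded with their error message, never silently dropped. All
#' randomness derives from `seed`.
#'
#' @param sim a [sim_config()] (or a ready `dag_mechanism`).
#' @param n sample size per replicate.
#' @param learner a function `(data, seed) -> dag` (e.g. wrap
#'   [hc_search()] or [bagged_dag()]).
#' @param n_replicates number of independent replicates.
#' @param seed integer master seed.
#' @param log_path optional path for a JSON-lines per-replicate log.
#' @param summary_path optional path for the summary TSV.
#' @param redraw_mechanism when `TRUE`, a fresh mechanism (topology and
#'   coefficients) is drawn for every replicate, so the summary averages
#'   over generating graphs as well as over data; by default one mechanism
#'   is drawn and only the data are replicated.
#' @return List with `summary` (data frame of mean/sd per metric),
#'   `replicates` (per-replicate data frame), `failures`, `mechanism`.
#' @export
run_experiment <- function(sim, n, learner, n_replicates = 100L,
                           seed = 1L, log_path = NULL, summary_path = NULL,
                           redraw_mechanism = FALSE) {
  mech <- if (inherits(sim, "dag_mechanism")) sim else random_mechanism(sim)
  set.seed(seed)
  seeds <- matrix(sample.int(2^31 - 1, 3L * n_replicates), ncol = 3L)
  mixed <- length(unique(mech$kinds)) > 1
  rows <- list()
  failures <- list()
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      if (redraw_mechanism && !inherits(sim, "dag_mechanism")) {
        cfg <- sim
        cfg$seed <- seeds[r, 3]
        mech <- random_mechanism(cfg)
      }
      d <- simulate_dataset(mech, n, seed = seeds[r, 1])
      est <- learner(d, seeds[r, 2])
      sk <- skeleton_metrics(est, mech$dag)
      row <- data.frame(replicate = r, n_edges_est = n_edges(est),
                        power = sk$power, fdr = sk$fdr, f1 = sk$f1)
      if (mixed) {
        dm <- directed_mixed_metrics(est, mech$dag, mech$kinds)
        row$mixed_power <- dm$power
        row$mixed_fdr <- dm$fdr
        row$mixed_f1 <- dm$f1
      }
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(replicate = r,
                                                message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  replicates <- do.call(rbind, rows)
  metric_cols <- setdiff(names(replicates), "replicate")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(replicates[[m]]), 0),
    sd = vapply(metric_cols, function(m) stats::sd(replicates[[m]]), 0),
    row.names = NULL)
  if (!is.null(log_path)) {
    con <- file(log_path, "w")
    for (i in seq_len(nrow(replicates))) {
      writeLines(jsonlite::toJSON(as.list(replicates[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
    close(con)
  }
  if (!is.null(summary_path)) {
    utils::write.table(summary, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(summary = summary, replicates = replicates, failures = failures,
       mechanism = mech)
}

#' Ready-made learners for [run_experiment()]
#'
#' `hc_learner` wraps a single hill-climbing fit; `bag_learner` wraps the
#' bootstrap-aggregation pipeline. The replicate seed is threaded into the
#' learner's configuration.
#'
#' @param config a [search_config()] / [bag_config()].
#' @param priors a [prior_lists()] or `NULL`.
#' @return A function `(data, seed) -> dag`.
#' @export
hc_learner <- function(config = search_config(), priors = NULL) {
  function(data, seed) {
    hc_search(data, priors = priors, config = config)$dag
  }
}

#' @rdname hc_learner
#' @export
bag_learner <- function(config = bag_config(), priors = NULL) {
  function(data, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    bagged_dag(data, priors = priors, config = cfg)$dag
  }
}
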