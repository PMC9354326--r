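#' Simulation configuration
#'
#' Describes a data-generating mechanism: a DAG over continuous and binary
#' nodes, Gaussian linear mechanisms for continuous children, logistic
#' mechanisms for binary children, and signal-to-noise calibrated residual
#' scales.
#'
#' @param p_continuous,p_binary node counts by kind.
#' @param n_edges number of edges of a random topology (ignored when
#'   `edges` is given).
#' @param edges optional explicit edge list (two-column parent/child of
#'   node names); must be acyclic.
#' @param coef_range magnitude range of linear coefficients; each drawn
#'   uniformly from `[-hi, -lo] U [lo, hi]` (default `[0.3, 0.5]`).
#' @param snr_range per-node signal-to-noise-ratio range (default
#'   `[0.5, 1.5]`): the ratio of the standard deviation of the parental
#'   signal to that of the noise in the linear mechanism.
#' @param gamma_range magnitude range of logistic coefficients (default
#'   `[1, 2]`, strong enough for parent effects on a binary node to be
#'   detectable at n of about 100).
#' @param gamma0 logistic intercept (default 0: balanced classes for root
#'   binary nodes).
#' @param noise_family residual distribution of the linear mechanism:
#'   `"gaussian"`, `"t_df3"`, `"t_df5"`, or `"gamma_1_2_centered"`
#'   (mean-centered Gamma with shape 1 and scale 2). All are standardized
#'   to unit variance by their analytic standard deviation before the
#'   SNR-calibrated scale is applied.
#' @param seed integer seed for mechanism generation.
#' @export
sim_config <- function(p_continuous, p_binary = 0L, n_edges = 0L,
                       edges = NULL, coef_range = c(0.3, 0.5),
                       snr_range = c(0.5, 1.5), gamma_range = c(1, 2),
                       gamma0 = 0, noise_family = "gaussian", seed = 1L) {
  p <- p_continuous + p_binary
  if (is.null(edges) && n_edges > p * (p - 1) / 2) {
    stop("n_edges exceeds the maximum for an acyclic graph")
  }
  if (!noise_family %in% names(noise_families)) {
    stop("unknown noise family '", noise_family, "'")
  }
  structure(list(p_continuous = as.integer(p_continuous),
                 p_binary = as.integer(p_binary),
                 n_edges = as.integer(n_edges), edges = edges,
                 coef_range = coef_range, snr_range = snr_range,
                 gamma_range = gamma_range, gamma0 = gamma0,
                 noise_family = noise_family, seed = as.integer(seed)),
            class = "sim_config")
}

## residual distributions, standardized to unit variance analytically
noise_families <- list(
  gaussian = function(n) stats::rnorm(n),
  t_df3 = function(n) stats::rt(n, df = 3) / sqrt(3),
  t_df5 = function(n) stats::rt(n, df = 5) / sqrt(5 / 3),
  gamma_1_2_centered = function(n) (stats::rgamma(n, shape = 1, scale = 2) - 2) / 2
)

#' Draw a random mechanism
#'
#' Samples a uniform permutation as topological order, draws `n_edges`
#' distinct order-respecting node pairs, then draws edge coefficients:
#' linear coefficients (into continuous children) uniformly from
#' `[-hi, -lo] U [lo, hi]` of `coef_range`, logistic coefficients (into
#' binary children) likewise from `gamma_range`, and one target SNR per
#' continuous node from `snr_range`. Binary nodes are interleaved at
#' random positions of the order, so either kind may be parent or child.
#'
#' @param config a [sim_config()].
#' @return A `dag_mechanism`: list with `dag`, `kinds`, coefficient matrix
#'   `coef` (`coef[j, v]` is the effect of parent j on child v), `gamma0`,
#'   `snr`, `noise_family`.
#' @export
random_mechanism <- function(config) {
  set.seed(config$seed)
  pc <- config$p_continuous
  pb <- config$p_binary
  p <- pc + pb
  nodes <- c(if (pc > 0) paste0("X", seq_len(pc)),
             if (pb > 0) paste0("Y", seq_len(pb)))
  kinds <- stats::setNames(rep(c("continuous", "binary"), c(pc, pb)), nodes)
  if (!is.null(config$edges)) {
    g <- dag(nodes, config$edges)
  } else {
    ord <- sample.int(p)                    # ord[k] = node at position k
    m <- config$n_edges
    if (m > 0) {
      pairs <- which(upper.tri(matrix(0, p, p)))  # position pairs a < b
      pick <- sample(pairs, m)
      a <- (pick - 1L) %% p + 1L
      b <- (pick - 1L) %/% p + 1L
      g <- dag(nodes, cbind(nodes[ord[a]], nodes[ord[b]]))
    } else {
      g <- empty_dag(nodes)
    }
  }
  finish_mechanism(g, kinds, config)
}

## draw coefficients and SNR targets for a fixed topology
finish_mechanism <- function(g, kinds, config) {
  nodes <- g$nodes
  p <- length(nodes)
  coef <- matrix(0, p, p, dimnames = list(nodes, nodes))
  draw_mag <- function(k, range) {
    stats::runif(k, range[1], range[2]) * sample(c(-1, 1), k, replace = TRUE)
  }
  for (v in seq_len(p)) {
    pa <- which(g$A[, v])
    if (length(pa) == 0) next
    rng <- if (kinds[v] == "continuous") config$coef_range else config$gamma_range
    coef[pa, v] <- draw_mag(length(pa), rng)
  }
  snr <- stats::setNames(
    stats::runif(p, config$snr_range[1], config$snr_range[2]), nodes)
  gamma0 <- stats::setNames(rep(config$gamma0, p), nodes)
  structure(list(dag = g, kinds = kinds, coef = coef, gamma0 = gamma0,
                 snr = snr, noise_family = config$noise_family,
                 config = config),
            class = "dag_mechanism")
}

#' @export
print.dag_mechanism <- function(x, ...) {
  cat("dag_mechanism: ", length(x$dag$nodes), " nodes (",
      sum(x$kinds == "continuous"), " continuous, ",
      sum(x$kinds == "binary"), " binary), ", n_edges(x$dag),
      " edges, noise ", x$noise_family, "\n", sep = "")
  invisible(x)
}

#' Mixed-motif mechanism fixture
#'
#' A named topology for low-dimensional mixed-node experiments: random
#' continuous-only DAG plus one binary node that is the child of two
#' continuous parents and the parent of one continuous child (the motif of
#' a clinical outcome embedded among biomarkers). With the defaults the
#' graph has 11 nodes and 8 edges.
#'
#' @param p_continuous number of continuous nodes (default 10).
#' @param n_extra_edges continuous-continuous edges beside the motif's
#'   three (default 5).
#' @param seed integer seed.
#' @param ... further arguments passed to [sim_config()].
#' @return A `dag_mechanism`.
#' @export
mixed_motif_mechanism <- function(p_continuous = 10L, n_extra_edges = 5L,
                                  seed = 1L, ...) {
  config <- sim_config(p_continuous = p_continuous, p_binary = 1L,
                       n_edges = n_extra_edges + 3L, seed = seed, ...)
  set.seed(seed)
  pc <- as.integer(p_continuous)
  xn <- paste0("X", seq_len(pc))
  yn <- "Y1"
  nodes <- c(xn, yn)
  kinds <- stats::setNames(rep(c("continuous", "binary"), c(pc, 1L)), nodes)
  ord <- sample(xn)                        # topological order of X's
  ## continuous backbone
  edges <- NULL
  if (n_extra_edges > 0) {
    pairs <- which(upper.tri(matrix(0, pc, pc)))
    pick <- sample(pairs, n_extra_edges)
    a <- (pick - 1L) %% pc + 1L
    b <- (pick - 1L) %/% pc + 1L
    edges <- cbind(ord[a], ord[b])
  }
  ## motif: two early parents -> Y1 -> one later child
  trio <- sort(sample.int(pc, 3L))
  edges <- rbind(edges,
                 cbind(ord[trio[1:2]], yn),
                 cbind(yn, ord[trio[3]]))
  g <- dag(nodes, edges)
  finish_mechanism(g, kinds, config)
}

#' Simulate a dataset from a mechanism
#'
#' Nodes are generated in topological order. A parentless continuous node
#' is standard normal. A continuous node with parents is the linear
#' combination of its parents (binary parents enter as 0/1) plus scaled
#' noise: the noise distribution is the mechanism's family standardized to
#' unit variance, and its scale is set so that the ratio of the realized
#' (empirical) signal standard deviation to the noise scale equals the
#' node's target SNR. A binary node is Bernoulli with success probability
#' `plogis(gamma0 + sum gamma_j * parent_j)`.
#'
#' @param mech a `dag_mechanism`.
#' @param n sample size.
#' @param seed integer seed.
#' @return A [make_dataset()] object; the attribute `"truth"` holds the
#'   generating `dag`.
#' @export
simulate_dataset <- function(mech, n, seed = 1L) {
  set.seed(seed)
  g <- mech$dag
  nodes <- g$nodes
  p <- length(nodes)
  ord <- topological_order(g$A)
  X <- matrix(0, n, p, dimnames = list(NULL, nodes))
  rnoise <- noise_families[[mech$noise_family]]
  for (v in ord) {
    pa <- which(g$A[, v])
    if (mech$kinds[v] == "continuous") {
      if (length(pa) == 0) {
        X[, v] <- stats::rnorm(n)
      } else {
        signal <- as.vector(X[, pa, drop = FALSE] %*% mech$coef[pa, v])
        sd_sig <- stats::sd(signal)
        sigma <- if (sd_sig > 0) sd_sig / mech$snr[v] else 1
        X[, v] <- signal + sigma * rnoise(n)
      }
    } else {
      eta <- mech$gamma0[v] +
        if (length(pa) > 0) {
          as.vector(X[, pa, drop = FALSE] %*% mech$coef[pa, v])
        } else 0
      X[, v] <- stats::rbinom(n, 1L, stats::plogis(eta))
    }
  }
  d <- make_dataset(X, kinds = mech$kinds)
  attr(d, "truth") <- g
  d
}
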