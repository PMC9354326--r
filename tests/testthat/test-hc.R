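test_that("eligible-operation enumeration follows the move rules", {
  g3 <- empty_dag(c("A", "B", "C"))
  ops <- enumerate_eligible(g3)
  expect_length(ops, 6L)   # p(p-1) ordered pairs, all adds
  expect_true(all(vapply(ops, `[[`, "", "kind") == "add"))

  chain <- dag(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
  ops <- enumerate_eligible(chain)
  sigs <- vapply(ops, function(o) paste(o$kind, o$from, o$to), "")
  expect_false("add C A" %in% sigs)       # would close a cycle
  expect_true("add A C" %in% sigs)
  expect_true(all(c("reverse A B", "reverse B C") %in% sigs))

  pri <- prior_lists(whitelist = data.frame(parent = "A", child = "B"))
  ab <- dag(c("A", "B"), cbind("A", "B"))
  sigs <- vapply(enumerate_eligible(ab, priors = pri),
                 function(o) paste(o$kind, o$from, o$to), "")
  expect_false(any(c("delete A B", "reverse A B") %in% sigs))
})

test_that("hill climbing recovers an identifiable v-structure", {
  mech <- random_mechanism(sim_config(
    p_continuous = 3,
    edges = data.frame(parent = c("X1", "X2"), child = c("X3", "X3")),
    seed = 61))
  d <- simulate_dataset(mech, 2000, seed = 62)
  fit <- hc_search(d)
  expect_true(fit$local_min)
  e <- dag_edges(fit$dag)
  expect_setequal(paste(e$parent, e$child), c("X1 X3", "X2 X3"))
})

test_that("whitelist and blacklist contracts hold in the search output", {
  set.seed(63)
  null_data <- make_dataset(matrix(rnorm(400), 100, 4,
                                   dimnames = list(NULL, LETTERS[1:4])))
  pri <- prior_lists(whitelist = data.frame(parent = "A", child = "B"))
  fit <- hc_search(null_data, priors = pri)
  expect_true(fit$dag$A["A", "B"])

  all_pairs <- subset(expand.grid(parent = LETTERS[1:4],
                                  child = LETTERS[1:4]),
                      parent != child)
  fit0 <- hc_search(null_data, priors = prior_lists(blacklist = all_pairs))
  expect_equal(n_edges(fit0$dag), 0L)
  expect_equal(nrow(fit0$trace), 0L)

  bl <- data.frame(parent = "A", child = "B")
  fit1 <- hc_search(null_data, priors = prior_lists(blacklist = bl))
  expect_false(fit1$dag$A["A", "B"])

  bad_init <- empty_dag(LETTERS[1:4])
  expect_error(hc_search(null_data, init = bad_init, priors = pri),
               "whitelist")
})

test_that("the trace is strictly decreasing and replays through the R
           operations to the same graph and score", {
  d <- mixed_fixture(n = 120, seed = 64)
  fit <- hc_search(d, config = search_config(max_parents = Inf))
  expect_true(all(fit$trace$delta < 0))
  expect_equal(fit$trace$total,
               cumsum(fit$trace$delta) + sum(score_graph(d, empty_dag(d$nodes))$node_scores),
               tolerance = 1e-8)

  g <- empty_dag(d$nodes)
  idx <- reachability(g)
  for (i in seq_len(nrow(fit$trace))) {
    st <- apply_operation(g, operation(fit$trace$kind[i], fit$trace$from[i],
                                       fit$trace$to[i]), idx)
    g <- st$dag
    idx <- st$index
    expect_acyclic(g)
  }
  expect_identical(g$A, fit$dag$A)
  expect_equal(score_graph(d, g)$total, fit$score, tolerance = 1e-8)
})

test_that("with tol = 0 and no binding cap the output is a local minimum", {
  d <- mixed_fixture(n = 100, seed = 65)
  fit <- hc_search(d, config = search_config(max_parents = Inf))
  expect_true(fit$local_min)
  cache <- score_graph(d, fit$dag)
  idx <- reachability(fit$dag)
  deltas <- vapply(enumerate_eligible(fit$dag, idx), function(op) {
    as.numeric(suppressWarnings(score_delta(d, fit$dag, cache, op)))
  }, 0)
  expect_gte(min(deltas), -1e-9)
})

test_that("the parent-set cap binds the learned in-degrees", {
  set.seed(66)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("V", 1:8)))
  X[, 8] <- X[, 1:5] %*% rep(0.8, 5) + rnorm(60, sd = 0.3)
  d <- make_dataset(X)
  fit2 <- hc_search(d, config = search_config(max_parents = 2))
  expect_lte(max(colSums(fit2$dag$A)), 2)
})
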