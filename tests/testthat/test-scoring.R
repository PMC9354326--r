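test_that("continuous score matches closed forms and the lm oracle", {
  d <- make_dataset(cbind(x = c(1, 2, 3)))
  expect_equal(score_continuous_node(d, "x", character(0)), 3 * log(2 / 3),
               tolerance = 1e-12)

  set.seed(21)
  dd <- mixed_fixture(n = 60)
  cont <- which(dd$kinds == "continuous")
  for (v in cont) {
    others <- setdiff(seq_along(dd$nodes), v)
    for (k in 0:3) {
      P <- others[seq_len(k)]
      expect_equal(score_continuous_node(dd, v, P),
                   lm_score(dd, v, P), tolerance = 1e-8)
      expect_equal(score_continuous_node(dd, v, P, form = "literal"),
                   lm_score(dd, v, P, form = "literal"), tolerance = 1e-8)
    }
  }
})

test_that("a perfectly determined continuous child is floored and flagged", {
  set.seed(3)
  x <- rnorm(30)
  d <- make_dataset(cbind(a = x, b = 2 * x))
  expect_warning(s <- score_continuous_node(d, "b", "a"), "floored")
  expect_true(is.finite(s))
  expect_lt(s, score_continuous_node(d, "b", character(0)))
})

test_that("binary score matches closed forms and the glm oracle", {
  d <- make_dataset(cbind(y = c(1, 1, 0, 0)))
  expect_equal(score_binary_node(d, "y", character(0)), -8 * log(0.5),
               tolerance = 1e-10)

  set.seed(22)
  dd <- mixed_fixture(n = 80)
  for (k in 0:2) {
    P <- c("X1", "X2")[seq_len(k)]
    expect_equal(score_binary_node(dd, "Y", P), glm_score(dd, 3, P),
                 tolerance = 1e-6)
  }
})

test_that("separation and single-class columns degrade gracefully", {
  d <- make_dataset(cbind(y = c(1, 1, 0, 0), x = c(5, 4, -4, -5)),
                    kinds = c("binary", "continuous"))
  expect_warning(s <- score_binary_node(d, "y", "x"),
                 "separation|ridge")
  expect_true(is.finite(s))

  d1 <- make_dataset(cbind(y = rep(1, 10), x = rnorm(10)),
                     kinds = c("binary", "continuous"))
  expect_warning(s1 <- score_binary_node(d1, "y", character(0)),
                 "single-class")
  expect_equal(s1, 0, tolerance = 1e-6)
})

test_that("larger parent sets never increase the binary deviance, and the
           penalty grows by exactly log(n)", {
  set.seed(23)
  dd <- mixed_fixture(n = 70)
  n <- dd$n
  dev <- function(P) score_binary_node(dd, "Y", P) - length(P) * log(n)
  expect_lte(dev(c("X1")), dev(character(0)) + 1e-8)
  expect_lte(dev(c("X1", "X2")), dev(c("X1")) + 1e-8)
  expect_lte(dev(c("X1", "X2", "X3")), dev(c("X1", "X2")) + 1e-8)
  ## same penalty increment for a continuous child
  s0 <- score_continuous_node(dd, "X2", "X1")
  s1 <- score_continuous_node(dd, "X2", c("X1", "X3"))
  rssdev <- function(P) score_continuous_node(dd, "X2", P) -
    length(P) * log(n)
  expect_lte(rssdev(c("X1", "X3")), rssdev("X1") + 1e-8)
})

test_that("graph score decomposes into node scores", {
  set.seed(24)
  dd <- mixed_fixture(n = 60)
  g <- dag(dd$nodes, data.frame(parent = c("X1", "X1", "X2", "Y"),
                                child = c("X2", "Y", "Y", "X3")))
  sc <- score_graph(dd, g)
  expect_equal(sc$total, sum(sc$node_scores))
  expect_equal(unname(sc$node_scores["X2"]),
               score_continuous_node(dd, "X2", "X1"))
  expect_equal(unname(sc$node_scores["Y"]),
               score_binary_node(dd, "Y", c("X1", "X2")))
  ## empty graph on continuous columns: sum of intercept-only deviances
  dc <- make_dataset(matrix(rnorm(200), 50, 4,
                            dimnames = list(NULL, paste0("V", 1:4))))
  sc0 <- score_graph(dc, empty_dag(dc$nodes))
  expect_equal(sc0$total,
               sum(vapply(1:4, function(v) lm_score(dc, v, integer(0)), 0)),
               tolerance = 1e-8)
})

test_that("score_delta equals the full-recompute difference for every move", {
  set.seed(25)
  dd <- mixed_fixture(n = 60)
  g <- empty_dag(dd$nodes)
  idx <- reachability(g)
  cache <- score_graph(dd, g)
  for (k in 1:20) {
    ops <- enumerate_eligible(g, idx)
    op <- ops[[sample.int(length(ops), 1)]]
    delta <- suppressWarnings(score_delta(dd, g, cache, op))
    st <- apply_operation(g, op, idx)
    full <- suppressWarnings(score_graph(dd, st$dag))
    expect_equal(as.numeric(delta), full$total - cache$total,
                 tolerance = 1e-8)
    g <- st$dag
    idx <- st$index
    cache <- attr(delta, "cache")
  }
  ## add then delete restores the original score
  g0 <- empty_dag(dd$nodes)
  c0 <- score_graph(dd, g0)
  d1 <- score_delta(dd, g0, c0, operation("add", "X1", "X3"))
  st1 <- apply_operation(g0, operation("add", "X1", "X3"))
  d2 <- score_delta(dd, st1$dag, attr(d1, "cache"),
                    operation("delete", "X1", "X3"))
  expect_equal(as.numeric(d1) + as.numeric(d2), 0, tolerance = 1e-10)
})
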