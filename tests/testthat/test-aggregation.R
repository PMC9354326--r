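four_member_ensemble <- function() {
  nodes <- c("A", "B")
  list(dag(nodes, cbind("A", "B")), dag(nodes, cbind("A", "B")),
       dag(nodes, cbind("B", "A")), empty_dag(nodes))
}

test_that("edge frequencies and gp match the worked example", {
  freq <- edge_frequencies(four_member_ensemble())
  expect_equal(freq$f["A", "B"], 0.5)
  expect_equal(freq$f["B", "A"], 0.25)
  expect_equal(freq$gp["A", "B"], 0.625)
  expect_equal(freq$gp["B", "A"], 0.5)
  expect_equal(freq$pair_mass, 0.75)
  expect_error(edge_frequencies(list()), "empty")
})

test_that("gp obeys its bounds and the per-pair 3/2 identity", {
  set.seed(31)
  for (rep in 1:10) {
    p <- sample(3:6, 1)
    nodes <- LETTERS[1:p]
    ens <- replicate(sample(2:8, 1), random_dag_r(p, 0.4, nodes),
                     simplify = FALSE)
    freq <- edge_frequencies(ens)
    expect_true(all(freq$gp >= 0 & freq$gp <= 1))
    expect_true(all(freq$f + t(freq$f) <= 1 + 1e-12))
    expect_equal(freq$gp + t(freq$gp), 1.5 * (freq$f + t(freq$f)))
  }
})

test_that("the aggregation score equals the brute-force mean SHD", {
  ens <- four_member_ensemble()
  freq <- edge_frequencies(ens)
  nodes <- c("A", "B")
  expect_equal(aggregation_score(empty_dag(nodes), freq), freq$pair_mass)
  gab <- dag(nodes, cbind("A", "B"))
  expect_equal(aggregation_score(gab, freq), 0.5)
  expect_equal(mean(vapply(ens, shd, 0, g1 = gab)), 0.5)
})

test_that("aggregation reproduces the enumerable two-node consensus", {
  ens <- four_member_ensemble()
  cons <- aggregate_dags(ens)
  expect_equal(dag_edges(cons),
               data.frame(parent = "A", child = "B",
                          stringsAsFactors = FALSE))
  ## identical members: the consensus is that member
  set.seed(32)
  g <- random_dag_r(5, 0.4)
  cons2 <- aggregate_dags(replicate(6, g, simplify = FALSE))
  expect_identical(cons2$A, g$A)
  ## a 30%-frequency, never-reversed edge is dropped (gp < 1/2)
  nodes <- c("A", "B")
  ens3 <- c(replicate(3, dag(nodes, cbind("A", "B")), simplify = FALSE),
            replicate(7, empty_dag(nodes), simplify = FALSE))
  expect_equal(n_edges(aggregate_dags(ens3)), 0L)
})

test_that("ensemble learning is seeded, degenerates to plain HC, and
           honors whitelists", {
  d <- mixed_fixture(n = 60, seed = 33)
  cfg1 <- bag_config(B = 1, seed = 5, resample = FALSE)
  ens1 <- learn_ensemble(d, config = cfg1)
  expect_identical(ens1$dags[[1]]$A, hc_search(d)$dag$A)

  cfg <- bag_config(B = 5, seed = 9)
  e1 <- learn_ensemble(d, config = cfg)
  e2 <- learn_ensemble(d, config = cfg)
  expect_identical(lapply(e1$dags, `[[`, "A"), lapply(e2$dags, `[[`, "A"))

  pri <- prior_lists(whitelist = data.frame(parent = "X1", child = "X3"))
  ens <- learn_ensemble(d, priors = pri, config = bag_config(B = 4, seed = 2))
  expect_true(all(vapply(ens$dags, function(g) g$A["X1", "X3"], NA)))

  bag <- bagged_dag(d, priors = pri, config = bag_config(B = 4, seed = 2))
  expect_true(bag$dag$A["X1", "X3"])
})

test_that("cyclic prior subsets are re-drawn per bootstrap", {
  d <- mixed_fixture(n = 50, seed = 34)
  wl <- data.frame(parent = c("X1", "X3"), child = c("X3", "X1"))
  cfg <- bag_config(B = 6, seed = 3, whitelist_fraction = 0.5)
  ens <- suppressWarnings(learn_ensemble(d, priors = prior_lists(wl),
                                         config = cfg))
  for (b in seq_len(cfg$B)) {
    wb <- ens$whitelists[[b]]
    expect_equal(nrow(wb), 1L)
    expect_true(ens$dags[[b]]$A[wb$parent, wb$child])
  }
})

test_that("a bag of size one with resampling off reduces to plain HC", {
  d <- mixed_fixture(n = 60, seed = 35)
  bag <- bagged_dag(d, config = bag_config(B = 1, seed = 1, resample = FALSE))
  expect_identical(bag$dag$A, hc_search(d)$dag$A)
})

test_that("consensus edge table reports ensemble support", {
  d <- mixed_fixture(n = 80, seed = 36)
  bag <- bagged_dag(d, config = bag_config(B = 8, seed = 4))
  ce <- consensus_edges(bag)
  expect_true(all(ce$gp > 0.5))
  expect_equal(ce$gp, ce$f_forward + ce$f_reverse / 2)
})
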