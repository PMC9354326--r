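test_that("random mechanisms respect the configured ranges and are seeded", {
  cfg <- sim_config(p_continuous = 12, p_binary = 3, n_edges = 20, seed = 71)
  mech <- random_mechanism(cfg)
  expect_equal(n_edges(mech$dag), 20L)
  expect_acyclic(mech$dag)
  ## linear coefficients into continuous children: |beta| in [0.3, 0.5]
  for (v in which(mech$kinds == "continuous")) {
    b <- mech$coef[mech$dag$A[, v], v]
    if (length(b)) expect_true(all(abs(b) >= 0.3 & abs(b) <= 0.5))
  }
  for (v in which(mech$kinds == "binary")) {
    g <- mech$coef[mech$dag$A[, v], v]
    if (length(g)) expect_true(all(abs(g) >= 1 & abs(g) <= 2))
  }
  expect_true(all(mech$snr >= 0.5 & mech$snr <= 1.5))
  mech2 <- random_mechanism(cfg)
  expect_identical(mech$dag$A, mech2$dag$A)
  expect_identical(mech$coef, mech2$coef)

  expect_equal(n_edges(random_mechanism(sim_config(5, seed = 1))$dag), 0L)
  expect_error(sim_config(3, n_edges = 10), "exceeds")
  expect_error(sim_config(3, noise_family = "cauchy"), "noise family")
})

test_that("parentless continuous nodes are standard normal", {
  mech <- random_mechanism(sim_config(p_continuous = 2, seed = 72))
  d <- simulate_dataset(mech, 1e5, seed = 73)
  for (v in 1:2) {
    expect_lt(abs(mean(d$values[, v])), 3 / sqrt(1e5))
    expect_lt(abs(sd(d$values[, v]) - 1), 3 / sqrt(2e5) + 1e-3)
  }
})

test_that("the realized signal-to-noise ratio tracks its target", {
  cfg <- sim_config(p_continuous = 6, n_edges = 8, seed = 74)
  mech <- random_mechanism(cfg)
  d <- simulate_dataset(mech, 5000, seed = 75)
  for (v in seq_along(mech$dag$nodes)) {
    pa <- which(mech$dag$A[, v])
    if (length(pa) == 0) next
    signal <- d$values[, pa, drop = FALSE] %*% mech$coef[pa, v]
    noise <- d$values[, v] - signal
    ratio <- sd(signal) / sd(noise)
    expect_equal(unname(ratio), unname(mech$snr[v]), tolerance = 0.1)
    expect_true(ratio > 0.4 && ratio < 1.7)
  }
})

test_that("binary nodes follow the logistic mechanism", {
  mech <- random_mechanism(sim_config(p_continuous = 0, p_binary = 1,
                                      seed = 76))
  d <- simulate_dataset(mech, 2e4, seed = 77)
  expect_true(all(d$values %in% c(0, 1)))
  expect_equal(mean(d$values[, 1]), 0.5, tolerance = 0.02)

  mm <- mixed_motif_mechanism(seed = 78)
  dd <- simulate_dataset(mm, 500, seed = 79)
  expect_identical(dd$kinds, mm$kinds)
  expect_true(all(dd$values[, "Y1"] %in% c(0, 1)))
})

test_that("the mixed-motif fixture has the documented topology", {
  mm <- mixed_motif_mechanism(p_continuous = 10, n_extra_edges = 5, seed = 80)
  expect_length(mm$dag$nodes, 11L)
  expect_equal(n_edges(mm$dag), 8L)
  expect_equal(sum(mm$dag$A[, "Y1"]), 2L)          # two continuous parents
  expect_equal(sum(mm$dag$A["Y1", ]), 1L)          # one continuous child
  expect_true(all(mm$kinds[names(which(mm$dag$A[, "Y1"]))] == "continuous"))
  expect_acyclic(mm$dag)
})

test_that("gaussian residuals pass a normality screen; gamma noise is
           right-skewed with skewness near 2", {
  mech <- random_mechanism(sim_config(p_continuous = 3,
                                      edges = cbind("X1", "X2"),
                                      seed = 81))
  d <- simulate_dataset(mech, 4000, seed = 82)
  resid <- d$values[, "X2"] - d$values[, "X1"] * mech$coef["X1", "X2"]
  expect_gt(shapiro.test(sample(resid, 3000))$p.value, 0.01)

  mechg <- random_mechanism(sim_config(p_continuous = 3,
                                       edges = cbind("X1", "X2"),
                                       noise_family = "gamma_1_2_centered",
                                       seed = 83))
  dg <- simulate_dataset(mechg, 2e4, seed = 84)
  residg <- dg$values[, "X2"] - dg$values[, "X1"] * mechg$coef["X1", "X2"]
  z <- (residg - mean(residg)) / sd(residg)
  skew <- mean(z^3)
  expect_equal(skew, 2, tolerance = 0.35)
})
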