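# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# transitive closure by depth-first search from every node
dfs_closure <- function(A) {
  p <- nrow(A)
  R <- matrix(FALSE, p, p)
  for (s in seq_len(p)) {
    stack <- which(A[s, ])
    seen <- rep(FALSE, p)
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(A[v, ] & !seen))
    }
    R[s, ] <- seen
  }
  dimnames(R) <- dimnames(A)
  R
}

# random DAG via a random topological order; uses the session RNG
random_dag_r <- function(p, edge_prob = 0.4, nodes = paste0("N", seq_len(p))) {
  ord <- sample.int(p)
  A <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  for (a in seq_len(p - 1)) for (b in seq((a + 1), p)) {
    if (stats::runif(1) < edge_prob) A[ord[a], ord[b]] <- TRUE
  }
  dag(nodes, which(A, arr.ind = TRUE))
}

# pairwise SHD by explicit enumeration over unordered pairs
shd_oracle <- function(g1, g2) {
  p <- length(g1$nodes)
  tot <- 0L
  for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
    tot <- tot + max(abs(g1$A[i, j] - g2$A[i, j]),
                     abs(g1$A[j, i] - g2$A[j, i]))
  }
  tot
}

# reference node scores through lm() / glm()
lm_score <- function(data, v, parents, form = "deviance") {
  y <- data$values[, v]
  n <- length(y)
  X <- data$values[, parents, drop = FALSE]
  fit <- if (length(parents) == 0) stats::lm(y ~ 1) else stats::lm(y ~ X)
  rss <- sum(stats::residuals(fit)^2)
  pen <- length(parents) * log(n)
  if (form == "literal") rss / n + pen else n * log(rss / n) + pen
}

glm_score <- function(data, v, parents) {
  y <- data$values[, v]
  n <- length(y)
  df <- as.data.frame(data$values[, parents, drop = FALSE])
  fit <- if (length(parents) == 0) {
    stats::glm(y ~ 1, family = stats::binomial())
  } else {
    stats::glm(y ~ ., data = df, family = stats::binomial())
  }
  as.numeric(fit$deviance) + length(parents) * log(n)
}

# small mixed dataset with dependencies, for scoring/search tests
mixed_fixture <- function(n = 80, seed = 404) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x1 - 1.2 * x2))
  x3 <- 0.9 * y + rnorm(n)
  make_dataset(cbind(X1 = x1, X2 = x2, Y = y, X3 = x3),
               kinds = c("continuous", "continuous", "binary", "continuous"))
}

expect_acyclic <- function(g) {
  expect_false(is.null(topological_order(g$A)))
}
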