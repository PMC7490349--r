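# independent U oracle: count pairs (different route from the rank-sum form)
u_pairs <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

test_that("U equals the pair-count definition and ties give CLES 0.5", {
  set.seed(6)
  for (i in 1:20) {
    x <- sample(1:6, 5, replace = TRUE)
    y <- sample(1:6, 4, replace = TRUE)
    expect_equal(mann_whitney(x, y)$U, u_pairs(x, y))
  }
  allsame <- mann_whitney(rep(2, 5), rep(2, 5))
  expect_equal(allsame$U, 12.5)
  expect_equal(allsame$cles, 0.5)
})

test_that("exact p values match brute-force enumeration for n1+n2 <= 10", {
  # oracle: enumerate group assignments, U by pair counting
  exact_oracle <- function(x, y, tail) {
    pooled <- c(x, y)
    n1 <- length(x)
    sets <- utils::combn(length(pooled), n1)
    u_obs <- u_pairs(x, y)
    u_all <- apply(sets, 2, function(s) u_pairs(pooled[s], pooled[-s]))
    pg <- mean(u_all >= u_obs - 1e-9)
    pl <- mean(u_all <= u_obs + 1e-9)
    switch(tail, greater = pg, less = pl, two = min(1, 2 * min(pg, pl)))
  }
  set.seed(8)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(seq(0, 3, 0.5), n1, replace = TRUE)  # ties likely
    y <- sample(seq(0, 3, 0.5), n2, replace = TRUE)
    for (tail in c("two", "greater", "less")) {
      expect_equal(mann_whitney(x, y, tail = tail)$p,
                   exact_oracle(x, y, tail),
                   label = sprintf("tail %s case %d", tail, i))
    }
  }
  # no-tie cases agree with wilcox.test's exact distribution
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(mann_whitney(x, y, tail = "two")$p,
                 wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(mann_whitney(x, y, tail = "greater")$p,
                 wilcox.test(x, y, exact = TRUE,
                             alternative = "greater")$p.value)
  }
})

test_that("the textbook worked example gives U = 4, p = 1/6", {
  res <- mann_whitney(c(3, 4), c(1, 2), tail = "greater")
  expect_equal(res$U, 4)
  expect_equal(res$p, 1 / 6)
  expect_equal(res$method, "exact")
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(9)
  x <- rnorm(15); y <- rnorm(15) + 0.5
  res <- mann_whitney(x, y, tail = "two")
  expect_equal(res$method, "normal approximation")
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
})

test_that("CLES satisfies its complement identity and bounds", {
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    u <- u_pairs(rnorm(n1), rnorm(n2))
    expect_gte(cles(u, n1, n2), 0)
    expect_lte(cles(u, n1, n2), 1)
    expect_equal(cles(u, n1, n2) + cles(n1 * n2 - u, n2, n1), 1)
  }
  expect_equal(cles(72, 12, 12), 0.5)
  expect_error(cles(200, 12, 12), "U <= ")
})

test_that("connected-component labelling agrees with igraph", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (i in 1:10) {
    n <- 30
    m <- 25
    e1 <- sample(n, m, replace = TRUE)
    e2 <- sample(n, m, replace = TRUE)
    keep <- e1 != e2
    comp <- tntphysio:::.components(n, e1[keep], e2[keep])
    g <- igraph::graph_from_edgelist(cbind(e1[keep], e2[keep]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    ref <- igraph::components(g)$membership
    # same partition up to relabelling
    expect_equal(length(unique(comp)), ref_n <- max(ref))
    expect_true(all(tapply(ref, comp, function(z) length(unique(z))) == 1))
  }
})

test_that("suprathreshold points cluster under the declared adjacency", {
  # two strong channels, not neighbors: two clusters
  adj <- adjacency_list(rbind(c("A", "B"), c("B", "C")))
  n <- 8
  d <- array(rnorm(n * 3 * 1 * 12, 0, 0.3), c(n, 3, 1, 12))
  d[, 1, 1, 5:7] <- d[, 1, 1, 5:7] + 4
  d[, 3, 1, 5:7] <- d[, 3, 1, 5:7] + 4
  res <- cluster_permutation(d, adj, channels = c("A", "B", "C"),
                             n_perm = 100, seed = 1)
  big <- Filter(function(cl) nrow(cl$points) >= 3, res$clusters)
  expect_equal(length(big), 2)
  chans <- sort(vapply(big, function(cl) cl$points[1, "channel"], integer(1)))
  expect_equal(chans, c(1L, 3L))
  # make them neighbors: one cluster
  adj2 <- adjacency_list(rbind(c("A", "C"), c("A", "B")))
  res2 <- cluster_permutation(d, adj2, channels = c("A", "B", "C"),
                              n_perm = 100, seed = 1)
  big2 <- Filter(function(cl) nrow(cl$points) >= 3, res2$clusters)
  expect_equal(length(big2), 1)
  expect_error(cluster_permutation(d, NULL, channels = c("A", "B", "C")),
               "adjacency")
})

test_that("sampled permutation p approximates the exhaustive reference", {
  set.seed(13)
  x <- matrix(rnorm(6 * 40), 6, 40)
  x[, 15:25] <- x[, 15:25] + 3
  ex <- cluster_permutation(x, exhaustive = "always")
  expect_true(ex$exhaustive)
  expect_equal(ex$n_perm, 64)
  sm <- cluster_permutation(x, n_perm = 2000, seed = 5, exhaustive = "never")
  expect_lt(abs(ex$clusters[[1]]$p - sm$clusters[[1]]$p), 0.02)
  # span of the detected cluster covers the boxcar
  expect_equal(range(ex$clusters[[1]]$points[, "time"]), c(15, 25),
               tolerance = 1)
  # reproducible under a fixed seed
  sm2 <- cluster_permutation(x, n_perm = 500, seed = 5, exhaustive = "never")
  sm3 <- cluster_permutation(x, n_perm = 500, seed = 5, exhaustive = "never")
  expect_identical(sm2$clusters[[1]]$p, sm3$clusters[[1]]$p)
})

test_that("null data yield empty results with a warning, not an error", {
  # antisymmetric rows: every pointwise mean (hence t) is exactly zero
  m <- matrix(rnorm(2 * 10), 2, 10)
  x <- rbind(m, -m)
  expect_warning(res <- cluster_permutation(x, n_perm = 50, seed = 2),
                 "no suprathreshold")
  expect_equal(length(res$clusters), 0)
})
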