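# Nonparametric cluster-based permutation inference over channel x
# frequency x time arrays, plus Mann-Whitney rank statistics with
# common-language effect sizes.

# union-find with path halving; edges restricted to suprathreshold points
.components <- function(n_points, e1, e2) {
  parent <- seq_len(n_points)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(e1)) {
    r1 <- find(e1[k]); r2 <- find(e2[k])
    if (r1 != r2) parent[r2] <- r1
  }
  vapply(seq_len(n_points), find, integer(1))
}

# max cluster mass among suprathreshold points of a statistic vector
.max_cluster_mass <- function(tvec, threshold, tail, e1, e2) {
  mass_one_sign <- function(mask) {
    sup <- which(mask)
    if (!length(sup)) return(0)
    sub <- integer(length(tvec))
    sub[sup] <- seq_along(sup)
    keep <- mask[e1] & mask[e2]
    comp <- .components(length(sup), sub[e1[keep]], sub[e2[keep]])
    max(abs(vapply(split(tvec[sup], comp), sum, numeric(1))))
  }
  switch(tail,
         greater = mass_one_sign(tvec > threshold),
         less = mass_one_sign(tvec < -threshold),
         two = max(mass_one_sign(tvec > threshold),
                   mass_one_sign(tvec < -threshold)))
}

.cluster_edges <- function(n_ch, n_f, n_t, adjacency, channels) {
  idx <- function(c, f, t) c + n_ch * ((f - 1) + n_f * (t - 1))
  e1 <- integer(0); e2 <- integer(0)
  grid <- expand.grid(c = seq_len(n_ch), f = seq_len(n_f), t = seq_len(n_t))
  if (n_t > 1) {
    g <- grid[grid$t < n_t, ]
    e1 <- c(e1, idx(g$c, g$f, g$t)); e2 <- c(e2, idx(g$c, g$f, g$t + 1))
  }
  if (n_f > 1) {
    g <- grid[grid$f < n_f, ]
    e1 <- c(e1, idx(g$c, g$f, g$t)); e2 <- c(e2, idx(g$c, g$f + 1, g$t))
  }
  if (n_ch > 1) {
    if (is.null(adjacency)) {
      stop("an adjacency list is required for multi-channel data",
           call. = FALSE)
    }
    if (!all(channels %in% adjacency$channels)) {
      stop("adjacency does not cover all data channels", call. = FALSE)
    }
    pairs <- cbind(match(adjacency$pairs[, 1], channels),
                   match(adjacency$pairs[, 2], channels))
    pairs <- pairs[stats::complete.cases(pairs) & pairs[, 1] < pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs)) {
      ft <- expand.grid(f = seq_len(n_f), t = seq_len(n_t))
      for (r in seq_len(nrow(pairs))) {
        e1 <- c(e1, idx(pairs[r, 1], ft$f, ft$t))
        e2 <- c(e2, idx(pairs[r, 2], ft$f, ft$t))
      }
    }
  }
  list(e1 = e1, e2 = e2)
}

#' Cluster-based permutation test on paired difference maps
#'
#' One-sample (paired-difference) cluster permutation inference: a paired t
#' statistic against zero is computed at every (channel, frequency, time)
#' point; suprathreshold points (cluster-forming threshold default 2.5) are
#' grouped into clusters connected under channel adjacency plus immediate
#' frequency/time neighborhood; each cluster's mass is the sum of t inside
#' it; and cluster p values come from the permutation distribution of the
#' maximal cluster mass under random sign flips of whole participant maps,
#' with the small-sample correction p = (1 + #\{perm >= observed\}) /
#' (1 + n_perm). When `2^n_participants <= n_perm` the full sign-flip set is
#' enumerated instead of sampled.
#'
#' @param data Participant x channel x frequency x time array of paired
#'   differences. A participant x time matrix or participant x freq x time
#'   array is promoted with singleton leading dims.
#' @param adjacency An `adjacency_list` (required when there is more than
#'   one channel).
#' @param channels Channel labels (default from `dimnames` or generated).
#' @param threshold Cluster-forming threshold on the t statistic.
#' @param tail `"greater"`, `"less"`, or `"two"`.
#' @param n_perm Number of permutations.
#' @param seed Seed for the sampled sign flips.
#' @param exhaustive `"auto"` (enumerate all flips when feasible),
#'   `"always"`, or `"never"`.
#' @return A list of class `cluster_result`: `clusters` (list with `points`
#'   index matrix (channel, freq, time), `mass`, `p`), `t_map`
#'   (channel x freq x time), `max_null` (permutation distribution),
#'   `threshold`, `tail`, `n_perm`, `exhaustive`.
#' @export
cluster_permutation <- function(data, adjacency = NULL, channels = NULL,
                                threshold = 2.5,
                                tail = c("greater", "less", "two"),
                                n_perm = 1024, seed = NULL,
                                exhaustive = c("auto", "always", "never")) {
  tail <- match.arg(tail)
  exhaustive <- match.arg(exhaustive)
  if (is.matrix(data)) data <- array(data, dim = c(nrow(data), 1, 1, ncol(data)))
  if (length(dim(data)) == 3) {
    data <- array(data, dim = c(dim(data)[1], 1, dim(data)[2], dim(data)[3]))
  }
  stopifnot(length(dim(data)) == 4)
  n <- dim(data)[1]; n_ch <- dim(data)[2]; n_f <- dim(data)[3]
  n_t <- dim(data)[4]
  if (n < 3) stop("cluster permutation needs at least 3 participants",
                  call. = FALSE)
  if (is.null(channels)) channels <- sprintf("CH%03d", seq_len(n_ch))
  x <- matrix(data, n, n_ch * n_f * n_t)
  edges <- .cluster_edges(n_ch, n_f, n_t, adjacency, channels)
  q <- colSums(x^2)
  t_of <- function(m) {
    v <- (q - n * m^2) / (n - 1)
    ifelse(v <= 0, 0, m / sqrt(v / n))
  }
  t_obs <- t_of(colMeans(x))
  # observed clusters
  obs_mask <- switch(tail, greater = t_obs > threshold,
                     less = t_obs < -threshold,
                     two = abs(t_obs) > threshold)
  clusters <- list()
  if (any(obs_mask)) {
    sup <- which(obs_mask)
    sub <- integer(length(t_obs)); sub[sup] <- seq_along(sup)
    keep <- obs_mask[edges$e1] & obs_mask[edges$e2]
    if (tail == "two") {
      # positive and negative points never connect (threshold > 0)
      same_sign <- sign(t_obs[edges$e1]) == sign(t_obs[edges$e2])
      keep <- keep & same_sign
    }
    comp <- .components(length(sup), sub[edges$e1[keep]],
                        sub[edges$e2[keep]])
    for (g in split(sup, comp)) {
      arr_idx <- arrayInd(g, c(n_ch, n_f, n_t))
      colnames(arr_idx) <- c("channel", "freq", "time")
      clusters[[length(clusters) + 1]] <-
        list(points = arr_idx, mass = sum(t_obs[g]), p = NA_real_)
    }
    ord <- order(-abs(vapply(clusters, `[[`, numeric(1), "mass")))
    clusters <- clusters[ord]
  } else {
    warning("no suprathreshold points: empty cluster result", call. = FALSE)
  }
  # permutation null of the max cluster mass
  do_exhaustive <- exhaustive == "always" ||
    (exhaustive == "auto" && 2^n <= n_perm)
  if (do_exhaustive) {
    n_total <- 2^n
    flips <- matrix(1, n_total, n)
    for (j in seq_len(n)) {
      flips[, j] <- ifelse(bitwAnd(seq_len(n_total) - 1L,
                                   bitwShiftL(1L, j - 1L)) > 0, -1, 1)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    n_total <- n_perm
    flips <- matrix(sample(c(-1, 1), n_total * n, replace = TRUE),
                    n_total, n)
  }
  max_null <- numeric(n_total)
  chunk <- 256L
  for (start in seq(1, n_total, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_total)
    m_chunk <- (flips[rows, , drop = FALSE] %*% x) / n
    for (r in seq_along(rows)) {
      t_perm <- t_of(m_chunk[r, ])
      max_null[rows[r]] <- .max_cluster_mass(t_perm, threshold, tail,
                                             edges$e1, edges$e2)
    }
  }
  for (i in seq_along(clusters)) {
    obs <- abs(clusters[[i]]$mass)
    clusters[[i]]$p <- (1 + sum(max_null >= obs)) / (1 + n_total)
  }
  structure(list(clusters = clusters,
                 t_map = array(t_obs, dim = c(n_ch, n_f, n_t)),
                 max_null = max_null, threshold = threshold, tail = tail,
                 n_perm = n_total, exhaustive = do_exhaustive,
                 channels = channels),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), threshold %g, tail %s, %d %s permutations\n",
              length(x$clusters), x$threshold, x$tail, x$n_perm,
              if (x$exhaustive) "exhaustive" else "sampled"))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: %d point(s), mass %.2f, p = %.4f\n", i,
                nrow(cl$points), cl$mass, cl$p))
  }
  invisible(x)
}

.mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test with common-language effect size
#'
#' U counts the pairs where an x value exceeds a y value, plus half the
#' ties. For small samples (`n1 + n2 <= exact_max`, default 12) the p value
#' is exact, by enumeration of all group-label assignments of the pooled
#' values (ties handled naturally); otherwise the normal approximation with
#' tie correction and continuity correction is used. The common-language
#' effect size is U / (n1 n2): the probability that a random x exceeds a
#' random y.
#'
#' @param x,y Numeric score vectors for the two groups.
#' @param tail `"two"`, `"greater"` (x tends larger) or `"less"`.
#' @param exact_max Largest `n1 + n2` for which the exact enumeration is
#'   used.
#' @return A list of class `rank_test`: `U`, `p`, `n1`, `n2`, `cles`,
#'   `tail`, `method`.
#' @export
mann_whitney <- function(x, y, tail = c("two", "greater", "less"),
                         exact_max = 12) {
  tail <- match.arg(tail)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  u <- .mw_u(x, y)
  if (n1 + n2 <= exact_max) {
    pooled <- c(x, y)
    r <- rank(pooled)
    sets <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_greater <- mean(u_all >= u - eps)
    p_less <- mean(u_all <= u + eps)
    p <- switch(tail, greater = p_greater, less = p_less,
                two = min(1, 2 * min(p_greater, p_less)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma <- sqrt(n1 * n2 / 12 * (nn + 1 - tie_term))
    z <- switch(tail,
                greater = (u - mu - 0.5) / sigma,
                less = (u - mu + 0.5) / sigma,
                two = (abs(u - mu) - 0.5) / sigma)
    p <- switch(tail,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two = 2 * stats::pnorm(z, lower.tail = FALSE))
    p <- min(1, max(0, p))
    method <- "normal approximation"
  }
  structure(list(U = u, p = p, n1 = n1, n2 = n2, cles = cles(u, n1, n2),
                 tail = tail, method = method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> U = %g (n1 = %d, n2 = %d), p = %.4g (%s, tail %s), CLES = %.2f\n",
              x$U, x$n1, x$n2, x$p, x$method, x$tail, x$cles))
  invisible(x)
}

#' Common-language effect size from a U statistic
#'
#' The probability that a randomly drawn member of the first group exceeds
#' a randomly drawn member of the second: U / (n1 n2).
#'
#' @param U Mann-Whitney U statistic.
#' @param n1,n2 Group sizes.
#' @return A proportion in [0, 1].
#' @export
cles <- function(U, n1, n2) {
  stopifnot(U >= 0, U <= n1 * n2)
  U / (n1 * n2)
}
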