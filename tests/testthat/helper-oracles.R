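# Independent oracles, deliberately implemented differently from the
# package internals.

# Enclosed-void count by explicit stack-based flood fill from the border
# (void 4-connected).
flood_fill_enclosed <- function(bone) {
  nr <- nrow(bone); nc <- ncol(bone)
  ext <- matrix(FALSE, nr, nc)
  stack <- list()
  for (i in seq_len(nr)) for (j in c(1, nc))
    if (!bone[i, j]) stack[[length(stack) + 1]] <- c(i, j)
  for (j in seq_len(nc)) for (i in c(1, nr))
    if (!bone[i, j]) stack[[length(stack) + 1]] <- c(i, j)
  while (length(stack)) {
    p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- p[1]; j <- p[2]
    if (i < 1 || i > nr || j < 1 || j > nc) next
    if (bone[i, j] || ext[i, j]) next
    ext[i, j] <- TRUE
    stack <- c(stack, list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1)))
  }
  sum(!bone & !ext)
}

# Shared-path-length matrix by climbing parent pointers to the MRCA.
vcv_bruteforce <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- n + 1
  anc_path <- function(v) {        # node sequence v .. root
    p <- v
    while (v != root) { v <- parent[v]; p <- c(p, v) }
    p
  }
  depth <- function(v) { d <- 0; while (v != root) { d <- d + elen[v]; v <- parent[v] }; d }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    mrca <- intersect(anc_path(i), anc_path(j))[1]
    C[i, j] <- depth(mrca)
  }
  diag(C) <- vapply(seq_len(n), depth, 0)
  C
}

# Direct dense-algebra GLS mean / MSE / MSE0 (plain solve()).
gls_oracle <- function(x, C) {
  n <- length(x)
  one <- rep(1, n)
  Ci <- solve(C)
  a <- drop((t(one) %*% Ci %*% x) / (t(one) %*% Ci %*% one))
  r <- x - a
  list(phylo_mean = a,
       MSE = drop(t(r) %*% Ci %*% r) / (n - 1),
       MSE0 = drop(t(r) %*% r) / (n - 1))
}

# Blomberg's K straight from its definition with plain matrix algebra.
blomberg_K_oracle <- function(x, C) {
  n <- length(x)
  g <- gls_oracle(x, C)
  expected <- (sum(diag(C)) - n / sum(solve(C))) / (n - 1)
  (g$MSE0 / g$MSE) / expected
}

# One-way F from the textbook sums of squares.
anova_F_oracle <- function(x, g) {
  g <- as.factor(g)
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  k <- nlevels(g); n <- length(x)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Generic numeric minimiser of the squared-change objective (BFGS on the
# stated sum with its gradient), independent of the linear-system solution.
scp_objective <- function(tree, x, weighted) {
  w <- if (weighted) tree$edge.length else rep(1, nrow(tree$edge))
  function(u) {
    states <- c(x, u)
    sum((states[tree$edge[, 2]] - states[tree$edge[, 1]])^2 / w)
  }
}

scp_numeric <- function(tree, x, weighted = TRUE) {
  w <- if (weighted) tree$edge.length else rep(1, nrow(tree$edge))
  n <- length(x)
  f <- scp_objective(tree, x, weighted)
  gr <- function(u) {
    states <- c(x, u)
    d <- 2 * (states[tree$edge[, 2]] - states[tree$edge[, 1]]) / w
    g <- numeric(tree$Nnode)
    for (e in seq_along(d)) {
      ch <- tree$edge[e, 2]; pa <- tree$edge[e, 1]
      if (ch > n) g[ch - n] <- g[ch - n] + d[e]
      g[pa - n] <- g[pa - n] - d[e]
    }
    g
  }
  u <- rep(mean(x), tree$Nnode)
  for (restart in 1:3)
    u <- stats::optim(u, f, gr, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-16))$par
  u
}

# Toy ornamented raster: 7 x 15, two crests (cols 4 and 12) of height 2
# above the shoulder, a pit between them.
two_crest_raster <- function() {
  bone <- matrix(FALSE, 7, 15)
  bone[5:7, 2:14] <- TRUE                 # body
  bone[3:4, c(3:5, 11:13)] <- TRUE        # two crest columns
  bone
}
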