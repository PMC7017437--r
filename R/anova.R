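# One-way F statistics for every column of a trait matrix at once; used
# by the simulation null.
.F_columns <- function(X, groups) {
  g <- as.factor(groups)
  n <- nrow(X); k <- nlevels(g)
  counts <- tabulate(g, k)
  G <- rowsum(X, g, reorder = TRUE)            # k x m group sums
  gm <- colSums(X) / n
  ssb <- colSums(G^2 / counts) - n * gm^2
  sst <- colSums(X^2) - n * gm^2
  ssw <- sst - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Classical one-way ANOVA F statistic
#'
#' The between-group over within-group mean-square ratio, computed through
#' an ordinary linear-model fit. This is the observed statistic that the
#' phylogenetic simulation null is compared against.
#'
#' @param traits Numeric vector.
#' @param groups Group label per value (>= 2 groups, at least one with
#'   >= 2 members).
#' @return The F value.
#' @export
classical_anova_F <- function(traits, groups) {
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) < 2) stop("need at least two groups")
  if (stats::var(as.numeric(traits)) == 0)
    stop("all trait values identical: F is undefined")
  fit <- stats::anova(stats::lm(as.numeric(traits) ~ droplevels(g)))
  unname(fit[1, "F value"])
}

#' Phylogenetic ANOVA
#'
#' Tests whether a continuous trait differs among groups while accounting
#' for the phylogenetic non-independence of the tips. Three constructions
#' of the null are offered:
#' \describe{
#'   \item{`bm_simulation` (default)}{The observed one-way F statistic is
#'     referred to a null distribution of F values obtained by simulating
#'     `n_sim` Brownian-motion trait vectors on the tree (rate estimated
#'     from the data by GLS; the F statistic is scale-free, so the rate
#'     only matters through the tree's structure).
#'     \eqn{p = (1 + \#\{F_{sim} \ge F_{obs}\}) / (n_{sim} + 1)}.}
#'   \item{`gls_lambda`}{Generalized least squares with covariance
#'     \eqn{\sigma^2 C(\hat\lambda)}, \eqn{\hat\lambda} fitted by
#'     [pagel_lambda()]; group effect tested by the GLS F test against
#'     \eqn{F_{k-1,\,n-k}}.}
#'   \item{`gls_K_scaled`}{As `gls_lambda` but with the untransformed
#'     Brownian covariance C — the covariance under which Blomberg's K is
#'     defined. A documented approximation: K itself does not induce a
#'     covariance transform.}
#' }
#'
#' @param traits Numeric tip values (named or aligned to tip order).
#' @param groups Group label per tip.
#' @param tree A `"phylo"` chronogram.
#' @param n_sim Simulations for the `bm_simulation` null (default 1000).
#' @param mode Null construction, see above.
#' @param seed Optional integer seed (simulation mode).
#' @return Object of class `"phylo_anova"`: list with `F_observed`,
#'   `p_phylogenetic`, `p_classical`, `n_simulations`, `mode`, `seed`.
#' @export
phylo_anova <- function(traits, groups, tree, n_sim = 1000,
                        mode = c("bm_simulation", "gls_lambda", "gls_K_scaled"),
                        seed = NULL) {
  mode <- match.arg(mode)
  x <- .align_traits(traits, tree)
  g <- as.factor(groups)
  if (length(g) != length(x)) stop("groups length does not match traits")
  k <- nlevels(droplevels(g))
  n <- length(x)
  F_obs <- classical_anova_F(x, g)
  p_classical <- stats::pf(F_obs, k - 1, n - k, lower.tail = FALSE)
  C <- phylo_covariance(tree)
  if (mode == "bm_simulation") {
    fit <- gls_mean_mse(x, C)
    sig2 <- fit$MSE                       # GLS rate estimate (per Myr)
    if (!is.null(seed)) set.seed(seed)
    U <- chol(C)
    X <- t(U) %*% matrix(stats::rnorm(n * n_sim, sd = sqrt(sig2)), n, n_sim)
    F_sim <- .F_columns(X, g)
    p_phylo <- (1 + sum(F_sim >= F_obs)) / (n_sim + 1)
    n_used <- n_sim
  } else {
    V <- if (mode == "gls_lambda") {
      lam <- pagel_lambda(x, C = C)$estimate
      lambda_transform(C, lam)
    } else {
      C
    }
    L <- chol(V)
    wx <- forwardsolve(t(L), x)
    W1 <- forwardsolve(t(L), model.matrix(~1, data.frame(g = g)))
    Wg <- forwardsolve(t(L), model.matrix(~g, data.frame(g = droplevels(g))))
    rss0 <- sum(stats::lm.fit(W1, wx)$residuals^2)
    rss1 <- sum(stats::lm.fit(Wg, wx)$residuals^2)
    F_gls <- ((rss0 - rss1) / (k - 1)) / (rss1 / (n - k))
    p_phylo <- stats::pf(F_gls, k - 1, n - k, lower.tail = FALSE)
    n_used <- NA_integer_
  }
  structure(list(F_observed = F_obs, p_phylogenetic = p_phylo,
                 p_classical = p_classical, n_simulations = n_used,
                 mode = mode,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "phylo_anova")
}

#' @export
print.phylo_anova <- function(x, ...) {
  cat("Phylogenetic ANOVA (", x$mode, ")\n",
      "  F = ", signif(x$F_observed, 4),
      ";  p (phylogenetic) = ", format(x$p_phylogenetic, digits = 3),
      ";  p (classical) = ", format(x$p_classical, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Round half away from zero
#'
#' Report-style rounding (0.325 -> 0.33 at 2 digits), as opposed to base
#' R's round-half-even. Computations are always carried at full precision;
#' this is for display and report tables only.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-lifestyle descriptive statistics
#'
#' For each lifestyle category: n, mean, median, sample standard deviation
#' (n - 1 denominator), minimum and maximum of porosity, at full
#' precision. Groups with a single record have an undefined sd, reported
#' as 0 with `sd_defined = FALSE`. The print method rounds half-up to two
#' decimals, as in report tables.
#'
#' @param table A `"specimen_table"`.
#' @return data.frame of class `"group_stats"` with one row per lifestyle
#'   present, columns `lifestyle`, `n`, `mean`, `median`, `sd`, `min`,
#'   `max`, `sd_defined`.
#' @export
group_stats <- function(table) {
  stopifnot(inherits(table, "specimen_table"))
  if (!nrow(table)) stop("empty specimen table")
  levels_present <- intersect(lifestyle_levels(attr(table, "dataset")),
                              unique(table$lifestyle))
  rows <- lapply(levels_present, function(lv) {
    v <- table$porosity[table$lifestyle == lv]
    data.frame(lifestyle = lv, n = length(v), mean = mean(v),
               median = stats::median(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = min(v), max = max(v),
               sd_defined = length(v) > 1)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_stats", "data.frame")
  attr(out, "dataset") <- attr(table, "dataset")
  out
}

#' @export
print.group_stats <- function(x, digits = 2, ...) {
  cat("Porosity by lifestyle (", attr(x, "dataset"), ")\n", sep = "")
  y <- as.data.frame(x)
  for (cl in c("mean", "median", "sd", "min", "max"))
    y[[cl]] <- round_half_up(y[[cl]], digits)
  print(y, row.names = FALSE, ...)
  if (!all(x$sd_defined))
    cat("  (sd reported as 0 for single-record groups)\n")
  invisible(x)
}
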