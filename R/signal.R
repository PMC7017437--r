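# Shared GLS quantities for a phylogenetic covariance: its inverse, the
# weight vector C^-1 1, its sum, and the trace.
.phylo_setup <- function(C) {
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e)
    stop("phylogenetic covariance is singular or not positive definite"))
  w <- rowSums(Cinv)
  list(Cinv = Cinv, w = w, s = sum(w), trC = sum(diag(C)), n = nrow(C))
}

.resolve_C <- function(tree, C, eps = 1e-8) {
  if (is.null(C)) {
    if (is.null(tree)) stop("supply either a tree or a covariance matrix")
    C <- phylo_covariance(tree)
    # zero-length pendant branches duplicate rows of C; perturb only when
    # they actually make it singular
    if (inherits(tryCatch(chol(C), error = identity), "error")) {
      tips <- tree$edge[, 2] <= length(tree$tip.label)
      zero_pend <- tree$edge[tips, 2][tree$edge.length[tips] == 0]
      if (length(zero_pend)) {
        idx <- match(tree$tip.label[zero_pend], rownames(C))
        diag(C)[idx] <- diag(C)[idx] + eps
      }
    }
  }
  C
}

#' GLS phylogenetic mean and mean squared errors
#'
#' Under Brownian motion the generalized-least-squares estimate of the
#' ancestral (phylogenetic) mean is
#' \eqn{\hat a = (1' C^{-1} 1)^{-1} 1' C^{-1} x}. The phylogenetically
#' corrected mean squared error is
#' \eqn{MSE = (x - \hat a 1)' C^{-1} (x - \hat a 1) / (n - 1)} and its
#' star-phylogeny counterpart
#' \eqn{MSE_0 = (x - \hat a 1)' (x - \hat a 1) / (n - 1)}; their ratio is
#' the ingredient of Blomberg's K.
#'
#' @param traits Numeric tip values (named by tip or aligned to the
#'   covariance's dimnames order).
#' @param C Phylogenetic covariance from [phylo_covariance()].
#' @return List with `phylo_mean`, `MSE`, `MSE0`.
#' @export
gls_mean_mse <- function(traits, C) {
  stopifnot(is.matrix(C))
  x <- if (!is.null(names(traits)) && !is.null(rownames(C)))
    traits[rownames(C)] else traits
  x <- as.numeric(x)
  if (length(x) != nrow(C)) stop("trait length does not match C")
  st <- .phylo_setup(C)
  a <- sum(st$w * x) / st$s
  r <- x - a
  list(phylo_mean = a,
       MSE = drop(crossprod(r, st$Cinv %*% r)) / (st$n - 1),
       MSE0 = sum(r^2) / (st$n - 1))
}

# K from precomputed setup; used by both the point estimate and the
# permutation test.
.blomberg_K_value <- function(x, st) {
  a <- sum(st$w * x) / st$s
  r <- x - a
  MSE <- drop(crossprod(r, st$Cinv %*% r)) / (st$n - 1)
  MSE0 <- sum(r^2) / (st$n - 1)
  if (MSE == 0 || MSE0 == 0)
    stop("constant trait: Blomberg's K is undefined")
  expected <- (st$trC - st$n / st$s) / (st$n - 1)
  (MSE0 / MSE) / expected
}

#' Blomberg's K
#'
#' Ratio statistic of phylogenetic signal for a continuous trait: the
#' observed MSE0/MSE ratio (see [gls_mean_mse()]) scaled by its
#' expectation under Brownian motion on the given tree,
#' \eqn{[\mathrm{tr}(C) - n / (1'C^{-1}1)] / (n - 1)}. K = 1 is the
#' Brownian expectation; K < 1 means less resemblance among relatives
#' than Brownian motion predicts, K > 1 more.
#'
#' @param traits Numeric tip values (named or aligned to tip order).
#' @param tree A `"phylo"` chronogram (ignored if `C` is given).
#' @param C Optional precomputed covariance matrix.
#' @return The K value (numeric scalar).
#' @export
blomberg_K <- function(traits, tree = NULL, C = NULL) {
  C <- .resolve_C(tree, C)
  if (nrow(C) < 3) stop("need at least 3 tips")
  x <- if (!is.null(names(traits)) && !is.null(rownames(C)))
    as.numeric(traits[rownames(C)]) else as.numeric(traits)
  .blomberg_K_value(x, .phylo_setup(C))
}

#' Randomization test for Blomberg's K
#'
#' Permutes the trait values across the tips of the tree `n_perm` times;
#' the p-value is the add-one estimator
#' \eqn{p = (1 + \#\{MSE_{perm} \le MSE_{obs}\}) / (n_{perm} + 1)}. A
#' phylogenetically corrected MSE lower than that of random assignments
#' indicates signal.
#'
#' @inheritParams blomberg_K
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `"signal_result"` with fields `statistic`
#'   (`"K"`), `estimate`, `p_value`, `n_randomizations`, `seed`.
#' @export
blomberg_K_test <- function(traits, tree = NULL, n_perm = 999, seed = NULL,
                            C = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  C <- .resolve_C(tree, C)
  if (nrow(C) < 3) stop("need at least 3 tips")
  x <- if (!is.null(names(traits)) && !is.null(rownames(C)))
    as.numeric(traits[rownames(C)]) else as.numeric(traits)
  st <- .phylo_setup(C)
  K <- .blomberg_K_value(x, st)
  a <- sum(st$w * x) / st$s
  r <- x - a
  mse_obs <- drop(crossprod(r, st$Cinv %*% r)) / (st$n - 1)
  if (!is.null(seed)) set.seed(seed)
  X <- replicate(n_perm, sample(x))
  q <- colSums(X * (st$Cinv %*% X))
  aP <- drop(crossprod(st$w, X)) / st$s
  mse_perm <- (q - st$s * aP^2) / (st$n - 1)
  p <- (1 + sum(mse_perm <= mse_obs)) / (n_perm + 1)
  structure(list(statistic = "K", estimate = K, p_value = p,
                 n_randomizations = n_perm,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "signal_result")
}

# Profile log-likelihood of lambda: mu and sigma^2 are maximised
# analytically. Returns -Inf when C(lambda) is not positive definite.
.lambda_loglik <- function(lam, x, C) {
  Cl <- lam * C
  diag(Cl) <- diag(C)
  L <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  n <- length(x)
  logdet <- 2 * sum(log(diag(L)))
  z <- backsolve(L, forwardsolve(t(L), x))      # C^-1 x
  o <- backsolve(L, forwardsolve(t(L), rep(1, n)))
  mu <- sum(o * x) / sum(o)
  r <- x - mu
  sig2 <- drop(crossprod(r, z - mu * o)) / n
  if (sig2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi) + n * log(sig2) + logdet + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' Estimates the off-diagonal multiplier of the Brownian covariance that
#' best fits the trait under a multivariate-normal model, profiling out
#' the mean (GLS) and rate analytically and maximising the resulting 1-D
#' profile likelihood over `bounds` (coarse grid scan followed by local
#' refinement). The p-value is a likelihood-ratio test of the estimate
#' against the null `lambda = 0` (no signal; set `null = "one"` to test
#' against pure Brownian motion), referred to a chi-squared distribution
#' with 1 degree of freedom.
#'
#' @inheritParams blomberg_K
#' @param bounds Search interval for lambda, default `c(0, 1)`.
#' @param null Null hypothesis for the likelihood-ratio test: `"zero"`
#'   (default) or `"one"`.
#' @return Object of class `"signal_result"` with `statistic`
#'   (`"lambda"`), `estimate`, `p_value`, `logL` (at the estimate),
#'   `logL_null`, `null`.
#' @export
pagel_lambda <- function(traits, tree = NULL, bounds = c(0, 1),
                         null = c("zero", "one"), C = NULL) {
  null <- match.arg(null)
  C <- .resolve_C(tree, C)
  x <- if (!is.null(names(traits)) && !is.null(rownames(C)))
    as.numeric(traits[rownames(C)]) else as.numeric(traits)
  if (length(x) != nrow(C)) stop("trait length does not match C")
  stopifnot(length(bounds) == 2, bounds[1] >= 0, bounds[2] > bounds[1])
  offdiag <- C; diag(offdiag) <- 0
  if (max(abs(offdiag)) < 1e-12 * max(diag(C))) {
    warning("star phylogeny: lambda is unidentifiable; returning the lower bound")
    lhat <- bounds[1]
  } else {
    grid <- seq(bounds[1], bounds[2], length.out = 51)
    ll <- vapply(grid, .lambda_loglik, 0, x = x, C = C)
    if (all(!is.finite(ll))) stop("non-finite likelihood over the whole interval")
    best <- which.max(ll)
    lo <- grid[max(1, best - 1)]
    hi <- grid[min(length(grid), best + 1)]
    opt <- stats::optimize(.lambda_loglik, c(lo, hi), x = x, C = C,
                           maximum = TRUE, tol = 1e-8)
    lhat <- opt$maximum
    # the interval interior never contains the endpoints; snap if better
    for (cand in c(bounds, grid[best]))
      if (.lambda_loglik(cand, x, C) > .lambda_loglik(lhat, x, C))
        lhat <- cand
  }
  ll_hat <- .lambda_loglik(lhat, x, C)
  if (!is.finite(ll_hat)) stop("non-finite likelihood at the estimate")
  lam0 <- if (null == "zero") 0 else 1
  ll_null <- .lambda_loglik(lam0, x, C)
  lr <- max(0, 2 * (ll_hat - ll_null))
  structure(list(statistic = "lambda", estimate = lhat,
                 p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 logL = ll_hat, logL_null = ll_null, null = null),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  lab <- if (x$statistic == "K") "Blomberg's K" else "Pagel's lambda"
  cat(lab, " = ", signif(x$estimate, 4),
      ", p = ", format(x$p_value, digits = 3), sep = "")
  if (x$statistic == "K")
    cat(" (", x$n_randomizations, " randomizations)", sep = "")
  else
    cat(" (LR vs lambda = ", if (x$null == "zero") "0" else "1", ")",
        sep = "")
  cat("\n")
  invisible(x)
}
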