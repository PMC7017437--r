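# Align a trait vector to the tree's tip order: by names when present,
# otherwise positionally.
.align_traits <- function(x, tree) {
  n <- length(tree$tip.label)
  if (!is.null(names(x))) {
    missing_tips <- setdiff(tree$tip.label, names(x))
    if (length(missing_tips))
      stop("trait value missing for tip: ", missing_tips[1])
    x <- x[tree$tip.label]
  } else if (length(x) != n) {
    stop("trait length (", length(x), ") != number of tips (", n, ")")
  }
  if (anyNA(x) || any(!is.finite(x))) stop("traits must be finite")
  as.numeric(x)
}

#' Squared-change parsimony ancestral states
#'
#' Reconstructs continuous ancestral values at every internal node by
#' minimising the sum of squared changes along branches, each change
#' optionally divided by its branch length:
#' \deqn{\sum_{branches} (x_{child} - x_{parent})^2 / w_b,}
#' with \eqn{w_b} the branch length (`weighted = TRUE`, default) or 1.
#' The objective is a strictly convex quadratic in the internal-node
#' states, solved exactly as a linear system; the branch-length-weighted
#' solution coincides with the maximum-likelihood ancestral states under
#' Brownian motion. Every reconstructed state lies within the range of the
#' tip values.
#'
#' @param tree A `"phylo"` chronogram; polytomies allowed. With
#'   `weighted = TRUE` all branch lengths must be positive.
#' @param traits Numeric vector of tip values, named by tip label or
#'   aligned to `tree$tip.label`.
#' @param weighted Divide squared changes by branch lengths (default).
#' @return Object of class `"ancestral_recon"`: list with `node_states`
#'   (named by ape node number), `tip_states`, `objective` (the minimised
#'   sum), `weighted`, and `tree`.
#' @export
squared_change_parsimony <- function(tree, traits, weighted = TRUE) {
  validate_chronogram(tree)
  x <- .align_traits(traits, tree)
  n <- length(tree$tip.label)
  m <- tree$Nnode
  w <- if (weighted) tree$edge.length else rep(1, nrow(tree$edge))
  if (any(w <= 0))
    stop(if (weighted) "weighted reconstruction requires positive branch lengths"
         else "invalid weights")
  a <- 1 / w
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - n          # parent is always internal
    ch <- tree$edge[e, 2]
    A[p, p] <- A[p, p] + a[e]
    if (ch > n) {
      q <- ch - n
      A[q, q] <- A[q, q] + a[e]
      A[p, q] <- A[p, q] - a[e]
      A[q, p] <- A[q, p] - a[e]
    } else {
      b[p] <- b[p] + a[e] * x[ch]
    }
  }
  u <- tryCatch(solve(A, b), error = function(e)
    stop("singular system; is the tree connected?"))
  states <- c(x, u)
  obj <- sum((states[tree$edge[, 2]] - states[tree$edge[, 1]])^2 * a)
  node_states <- u
  names(node_states) <- as.character(n + seq_len(m))
  structure(list(node_states = node_states,
                 tip_states = stats::setNames(x, tree$tip.label),
                 objective = obj, weighted = weighted, tree = tree),
            class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("Squared-change parsimony reconstruction (",
      if (x$weighted) "branch-length weighted" else "unweighted", ")\n",
      "  ", length(x$tip_states), " tips, ", length(x$node_states),
      " internal nodes; objective = ", signif(x$objective, 6), "\n", sep = "")
  cat("  root state: ", signif(x$node_states[1], 6), "\n", sep = "")
  invisible(x)
}

#' @describeIn squared_change_parsimony Table of reconstructed states:
#'   one row per internal node with its ape node id, time from the root
#'   (Myr) and state.
#' @param row.names,optional,... Standard [as.data.frame()] arguments
#'   (ignored).
#' @export
as.data.frame.ancestral_recon <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  times <- .node_times(x$tree)
  n <- length(x$tip_states)
  ids <- n + seq_along(x$node_states)
  data.frame(node_id = ids,
             time_from_root = times[ids],
             state = unname(x$node_states))
}
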