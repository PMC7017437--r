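#' Simulate a chronogram
#'
#' Generates small study-shaped trees with branch lengths in Myr:
#' `"star"` (all tips attached to the root, pendant length `depth`),
#' `"balanced"` (fully balanced bifurcating, every tip at `depth`; needs a
#' power-of-two tip count), `"yule"` (a birth-only coalescent-shaped tree
#' rescaled so the root-to-tip depth is `depth`; ultrametric) or
#' `"fixed"` (parse `newick`).
#'
#' @param n_tips Number of tips (>= 3 for the analyses downstream).
#' @param shape One of `"balanced"`, `"yule"`, `"star"`, `"fixed"`.
#' @param depth Root-to-tip depth in Myr.
#' @param seed Optional integer seed (`"yule"` is the only random shape).
#' @param newick Newick string for `shape = "fixed"`.
#' @return A `"phylo"` chronogram with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_tips, shape = c("balanced", "yule", "star", "fixed"),
                          depth = 100, seed = NULL, newick = NULL) {
  shape <- match.arg(shape)
  if (shape != "fixed") stopifnot(n_tips >= 2, depth > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- switch(shape,
    star = {
      tr <- ape::stree(n_tips)
      tr$edge.length <- rep(depth, n_tips)
      tr
    },
    balanced = {
      k <- log2(n_tips)
      if (k != round(k))
        stop("balanced shape needs a power-of-two tip count, got ", n_tips)
      tr <- ape::stree(n_tips, type = "balanced")
      tr$edge.length <- rep(depth / k, nrow(tr$edge))
      tr
    },
    yule = {
      tr <- ape::rphylo(n_tips, birth = 1, death = 0)
      tr$edge.length <- tr$edge.length *
        (depth / max(ape::node.depth.edgelength(tr)))
      tr
    },
    fixed = {
      if (is.null(newick)) stop("shape = 'fixed' needs a newick string")
      read_chronogram(newick)
    })
  validate_chronogram(tree)
}

#' Simulate a continuous trait on a tree
#'
#' Draws one trait vector from the multivariate-normal model
#' \eqn{x \sim N(\mu + \mathrm{effects}[groups],\; \sigma^2 C(\lambda))}.
#' For `lam = 1` the draw is realised exactly by Brownian branch
#' increments (root-to-tip sums of independent normal increments with
#' variance `sigma2` times branch length), which stays cheap on large
#' trees; for `lam < 1` the lambda-blended covariance is factorised and
#' sampled densely.
#'
#' @param tree A `"phylo"` chronogram.
#' @param sigma2 Brownian rate (trait variance per Myr).
#' @param lam Pagel's lambda in \[0, 1\].
#' @param mu Root (grand) mean.
#' @param groups Optional group label per tip (named by tip or in tip
#'   order) for lifestyle-dependent mean shifts.
#' @param effects Named numeric: mean shift added to each group's tips.
#' @param seed Optional integer seed.
#' @return Named numeric vector in `tree$tip.label` order.
#' @export
simulate_traits <- function(tree, sigma2 = 1, lam = 1, mu = 0,
                            groups = NULL, effects = NULL, seed = NULL) {
  validate_chronogram(tree)
  stopifnot(sigma2 >= 0, lam >= 0, lam <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  x <- if (lam == 1) {
    tr <- stats::reorder(tree, "cladewise")   # parents precede children
    nn <- n + tr$Nnode
    val <- numeric(nn)
    inc <- stats::rnorm(nrow(tr$edge), 0, sqrt(sigma2 * tr$edge.length))
    for (e in seq_len(nrow(tr$edge)))
      val[tr$edge[e, 2]] <- val[tr$edge[e, 1]] + inc[e]
    val[seq_len(n)]
  } else {
    C <- lambda_transform(phylo_covariance(tree), lam)
    drop(t(chol(C)) %*% stats::rnorm(n, 0, sqrt(sigma2)))
  }
  x <- x + mu
  if (!is.null(groups)) {
    g <- if (!is.null(names(groups))) groups[tree$tip.label] else groups
    if (length(g) != n) stop("groups length does not match tips")
    if (!is.null(effects)) {
      shift <- effects[as.character(g)]
      shift[is.na(shift)] <- 0
      x <- x + shift
    }
  }
  stats::setNames(x, tree$tip.label)
}

.sample1 <- function(v) v[sample.int(length(v), 1)]

# Pixel offsets of a filled disc of radius r.
.disc_offsets <- function(r) {
  d <- -r:r
  g <- expand.grid(dr = d, dc = d)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Generate a synthetic binary cross-section with known ground truth
#'
#' Builds a rectangular bone body (optionally ornamented with triangular
#' crests separated by pits on its top surface) and carves non-overlapping
#' circular pores plus single-pixel adjustment pores into its interior
#' until the ground-truth porosity hits `target_porosity` exactly in
#' pixels. All apex heights are equal, so the crest-bridging chords are
#' horizontal and the pit area enclosed by bridging is known exactly.
#'
#' The ground-truth total area counts bone, pores, pits and the future
#' bridge pixels (the apex-row gap between consecutive crests), so that
#' [measure_vascular_area()] with `bridge = TRUE` reproduces
#' `porosity_true` on the bridged section.
#'
#' @param width,height Raster size in pixels.
#' @param target_porosity Target vascular fraction in \[0, 0.6).
#' @param pore_radius Integer range of pore radii (min, max).
#' @param ornamented Carve crests and pits on the top surface.
#' @param n_crests Number of crests (>= 2 when ornamented).
#' @param crest_height Crest apex height above the inter-ornament surface,
#'   pixels.
#' @param pit_depth Pit depth below the apices, pixels (<= `crest_height`).
#' @param margin Exterior margin around the body, pixels.
#' @param seed Optional integer seed; the generator is fully deterministic
#'   under it.
#' @return List with `section` (a `"binary_section"`), `pore_mask` and
#'   `pit_mask` (logical matrices), `apices` (data.frame `row`, `col`),
#'   `porosity_true`, `pore_area`, `pit_area`, `total_area`, `target`.
#' @export
generate_section <- function(width = 240, height = 160, target_porosity = 0.2,
                             pore_radius = c(2, 6), ornamented = FALSE,
                             n_crests = 5, crest_height = 12, pit_depth = 8,
                             margin = 4, seed = NULL) {
  stopifnot(target_porosity >= 0, target_porosity < 0.6,
            width > 6 * margin, height > 6 * margin)
  if (ornamented)
    stopifnot(n_crests >= 2, pit_depth >= 1, pit_depth <= crest_height)
  if (!is.null(seed)) set.seed(seed)
  bone <- matrix(FALSE, height, width)
  c0 <- margin + 1; c1 <- width - margin
  r_bot <- height - margin
  pit <- matrix(FALSE, height, width)
  gap_row_px <- 0L
  apices <- data.frame(row = integer(0), col = integer(0))
  if (ornamented) {
    r_apex <- margin + 1
    r_base <- r_apex + crest_height
    a <- round(seq(c0 + 2, c1 - 2, length.out = n_crests))
    surf <- rep(r_base, width)
    for (m in seq_len(n_crests - 1)) {
      jj <- a[m]:a[m + 1]
      half <- (a[m + 1] - a[m]) / 2
      d <- pmin(jj - a[m], a[m + 1] - jj)
      surf[jj] <- r_apex + round(pit_depth * pmin(1, d / half))
    }
    surf[a] <- r_apex
    for (j in c0:c1) bone[surf[j]:r_bot, j] <- TRUE
    # enclosed pit void: strictly below the apex-row chord, above the surface
    for (j in (a[1] + 1):(a[n_crests] - 1)) {
      if (surf[j] > r_apex + 1) pit[(r_apex + 1):(surf[j] - 1), j] <- TRUE
    }
    gap_row_px <- sum(!bone[r_apex, a[1]:a[n_crests]])
    apices <- data.frame(row = rep(r_apex, n_crests), col = a)
  } else {
    r_top <- margin + 1
    for (j in c0:c1) bone[r_top:r_bot, j] <- TRUE
  }
  pit_area <- sum(pit)
  total_area <- sum(bone) + pit_area + gap_row_px
  pores_needed <- round(target_porosity * total_area) - pit_area
  if (pores_needed < 0)
    stop("target porosity unreachable: pit area alone exceeds the target")
  pore <- matrix(FALSE, height, width)
  # interior where pores may sit, keeping a 2-px bone buffer everywhere
  r_lo <- (if (ornamented) max(margin + 1 + crest_height + pit_depth,
                               margin + 1) else margin + 1) + 3
  r_hi <- r_bot - 3
  c_lo <- c0 + 3; c_hi <- c1 - 3
  if (pores_needed > 0 && (r_hi <= r_lo || c_hi <= c_lo))
    stop("target porosity unreachable given the geometry")
  placed <- matrix(numeric(0), 0, 3)          # row, col, radius
  area <- 0L
  rmin <- pore_radius[1]; rmax <- pore_radius[2]
  min_disc <- nrow(.disc_offsets(rmin))
  attempts <- 0L
  while (area + min_disc <= pores_needed) {
    attempts <- attempts + 1L
    if (attempts > 200 * max(1, pores_needed))
      stop("target porosity unreachable given the geometry")
    r <- .sample1(rmin:rmax)
    if (r_lo + r >= r_hi - r || c_lo + r >= c_hi - r) next
    ri <- .sample1(seq(r_lo + r, r_hi - r))
    ci <- .sample1(seq(c_lo + r, c_hi - r))
    if (nrow(placed) &&
        any((placed[, 1] - ri)^2 + (placed[, 2] - ci)^2 <
            (placed[, 3] + r + 2)^2)) next
    off <- .disc_offsets(r)
    px <- cbind(ri + off$dr, ci + off$dc)
    if (area + nrow(px) > pores_needed) next   # overshoot; try smaller
    pore[px] <- TRUE
    placed <- rbind(placed, c(ri, ci, r))
    area <- area + nrow(px)
  }
  while (area < pores_needed) {                # single-pixel adjustment pores
    attempts <- attempts + 1L
    if (attempts > 500 * max(1, pores_needed))
      stop("target porosity unreachable given the geometry")
    ri <- .sample1(r_lo:r_hi); ci <- .sample1(c_lo:c_hi)
    if (any(pore[(ri - 2):(ri + 2), (ci - 2):(ci + 2)])) next
    pore[ri, ci] <- TRUE
    area <- area + 1L
  }
  bone[pore] <- FALSE
  porosity_true <- (area + pit_area) / total_area
  list(section = binary_section(bone),
       pore_mask = pore, pit_mask = pit, apices = apices,
       porosity_true = porosity_true, pore_area = as.integer(area),
       pit_area = as.integer(pit_area), total_area = as.integer(total_area),
       target = target_porosity)
}
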