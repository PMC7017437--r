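#' Read a time-scaled phylogeny
#'
#' Parses a rooted tree with branch lengths in Myr from a Newick file or
#' string, or from a NEXUS file containing a TREES block. Validates that
#' every edge has a non-negative length and that tip labels are unique;
#' polytomies are allowed and fossil tips may end at different ages
#' (non-ultrametric chronograms).
#'
#' @param source Path to a `.nwk`/`.tre`/`.nex` file, or a Newick string.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
read_chronogram <- function(source) {
  if (length(source) == 1 && !grepl("[(;]", source) && file.exists(source)) {
    first <- readLines(source, n = 1, warn = FALSE)
    tree <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) {
      tr <- ape::read.nexus(source)
      if (inherits(tr, "multiPhylo")) tr[[1]] else tr
    } else {
      ape::read.tree(source)
    }
  } else {
    tree <- ape::read.tree(text = as.character(source))
  }
  if (is.null(tree)) stop("could not parse tree from: ", source)
  validate_chronogram(tree)
}

#' Validate a chronogram
#'
#' @param tree A `"phylo"` object.
#' @return The tree, invisibly returned after validation.
#' @export
validate_chronogram <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on the edge to node ", tree$edge[bad, 2])
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  tree
}

#' Write a chronogram to Newick
#'
#' @param tree A `"phylo"` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chronogram <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Packaged reconstructed chronograms
#'
#' Coarse, clearly approximate time-scalings of the study phylogenies:
#' species-level topologies assembled from the published relationships of
#' the sampled taxa, with stage-midpoint tip ages and round node ages in
#' Myr. Branch lengths are reconstructions, not published values; every
#' numeric result computed on them is tree-dependent and should be read
#' accordingly. Tip labels are taxon slugs ([taxon_slug()]); expand to one
#' tip per specimen with [split_conspecific_tips()] and
#' [specimen_groups()].
#'
#' @param dataset `"testudinata"` or `"pseudosuchia"`.
#' @return A `"phylo"` chronogram.
#' @export
chronogram_fixture <- function(dataset = c("testudinata", "pseudosuchia")) {
  dataset <- match.arg(dataset)
  path <- system.file("extdata", paste0(dataset, "_tree_reconstructed.nwk"),
                      package = "dermovasc", mustWork = TRUE)
  read_chronogram(path)
}

#' Split conspecific specimens into 1-Myr cherries
#'
#' Dermal plates from the same species (or specimen) are distinct sampling
#' units; each placeholder tip carrying a k-specimen group is replaced by a
#' hypothetical common ancestor `delta` Myr before the tip's age, bearing k
#' pendant branches of length `delta`, one per specimen. For `delta` = 1
#' Myr the distortion of path lengths is below 1% of the tree's timescale.
#' Groups of size one simply rename the tip.
#'
#' @param tree A `"phylo"` chronogram whose tips include the group names.
#' @param groups Named list: placeholder tip label -> character vector of
#'   specimen ids.
#' @param delta Split depth in Myr (default 1).
#' @return The expanded `"phylo"` tree, with one tip per specimen id.
#' @export
split_conspecific_tips <- function(tree, groups, delta = 1.0) {
  validate_chronogram(tree)
  if (delta <= 0) stop("delta must be positive")
  missing_tips <- setdiff(names(groups), tree$tip.label)
  if (length(missing_tips))
    stop("group tip not found in tree: ", missing_tips[1])
  for (label in names(groups)) {
    members <- groups[[label]]
    if (!length(members)) stop("empty group: ", label)
    if (length(members) == 1) {
      tree$tip.label[tree$tip.label == label] <- members
      next
    }
    tip <- which(tree$tip.label == label)
    pend <- tree$edge.length[tree$edge[, 2] == tip]
    if (pend < delta)
      stop("pendant branch of '", label, "' (", pend,
           " Myr) is shorter than delta = ", delta)
    star <- ape::read.tree(text = paste0(
      "(", paste0(members, ":", delta, collapse = ","), ");"))
    tree <- ape::bind.tree(tree, star, where = tip, position = delta)
    tree <- ape::drop.tip(tree, label)
  }
  validate_chronogram(tree)
}

#' Brownian-motion phylogenetic covariance
#'
#' The n x n matrix of shared evolutionary history: entry (i, j) is the
#' summed branch length from the root to the most recent common ancestor
#' of tips i and j (Myr), the covariance structure of a trait evolving by
#' Brownian motion on the tree. Diagonal entries are the root-to-tip path
#' lengths; on an ultrametric tree they are all equal.
#'
#' @param tree A `"phylo"` chronogram.
#' @return Symmetric numeric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_chronogram(tree)
  ape::vcv(tree)
}

#' Pagel's lambda transform of a phylogenetic covariance
#'
#' Multiplies the off-diagonal entries of C by `lam`, leaving tip
#' variances unchanged: `lam` = 1 is untransformed Brownian covariance,
#' `lam` = 0 removes all shared history (a star phylogeny with the
#' original tip depths).
#'
#' @param C Covariance matrix from [phylo_covariance()].
#' @param lam Lambda, usually in \[0, 1\].
#' @param check Error if the transformed matrix is not positive definite
#'   (signals `lam` too large for this tree). Default `TRUE`.
#' @return The transformed covariance matrix.
#' @export
lambda_transform <- function(C, lam, check = TRUE) {
  stopifnot(is.matrix(C), lam >= 0)
  Cl <- lam * C
  diag(Cl) <- diag(C)
  if (check) {
    ok <- tryCatch({ chol(Cl); TRUE }, error = function(e) FALSE)
    if (!ok)
      stop("lambda-transformed covariance is not positive definite ",
           "(lam = ", lam, " too large for this tree)")
  }
  Cl
}

# Root-to-node path lengths (time from root) for all nodes.
.node_times <- function(tree) ape::node.depth.edgelength(tree)
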