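test_that("Newick parsing preserves topology, lengths and depths", {
  tr <- read_chronogram("((A:1,B:1):1,C:2);")
  expect_identical(length(tr$tip.label), 3L)
  d <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(unname(d), c(2, 2, 2))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_chronogram(tr, f)
  back <- read_chronogram(f)
  expect_equal(back$edge.length, tr$edge.length)
  expect_identical(back$tip.label, tr$tip.label)
  expect_true(ape::all.equal.phylo(back, tr, use.edge.length = TRUE))
  expect_error(read_chronogram("((A,B),C);"), "branch length")
  expect_error(read_chronogram("((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("NEXUS tree files are accepted", {
  tr <- read_chronogram("((A:1,B:1):1,C:2);")
  f <- withr::local_tempfile(fileext = ".nex")
  ape::write.nexus(tr, file = f)
  back <- read_chronogram(f)
  expect_true(ape::all.equal.phylo(back, tr, use.edge.length = TRUE))
})

test_that("zero-length cherries do not break the signal statistics", {
  tr <- read_chronogram("((A:0,B:0):5,(C:2,D:3):4);")
  x <- c(A = 1.0, B = 1.4, C = 0.2, D = 2.2)
  expect_true(is.finite(blomberg_K(x, tr)))
  expect_true(is.finite(pagel_lambda(x, tr)$estimate))
})

test_that("the packaged reconstructed chronograms match the specimen tables", {
  for (ds in c("testudinata", "pseudosuchia")) {
    tab <- specimen_fixture(ds)
    tr <- chronogram_fixture(ds)
    groups <- specimen_groups(tab)
    expect_setequal(tr$tip.label, names(groups))
    sp <- split_conspecific_tips(tr, groups)
    expect_identical(length(sp$tip.label), nrow(tab))
    expect_setequal(sp$tip.label, tab$specimen_id)
  }
})

test_that("the 1-Myr conspecific split follows the cherry rule", {
  tr <- read_chronogram("(A:10,B:20);")
  out <- split_conspecific_tips(tr, list(A = c("a1", "a2")), delta = 1)
  expect_setequal(out$tip.label, c("a1", "a2", "B"))
  d <- ape::node.depth.edgelength(out)
  names(d) <- c(out$tip.label, rep("", out$Nnode))
  expect_equal(unname(d[c("a1", "a2")]), c(10, 10))   # tip ages preserved
  # pendant branches of length delta under a node 1 Myr before the tip age
  pend <- out$edge.length[match(match(c("a1", "a2"), out$tip.label),
                                out$edge[, 2])]
  expect_equal(pend, c(1, 1))
  # size-1 groups only rename; size-3 groups trifurcate
  ren <- split_conspecific_tips(tr, list(B = "b1"))
  expect_setequal(ren$tip.label, c("A", "b1"))
  expect_equal(sort(ren$edge.length), sort(tr$edge.length))
  tri <- split_conspecific_tips(tr, list(B = c("b1", "b2", "b3")), delta = 1)
  expect_identical(length(tri$tip.label), 4L)
  d3 <- ape::node.depth.edgelength(tri)
  names(d3) <- c(tri$tip.label, rep("", tri$Nnode))
  expect_equal(unname(d3[c("b1", "b2", "b3")]), c(20, 20, 20))
  parent_of <- function(tree, lab)
    tree$edge[tree$edge[, 2] == match(lab, tree$tip.label), 1]
  expect_identical(length(unique(vapply(c("b1", "b2", "b3"), parent_of,
                                        0, tree = tri))), 1L)
  expect_error(split_conspecific_tips(tr, list(A = c("a1", "a2")),
                                      delta = 0), "positive")
  expect_error(split_conspecific_tips(tr, list(Z = "z1")), "not found")
  expect_error(split_conspecific_tips(tr, list(A = c("a1", "a2")),
                                      delta = 15), "shorter than delta")
})

test_that("splitting preserves between-group shared history", {
  tr <- chronogram_fixture("testudinata")
  tab <- specimen_fixture("testudinata")
  sp <- split_conspecific_tips(tr, specimen_groups(tab))
  C0 <- phylo_covariance(tr)
  C1 <- phylo_covariance(sp)
  # specimens of different taxa share exactly the history of their taxa
  expect_equal(C1["Caretta_caretta_1", "Archelon_ischyros"],
               C0["Caretta_caretta", "Archelon_ischyros"])
  expect_equal(C1["Bothremys_barberi_2", "Taphrosphys_sulcatus_1"],
               C0["Bothremys_barberi", "Taphrosphys_sulcatus"])
  # conspecific specimens split delta = 1 Myr before the tip age
  expect_equal(C1["Caretta_caretta_1", "Caretta_caretta_2"],
               C1["Caretta_caretta_1", "Caretta_caretta_1"] - 1)
})

test_that("phylo_covariance matches path sums, brute force and the star identity", {
  tr <- read_chronogram("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(unname(C[c("A", "B", "C"), c("A", "B", "C")]),
               rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  star <- simulate_tree(7, "star", depth = 3)
  expect_equal(unname(phylo_covariance(star)), diag(3, 7))
  set.seed(9)
  rand <- simulate_tree(12, "yule", depth = 50, seed = 9)
  expect_equal(phylo_covariance(rand), vcv_bruteforce(rand))
  # non-ultrametric: fossil tips end early, diagonals differ
  fossil <- read_chronogram("((A:5,B:2):3,C:9);")
  expect_equal(unname(diag(phylo_covariance(fossil))), c(8, 5, 9))
  expect_equal(phylo_covariance(fossil), vcv_bruteforce(fossil))
})

test_that("lambda transform scales off-diagonals only and flags invalid lambda", {
  tr <- read_chronogram("((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(unname(lambda_transform(C, 0)), diag(2, 3))
  half <- lambda_transform(C, 0.5)
  expect_equal(unname(half[c("A", "B", "C"), c("A", "B", "C")]),
               rbind(c(2, 0.5, 0), c(0.5, 2, 0), c(0, 0, 2)))
  # linear in lambda off-diagonal
  l1 <- lambda_transform(C, 0.3); l2 <- lambda_transform(C, 0.6)
  expect_equal(l2["A", "B"], 2 * l1["A", "B"])
  expect_error(lambda_transform(C, 3), "not positive definite")
})
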