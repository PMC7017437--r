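test_that("the one-way F statistic matches hand computation and the oracle", {
  # equal group means -> F = 0
  expect_equal(classical_anova_F(c(1, 3, 0, 4), c("a", "a", "b", "b")), 0)
  # worked 2x3 instance: groups (1,2,3) and (3,4,5): SSB = 6, SSW = 4,
  # F = 6 / (4/4) = 6
  expect_equal(classical_anova_F(c(1, 2, 3, 3, 4, 5),
                                 rep(c("a", "b"), each = 3)), 6)
  set.seed(101)
  for (i in 1:5) {
    x <- rnorm(20)
    g <- sample(letters[1:3], 20, replace = TRUE)
    expect_equal(classical_anova_F(x, g), anova_F_oracle(x, g),
                 tolerance = 1e-10)
  }
  expect_error(classical_anova_F(rep(1, 6), rep(c("a", "b"), 3)),
               "identical")
  expect_error(classical_anova_F(1:4, rep("a", 4)), "two groups")
})

test_that("the vectorised F used by the simulation null matches the scalar path", {
  set.seed(55)
  X <- matrix(rnorm(15 * 20), 15, 20)
  g <- rep(c("u", "v", "w"), each = 5)
  Fv <- dermovasc:::.F_columns(X, g)
  Fs <- apply(X, 2, classical_anova_F, groups = g)
  expect_equal(Fv, Fs, tolerance = 1e-10)
})

test_that("phylo_anova p-values are invariant to label renaming and affine traits", {
  tr <- simulate_tree(16, "yule", depth = 30, seed = 81)
  x <- simulate_traits(tr, seed = 82)
  g <- rep(c("g1", "g2"), each = 8)
  a1 <- phylo_anova(x, g, tr, n_sim = 500, seed = 9)
  a2 <- phylo_anova(x, ifelse(g == "g1", "left", "right"), tr,
                    n_sim = 500, seed = 9)
  expect_equal(a1$p_phylogenetic, a2$p_phylogenetic)
  a3 <- phylo_anova(5 * x - 2, g, tr, n_sim = 500, seed = 9)
  expect_equal(a1$F_observed, a3$F_observed, tolerance = 1e-9)
  expect_equal(a1$p_phylogenetic, a3$p_phylogenetic)
  expect_error(phylo_anova(x, g, tr, mode = "nonsense"), "arg")
})

test_that("phylogeny absorbs clade-aligned apparent effects", {
  # groups assigned by clade, strong Brownian signal, no true effect:
  # the phylogenetic p should exceed the classical p on average
  tr <- simulate_tree(16, "balanced", depth = 30)
  clade <- rep(c("g1", "g2"), each = 8)     # the two root subclades
  set.seed(202)
  diff <- vapply(1:50, function(i) {
    x <- simulate_traits(tr, sigma2 = 1)
    a <- phylo_anova(x, clade, tr, n_sim = 199)
    a$p_phylogenetic - a$p_classical
  }, 0)
  expect_gt(mean(diff), 0)
})

test_that("a large lifestyle shift on a star tree is detected with high power", {
  star <- simulate_tree(24, "star", depth = 10)
  g <- rep(c("a", "b"), each = 12)
  set.seed(303)
  rej <- vapply(1:60, function(i) {
    # shift of 3 within-group sd (sd = sqrt(10) at depth 10, sigma2 = 1)
    x <- simulate_traits(star, sigma2 = 1, groups = g,
                         effects = c(a = 0, b = 3 * sqrt(10)))
    phylo_anova(x, g, star, n_sim = 199)$p_phylogenetic <= 0.05
  }, NA)
  expect_gte(mean(rej), 0.9)
})

test_that("GLS modes agree with the simulation mode in the no-structure limit", {
  star <- simulate_tree(20, "star", depth = 5)
  x <- simulate_traits(star, seed = 91)
  g <- rep(c("a", "b"), 10)
  sim <- phylo_anova(x, g, star, n_sim = 5000, seed = 92)
  glsK <- phylo_anova(x, g, star, mode = "gls_K_scaled")
  # on a star tree the GLS test reduces to the classical one
  expect_equal(glsK$p_phylogenetic, sim$p_classical, tolerance = 1e-9)
  expect_true(is.na(glsK$n_simulations))
})

test_that("group_stats matches brute-force recomputation and flags singletons", {
  t1b <- specimen_fixture("pseudosuchia")
  gs <- group_stats(t1b)
  med_bf <- function(v) {       # midpoint of the two central values
    s <- sort(v); n <- length(v)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  for (r in seq_len(nrow(gs))) {
    v <- t1b$porosity[t1b$lifestyle == gs$lifestyle[r]]
    expect_identical(gs$n[r], length(v))
    expect_equal(gs$mean[r], sum(v) / length(v))
    expect_equal(gs$median[r], med_bf(v))
    expect_equal(gs$sd[r], sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
    expect_identical(gs$min[r], min(v))
    expect_identical(gs$max[r], max(v))
  }
  # random subsets keep the agreement
  set.seed(404)
  idx <- sort(sample(nrow(t1b), 15))
  sub <- as_specimen_table(as.data.frame(t1b)[idx, ], "pseudosuchia")
  gs2 <- group_stats(sub)
  for (r in seq_len(nrow(gs2))) {
    v <- sub$porosity[sub$lifestyle == gs2$lifestyle[r]]
    expect_equal(gs2$median[r], median(v))
  }
  single <- as_specimen_table(as.data.frame(t1b)[1, ], "pseudosuchia")
  gs3 <- group_stats(single)
  expect_false(gs3$sd_defined[1])
  expect_identical(gs3$sd[1], 0)
  expect_equal(gs3$mean[1], gs3$median[1])
})

test_that("report rounding is half away from zero", {
  expect_identical(round_half_up(0.325, 2), 0.33)
  expect_identical(round_half_up(0.175, 2), 0.18)
  expect_identical(round_half_up(-0.325, 2), -0.33)
  expect_identical(round_half_up(0.08833333, 2), 0.09)
})
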