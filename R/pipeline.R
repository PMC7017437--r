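#' Run the full comparative analysis for one dataset
#'
#' Loads (or accepts) a specimen table and a species-level chronogram,
#' expands conspecific plates into 1-Myr cherries, and computes the whole
#' analysis surface: per-lifestyle descriptive statistics, Blomberg's K
#' with randomization test, Pagel's lambda by ML, the phylogenetic ANOVA
#' of porosity against lifestyle, squared-change parsimony ancestral
#' states, and long-format data for lifestyle boxplots.
#'
#' @param dataset `"testudinata"` or `"pseudosuchia"` (selects the
#'   packaged fixtures when `table`/`tree` are not supplied).
#' @param table Optional `"specimen_table"`; defaults to
#'   [specimen_fixture()].
#' @param tree Optional species-level `"phylo"` chronogram whose tips are
#'   the taxon slugs of the table; defaults to [chronogram_fixture()].
#' @param delta Conspecific split depth in Myr (default 1).
#' @param n_perm Randomizations for the K test.
#' @param n_sim Simulations for the phylogenetic ANOVA null.
#' @param anova_mode Null construction, see [phylo_anova()].
#' @param include_outgroup Keep specimens whose clade is
#'   `"Avemetatarsalia-outgroup"` (default `TRUE`, reproducing the
#'   analysed sample; set `FALSE` to restrict to the named clade).
#' @param seed Integer seed driving the K randomization and the ANOVA
#'   simulations.
#' @param out_dir Optional directory; when given, the result tables are
#'   written there as CSV files.
#' @return Object of class `"dermovasc_run"`: list with `dataset`,
#'   `table`, `tree` (the specimen-level tree), `group_stats`, `K`,
#'   `lambda`, `anova`, `ancestral`, `boxplot_data`.
#' @export
run_pipeline <- function(dataset = c("testudinata", "pseudosuchia"),
                         table = NULL, tree = NULL, delta = 1,
                         n_perm = 999, n_sim = 1000,
                         anova_mode = "bm_simulation",
                         include_outgroup = TRUE, seed = 1,
                         out_dir = NULL) {
  dataset <- match.arg(dataset)
  if (is.null(table)) table <- specimen_fixture(dataset)
  if (is.null(tree)) tree <- chronogram_fixture(dataset)
  if (!include_outgroup) {
    drop_slugs <- unique(taxon_slug(table$taxon[table$clade ==
                                                "Avemetatarsalia-outgroup"]))
    table <- table[table$clade != "Avemetatarsalia-outgroup", , drop = FALSE]
    class(table) <- c("specimen_table", "data.frame")
    attr(table, "dataset") <- dataset
    tree <- ape::drop.tip(tree, intersect(drop_slugs, tree$tip.label))
  }
  groups <- specimen_groups(table)
  missing_tips <- setdiff(names(groups), tree$tip.label)
  if (length(missing_tips))
    stop("taxon missing from the tree: ", missing_tips[1])
  sp_tree <- split_conspecific_tips(tree, groups, delta = delta)
  traits <- stats::setNames(table$porosity, table$specimen_id)
  lifestyles <- stats::setNames(table$lifestyle,
                                table$specimen_id)[sp_tree$tip.label]
  stats_tab <- group_stats(table)
  K <- blomberg_K_test(traits, sp_tree, n_perm = n_perm, seed = seed)
  lam <- pagel_lambda(traits, sp_tree)
  av <- phylo_anova(traits, lifestyles, sp_tree, n_sim = n_sim,
                    mode = anova_mode, seed = seed + 1)
  anc <- squared_change_parsimony(sp_tree, traits)
  box <- data.frame(specimen_id = table$specimen_id,
                    lifestyle = table$lifestyle,
                    porosity = table$porosity)
  out <- structure(list(dataset = dataset, table = table, tree = sp_tree,
                        group_stats = stats_tab, K = K, lambda = lam,
                        anova = av, ancestral = anc, boxplot_data = box),
                   class = "dermovasc_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(stats_tab),
                     file.path(out_dir, "group_stats.csv"), row.names = FALSE)
    sig <- data.frame(statistic = c("K", "lambda"),
                      estimate = c(K$estimate, lam$estimate),
                      p_value = c(K$p_value, lam$p_value))
    utils::write.csv(sig, file.path(out_dir, "signal.csv"), row.names = FALSE)
    utils::write.csv(data.frame(F_observed = av$F_observed,
                                p_phylogenetic = av$p_phylogenetic,
                                p_classical = av$p_classical,
                                mode = av$mode),
                     file.path(out_dir, "anova.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(anc),
                     file.path(out_dir, "ancestral_states.csv"),
                     row.names = FALSE)
    utils::write.csv(box, file.path(out_dir, "boxplot_data.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.dermovasc_run <- function(x, ...) {
  cat("== dermovasc analysis:", x$dataset, "==\n")
  cat(nrow(x$table), "specimens,", length(x$tree$tip.label),
      "tree tips\n\n")
  print(x$group_stats)
  cat("\n")
  print(x$K)
  print(x$lambda)
  print(x$anova)
  invisible(x)
}

#' @describeIn run_pipeline Boxplot of porosity by lifestyle.
#' @param x A `"dermovasc_run"`.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.dermovasc_run <- function(x, ...) {
  graphics::boxplot(porosity ~ lifestyle, data = x$boxplot_data,
                    ylab = "vascular area fraction",
                    main = x$dataset, ...)
  invisible(x)
}
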