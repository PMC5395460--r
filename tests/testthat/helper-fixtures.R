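# Shared fixtures, built in code. Helpers load once per test run.

# the 3-tip worked example used throughout the operation contracts
toy_tree <- function() parse_newick("((A:1,B:1):1,C:2);")

# balanced 4-tip tree with cherries at age 1 and root at age 3
quartet_tree <- function() parse_newick("((A:1,B:1):2,(C:1,D:1):2);")

# occurrence fixture matching the worked WE/PE examples:
# A in cells {1,2}, B in {1}, C in {2,3}
toy_occ <- function() {
  occurrence_matrix(
    data.frame(species = c("A", "A", "B", "C", "C"),
               cell = c(1L, 2L, 1L, 2L, 3L)),
    width = 3L, height = 1L)
}

# medium synthetic dataset reused across tests (computed once per run)
.fixture_cache <- new.env(parent = emptyenv())

medium_dataset <- function() {
  if (is.null(.fixture_cache$medium)) {
    cfg <- sim_config(seed = 42L, n_species = 120L, n_genera = 8L,
                      threat_mode = "clustered", grid_width = 20L,
                      grid_height = 12L)
    tree <- simulate_cycad_like_tree(cfg)
    .fixture_cache$medium <- list(
      cfg = cfg,
      tree = tree,
      threats = simulate_threats(tree, cfg),
      occ = simulate_occurrences(tree, cfg),
      mask = simulate_protected_mask(cfg))
  }
  .fixture_cache$medium
}

# an internal node whose clade holds 10-25 tips (so both the clade and its
# complement have plenty of branches)
pick_mid_clade <- function(tree) {
  n <- ape::Ntip(tree)
  for (nd in (n + 1L):(n + tree$Nnode)) {
    k <- length(clade_tips(tree, nd))
    if (k >= 10 && k <= min(25, n - 10)) return(nd)
  }
  stop("no mid-sized clade in fixture tree")
}

# random non-ultrametric trees for round-trip properties
random_newick_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- round(tr$edge.length, 6)
  tr
}

expect_tree_equal <- function(a, b, tol = 1e-9) {
  expect_identical(sort(a$tip.label), sort(b$tip.label))
  expect_equal(ape::dist.topo(ape::unroot(a), ape::unroot(b)), 0,
               ignore_attr = TRUE)
  da <- ape::cophenetic.phylo(a)
  db <- ape::cophenetic.phylo(b)[rownames(da), colnames(da)]
  expect_equal(da, db, tolerance = tol)
}
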