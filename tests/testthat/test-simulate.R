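test_that("simulate_tree yields ultrametric trees of the requested size, deterministically", {
  cfg <- sim_config(seed = 1L, n_species = 50L, birth = 0.1)
  tr <- simulate_tree(cfg)
  expect_equal(ape::Ntip(tr), 50L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  tr2 <- simulate_tree(cfg)
  expect_identical(write_newick(tr), write_newick(tr2))
  expect_error(simulate_tree(sim_config(seed = 1L, birth = 0)),
               "birth rate must be > 0")
})

test_that("Yule waiting times match the exponential-growth expectation", {
  # from 2 lineages, the wait at k lineages is Exp(k r), so the root age of
  # an n-tip tree (with the final unapplied wait at n lineages) has exact
  # mean (H_{n-1} - 1 + 1/n) / r -- the discrete counterpart of
  # E[N(T)] = 2 exp(rT) growth. Checked over replicates within 4 SE.
  r <- 0.2
  n <- 40L
  ages <- vapply(1:200, function(i)
    branching_times(simulate_tree(sim_config(seed = 5000L + i,
                                             n_species = n, birth = r)))[1],
    numeric(1))
  expected <- (sum(1 / seq_len(n - 1)) - 1 + 1 / n) / r
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - expected), 4 * se)
})

test_that("birth-death simulation prunes extinct lineages and stays ultrametric", {
  cfg <- sim_config(seed = 3L, n_species = 40L, birth = 0.3, death = 0.1)
  tr <- simulate_tree(cfg)
  expect_equal(ape::Ntip(tr), 40L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
})

test_that("cycad-like trees have monophyletic genera with stems older than crowns", {
  d <- medium_dataset()
  tree <- d$tree
  genus <- attr(tree, "genus")
  expect_equal(ape::Ntip(tree), d$cfg$n_species)
  expect_true(ape::is.ultrametric(tree, tol = 1e-8))
  ages <- node_ages(tree)
  for (g in unique(genus)) {
    tips <- names(genus)[genus == g]
    if (length(tips) < 2L) next
    crown <- ape::getMRCA(tree, tips)
    expect_setequal(clade_tips(tree, crown), tips) # monophyly
    stem_parent <- tree$edge[tree$edge[, 2] == crown, 1]
    expect_lt(ages[crown], 13 + 1e-9)   # crown radiation recent
    expect_gt(ages[stem_parent], 40 - 1e-9) # stem attachment deep
  }
  expect_error(simulate_cycad_like_tree(sim_config(n_species = 5L,
                                                   n_genera = 8L)),
               "n_species must be >= n_genera")
})

test_that("a monotypic genus concentrates more ED than tips of a big radiation", {
  # this draw has two monotypic genera and a 96-species radiation
  cfg <- sim_config(seed = 7L, n_species = 120L, n_genera = 8L)
  tree <- simulate_cycad_like_tree(cfg)
  genus <- attr(tree, "genus")
  sizes <- table(genus)
  ed <- fair_proportion_ed(tree)
  mono <- names(sizes)[sizes == 1]
  big <- names(sizes)[which.max(sizes)]
  expect_gte(length(mono), 1)
  expect_gte(max(sizes), 90)
  ed_mono <- mean(ed[names(genus)[genus %in% mono]])
  ed_big <- mean(ed[names(genus)[genus == big]])
  expect_gt(ed_mono, ed_big)
})

test_that("threat simulation matches requested marginals", {
  d <- medium_dataset()
  # clustered mode: quantile assignment gives exact quota counts
  th <- d$threats
  probs <- d$cfg$category_probs
  n <- d$cfg$n_species
  cnt <- table(factor(th$category, levels = names(probs)))
  expect_equal(sum(cnt[c("VU", "EN", "CR")]),
               sum(round(probs[c("VU", "EN", "CR")] * n)), tolerance = 1)
  # iid mode with degenerate probs
  cfg_lc <- sim_config(seed = 2L, n_species = 30L,
                       category_probs = c(LC = 1, NT = 0, VU = 0, EN = 0,
                                          CR = 0, DD = 0))
  tr <- simulate_tree(cfg_lc)
  expect_true(all(simulate_threats(tr, cfg_lc)$category == "LC"))
})

test_that("emulated IUCN marginals give 215 threatened of 339 in expectation", {
  cfg <- sim_config(seed = 9L, n_species = 339L, n_genera = 11L)
  tree <- simulate_cycad_like_tree(cfg)
  th <- simulate_threats(tree, cfg) # iid mode
  n_thr <- sum(th$category %in% c("VU", "EN", "CR"))
  p <- sum(cfg$category_probs[c("VU", "EN", "CR")])
  expect_equal(p, 215 / 339, tolerance = 1e-12)
  sd_bin <- sqrt(339 * p * (1 - p))
  expect_lt(abs(n_thr - 215), 4 * sd_bin)
})

test_that("occurrences cover every species with contiguous patches", {
  d <- medium_dataset()
  occ <- d$occ
  expect_setequal(unique(occ$species), d$tree$tip.label)
  expect_true(all(occ$cell >= 1 &
                    occ$cell <= d$cfg$grid_width * d$cfg$grid_height))
  # determinism
  occ2 <- simulate_occurrences(d$tree, d$cfg)
  expect_identical(occ, occ2)
})

test_that("Brownian niche centers make sister species overlap more than random pairs", {
  overlap <- function(occ, s1, s2) {
    c1 <- occ$cell[occ$species == s1]
    c2 <- occ$cell[occ$species == s2]
    length(intersect(c1, c2)) / min(length(c1), length(c2))
  }
  set.seed(31)
  sis_vals <- rand_vals <- numeric(0)
  for (i in 1:30) {
    cfg <- sim_config(seed = 600L + i, n_species = 60L, n_genera = 6L,
                      grid_width = 15L, grid_height = 10L)
    tree <- simulate_cycad_like_tree(cfg)
    occ <- simulate_occurrences(tree, cfg)
    # sister pairs: cherries
    n <- ape::Ntip(tree)
    par <- tree$edge[tree$edge[, 2] <= n, 1]
    cherries <- names(which(table(par) == 2))
    for (nd in cherries) {
      pair <- tree$tip.label[tree$edge[tree$edge[, 1] == as.integer(nd), 2]]
      sis_vals <- c(sis_vals, overlap(occ, pair[1], pair[2]))
    }
    rnd <- replicate(length(cherries), sample(tree$tip.label, 2))
    rand_vals <- c(rand_vals,
                   apply(rnd, 2, function(p) overlap(occ, p[1], p[2])))
  }
  expect_gt(mean(sis_vals), mean(rand_vals))
})

test_that("protected mask hits its target mean and its extremes", {
  cfg <- sim_config(seed = 4L, protected_fraction = 0.3, grid_width = 30L,
                    grid_height = 20L)
  mask <- simulate_protected_mask(cfg)
  expect_equal(nrow(mask), 600L)
  expect_true(all(mask$protected_fraction >= 0 &
                    mask$protected_fraction <= 1))
  expect_lt(abs(mean(mask$protected_fraction) - 0.3), 0.05)
  expect_identical(mask, simulate_protected_mask(cfg))

  m0 <- simulate_protected_mask(sim_config(seed = 4L, protected_fraction = 0))
  expect_true(all(m0$protected_fraction == 0))
  m1 <- simulate_protected_mask(sim_config(seed = 4L, protected_fraction = 1))
  expect_true(all(m1$protected_fraction == 1))
})

test_that("grafting adds congeners without disturbing original relationships", {
  d <- medium_dataset()
  tree <- d$tree
  genus <- attr(tree, "genus")
  taxon_list <- data.frame(species = names(genus), genus = unname(genus))
  # empty list of missing species: identity
  expect_identical(graft_missing_taxa(tree, taxon_list[0, ], seed = 1),
                   tree)
  # remove a third of the tips (keeping one per genus), graft them back
  set.seed(77)
  keep_one <- vapply(split(names(genus), genus), `[`, "", 1)
  missing <- sample(setdiff(tree$tip.label, keep_one), 40)
  constraint <- prune_to(tree, setdiff(tree$tip.label, missing))
  full <- graft_missing_taxa(constraint, taxon_list, seed = 5)
  expect_equal(ape::Ntip(full), ape::Ntip(tree))
  expect_true(ape::is.ultrametric(full, tol = 1e-8))
  # genus monophyly preserved
  g2 <- genus[full$tip.label]
  for (g in unique(g2)) {
    tips <- full$tip.label[g2 == g]
    if (length(tips) < 2) next
    expect_setequal(clade_tips(full, ape::getMRCA(full, tips)), tips)
  }
  # original subtree relationships unchanged
  back <- prune_to(full, constraint$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(constraint)), 0,
               ignore_attr = TRUE)
  # genus with no anchor is an error
  orphan <- data.frame(species = "Zz_sp1", genus = "Zz")
  expect_error(graft_missing_taxa(constraint, orphan, seed = 1),
               "absent from constraint tree")
})

test_that("grafting one species into a two-tip genus keeps monophyly", {
  tr <- parse_newick("((G1_sp1:5,G1_sp2:5):45,G2_sp1:50);")
  tl <- data.frame(species = c("G1_sp1", "G1_sp2", "G1_sp3", "G2_sp1"),
                   genus = c("G1", "G1", "G1", "G2"))
  out <- graft_missing_taxa(tr, tl, seed = 3)
  expect_equal(ape::Ntip(out), 4L)
  expect_true(ape::is.ultrametric(out, tol = 1e-8))
  g1 <- c("G1_sp1", "G1_sp2", "G1_sp3")
  expect_setequal(clade_tips(out, ape::getMRCA(out, g1)), g1)
})
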