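test_that("faith_pd reproduces the worked 3-tip values", {
  tr <- toy_tree()
  expect_equal(faith_pd(tr, c("A", "B", "C")), 5)
  expect_equal(faith_pd(tr, c("A", "B")), 3)
  expect_equal(faith_pd(tr, "A"), 2)
  expect_equal(faith_pd(tr, "C"), 2)
  expect_error(faith_pd(tr, character(0)), "undefined")
  expect_error(faith_pd(tr, "Z"), "not on tree")
})

test_that("faith_pd is monotone under inclusion and matches picante", {
  d <- medium_dataset()
  tree <- d$tree
  set.seed(11)
  for (i in 1:10) {
    small <- sample(tree$tip.label, 10)
    big <- union(small, sample(tree$tip.label, 30))
    expect_lte(faith_pd(tree, small), faith_pd(tree, big) + 1e-9)
  }
  skip_if_not_installed("picante")
  subs <- sample(tree$tip.label, 25)
  comm <- matrix(as.integer(tree$tip.label %in% subs), nrow = 1,
                 dimnames = list("cell", tree$tip.label))
  oracle <- picante::pd(comm, tree, include.root = TRUE)$PD
  expect_equal(faith_pd(tree, subs), oracle, tolerance = 1e-9)
})

test_that("fair-proportion ED matches hand values and conserves PD", {
  ed <- fair_proportion_ed(toy_tree())
  expect_equal(unname(ed[c("A", "B", "C")]), c(1.5, 1.5, 2))
  # star tree symmetry
  star <- parse_newick("(A:3,B:3,C:3,D:3);")
  expect_true(all(abs(fair_proportion_ed(star) - 3) < 1e-12))
  # conservation on a large simulated tree
  d <- medium_dataset()
  ed_big <- fair_proportion_ed(d$tree)
  expect_equal(sum(ed_big), total_tree_length(d$tree),
               tolerance = 1e-6)
  skip_if_not_installed("picante")
  oracle <- picante::evol.distinct(d$tree, type = "fair.proportion")
  expect_equal(unname(ed_big[oracle$Species]), oracle$w, tolerance = 1e-9)
})

test_that("GE coding follows the fixed IUCN mapping and excludes DD", {
  expect_identical(ge_code(c("LC", "NT", "CD", "VU", "EN", "CR")),
                   c(0L, 1L, 1L, 2L, 3L, 4L))
  expect_error(ge_code("DD"), "excluded before EDGE")
  expect_error(ge_code("VULNERABLE"), "unknown IUCN")
})

test_that("EDGE formula and ranking behave per contract", {
  # frozen high-precision formula evaluations: ln(1+ED) + GE ln 2
  th <- data.frame(species = c("a", "b", "c"),
                   category = c("CR", "EN", "LC"))
  ed <- c(a = exp(1) - 1, b = 1.5, c = 0)
  tab <- edge_scores(ed, th)
  expect_equal(tab$EDGE[tab$species == "a"], 1 + 4 * log(2))
  expect_equal(tab$EDGE[tab$species == "a"], 3.772588722239781,
               tolerance = 1e-12)
  expect_equal(tab$EDGE[tab$species == "b"], log(2.5) + 3 * log(2))
  expect_equal(tab$EDGE[tab$species == "b"], 2.995732273553991,
               tolerance = 1e-12)
  expect_equal(tab$EDGE[tab$species == "c"], 0)
  expect_identical(tab$rank, 1:3)
  expect_true(all(diff(tab$EDGE) <= 0))

  # EDGE strictly increasing in ED at fixed GE, and in GE at fixed ED
  expect_gt(log1p(2) + 2 * log(2), log1p(1.5) + 2 * log(2))
  tab2 <- edge_scores(c(a = 1, b = 1), data.frame(
    species = c("a", "b"), category = c("EN", "VU")))
  expect_gt(tab2$EDGE[tab2$species == "a"], tab2$EDGE[tab2$species == "b"])

  # DD excluded before scoring; missing ED for scored species errors
  th_dd <- data.frame(species = c("a", "b"), category = c("DD", "LC"))
  expect_identical(edge_scores(c(a = 1, b = 1), th_dd)$species, "b")
  expect_error(edge_scores(c(a = 1), data.frame(species = "z",
                                                category = "LC")),
               "missing ED")
})

test_that("grid SR counts species per occupied cell only", {
  sr <- grid_sr(toy_occ())
  expect_equal(sr$value[match(1:3, sr$cell)], c(2, 2, 1))
  # unoccupied cells are absent rather than zero
  sparse <- occurrence_matrix(data.frame(species = c("A", "B", "C"),
                                         cell = c(1L, 1L, 5L)), 5L, 1L)
  sr2 <- grid_sr(sparse)
  expect_setequal(sr2$cell, c(1L, 5L))
  expect_equal(sr2$value[sr2$cell == 1], 2)
  # all species stacked in one cell
  expect_equal(max(grid_sr(toy_occ())$value), 2)
})

test_that("grid PD uses the rooted PD of the cell's species", {
  tr <- toy_tree()
  pd <- grid_pd(tr, toy_occ())
  # cell 1 = {A,B} -> 3; cell 2 = {A,C} -> 1+1+2 = 4; cell 3 = {C} -> 2
  expect_equal(pd$value[match(1:3, pd$cell)], c(3, 4, 2))
  total <- total_tree_length(tr)
  expect_true(all(pd$value <= total + 1e-12))
  bad <- occurrence_matrix(data.frame(species = "Z", cell = 1L), 3L, 1L)
  expect_error(grid_pd(tr, bad), "missing from tree: Z")
})

test_that("weighted endemism reproduces hand values and conserves richness", {
  we <- weighted_endemism(toy_occ())
  expect_equal(we$WE$value[match(1:3, we$WE$cell)], c(1.5, 1.0, 0.5))
  expect_equal(sum(we$WE$value), 3) # = number of species
  expect_equal(we$CWE$value[we$CWE$cell == 1], 0.75)
  # single-cell endemic alone in its cell
  solo <- occurrence_matrix(data.frame(species = "X", cell = 5L), 5L, 1L)
  ws <- weighted_endemism(solo)
  expect_equal(ws$WE$value, 1)
  expect_equal(ws$CWE$value, 1)
})

test_that("phylogenetic endemism reproduces hand values and conserves PD", {
  tr <- toy_tree()
  pe <- phylogenetic_endemism(tr, toy_occ())
  expect_equal(pe$value[match(1:3, pe$cell)], c(2, 2, 1))
  expect_equal(sum(pe$value), 5) # = total PD
  # all species in one cell: PE(cell) = total PD
  one <- occurrence_matrix(data.frame(species = c("A", "B", "C"),
                                      cell = c(2L, 2L, 2L)), 3L, 1L)
  pe1 <- phylogenetic_endemism(tr, one)
  expect_equal(pe1$value, 5)
})

test_that("conservation laws and PE <= PD hold on simulated data", {
  d <- medium_dataset()
  we <- weighted_endemism(d$occ)
  expect_equal(sum(we$WE$value), length(unique(d$occ$species)),
               tolerance = 1e-6)
  pe <- phylogenetic_endemism(d$tree, d$occ)
  expect_equal(sum(pe$value), total_tree_length(d$tree), tolerance = 1e-6)
  pd <- grid_pd(d$tree, d$occ)
  joined <- merge(pe, pd, by = "cell")
  expect_true(all(joined$value.x <= joined$value.y + 1e-9))
})

test_that("mean EDGE per cell ignores DD species", {
  tr <- toy_tree()
  th <- data.frame(species = c("A", "B", "C"),
                   category = c("CR", "LC", "DD"))
  tab <- edge_scores(fair_proportion_ed(tr), th)
  occ <- toy_occ()
  me <- grid_mean_edge(tab, occ)
  edge_of <- stats::setNames(tab$EDGE, tab$species)
  # cell 1 = {A,B}; cell 2 = {A,C} but C is DD -> only A; cell 3 = {C} -> absent
  expect_equal(me$value[me$cell == 1],
               mean(edge_of[c("A", "B")]))
  expect_equal(me$value[me$cell == 2], unname(edge_of["A"]))
  expect_false(3 %in% me$cell)
})
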