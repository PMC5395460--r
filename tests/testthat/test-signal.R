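test_that("trait_change_sum matches hand recursion on small trees", {
  cherry <- parse_newick("(A:1,B:1);")
  expect_equal(trait_change_sum(cherry, c(A = 1, B = 0)), 1)
  q <- quartet_tree()
  # contrasts 0, 0 at the cherries, then |1 - 0| at the root
  expect_equal(trait_change_sum(q, c(A = 1, B = 1, C = 0, D = 0)), 1)
  expect_equal(trait_change_sum(q, c(A = 1, B = 0, C = 1, D = 0)), 2)
  expect_error(trait_change_sum(q, c(A = 1, B = 1, C = 1, D = 1)),
               "monomorphic")
  expect_error(trait_change_sum(q, c(A = 1, B = 0, C = 1)), "missing")
})

test_that("D calibrates to 1 under permuted traits and 0 under Brownian-threshold", {
  set.seed(8)
  n_rep <- 30L
  D_rand <- D_bm <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(seed = 2000L + i, n_species = 120L, birth = 0.1)
    tree <- simulate_tree(cfg)
    n <- ape::Ntip(tree)
    x <- stats::setNames(sample(rep(c(1, 0), c(50, n - 50))),
                         tree$tip.label)
    D_rand[i] <- d_statistic(tree, x, n_perm = 200, n_sim = 200,
                             seed = i)$D
    cfg_cl <- sim_config(seed = 2000L + i, n_species = 120L, birth = 0.1,
                         threat_mode = "clustered",
                         category_probs = c(LC = 0.5, NT = 0, VU = 0,
                                            EN = 0, CR = 0.5, DD = 0))
    y <- threat_trait(simulate_threats(tree, cfg_cl))
    D_bm[i] <- d_statistic(tree, y, n_perm = 200, n_sim = 200,
                           seed = i)$D
  }
  se_rand <- stats::sd(D_rand) / sqrt(n_rep)
  se_bm <- stats::sd(D_bm) / sqrt(n_rep)
  expect_lt(abs(mean(D_rand) - 1), 4 * se_rand)
  expect_lt(abs(mean(D_bm) - 0), 4 * se_bm)
})

test_that("a perfectly clumped trait on a deep two-clade tree gives D < 0", {
  tree <- parse_newick(paste0(
    "(((A:1,B:1):19,(C:1,D:1):19):5,",
    "((E:1,F:1):19,(G:1,H:1):19):5);"))
  trait <- c(A = 1, B = 1, C = 1, D = 1, E = 0, F = 0, G = 0, H = 0)
  res <- suppressWarnings(
    d_statistic(tree, trait, n_perm = 500, n_sim = 500, seed = 2))
  expect_lt(res$D, 0)
  expect_lt(res$P_rand, 0.05)
})

test_that("D is invariant to swapping the 0/1 labels", {
  d <- medium_dataset()
  tree <- d$tree
  trait <- threat_trait(d$threats)
  a <- d_statistic(tree, trait, n_perm = 400, n_sim = 400, seed = 3)
  b <- d_statistic(tree, 1 - trait, n_perm = 400, n_sim = 400, seed = 3)
  # prevalence-complement symmetry within Monte-Carlo error
  expect_lt(abs(a$D - b$D), 0.35)
  expect_equal(a$d_obs, b$d_obs) # the observed change sum is exactly symmetric
})

test_that("tail conventions and smoothing follow the result contract", {
  d <- medium_dataset()
  res <- d_statistic(d$tree, threat_trait(d$threats), n_perm = 200,
                     n_sim = 200, seed = 4)
  expect_true(res$P_rand >= 0 && res$P_rand <= 1)
  expect_true(res$P_BM >= 0 && res$P_BM <= 1)
  expect_gt(res$P_rand_smoothed, 0)
  expect_gt(res$P_BM_smoothed, 0)
  expect_equal(res$P_rand_smoothed, (1 + res$P_rand * res$n_perm) /
                 (res$n_perm + 1), tolerance = 1e-12)
})

test_that("polytomies are resolved before computing contrasts", {
  poly <- parse_newick("((A:1,B:1,C:1):1,D:2);")
  expect_silent(d <- trait_change_sum(poly, c(A = 1, B = 0, C = 1, D = 0)))
  expect_true(is.finite(d))
})

test_that("ed_group_test is a classical one-way ANOVA", {
  # identical groups: F = 0
  ed <- c(a = 1, b = 2, c = 3, d = 1, e = 2, f = 3)
  grp <- c(a = "x", b = "x", c = "x", d = "y", e = "y", f = "y")
  res <- ed_group_test(ed, grp)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  # well-separated groups: tiny p
  ed2 <- c(a = 0.01, b = -0.01, c = 0.02, d = -0.02,
           e = 10.01, f = 9.99, g = 10.02, h = 9.98)
  grp2 <- stats::setNames(rep(c("lo", "hi"), each = 4), names(ed2))
  res2 <- ed_group_test(ed2, grp2)
  expect_lt(res2$p, 1e-3)
  # oracle: matches stats::oneway.test with equal variances
  set.seed(12)
  ed3 <- stats::setNames(rnorm(30), paste0("s", 1:30))
  grp3 <- stats::setNames(rep(c("u", "v", "w"), 10), names(ed3))
  res3 <- ed_group_test(ed3, grp3)
  oracle <- stats::oneway.test(ed3 ~ factor(grp3), var.equal = TRUE)
  expect_equal(res3$F, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(res3$p, oracle$p.value, tolerance = 1e-9)
  expect_error(ed_group_test(ed["a"], grp["a"]), "at least 2 groups")
  expect_error(ed_group_test(c(a = 1, b = 2, c = 3),
                             c(a = "x", b = "x", c = "y")), "< 2 members")
})

test_that("threat_trait derives the binary trait and drops DD", {
  th <- data.frame(species = c("a", "b", "c", "d"),
                   category = c("CR", "LC", "DD", "VU"))
  tr <- threat_trait(th)
  expect_equal(tr, c(a = 1, b = 0, d = 1))
})
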