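test_that("multi-rate likelihood collapses exactly to pure birth", {
  bt <- c(10, 7, 5, 3, 2, 1.5, 1, 0.5)
  for (r in c(0.05, 0.13, 0.7)) {
    base <- piecewise_yule_loglik(bt, r)
    expect_equal(piecewise_yule_loglik(bt, c(r, r), shifts = 4), base)
    expect_equal(piecewise_yule_loglik(bt, c(r, r, r), shifts = c(6, 2.2)),
                 base)
    expect_equal(bd_loglik(bt, r, 0), base, tolerance = 1e-12)
  }
  # worked 2-era example from the contract: equal rates, btimes [2, 1]
  bt2 <- c(2, 1)
  expect_equal(piecewise_yule_loglik(bt2, c(0.5, 0.5), shifts = 1.5),
               piecewise_yule_loglik(bt2, 0.5))
  expect_error(piecewise_yule_loglik(bt, c(0.1, 0.2), shifts = 12),
               "inside")
})

test_that("pure-birth closed form equals ape::yule and the numeric optimum", {
  cfg <- sim_config(seed = 5L, n_species = 150L, birth = 0.1)
  tree <- simulate_tree(cfg)
  bt <- branching_times(tree)
  fit <- fit_rate_constant(bt)$pureBirth
  expect_equal(fit$params[["r"]], ape::yule(tree)$lambda, tolerance = 1e-9)
  # the worked 3-tip branching times: closed form = numeric optimum
  bt3 <- c(2, 1)
  lt_total <- 2 * (2 - 1) + 3 * 1 # lineage-time
  expect_equal(fit_rate_constant(bt3)$pureBirth$params[["r"]], 1 / lt_total)
})

test_that("birth-death fit agrees with ape::birthdeath on simulated trees", {
  cfg <- sim_config(seed = 23L, n_species = 150L, birth = 0.25, death = 0.1)
  tree <- simulate_tree(cfg)
  bt <- branching_times(tree)
  ours <- fit_rate_constant(bt, seed = 2)$bd
  oracle <- ape::birthdeath(tree)
  expect_equal(ours$params[["r"]], unname(oracle$para["b-d"]),
               tolerance = 1e-3)
  expect_equal(ours$params[["a"]], unname(oracle$para["d/b"]),
               tolerance = 5e-3)
})

test_that("density-dependent models collapse at their boundary parameters", {
  cfg <- sim_config(seed = 6L, n_species = 80L, birth = 0.15)
  bt <- branching_times(simulate_tree(cfg))
  r <- 0.15
  base <- piecewise_yule_loglik(bt, r)
  ddx0 <- cycadrisk:::dd_loglik(bt, function(k) r * k^0)
  expect_equal(ddx0, base, tolerance = 1e-12)
  ddl_inf <- cycadrisk:::dd_loglik(bt, function(k) r * (1 - k / 1e9))
  expect_equal(ddl_inf, base, tolerance = 1e-3)
})

test_that("fitted DDL respects K > n and AIC bookkeeping is 2k - 2lnL", {
  cfg <- sim_config(seed = 31L, n_species = 100L, birth = 0.12)
  bt <- branching_times(simulate_tree(cfg))
  fits <- fit_diversification_models(bt, seed = 3)
  expect_gt(fits$DDL$params[["K"]], length(bt) + 1)
  k_expected <- c(pureBirth = 1, bd = 2, DDL = 2, DDX = 2,
                  yule2rate = 3, yule3rate = 5)
  for (nm in names(k_expected)) {
    expect_equal(fits[[nm]]$n_params, unname(k_expected[nm]))
    expect_equal(fits[[nm]]$AIC, 2 * fits[[nm]]$n_params - 2 * fits[[nm]]$lnL)
  }
  # nested-family ordering of maximized likelihoods
  expect_gte(fits$yule2rate$lnL, fits$pureBirth$lnL - 1e-9)
  expect_gte(fits$yule3rate$lnL, fits$yule2rate$lnL - 1e-9)
  expect_gte(fits$bd$lnL, fits$pureBirth$lnL - 1e-6)
  expect_gte(fits$DDX$lnL, fits$pureBirth$lnL - 1e-6)
})

test_that("two-era truth outranks swapped rates in the likelihood", {
  hits <- vapply(1:40, function(i) {
    cfg <- sim_config(seed = 4000L + i, n_species = 100L, birth = 0.2,
                      shift_times = 20, shift_rates = 0.02)
    bt <- branching_times(simulate_tree(cfg))
    shift_age <- bt[1] - 20
    if (shift_age <= 0) return(NA)
    piecewise_yule_loglik(bt, c(0.2, 0.02), shifts = shift_age) >
      piecewise_yule_loglik(bt, c(0.02, 0.2), shifts = shift_age)
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("select_model applies the delta-AIC rule with ties to rate-constant", {
  mkfit <- function(model, aic) list(model = model, AIC = aic, lnL = 0,
                                     n_params = 1)
  fits <- list(pureBirth = mkfit("pureBirth", 100), bd = mkfit("bd", 102),
               DDL = mkfit("DDL", 99), DDX = mkfit("DDX", 101),
               yule2rate = mkfit("yule2rate", 103),
               yule3rate = mkfit("yule3rate", 104))
  sel <- select_model(fits)
  expect_equal(sel$delta_aic_rc, 1)
  expect_identical(sel$verdict, "rate_variable")
  fits$DDL$AIC <- 100 # exact tie
  sel2 <- select_model(fits)
  expect_equal(sel2$delta_aic_rc, 0)
  expect_identical(sel2$verdict, "rate_constant")
  expect_error(select_model(fits["DDL"]), "per family")
})

test_that("clade rate comparison: pooled equals separate at equal means, power on scaled clades", {
  # LRT = 0 when the two sets have identical mean branch lengths
  tr <- parse_newick("(((A:1,B:1):1,C:1):1,((D:1,E:1):1,F:1):1);")
  n <- ape::Ntip(tr)
  res0 <- clade_rate_comparison(tr, ape::getMRCA(tr, c("A", "B", "C")))
  expect_equal(res0$lrt, 0, tolerance = 1e-9)
  expect_equal(res0$rate_ratio, 1, tolerance = 1e-9)

  # null calibration: iid exponential branch lengths, p approx uniform
  set.seed(9)
  base <- ape::rtree(40)
  clade <- pick_mid_clade(base)
  ps <- vapply(1:200, function(i) {
    tr2 <- base
    tr2$edge.length <- stats::rexp(nrow(tr2$edge), rate = 2)
    clade_rate_comparison(tr2, clade)$p
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)

  # power: clade branches scaled x0.1 flags hot at small p
  hot <- vapply(1:40, function(i) {
    tr2 <- base
    tr2$edge.length <- stats::rexp(nrow(tr2$edge), rate = 2)
    desc <- which(tr2$edge[, 2] %in%
                    cycadrisk:::crown_descendant_nodes(tr2, clade))
    tr2$edge.length[desc] <- tr2$edge.length[desc] * 0.1
    r <- clade_rate_comparison(tr2, clade)
    r$hot && r$p < 0.01
  }, logical(1))
  expect_gte(mean(hot), 0.95)
  expect_error(clade_rate_comparison(tr, 1L), "internal node")
})
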