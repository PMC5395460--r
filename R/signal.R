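# --- Fritz-Purvis D statistic for binary traits ---------------------------
#
# The observed trait-change sum d is computed by estimating internal node
# values tips-to-root as the unweighted mean of child values and summing the
# absolute child-vs-child differences over all internal nodes. D scales d_obs
# between the expectation under tip-label permutation (random, D = 1) and
# under a Brownian threshold model with matched prevalence (D = 0). Because
# the same estimator is used for the observed trait and both nulls, the
# construction is self-normalizing.

# per-node children list for a (binary-resolved) tree
children_list <- function(tree) {
  split(tree$edge[, 2L], factor(tree$edge[, 1L],
                                levels = seq_len(ape::Ntip(tree) + tree$Nnode)))
}

# trait-change sums for one or many trait columns at once.
# states: matrix (Ntip x nsim) of numeric tip values in tree tip order.
d_values_matrix <- function(tree, states) {
  n <- ape::Ntip(tree)
  nsim <- ncol(states)
  V <- matrix(0, n + tree$Nnode, nsim)
  V[seq_len(n), ] <- states
  po <- postorder_edges(tree)
  nodes <- unique(po$edge[, 1L]) # postorder: children before parents
  ch <- children_list(tree)
  d <- numeric(nsim)
  for (nd in nodes) {
    kids <- ch[[nd]]
    vals <- V[kids, , drop = FALSE]
    if (length(kids) == 2L) {
      d <- d + abs(vals[1L, ] - vals[2L, ])
    } else {
      prs <- utils::combn(length(kids), 2L)
      for (j in seq_len(ncol(prs)))
        d <- d + abs(vals[prs[1L, j], ] - vals[prs[2L, j], ])
    }
    V[nd, ] <- colMeans(vals)
  }
  d
}

#' Observed trait-change sum of a binary trait on a tree
#'
#' Internal node values are estimated tips-to-root as the unweighted mean of
#' child values; d is the sum over internal nodes of absolute differences
#' between child values (over all unordered child pairs at polytomies, which
#' are first resolved deterministically to zero-length bifurcations).
#'
#' @param tree A `"phylo"` object.
#' @param trait Named vector (tip labels) of 0/1 states, both states present.
#' @return The scalar trait-change sum d.
#' @export
trait_change_sum <- function(tree, trait) {
  tree <- resolve_polytomies(tree)
  x <- check_binary_trait(tree, trait)
  d_values_matrix(tree, matrix(x, ncol = 1L))
}

check_binary_trait <- function(tree, trait) {
  if (is.null(names(trait)))
    stop("trait must be named by tip label", call. = FALSE)
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss))
    stop("trait missing for tips: ", paste(utils::head(miss, 5),
                                           collapse = ", "), call. = FALSE)
  x <- as.numeric(trait[tree$tip.label])
  if (!all(x %in% c(0, 1))) stop("trait must be 0/1", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("no variation: trait is monomorphic", call. = FALSE)
  x
}

#' Fritz-Purvis D statistic for phylogenetic signal in a binary trait
#'
#' `D = (d_obs - mean d_BM) / (mean d_rand - mean d_BM)` where `d_rand` comes
#' from tip-label permutations preserving prevalence and `d_BM` from
#' Brownian-motion simulations (sigma = 1) thresholded so the number of 1s
#' matches the observed count. D is about 1 for a phylogenetically random
#' trait, about 0 for Brownian-threshold clumping, below 0 for stronger
#' clumping, above 1 for overdispersion.
#'
#' Tail conventions: `P_rand` is the fraction of permutation d-values <=
#' d_obs (small means significantly clumped relative to random, i.e. D
#' departs from 1); `P_BM` is the fraction of Brownian d-values >= d_obs
#' (small means significantly *less* clumped than Brownian, i.e. D departs
#' from 0 upward). Raw Monte-Carlo fractions are reported alongside add-one
#' smoothed versions (which can never be exactly 0).
#'
#' @param tree A `"phylo"` object (ideally >= 10 tips; a warning is issued
#'   below that).
#' @param trait Named 0/1 vector over all tips, both states present.
#' @param n_perm,n_sim Permutation and Brownian replicates (default 1000).
#' @param seed Integer seed.
#' @return A list of class `"d_stat"`: `D`, `d_obs`, `mean_d_rand`,
#'   `mean_d_bm`, `P_rand`, `P_BM`, `P_rand_smoothed`, `P_BM_smoothed`,
#'   `n_perm`, `n_sim`, `prevalence`.
#' @export
d_statistic <- function(tree, trait, n_perm = 1000L, n_sim = 1000L,
                        seed = 1L) {
  tree <- resolve_polytomies(tree)
  x <- check_binary_trait(tree, trait)
  n <- ape::Ntip(tree)
  if (n < 10L) warning("D statistic is unstable below 10 tips")
  set.seed(seed)
  d_obs <- d_values_matrix(tree, matrix(x, ncol = 1L))
  k1 <- sum(x)
  perm <- vapply(seq_len(n_perm), function(i) x[sample.int(n)],
                 numeric(n))
  d_rand <- d_values_matrix(tree, perm)
  liab <- bm_tips(tree, n_sim)
  bm_states <- apply(liab, 2L, function(z)
    as.numeric(rank(z, ties.method = "first") > n - k1))
  d_bm <- d_values_matrix(tree, bm_states)
  denom <- mean(d_rand) - mean(d_bm)
  if (abs(denom) < sqrt(.Machine$double.eps))
    stop(sprintf(
      "degenerate nulls: mean d_rand (%.6g) equals mean d_BM (%.6g)",
      mean(d_rand), mean(d_bm)), call. = FALSE)
  structure(list(
    D = (d_obs - mean(d_bm)) / denom,
    d_obs = d_obs,
    mean_d_rand = mean(d_rand),
    mean_d_bm = mean(d_bm),
    P_rand = mean(d_rand <= d_obs),
    P_BM = mean(d_bm >= d_obs),
    P_rand_smoothed = (1 + sum(d_rand <= d_obs)) / (n_perm + 1),
    P_BM_smoothed = (1 + sum(d_bm >= d_obs)) / (n_sim + 1),
    n_perm = n_perm, n_sim = n_sim,
    prevalence = k1 / n), class = "d_stat")
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("Fritz-Purvis D = %.3f (d_obs = %.3f)\n", x$D, x$d_obs))
  cat(sprintf("  P_rand = %.4g (departure from D = 1), P_BM = %.4g (departure from D = 0)\n",
              x$P_rand, x$P_BM))
  cat(sprintf("  %d permutations, %d Brownian simulations, prevalence %.3f\n",
              x$n_perm, x$n_sim, x$prevalence))
  invisible(x)
}

#' One-way ANOVA of ED (or any score) across groups
#'
#' Classical one-way F test, e.g. evolutionary distinctiveness of threatened
#' vs. nonthreatened species, or across the five IUCN threat levels.
#'
#' @param ed Named numeric vector (species -> score).
#' @param groups Named character vector (species -> group label); species are
#'   matched by name.
#' @return List with `F`, `p`, `df`, and per-group `means` and `n`.
#' @export
ed_group_test <- function(ed, groups) {
  common <- intersect(names(ed), names(groups))
  y <- ed[common]
  g <- factor(groups[common])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2L))
    stop("groups with < 2 members: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  fit <- stats::anova(stats::lm(y ~ g))
  list(F = fit[["F value"]][1L],
       p = fit[["Pr(>F)"]][1L],
       df = unname(fit[["Df"]]),
       means = tapply(y, g, mean),
       n = as.integer(sizes))
}

#' Derive the binary threatened / nonthreatened trait from IUCN categories
#'
#' Threatened = VU, EN or CR; LC and NT (and CD) are nonthreatened. DD
#' species are dropped (unknown status).
#'
#' @param threats Data frame `species`, `category`.
#' @return Named 0/1 vector over non-DD species.
#' @export
threat_trait <- function(threats) {
  validate_threats(threats)
  keep <- threats$category != "DD"
  stats::setNames(
    as.numeric(threats$category[keep] %in% threatened_categories()),
    threats$species[keep])
}
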