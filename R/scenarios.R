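#' Phylogenetic diversity remaining after a set of tips is lost
#'
#' Faith's PD of the surviving tips (rooted convention); 0 when every tip is
#' lost, total tree length when none is.
#'
#' @param tree A `"phylo"` object.
#' @param lost Character vector of tip labels lost to extinction (may be
#'   empty).
#' @return Remaining PD in Myr.
#' @export
remaining_pd <- function(tree, lost) {
  lost <- unique(as.character(lost))
  unknown <- setdiff(lost, tree$tip.label)
  if (length(unknown))
    stop("lost tips not on tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  survivors <- setdiff(tree$tip.label, lost)
  if (!length(survivors)) return(0)
  faith_pd(tree, survivors)
}

#' Percent of total PD lost
#'
#' `100 * (1 - remaining / total)`; also usable directly on printed PD
#' totals, since `100 * lost_pd / total_pd` is the same number when
#' `remaining = total - lost`.
#'
#' @param remaining_pd,total_pd PD values in the same units.
#' @return Percentage in \[0, 100\].
#' @export
pct_pd_lost <- function(remaining_pd, total_pd) {
  100 * (1 - remaining_pd / total_pd)
}

#' Null distribution of remaining PD under random pruning
#'
#' Deletes `k` tips uniformly at random (without replacement within each
#' draw) `reps` times and returns the remaining PD values. With
#' `exhaustive = TRUE` every one of the `choose(n, k)` loss sets is evaluated
#' exactly once (feasible on small trees), making the null mean exact.
#'
#' @param tree A `"phylo"` object.
#' @param k Number of tips to prune per draw, `0 < k < Ntip`.
#' @param reps Number of random draws (ignored when exhaustive).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all combinations instead of sampling.
#' @return Numeric vector of remaining PD values.
#' @export
random_prune_null <- function(tree, k, reps = 100L, seed = 1L,
                              exhaustive = FALSE) {
  n <- ape::Ntip(tree)
  k <- as.integer(k)
  if (k <= 0L || k >= n)
    stop("k must satisfy 0 < k < number of tips", call. = FALSE)
  if (exhaustive) {
    combos <- utils::combn(tree$tip.label, k, simplify = FALSE)
    return(vapply(combos, function(s) remaining_pd(tree, s), numeric(1)))
  }
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  set.seed(seed)
  vapply(seq_len(reps), function(i) {
    remaining_pd(tree, sample(tree$tip.label, k))
  }, numeric(1))
}

#' Test whether a scenario loses more PD than random extinction
#'
#' Compares the PD remaining after the scenario's loss set is pruned with a
#' null of equally many tips pruned at random. One-tailed in the direction
#' "more loss than random": `p = (1 + #\{null <= observed\}) / (reps + 1)`
#' (add-one estimator, so p is never exactly 0), and
#' `z = (observed - mean(null)) / sd(null)` (NA when the null sd is 0).
#'
#' @param tree A `"phylo"` object.
#' @param lost Character vector of tips lost (nonempty proper subset).
#' @param reps Null randomizations (default 100).
#' @param seed Integer seed.
#' @param scenario Name carried into the result.
#' @param exhaustive Use the exhaustive null (see [random_prune_null()]).
#' @return A list of class `"scenario_result"`: `scenario`, `lost_count`,
#'   `observed_remaining_pd`, `total_pd`, `pct_pd_lost`, `null_remaining_pd`,
#'   `null_mean`, `null_sd`, `p_value`, `z_score`, `reps`.
#' @export
scenario_test <- function(tree, lost, reps = 100L, seed = 1L,
                          scenario = "scenario", exhaustive = FALSE) {
  lost <- unique(as.character(lost))
  n <- ape::Ntip(tree)
  if (!length(lost) || length(lost) >= n)
    stop("lost must be a nonempty proper subset of tips", call. = FALSE)
  total <- total_tree_length(tree)
  obs <- remaining_pd(tree, lost)
  null <- random_prune_null(tree, length(lost), reps = reps, seed = seed,
                            exhaustive = exhaustive)
  nreps <- length(null)
  sd0 <- stats::sd(null)
  structure(list(
    scenario = scenario,
    lost_count = length(lost),
    observed_remaining_pd = obs,
    total_pd = total,
    pct_pd_lost = pct_pd_lost(obs, total),
    null_remaining_pd = null,
    null_mean = mean(null),
    null_sd = sd0,
    p_value = (1 + sum(null <= obs)) / (nreps + 1),
    z_score = if (isTRUE(sd0 > 0)) (obs - mean(null)) / sd0 else NA_real_,
    reps = nreps), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s': %d species lost, %.4g of %.4g PD remaining (%.1f%% lost)\n",
    x$scenario, x$lost_count, x$observed_remaining_pd, x$total_pd,
    x$pct_pd_lost))
  cat(sprintf("  null mean %.4g (sd %.3g), p = %.4g, z = %.3g [%d reps]\n",
              x$null_mean, x$null_sd, x$p_value, x$z_score, x$reps))
  invisible(x)
}

#' Run the standard extinction scenarios
#'
#' Five scenarios of species loss, each tested against random pruning of
#' equally many tips: (1) the top-ED species (`top_ed_count` highest
#' fair-proportion ED, ties broken by label), (2) all threatened species
#' (VU, EN, or CR), and (3-5) each threatened category alone. DD species
#' never belong to a threat scenario. Scenarios with an empty loss set are
#' skipped with a warning.
#'
#' @param tree A `"phylo"` object.
#' @param threats Data frame `species`, `category` covering all tips.
#' @param top_ed_count How many top-ED species the first scenario loses
#'   (default: half the tips, rounded down).
#' @param reps,seed Passed to [scenario_test()] (a distinct seed is derived
#'   per scenario).
#' @return Named list of `"scenario_result"` objects.
#' @export
run_standard_scenarios <- function(tree, threats,
                                   top_ed_count = floor(ape::Ntip(tree) / 2),
                                   reps = 100L, seed = 1L) {
  validate_threats(threats)
  missing <- setdiff(tree$tip.label, threats$species)
  if (length(missing))
    stop("threat table does not cover all tips: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  cat_of <- stats::setNames(threats$category, threats$species)[tree$tip.label]
  ed <- fair_proportion_ed(tree)
  ord <- order(-ed, names(ed))
  loss_sets <- list(
    topED = names(ed)[ord][seq_len(min(top_ed_count, length(ed)))],
    threatened = tree$tip.label[cat_of %in% threatened_categories()],
    VU = tree$tip.label[cat_of == "VU"],
    EN = tree$tip.label[cat_of == "EN"],
    CR = tree$tip.label[cat_of == "CR"])
  out <- list()
  for (i in seq_along(loss_sets)) {
    nm <- names(loss_sets)[i]
    lost <- loss_sets[[i]]
    if (!length(lost)) {
      warning("scenario '", nm, "' has an empty loss set; skipped",
              call. = FALSE)
      next
    }
    out[[nm]] <- scenario_test(tree, lost, reps = reps, seed = seed + i,
                               scenario = nm)
  }
  out
}

#' Write scenario results as JSON plus a TSV of null draws
#'
#' @param results List of `"scenario_result"` objects.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_scenarios <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- lapply(results, function(r)
    r[c("scenario", "lost_count", "observed_remaining_pd", "total_pd",
        "pct_pd_lost", "null_mean", "null_sd", "p_value", "z_score", "reps")])
  json_path <- file.path(dir, "scenarios.json")
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  tsv_path <- file.path(dir, "scenario_null_draws.tsv")
  draws <- do.call(rbind, lapply(results, function(r)
    data.frame(scenario = r$scenario, remaining_pd = r$null_remaining_pd)))
  utils::write.table(draws, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(json_path, tsv_path))
}
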