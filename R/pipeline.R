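# --- I/O for the on-disk interchange formats -------------------------------

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, quote = "\"",
                    check.names = TRUE)
}

#' Read a threat-status table (species, category)
#' @param path CSV or TSV with header `species,category`.
#' @return Data frame `species`, `category`.
#' @export
read_threats <- function(path) {
  df <- read_delim_auto(path)
  stopifnot(all(c("species", "category") %in% names(df)))
  df[, c("species", "category")]
}

#' Read a species-by-cell occurrence table
#' @param path CSV or TSV with header `species,cell_id`.
#' @param width,height Grid dimensions.
#' @return An `"occ_grid"` table.
#' @export
read_occurrences <- function(path, width, height) {
  df <- read_delim_auto(path)
  stopifnot(all(c("species", "cell_id") %in% names(df)))
  occurrence_matrix(data.frame(species = df$species, cell = df$cell_id),
                    width, height)
}

#' Read a protected-area mask
#' @param path CSV or TSV with header `cell_id,protected_fraction`.
#' @return Data frame `cell`, `protected_fraction`.
#' @export
read_mask <- function(path) {
  df <- read_delim_auto(path)
  stopifnot(all(c("cell_id", "protected_fraction") %in% names(df)))
  data.frame(cell = df$cell_id, protected_fraction = df$protected_fraction)
}

#' Validate a set of input files for mutual consistency
#'
#' Reports (without stopping) species-name mismatches between tree, threat
#' table and occurrences, unknown IUCN categories, duplicate rows, and
#' non-ultrametric trees.
#'
#' @param tree_path,threats_path,occ_path Paths; any may be `NULL` to skip.
#' @param mask_path Optional mask path (checked for readability and range).
#' @return Data frame of findings (`level`, `message`); zero rows when
#'   everything is consistent.
#' @export
validate_inputs <- function(tree_path = NULL, threats_path = NULL,
                            occ_path = NULL, mask_path = NULL) {
  findings <- list()
  note <- function(level, msg)
    findings[[length(findings) + 1L]] <<- data.frame(level = level,
                                                     message = msg)
  tree <- threats <- occ <- NULL
  if (!is.null(tree_path)) {
    tree <- tryCatch(read_newick(tree_path), error = function(e) {
      note("error", paste("tree:", conditionMessage(e))); NULL })
    if (!is.null(tree) && ultrametric_deviation(tree) > 1e-6)
      note("warning", sprintf("tree not ultrametric (relative deviation %.3g)",
                              ultrametric_deviation(tree)))
  }
  if (!is.null(threats_path)) {
    threats <- tryCatch(read_threats(threats_path), error = function(e) {
      note("error", paste("threats:", conditionMessage(e))); NULL })
    if (!is.null(threats)) {
      bad <- setdiff(unique(threats$category), iucn_categories())
      if (length(bad))
        note("error", paste("unknown categories:", paste(bad, collapse = ", ")))
      if (anyDuplicated(threats$species))
        note("error", "duplicate species rows in threat table")
    }
  }
  if (!is.null(occ_path)) {
    occ <- tryCatch(read_delim_auto(occ_path), error = function(e) {
      note("error", paste("occurrences:", conditionMessage(e))); NULL })
    if (!is.null(occ) && anyDuplicated(occ))
      note("warning", "duplicate occurrence rows")
  }
  if (!is.null(mask_path)) {
    mask <- tryCatch(read_mask(mask_path), error = function(e) {
      note("error", paste("mask:", conditionMessage(e))); NULL })
    if (!is.null(mask) &&
        any(mask$protected_fraction < 0 | mask$protected_fraction > 1))
      note("error", "protected fractions outside [0, 1]")
  }
  if (!is.null(tree) && !is.null(threats)) {
    d1 <- setdiff(tree$tip.label, threats$species)
    d2 <- setdiff(threats$species, tree$tip.label)
    if (length(d1))
      note("error", paste("tips without threat status:",
                          paste(utils::head(d1, 10), collapse = ", ")))
    if (length(d2))
      note("warning", paste("threat rows not on tree:",
                            paste(utils::head(d2, 10), collapse = ", ")))
  }
  if (!is.null(tree) && !is.null(occ) && "species" %in% names(occ)) {
    d3 <- setdiff(unique(occ$species), tree$tip.label)
    if (length(d3))
      note("error", paste("occurrence species not on tree:",
                          paste(utils::head(d3, 10), collapse = ", ")))
  }
  if (!length(findings))
    return(data.frame(level = character(0), message = character(0)))
  do.call(rbind, findings)
}

#' Pipeline configuration
#'
#' Either `input` (paths to tree/threats/occurrences/mask files) or `sim` (a
#' [sim_config()]) must be given, not both.
#'
#' @param input Named list with `tree`, `threats`, `occurrences`, `mask`
#'   paths (plus `grid_width`, `grid_height`).
#' @param sim A [sim_config()].
#' @param reps Null randomizations for scenarios (default 100).
#' @param seed Master seed for the stochastic stages.
#' @param hotspot_thresholds Percent tiers (default `c(2.5, 5)`).
#' @param top_ed_fraction Fraction of species in the top-ED loss scenario
#'   (default 0.5); `top_ed_count` overrides it.
#' @param top_ed_count Explicit count, or `NULL`.
#' @param out_dir Output directory for the report bundle.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, reps = 100L, seed = 1L,
                            hotspot_thresholds = c(2.5, 5),
                            top_ed_fraction = 0.5, top_ed_count = NULL,
                            out_dir = tempfile("cycadrisk_run_")) {
  if (is.null(input) == is.null(sim))
    stop("exactly one of `input` or `sim` must be given", call. = FALSE)
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(input = input, sim = sim, reps = as.integer(reps),
                 seed = as.integer(seed),
                 hotspot_thresholds = hotspot_thresholds,
                 top_ed_fraction = top_ed_fraction,
                 top_ed_count = top_ed_count, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates or loads the inputs, then runs every stage: ED/EDGE scoring,
#' extinction scenarios with random-pruning nulls, phylogenetic signal of
#' threat (D statistic and ED ANOVA), diversification model selection, grid
#' diversity metrics, hotspot extraction and protected-area coverage. Writes
#' the report bundle (TSV/JSON plus a manifest echoing the configuration)
#' under `config$out_dir` and returns all results invisibly.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's objects and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$sim)) {
    tree <- simulate_cycad_like_tree(config$sim)
    threats <- simulate_threats(tree, config$sim)
    occ <- simulate_occurrences(tree, config$sim)
    mask <- simulate_protected_mask(config$sim)
  } else {
    inp <- config$input
    tree <- read_newick(inp$tree)
    threats <- read_threats(inp$threats)
    occ <- read_occurrences(inp$occurrences, inp$grid_width, inp$grid_height)
    mask <- read_mask(inp$mask)
    d3 <- setdiff(unique(occ$species), tree$tip.label)
    d4 <- setdiff(tree$tip.label, threats$species)
    if (length(d3) || length(d4))
      stop("inconsistent inputs; occurrence-only species: ",
           paste(d3, collapse = ", "), "; tips without status: ",
           paste(d4, collapse = ", "), call. = FALSE)
  }
  validate_threats(threats)

  # species scores
  ed <- fair_proportion_ed(tree)
  all_dd <- all(threats$category == "DD")
  edge_tab <- NULL
  if (all_dd) {
    warning("all species are DD; EDGE stage skipped", call. = FALSE)
  } else {
    edge_tab <- edge_scores(ed, threats)
  }

  # extinction scenarios
  n_scored <- sum(threats$category != "DD")
  top_k <- config$top_ed_count %||%
    max(1L, floor(config$top_ed_fraction * n_scored))
  scen <- run_standard_scenarios(tree, threats, top_ed_count = top_k,
                                 reps = config$reps, seed = config$seed)

  # phylogenetic signal (non-DD species only)
  trait <- threat_trait(threats)
  sig_tree <- if (length(trait) < ape::Ntip(tree))
    prune_to(tree, names(trait)) else tree
  dstat <- NULL
  if (length(unique(trait)) == 2L)
    dstat <- d_statistic(sig_tree, trait, seed = config$seed + 100L)
  grp <- stats::setNames(ifelse(trait == 1, "threatened", "nonthreatened"),
                         names(trait))
  anova_res <- tryCatch(ed_group_test(ed, grp), error = function(e) NULL)

  # diversification
  fits <- fit_diversification_models(tree, seed = config$seed + 200L)
  selection <- select_model(fits)

  # grid metrics
  maps <- list(SR = grid_sr(occ), PD = grid_pd(tree, occ))
  we <- weighted_endemism(occ)
  maps$WE <- we$WE
  maps$CWE <- we$CWE
  maps$PE <- phylogenetic_endemism(tree, occ)
  if (!is.null(edge_tab)) maps$meanEDGE <- grid_mean_edge(edge_tab, occ)

  # hotspots per tier: CWE used for the endemism hotspot (the cited metric)
  hot_metrics <- intersect(c("SR", "PD", "CWE", "PE", "meanEDGE"),
                           names(maps))
  hotspots <- lapply(config$hotspot_thresholds, function(th)
    stats::setNames(lapply(hot_metrics, function(m)
      select_hotspots(maps[[m]], th)), hot_metrics))
  names(hotspots) <- paste0("tier_", config$hotspot_thresholds)
  tier1 <- hotspots[[1L]]
  venn <- hotspot_overlap(tier1)
  cumul <- cumulative_hotspots(tier1, n_occupied = nrow(maps$SR))
  protection <- protection_coverage(tier1, mask)

  paths <- write_bundle(config, tree, threats, occ, mask, edge_tab, scen,
                        dstat, anova_res, fits, selection, maps, hotspots,
                        venn, cumul, protection)
  invisible(list(tree = tree, threats = threats, occ = occ, mask = mask,
                 ed = ed, edge_table = edge_tab, scenarios = scen,
                 d_stat = dstat, ed_anova = anova_res, fits = fits,
                 selection = selection, maps = maps, hotspots = hotspots,
                 venn = venn, cumulative = cumul, protection = protection,
                 paths = paths))
}

write_bundle <- function(config, tree, threats, occ, mask, edge_tab, scen,
                         dstat, anova_res, fits, selection, maps, hotspots,
                         venn, cumul, protection) {
  out <- config$out_dir
  paths <- write_dataset(tree, threats, occ, mask, file.path(out, "data"))
  if (!is.null(edge_tab)) {
    p <- file.path(out, "edge_table.tsv")
    utils::write.table(edge_tab, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, edge_table = p)
  }
  paths <- c(paths, write_scenarios(scen, out))
  if (!is.null(dstat)) {
    p <- file.path(out, "d_statistic.json")
    jsonlite::write_json(unclass(dstat), p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, d_statistic = p)
  }
  if (!is.null(anova_res)) {
    p <- file.path(out, "ed_anova.json")
    jsonlite::write_json(list(F = anova_res$F, p = anova_res$p,
                              means = as.list(anova_res$means)),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, ed_anova = p)
  }
  paths <- c(paths, write_diversification(fits, selection, out))
  gm <- do.call(rbind, lapply(names(maps), function(m)
    data.frame(cell_id = maps[[m]]$cell, metric = m,
               value = maps[[m]]$value)))
  p <- file.path(out, "grid_metrics.tsv")
  utils::write.table(gm, p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, grid_metrics = p)
  hs <- do.call(rbind, lapply(names(hotspots), function(tier)
    do.call(rbind, lapply(names(hotspots[[tier]]), function(m) {
      h <- hotspots[[tier]][[m]]
      data.frame(tier = tier, metric = m, cell_id = h$cells,
                 value = h$values)
    }))))
  p <- file.path(out, "hotspots.tsv")
  utils::write.table(hs, p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, hotspots = p)
  p <- file.path(out, "venn_regions.tsv")
  utils::write.table(data.frame(region = names(venn), n_cells = venn),
                     p, sep = "\t", row.names = FALSE, quote = FALSE)
  paths <- c(paths, venn = p)
  p <- file.path(out, "protection_report.json")
  jsonlite::write_json(list(per_set = protection$per_set,
                            overall_coverage = protection$overall_coverage,
                            fully_covered = protection$fully_covered,
                            gaps = protection$gaps,
                            rule_threshold = protection$rule_threshold,
                            cumulative_hotspot_cells = cumul$n_cells,
                            cumulative_hotspot_area_km2 = cumul$area_km2,
                            pct_of_occupied = cumul$pct_of_occupied),
                       p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, protection = p)
  manifest <- list(
    package = "cycadrisk",
    version = as.character(utils::packageVersion("cycadrisk")),
    seed = config$seed, reps = config$reps,
    hotspot_thresholds = config$hotspot_thresholds,
    top_ed_fraction = config$top_ed_fraction,
    top_ed_count = config$top_ed_count,
    mode = if (is.null(config$sim)) "files" else "simulation",
    sim = if (!is.null(config$sim))
      unclass(config$sim)[c("seed", "n_species", "n_genera", "birth",
                            "death", "threat_mode", "grid_width",
                            "grid_height", "protected_fraction")])
  p <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(paths, manifest = p)
}
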