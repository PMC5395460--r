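#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the cycad study system: 339 species in 11 monophyletic genera, threat
#' marginals of 78 VU / 70 EN / 67 CR (215 threatened of 339, the remainder
#' least-concern or near-threatened), right-skewed range sizes on a 40 x 20
#' abstract equal-area lattice of nominal 100 x 100 km cells, and a patchy
#' protected-area mask covering ~30% of the grid.
#'
#' @param seed Integer seed; identical configs (including seed) give
#'   identical outputs.
#' @param n_species,n_genera Tip and genus counts for the clade-structured
#'   simulator.
#' @param birth,death Speciation/extinction rates in events/Myr for
#'   [simulate_tree()].
#' @param shift_times Times since the process start (root) at which the
#'   birth rate changes, Myr.
#' @param shift_rates Birth rates after each shift (same length as
#'   `shift_times`).
#' @param threat_mode `"iid"` (categories independent of the tree) or
#'   `"clustered"` (Brownian-liability threshold model, which induces
#'   phylogenetic signal, D < 1).
#' @param category_probs Named probabilities over LC/NT/VU/EN/CR/DD summing
#'   to 1.
#' @param grid_width,grid_height Lattice dimensions in cells.
#' @param range_size_log_mean,range_size_log_sd Lognormal parameters of range
#'   size in cells.
#' @param protected_fraction Target mean of the protected-area mask in
#'   \[0, 1\].
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 339L,
                       n_genera = 11L,
                       birth = 0.1,
                       death = 0,
                       shift_times = NULL,
                       shift_rates = NULL,
                       threat_mode = c("iid", "clustered"),
                       category_probs = c(LC = 100, NT = 24, VU = 78,
                                          EN = 70, CR = 67, DD = 0) / 339,
                       grid_width = 40L,
                       grid_height = 20L,
                       range_size_log_mean = log(5),
                       range_size_log_sd = 1,
                       protected_fraction = 0.3) {
  threat_mode <- match.arg(threat_mode)
  stopifnot(birth >= 0, death >= 0, grid_width >= 1, grid_height >= 1,
            protected_fraction >= 0, protected_fraction <= 1,
            length(shift_times) == length(shift_rates))
  if (abs(sum(category_probs) - 1) > 1e-9)
    stop("category_probs must sum to 1", call. = FALSE)
  if (is.null(names(category_probs)) ||
      !all(names(category_probs) %in% c("LC", "NT", "VU", "EN", "CR", "DD")))
    stop("category_probs must be named with IUCN categories", call. = FALSE)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_genera = as.integer(n_genera), birth = birth,
                 death = death, shift_times = shift_times,
                 shift_rates = shift_rates, threat_mode = threat_mode,
                 category_probs = category_probs,
                 grid_width = as.integer(grid_width),
                 grid_height = as.integer(grid_height),
                 range_size_log_mean = range_size_log_mean,
                 range_size_log_sd = range_size_log_sd,
                 protected_fraction = protected_fraction),
            class = "sim_config")
}

# piecewise-constant birth rate at elapsed time t
rate_at <- function(t, birth, shift_times, shift_rates) {
  if (!length(shift_times)) return(birth)
  i <- findInterval(t, shift_times)
  if (i == 0) birth else shift_rates[i]
}

#' Simulate an ultrametric birth-death tree with a fixed tip count
#'
#' Forward Gillespie simulation starting from two lineages. The process runs
#' until `n_species` extant lineages exist, then advances by one further
#' (unapplied) waiting time so terminal branches have positive length.
#' Extinct lineages are pruned. With `shift_times`/`shift_rates` set the
#' birth rate is piecewise constant in time since the root, giving the
#' multi-rate pure-birth trees used for rate-shift recovery tests.
#'
#' @param config A [sim_config()]; uses `n_species`, `birth`, `death`,
#'   `shift_times`, `shift_rates`, `seed`.
#' @param max_retries Retries when the whole clade goes extinct (default
#'   1000).
#' @return An ultrametric `"phylo"` object with `n_species` tips labelled
#'   `t1..tn`, plus attribute `"event_times"` (node ages recorded by the
#'   simulator, descending).
#' @export
simulate_tree <- function(config, max_retries = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$birth <= 0) stop("birth rate must be > 0", call. = FALSE)
  if (config$n_species < 2L) stop("need n_species >= 2", call. = FALSE)
  set.seed(config$seed)
  for (try in seq_len(max_retries)) {
    tr <- gillespie_tree(config$n_species, config$birth, config$death,
                         config$shift_times, config$shift_rates)
    if (!is.null(tr)) return(tr)
  }
  stop("no surviving clade after ", max_retries, " attempts", call. = FALSE)
}

# one forward simulation; NULL when the clade dies out
gillespie_tree <- function(n_target, birth, death, shift_times, shift_rates) {
  # lineage bookkeeping: parent node of each lineage, birth time of the
  # lineage, alive flag; internal events recorded as (time, lineage split)
  max_nodes <- 4L * n_target + 8L
  parent <- integer(0)      # index of parent event, 0 for the two roots
  btime <- numeric(0)       # time the lineage started
  alive <- logical(0)
  dtime <- numeric(0)       # death/end time (NA while alive)
  child1 <- integer(0); child2 <- integer(0) # on split: children lineages
  new_lineage <- function(start) {
    parent[length(parent) + 1L] <<- 0L
    btime[length(btime) + 1L] <<- start
    alive[length(alive) + 1L] <<- TRUE
    dtime[length(dtime) + 1L] <<- NA_real_
    child1[length(child1) + 1L] <<- 0L
    child2[length(child2) + 1L] <<- 0L
    length(btime)
  }
  t <- 0
  l1 <- new_lineage(0); l2 <- new_lineage(0)
  repeat {
    live <- which(alive)
    k <- length(live)
    if (k == 0L) return(NULL)
    if (k >= n_target) break
    b <- rate_at(t, birth, shift_times, shift_rates)
    total <- k * (b + death)
    if (total <= 0) return(NULL)
    # waiting time truncated at the next rate shift
    repeat {
      wait <- stats::rexp(1, total)
      nxt <- if (length(shift_times)) shift_times[shift_times > t][1] else NA
      if (!is.na(nxt) && t + wait > nxt) {
        t <- nxt
        b <- rate_at(t, birth, shift_times, shift_rates)
        total <- k * (b + death)
        if (total <= 0) return(NULL)
      } else {
        t <- t + wait
        break
      }
    }
    lin <- live[sample.int(k, 1L)]
    if (stats::runif(1) < b / (b + death)) {
      alive[lin] <- FALSE
      dtime[lin] <- t
      c1 <- new_lineage(t); c2 <- new_lineage(t)
      child1[lin] <- c1; child2[lin] <- c2
    } else {
      alive[lin] <- FALSE
      dtime[lin] <- t
    }
  }
  # advance by one unapplied waiting time so the last split is interior
  b <- rate_at(t, birth, shift_times, shift_rates)
  t_end <- t + stats::rexp(1, max(length(which(alive)) * (b + death), 1e-12))
  split_ages <- t_end - dtime[child1 > 0L]
  dtime[alive] <- t_end
  build_phylo_from_lineages(btime, dtime, child1, child2, alive, t_end,
                            if (death == 0) split_ages else NULL)
}

# convert the lineage table to a phylo: recursively emit newick
build_phylo_from_lineages <- function(btime, dtime, child1, child2, alive,
                                      t_end, split_ages = NULL) {
  tip_counter <- 0L
  emit <- function(lin) {
    len <- dtime[lin] - btime[lin]
    if (child1[lin] > 0L) {
      a <- emit(child1[lin]); b <- emit(child2[lin])
      if (is.null(a) && is.null(b)) return(NULL)
      if (is.null(a)) return(sub_len(b, len))
      if (is.null(b)) return(sub_len(a, len))
      sprintf("(%s,%s):%.12g", a, b, len)
    } else if (alive[lin]) {
      tip_counter <<- tip_counter + 1L
      sprintf("t%d:%.12g", tip_counter, len)
    } else NULL # extinct: pruned
  }
  sub_len <- function(newick, extra) {
    # lengthen the subtree's stem by `extra` (suppressing a dead split)
    pos <- regexpr(":[0-9eE.+-]+$", newick)
    stem <- as.numeric(substr(newick, pos + 1L, nchar(newick)))
    paste0(substr(newick, 1L, pos - 1L),
           sprintf(":%.12g", stem + extra))
  }
  a <- emit(1L); b <- emit(2L)
  if (is.null(a) || is.null(b)) return(NULL)
  tree <- ape::read.tree(text = sprintf("(%s,%s);", a, b))
  if (is.null(tree)) return(NULL)
  # event ages recorded by the simulator itself (pure birth: every split is
  # a surviving node, plus the root at t_end); with extinction the pruned
  # tree's nodes are a subset, so no record is attached
  attr(tree, "event_times") <-
    if (!is.null(split_ages)) sort(c(t_end, split_ages), decreasing = TRUE)
    else NULL
  tree
}

# Yule tree with given crown age: simulate topology/times, rescale depth
yule_crown_tree <- function(n, crown_age, rate = 1) {
  tr <- gillespie_tree(n, rate, 0, NULL, NULL)
  while (is.null(tr)) tr <- gillespie_tree(n, rate, 0, NULL, NULL)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (crown_age / depth)
  tr
}

#' Simulate a cycad-like tree: old monophyletic genera, recent radiations
#'
#' Emulates the coalescent-like shape of the cycad tree of life: a deep
#' backbone joining `n_genera` monophyletic genus clades whose stems attach
#' between 40 and 300 Myr, while each genus crown radiates recently (crown
#' ages uniform on 2-13 Myr, the scale of the cycad secondary calibrations).
#' Genus sizes are a skewed multinomial (lognormal weights) with every genus
#' keeping at least one species, so monotypic genera on very long stems occur
#' naturally.
#'
#' @param config A [sim_config()]; uses `n_species`, `n_genera`, `seed`.
#' @return Ultrametric `"phylo"` with tips `G<i>_sp<j>`, plus attribute
#'   `"genus"` (named character vector tip -> genus).
#' @export
simulate_cycad_like_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$n_genera
  n <- config$n_species
  if (g < 2L) stop("need n_genera >= 2", call. = FALSE)
  if (n < g) stop("n_species must be >= n_genera", call. = FALSE)
  set.seed(config$seed)
  # skewed genus sizes, each >= 1
  w <- exp(stats::rnorm(g, sd = 1.5))
  sizes <- rep(1L, g)
  extra <- stats::rmultinom(1, n - g, prob = w)[, 1]
  sizes <- sizes + extra
  crown_ages <- stats::runif(g, 2, 13)
  # backbone: sequential random coalescent with join ages in (40, 300)
  join_ages <- sort(stats::runif(g - 1, 40, 300))
  groups <- as.list(seq_len(g))        # genus indices per backbone lineage
  nwk <- vapply(seq_len(g), function(i) sprintf("@%d", i), character(1))
  age <- rep(0, g) # age at the top of each subtree string (attachment age 0 = crown placeholder)
  for (j in seq_len(g - 1)) {
    pick <- sample.int(length(nwk), 2L)
    a <- pick[1]; b <- pick[2]
    ja <- join_ages[j]
    merged <- sprintf("(%s:%.12g,%s:%.12g)", nwk[a], ja - age[a],
                      nwk[b], ja - age[b])
    nwk <- c(nwk[-pick], merged)
    age <- c(age[-pick], ja)
  }
  backbone <- paste0(nwk, ";")
  # genus subtrees: placeholder @i is the genus crown point at age 0; the
  # stem length printed above must be shortened by the crown age, so instead
  # substitute "(subtree)" whose printed stem absorbs crown age
  for (i in seq_len(g)) {
    lab <- function(j) sprintf("G%d_sp%d", i, j)
    if (sizes[i] == 1L) {
      sub <- lab(1)
      crown <- 0
    } else {
      st <- yule_crown_tree(sizes[i], crown_ages[i])
      st$tip.label <- vapply(seq_len(sizes[i]), lab, character(1))
      sub <- sub(";$", "", ape::write.tree(st, digits = 15))
      crown <- crown_ages[i]
    }
    # the backbone wrote "@i:stemlen" with stemlen measured to age 0; the
    # genus crown sits at `crown`, so shorten the stem accordingly
    m <- regexpr(sprintf("@%d:[0-9eE.+-]+", i), backbone)
    tok <- regmatches(backbone, m)
    stemlen <- as.numeric(sub(sprintf("@%d:", i), "", tok))
    regmatches(backbone, m) <- sprintf("%s:%.12g", sub, stemlen - crown)
  }
  tree <- ape::read.tree(text = backbone)
  genus <- sub("_sp[0-9]+$", "", tree$tip.label)
  attr(tree, "genus") <- stats::setNames(genus, tree$tip.label)
  tree
}

# Brownian motion tip values simulated down the tree; matrix tips x nsim
bm_tips <- function(tree, nsim = 1L) {
  n <- ape::Ntip(tree)
  V <- matrix(0, n + tree$Nnode, nsim)
  tr <- ape::reorder.phylo(tree, "cladewise") # parents before children
  e <- tr$edge
  len <- tr$edge.length
  for (i in seq_len(nrow(e)))
    V[e[i, 2L], ] <- V[e[i, 1L], ] + stats::rnorm(nsim, 0, sqrt(max(len[i], 0)))
  rownames(V) <- c(tree$tip.label, rep(NA, tree$Nnode))
  V[seq_len(n), , drop = FALSE]
}

# integer category counts matching probs exactly (largest remainder)
quota_counts <- function(probs, n) {
  raw <- probs * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    frac <- raw - cnt
    add <- order(frac, decreasing = TRUE)[seq_len(left)]
    cnt[add] <- cnt[add] + 1
  }
  as.integer(cnt)
}

#' Simulate IUCN threat categories on a tree
#'
#' In `"iid"` mode categories are drawn independently per tip from
#' `category_probs`. In `"clustered"` mode a single Brownian liability is
#' simulated on the tree and categories are assigned by liability quantiles
#' whose counts match `category_probs` exactly (higher liability, more
#' threatened) — precisely the Brownian-threshold null of the D statistic, so
#' the induced binary threat trait calibrates to D of about 0.
#'
#' @param tree A `"phylo"` object.
#' @param config A [sim_config()]; uses `threat_mode`, `category_probs`,
#'   `seed`.
#' @return Data frame `species`, `category`.
#' @export
simulate_threats <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  probs <- config$category_probs
  tips <- tree$tip.label
  n <- length(tips)
  if (config$threat_mode == "iid") {
    cat <- sample(names(probs), n, replace = TRUE, prob = probs)
  } else {
    # DD is not an ordered severity state: assign it iid first, then the
    # ordered categories by liability quantile among the rest
    is_dd <- stats::runif(n) < probs[["DD"]]
    rest <- which(!is_dd)
    liab <- bm_tips(tree)[rest, 1]
    ord_cats <- c("LC", "NT", "VU", "EN", "CR")
    p_rest <- probs[ord_cats] / sum(probs[ord_cats])
    cnt <- quota_counts(p_rest, length(rest))
    cat <- character(n)
    cat[is_dd] <- "DD"
    cat[rest[order(liab)]] <- rep(ord_cats, cnt)
  }
  data.frame(species = tips, category = cat, stringsAsFactors = FALSE)
}

# neighbors of a cell on the lattice (4-neighborhood, clipped at borders)
cell_neighbors <- function(cell, width, height) {
  row <- (cell - 1L) %/% width + 1L
  col <- (cell - 1L) %% width + 1L
  out <- integer(0)
  if (col > 1L) out <- c(out, cell - 1L)
  if (col < width) out <- c(out, cell + 1L)
  if (row > 1L) out <- c(out, cell - width)
  if (row < height) out <- c(out, cell + width)
  out
}

# grow a contiguous patch of `size` cells from `start` by random accretion
grow_patch <- function(start, size, width, height) {
  patch <- start
  frontier <- setdiff(cell_neighbors(start, width, height), patch)
  while (length(patch) < size && length(frontier)) {
    nxt <- frontier[sample.int(length(frontier), 1L)]
    patch <- c(patch, nxt)
    frontier <- setdiff(union(frontier, cell_neighbors(nxt, width, height)),
                        patch)
  }
  patch
}

#' Simulate gridded species occurrences
#'
#' Each species occupies a contiguous patch grown by random accretion from a
#' niche center; range sizes are lognormal (right-skewed). Niche centers
#' evolve by two-dimensional Brownian motion on the tree (rank-mapped onto
#' the lattice), so close relatives co-occur more than random pairs.
#'
#' @param tree A `"phylo"` object.
#' @param config A [sim_config()]; uses grid dims, range-size lognormal
#'   parameters, `seed`.
#' @param phylo_centers Evolve niche centers on the tree (default `TRUE`);
#'   `FALSE` places centers uniformly at random.
#' @return An `"occ_grid"` table (see [occurrence_matrix()]).
#' @export
simulate_occurrences <- function(tree, config, phylo_centers = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  W <- config$grid_width; H <- config$grid_height
  tips <- tree$tip.label
  n <- length(tips)
  if (phylo_centers) {
    xy <- bm_tips(tree, 2L)
    cx <- as.integer(ceiling(rank(xy[, 1], ties.method = "first") / n * W))
    cy <- as.integer(ceiling(rank(xy[, 2], ties.method = "first") / n * H))
  } else {
    cx <- sample.int(W, n, replace = TRUE)
    cy <- sample.int(H, n, replace = TRUE)
  }
  sizes <- pmax(1L, pmin(W * H, as.integer(round(stats::rlnorm(
    n, config$range_size_log_mean, config$range_size_log_sd)))))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    start <- (cy[i] - 1L) * W + cx[i]
    recs[[i]] <- data.frame(species = tips[i],
                            cell = grow_patch(start, sizes[i], W, H),
                            stringsAsFactors = FALSE)
  }
  occurrence_matrix(do.call(rbind, recs), W, H)
}

#' Simulate a patchy protected-area mask
#'
#' Random-accretion blobs of fully protected cells are grown until the grid
#' mean reaches `protected_fraction`; the final boundary cell gets a partial
#' fraction so the mean is matched closely.
#'
#' @param config A [sim_config()]; uses grid dims, `protected_fraction`,
#'   `seed`.
#' @return Data frame `cell`, `protected_fraction` covering every grid cell.
#' @export
simulate_protected_mask <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  W <- config$grid_width; H <- config$grid_height
  ncell <- W * H
  frac <- rep(0, ncell)
  target <- config$protected_fraction * ncell
  if (config$protected_fraction >= 1) {
    frac[] <- 1
  } else if (target > 0) {
    budget <- target
    while (budget > 1e-9) {
      free <- which(frac == 0)
      if (!length(free)) break
      blob_size <- min(length(free), max(1L, stats::rpois(1, 8)))
      seed_cell <- free[sample.int(length(free), 1L)]
      blob <- grow_patch(seed_cell, blob_size, W, H)
      blob <- blob[frac[blob] == 0]
      for (cl in blob) {
        add <- min(1, budget)
        frac[cl] <- add
        budget <- budget - add
        if (budget <= 1e-9) break
      }
    }
  }
  data.frame(cell = seq_len(ncell), protected_fraction = frac)
}

#' Graft missing congeners onto a constraint tree
#'
#' Stand-in for taxonomic imputation of species lacking DNA data: each
#' missing species is attached to a branch chosen uniformly at random within
#' its genus crown group (or to the genus stem branch when the genus is
#' represented by a single tip), at an attachment age uniform on that branch.
#' The output stays ultrametric and genus monophyly and the relationships
#' among the original tips are preserved. Species whose genus has no
#' representative in the tree are an error (no taxonomic anchor).
#'
#' @param constraint_tree Ultrametric `"phylo"`.
#' @param taxon_list Data frame `species`, `genus` covering at least all
#'   missing species; tips of `constraint_tree` absent from the list have
#'   their genus inferred from the `Genus_...` label prefix.
#' @param seed Integer seed.
#' @return Ultrametric `"phylo"` containing all of `taxon_list$species`.
#' @export
graft_missing_taxa <- function(constraint_tree, taxon_list, seed = 1L) {
  stopifnot(is.data.frame(taxon_list),
            all(c("species", "genus") %in% names(taxon_list)))
  set.seed(seed)
  tree <- constraint_tree
  missing <- setdiff(taxon_list$species, tree$tip.label)
  if (!length(missing)) return(tree)
  genus_of <- stats::setNames(taxon_list$genus, taxon_list$species)
  tip_genus <- function(tr) {
    g <- genus_of[tr$tip.label]
    g[is.na(g)] <- sub("_.*$", "", tr$tip.label[is.na(g)])
    unname(g)
  }
  absent <- setdiff(unique(genus_of[missing]), tip_genus(tree))
  if (length(absent))
    stop("genera absent from constraint tree (no anchor): ",
         paste(absent, collapse = ", "), call. = FALSE)
  for (sp in missing) {
    g <- genus_of[[sp]]
    tg <- tip_genus(tree)
    members <- which(tg == g)
    ages <- node_ages(tree)
    if (length(members) == 1L) {
      # monotypic: attach along the stem (terminal) branch
      child <- members
      edge_i <- which(tree$edge[, 2L] == child)
    } else {
      crown <- ape::getMRCA(tree, tree$tip.label[members])
      desc <- crown_descendant_nodes(tree, crown)
      edge_i_all <- which(tree$edge[, 2L] %in% desc)
      edge_i <- edge_i_all[sample.int(length(edge_i_all), 1L)]
      child <- tree$edge[edge_i, 2L]
    }
    lo <- ages[child]
    hi <- ages[tree$edge[edge_i, 1L]]
    attach_age <- stats::runif(1, lo, hi)
    tiptree <- single_tip_tree(sp, attach_age)
    tree <- ape::bind.tree(tree, tiptree, where = child,
                           position = attach_age - lo)
  }
  tree
}

# all nodes strictly below `node` (the crown), i.e. candidates whose parent
# edge lies within the crown group
crown_descendant_nodes <- function(tree, node) {
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer(0)
  stack <- node
  n <- ape::Ntip(tree)
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- children[[as.character(cur)]]
    out <- c(out, ch)
    stack <- c(stack, ch[ch > n])
  }
  out
}

#' Write the synthetic dataset as plain-text files
#'
#' Newick tree plus three TSVs (`threats.tsv`: species, category;
#' `occurrences.tsv`: species, cell_id; `mask.tsv`: cell_id,
#' protected_fraction), the on-disk interchange format of the pipeline.
#'
#' @param tree,threats,occ,mask Objects from the `simulate_*` generators.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(tree, threats, occ, mask, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             threats = file.path(dir, "threats.tsv"),
             occurrences = file.path(dir, "occurrences.tsv"),
             mask = file.path(dir, "mask.tsv"))
  write_newick(tree, paths[["tree"]])
  utils::write.table(threats, paths[["threats"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  occ_out <- data.frame(species = occ$species, cell_id = occ$cell)
  utils::write.table(occ_out, paths[["occurrences"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  mask_out <- data.frame(cell_id = mask$cell,
                         protected_fraction = mask$protected_fraction)
  utils::write.table(mask_out, paths[["mask"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
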