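#' Faith's phylogenetic diversity of a tip set
#'
#' Sum of branch lengths of the minimal rooted spanning subtree connecting
#' `subset`, *including* the path to the tree's root (and any root edge).
#' This rooted convention makes fair-proportion ED sum exactly to total PD
#' and keeps "remaining PD" well defined when one side of the root is lost.
#'
#' @param tree A `"phylo"` object.
#' @param subset Character vector of tip labels (nonempty).
#' @return PD in Myr. For `subset` equal to all tips this is the total branch
#'   length of the tree.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' faith_pd(tr, c("A", "B", "C")) # 5
#' faith_pd(tr, c("A", "B"))      # 3
#' @export
faith_pd <- function(tree, subset) {
  subset <- unique(as.character(subset))
  if (!length(subset))
    stop("PD of an empty set is undefined; use 0 explicitly for 'all lost'",
         call. = FALSE)
  idx <- match(subset, tree$tip.label)
  if (anyNA(idx))
    stop("tips not on tree: ", paste(subset[is.na(idx)], collapse = ", "),
         call. = FALSE)
  po <- postorder_edges(tree)
  n <- ape::Ntip(tree)
  present <- logical(n + tree$Nnode)
  present[idx] <- TRUE
  e <- po$edge
  len <- po$edge.length
  keep <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    if (present[e[i, 2L]]) {
      keep[i] <- TRUE
      present[e[i, 1L]] <- TRUE
    }
  }
  sum(len[keep]) + root_edge_length(tree)
}

# number of tips descending from the child node of each edge, and per-node
# descendant-tip counts
edge_tip_counts <- function(tree) {
  po <- postorder_edges(tree)
  n <- ape::Ntip(tree)
  cnt <- c(rep(1L, n), rep(0L, tree$Nnode))
  e <- po$edge
  for (i in seq_len(nrow(e)))
    cnt[e[i, 1L]] <- cnt[e[i, 1L]] + cnt[e[i, 2L]]
  list(po = po, counts = cnt)
}

#' Fair-proportion evolutionary distinctiveness
#'
#' Each branch's length is divided equally among its descendant tips and
#' summed per tip (Isaac et al.'s fair-proportion scheme). Any root edge is
#' shared equally by all tips. By construction the ED values sum to the
#' tree's total PD.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Named numeric vector of ED scores (Myr), one per tip.
#' @examples
#' fair_proportion_ed(parse_newick("((A:1,B:1):1,C:2);"))
#' # A = 1.5, B = 1.5, C = 2
#' @export
fair_proportion_ed <- function(tree) {
  n <- ape::Ntip(tree)
  if (n == 1L)
    return(stats::setNames(total_tree_length(tree), tree$tip.label))
  etc <- edge_tip_counts(tree)
  po <- etc$po
  share <- po$edge.length / etc$counts[po$edge[, 2L]]
  # preorder accumulation: reverse postorder visits parents before children
  acc <- numeric(n + tree$Nnode)
  acc[n + 1L] <- root_edge_length(tree)
  e <- po$edge
  for (i in rev(seq_len(nrow(e))))
    acc[e[i, 2L]] <- acc[e[i, 1L]] + share[i]
  # the root-edge share accumulated so far is the full root edge on every
  # path; the fair share is root.edge / n
  ed <- acc[seq_len(n)] - root_edge_length(tree) * (1 - 1 / n)
  stats::setNames(ed, tree$tip.label)
}

#' Global endangerment (GE) code of an IUCN category
#'
#' Fixed coding: LC = 0, NT and CD = 1, VU = 2, EN = 3, CR = 4. Data
#' deficient (DD) species are excluded before EDGE evaluation and are an
#' error here.
#'
#' @param category Character vector of categories in
#'   `c("LC","NT","CD","VU","EN","CR")`.
#' @return Integer vector of GE codes.
#' @export
ge_code <- function(category) {
  map <- c(LC = 0L, NT = 1L, CD = 1L, VU = 2L, EN = 3L, CR = 4L)
  category <- as.character(category)
  if (any(category == "DD"))
    stop("DD species are excluded before EDGE evaluation", call. = FALSE)
  bad <- setdiff(unique(category), names(map))
  if (length(bad))
    stop("unknown IUCN categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  unname(map[category])
}

iucn_categories <- function() c("LC", "NT", "CD", "VU", "EN", "CR", "DD")
threatened_categories <- function() c("VU", "EN", "CR")

validate_threats <- function(threats) {
  stopifnot(is.data.frame(threats),
            all(c("species", "category") %in% names(threats)))
  if (anyDuplicated(threats$species))
    stop("duplicate species rows in threat table", call. = FALSE)
  bad <- setdiff(unique(threats$category), iucn_categories())
  if (length(bad))
    stop("unknown IUCN categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(threats)
}

#' EDGE scores: Evolutionarily Distinct and Globally Endangered
#'
#' `EDGE = ln(1 + ED) + GE * ln(2)`. DD species are excluded before scoring.
#' The table is sorted descending by EDGE, with ties broken by species label,
#' and carries a 1-based rank.
#'
#' @param ed Named numeric vector of ED scores (Myr), as from
#'   [fair_proportion_ed()].
#' @param threats Data frame with columns `species`, `category`.
#' @return Data frame with columns `species`, `category`, `GE`, `ED`, `EDGE`,
#'   `rank`.
#' @export
edge_scores <- function(ed, threats) {
  validate_threats(threats)
  scored <- threats[threats$category != "DD", , drop = FALSE]
  if (!nrow(scored)) stop("no non-DD species to score", call. = FALSE)
  missing_ed <- setdiff(scored$species, names(ed))
  if (length(missing_ed))
    stop("missing ED for scored species: ",
         paste(missing_ed, collapse = ", "), call. = FALSE)
  ge <- ge_code(scored$category)
  edv <- unname(ed[scored$species])
  edge <- log1p(edv) + ge * log(2)
  out <- data.frame(species = scored$species, category = scored$category,
                    GE = ge, ED = edv, EDGE = edge,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$EDGE, out$species), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Construct a species-by-grid-cell occurrence table
#'
#' Long-format presence records on a `width` x `height` lattice of nominal
#' 100 x 100 km cells. Cell ids are `(row - 1) * width + col`, in
#' `1..width*height`.
#'
#' @param records Data frame with columns `species`, `cell`.
#' @param width,height Grid dimensions in cells.
#' @return An `"occ_grid"` data frame (deduplicated, sorted).
#' @export
occurrence_matrix <- function(records, width, height) {
  stopifnot(is.data.frame(records),
            all(c("species", "cell") %in% names(records)),
            width >= 1, height >= 1)
  records$cell <- as.integer(records$cell)
  if (any(records$cell < 1L | records$cell > width * height))
    stop("cell ids outside the grid", call. = FALSE)
  records <- unique(records[, c("species", "cell")])
  records <- records[order(records$species, records$cell), , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "width") <- as.integer(width)
  attr(records, "height") <- as.integer(height)
  class(records) <- c("occ_grid", "data.frame")
  records
}

occ_dims <- function(occ) c(attr(occ, "width"), attr(occ, "height"))

grid_map <- function(cells, values, metric) {
  out <- data.frame(cell = as.integer(cells), value = as.numeric(values))
  out <- out[order(out$cell), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  class(out) <- c("grid_metric", "data.frame")
  out
}

#' Species richness per grid cell
#'
#' @param occ An `"occ_grid"` table from [occurrence_matrix()].
#' @return A `"grid_metric"` data frame (`cell`, `value`) over occupied cells
#'   only; cells absent from the table are unoccupied.
#' @export
grid_sr <- function(occ) {
  if (!nrow(occ)) stop("empty occurrence table", call. = FALSE)
  tab <- table(occ$cell)
  grid_map(as.integer(names(tab)), as.integer(tab), "SR")
}

#' Faith's PD per grid cell
#'
#' @param tree A `"phylo"` object covering all occurring species.
#' @param occ An `"occ_grid"` table.
#' @return A `"grid_metric"` data frame of per-cell PD (rooted convention).
#' @export
grid_pd <- function(tree, occ) {
  miss <- setdiff(unique(occ$species), tree$tip.label)
  if (length(miss))
    stop("species missing from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  by_cell <- split(occ$species, occ$cell)
  vals <- vapply(by_cell, function(sp) faith_pd(tree, sp), numeric(1))
  grid_map(as.integer(names(by_cell)), vals, "PD")
}

#' Weighted and corrected weighted endemism per grid cell
#'
#' WE(c) is the sum over species present in cell c of 1/range, where range is
#' the number of cells the species occupies; summed over cells, WE equals the
#' number of species. CWE = WE / SR (richness-corrected).
#'
#' @param occ An `"occ_grid"` table.
#' @return List with `"grid_metric"` elements `WE` and `CWE`.
#' @export
weighted_endemism <- function(occ) {
  if (!nrow(occ)) stop("empty occurrence table", call. = FALSE)
  range_size <- table(occ$species)
  w <- 1 / as.numeric(range_size[occ$species])
  we <- tapply(w, occ$cell, sum)
  sr <- tapply(w, occ$cell, length)
  cells <- as.integer(names(we))
  list(WE = grid_map(cells, as.numeric(we), "WE"),
       CWE = grid_map(cells, as.numeric(we) / as.numeric(sr), "CWE"))
}

#' Phylogenetic endemism per grid cell
#'
#' Each branch's range is the union of the cells of its descendant tips; the
#' branch's length is spread equally over that range, so
#' `PE(c) = sum over branches whose range contains c of length / |range|`.
#' Summed over cells, PE equals the total PD of species with nonempty ranges
#' (range-weighted PD). Any root edge is treated as a branch ancestral to all
#' occurring species.
#'
#' @param tree A `"phylo"` object covering all occurring species.
#' @param occ An `"occ_grid"` table.
#' @return A `"grid_metric"` data frame of per-cell PE.
#' @export
phylogenetic_endemism <- function(tree, occ) {
  miss <- setdiff(unique(occ$species), tree$tip.label)
  if (length(miss))
    stop("species missing from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- ape::Ntip(tree)
  cells_by_sp <- split(occ$cell, occ$species)
  ranges <- vector("list", n + tree$Nnode)
  for (i in seq_len(n))
    ranges[[i]] <- cells_by_sp[[tree$tip.label[i]]] %||% integer(0)
  po <- postorder_edges(tree)
  e <- po$edge
  for (i in seq_len(nrow(e)))
    ranges[[e[i, 1L]]] <- union(ranges[[e[i, 1L]]], ranges[[e[i, 2L]]])
  pe <- new.env()
  add <- function(cells, amount) {
    for (cl in cells) {
      key <- as.character(cl)
      pe[[key]] <- (pe[[key]] %||% 0) + amount
    }
  }
  for (i in seq_len(nrow(e))) {
    rng <- ranges[[e[i, 2L]]]
    if (length(rng)) add(rng, po$edge.length[i] / length(rng))
  }
  re <- root_edge_length(tree)
  root_range <- ranges[[n + 1L]]
  if (re > 0 && length(root_range)) add(root_range, re / length(root_range))
  cells <- sort(as.integer(ls(pe)))
  grid_map(cells, vapply(as.character(cells), function(k) pe[[k]],
                         numeric(1)), "PE")
}

#' Mean EDGE score per grid cell
#'
#' Arithmetic mean of EDGE over the scored (non-DD) species present in each
#' cell. Cells whose occupants are all DD carry no value (unoccupied for this
#' metric).
#'
#' @param edge_table Output of [edge_scores()].
#' @param occ An `"occ_grid"` table.
#' @return A `"grid_metric"` data frame of per-cell mean EDGE.
#' @export
grid_mean_edge <- function(edge_table, occ) {
  scored <- occ[occ$species %in% edge_table$species, , drop = FALSE]
  if (!nrow(scored))
    stop("no scored species occur on the grid", call. = FALSE)
  edge <- stats::setNames(edge_table$EDGE, edge_table$species)
  vals <- tapply(edge[scored$species], scored$cell, mean)
  grid_map(as.integer(names(vals)), as.numeric(vals), "meanEDGE")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
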