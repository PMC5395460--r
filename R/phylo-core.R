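#' @importFrom ape read.tree write.tree drop.tip branching.times multi2di
#'   bind.tree getMRCA node.depth.edgelength Ntip Nnode is.ultrametric
#'   extract.clade reorder.phylo
NULL

#' Parse a Newick string into a validated phylogeny
#'
#' Reads a single rooted Newick statement and validates it: parentheses must
#' balance, tip labels must be unique, and branch lengths must be finite and
#' non-negative. Branch lengths are interpreted as millions of years (Myr)
#' throughout the package and stored as read, without rescaling.
#'
#' @param text A single Newick string ending in `";"`.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' sum(tr$edge.length) # 5
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";"))
    stop("Newick statement must end in ';'", call. = FALSE)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'", n_open, n_close),
         call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick string", call. = FALSE)
  validate_phylogeny(tree)
  tree
}

#' Read a phylogeny from a Newick file
#'
#' @param path Path to a file holding one Newick statement.
#' @return A `"phylo"` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a phylogeny as Newick
#'
#' @param tree A `"phylo"` object.
#' @param file Output path, or `""` to return the string.
#' @param digits Significant digits for branch lengths (default 15, enough
#'   for round-trips at 1e-9 relative tolerance).
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = "", digits = 15L) {
  txt <- ape::write.tree(tree, digits = digits)
  if (nzchar(file)) {
    writeLines(txt, file)
    invisible(txt)
  } else txt
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks unique tip labels and finite, non-negative branch lengths. Called
#' by [parse_newick()]; exported so that programmatically built trees can be
#' checked too.
#'
#' @param tree A `"phylo"` object.
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length)))
      stop("non-finite branch lengths", call. = FALSE)
    if (any(tree$edge.length < 0)) {
      bad <- which(tree$edge.length < 0)[1L]
      stop(sprintf("negative branch length %g on edge to node %d",
                   tree$edge.length[bad], tree$edge[bad, 2L]), call. = FALSE)
    }
  }
  invisible(tree)
}

root_edge_length <- function(tree) {
  if (is.null(tree$root.edge)) 0 else tree$root.edge
}

#' Total branch length of a tree, including any root edge
#'
#' This is the tree's total phylogenetic diversity under the rooted
#' convention used throughout the package.
#'
#' @param tree A `"phylo"` object.
#' @return Total length in Myr.
#' @export
total_tree_length <- function(tree) {
  sum(tree$edge.length) + root_edge_length(tree)
}

#' Node ages of an ultrametric tree
#'
#' Ages are computed from tip depth (all tips at age 0).
#'
#' @param tree A `"phylo"` object.
#' @return Numeric vector of ages indexed by node number (tips then
#'   internals, ape numbering).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

ultrametric_deviation <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  (max(depth) - min(depth)) / max(depth)
}

assert_ultrametric <- function(tree, tol = 1e-6) {
  dev <- ultrametric_deviation(tree)
  if (dev > tol)
    stop(sprintf("tree is not ultrametric: max relative root-to-tip deviation %.3g exceeds %g",
                 dev, tol), call. = FALSE)
  invisible(tree)
}

single_tip_tree <- function(label, length) {
  tr <- list(edge = matrix(c(2L, 1L), 1L, 2L), Nnode = 1L,
             tip.label = label, edge.length = length)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Prune a tree to a set of tips, retaining the path to the original root
#'
#' Unbranched internal nodes created by pruning are suppressed with their
#' lengths summed. The path from the original root down to the most recent
#' common ancestor of `keep` is retained as the pruned tree's root edge, so
#' that phylogenetic diversity of the kept tips is preserved exactly
#' (see [faith_pd()]).
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (nonempty).
#' @return A `"phylo"` object with `root.edge` set where root path length is
#'   positive.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' total_tree_length(prune_to(tr, c("A", "B"))) # 3
#' @export
prune_to <- function(tree, keep) {
  keep <- unique(as.character(keep))
  if (!length(keep)) stop("keep must be nonempty", call. = FALSE)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip labels: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  ages <- ape::node.depth.edgelength(tree)
  if (length(keep) == 1L) {
    out <- single_tip_tree(keep, ages[match(keep, tree$tip.label)] +
                                   root_edge_length(tree))
    return(out)
  }
  mrca <- ape::getMRCA(tree, keep)
  stem <- ages[mrca] + root_edge_length(tree)
  out <- ape::drop.tip(tree, setdiff(tree$tip.label, keep))
  if (stem > 0) out$root.edge <- stem else out$root.edge <- NULL
  out
}

#' Branching times of an ultrametric tree
#'
#' Ages of the internal nodes, in descending order (root first). These are
#' the sufficient data for the diversification likelihoods in
#' [fit_diversification_models()].
#'
#' @param tree An ultrametric `"phylo"` object with at least 3 tips.
#' @param tol Relative ultrametricity tolerance (default 1e-6).
#' @return Numeric vector of node ages in Myr, descending, length equal to
#'   the number of internal nodes.
#' @export
branching_times <- function(tree, tol = 1e-6) {
  if (ape::Ntip(tree) < 3L) stop("need at least 3 tips", call. = FALSE)
  assert_ultrametric(tree, tol)
  bt <- sort(unname(ape::branching.times(tree)), decreasing = TRUE)
  bt
}

#' Tips descending from a node
#'
#' @param tree A `"phylo"` object.
#' @param node Node number in ape convention (tips `1..Ntip`, internals
#'   `Ntip+1..Ntip+Nnode`).
#' @return Character vector of tip labels; for a tip node, the tip itself.
#' @export
clade_tips <- function(tree, node) {
  n <- ape::Ntip(tree)
  node <- as.integer(node)
  if (length(node) != 1L || is.na(node) || node < 1L || node > n + tree$Nnode)
    stop("unknown node: ", node, call. = FALSE)
  if (node <= n) return(tree$tip.label[node])
  kids <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- children[[as.character(cur)]]
    tips <- ch[ch <= n]
    kids <- c(kids, tips)
    stack <- c(stack, ch[ch > n])
  }
  tree$tip.label[sort(kids)]
}

#' Resolve polytomies deterministically
#'
#' Multifurcations are resolved into bifurcations with zero-length branches,
#' deterministically (same input always yields the same binary tree).
#' Operations requiring binary trees (the D statistic, diversification fits)
#' call this internally.
#'
#' @param tree A `"phylo"` object.
#' @return A binary `"phylo"` object.
#' @export
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}

#' Drop outgroup taxa from a tree
#'
#' Diversification-rate analyses are run on the ingroup only; this is the
#' explicit outgroup-removal step, rather than silently guessing which
#' analyses include outgroups.
#'
#' @param tree A `"phylo"` object.
#' @param outgroups Character vector of tip labels (silently ignored if not
#'   present).
#' @return Pruned `"phylo"` object.
#' @export
drop_outgroups <- function(tree, outgroups) {
  present <- intersect(outgroups, tree$tip.label)
  if (!length(present)) return(tree)
  prune_to(tree, setdiff(tree$tip.label, present))
}

# parent lookup: vector indexed by node, 0 for root
parent_vector <- function(tree) {
  p <- integer(ape::Ntip(tree) + tree$Nnode)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# edges in postorder (children before parents)
postorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "postorder")
}
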