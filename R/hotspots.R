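#' Select the richest cells of a grid metric as a hotspot set
#'
#' Occupied cells are ranked descending by value with ties broken by
#' ascending cell id; the top `ceiling(threshold_percent/100 * n_occupied)`
#' cells form the hotspot. Only occupied cells enter the percentile base.
#'
#' @param map A `"grid_metric"` data frame (`cell`, `value`).
#' @param threshold_percent Percentile threshold in (0, 100\]; 2.5 is the
#'   conventional biodiversity-hotspot cut, 5 the second display tier.
#' @return List of class `"hotspot_set"`: `metric`, `threshold`, `cells`,
#'   `values`.
#' @export
select_hotspots <- function(map, threshold_percent = 2.5) {
  if (!nrow(map)) stop("no occupied cells", call. = FALSE)
  stopifnot(threshold_percent > 0, threshold_percent <= 100)
  k <- ceiling(threshold_percent / 100 * nrow(map))
  ord <- order(-map$value, map$cell)
  pick <- ord[seq_len(k)]
  structure(list(metric = attr(map, "metric") %||% "metric",
                 threshold = threshold_percent,
                 cells = map$cell[pick],
                 values = map$value[pick]),
            class = "hotspot_set")
}

#' Venn region counts for a collection of hotspot sets
#'
#' Counts the cells in every nonempty intersection region (the exclusive
#' regions of the Venn diagram: `2^k - 1` for `k` sets). Region names are
#' `+`-joined set names; the counts partition the union exactly.
#'
#' @param sets Named list of `"hotspot_set"` objects (>= 2).
#' @return Named integer vector over all `2^k - 1` regions.
#' @export
hotspot_overlap <- function(sets) {
  if (length(sets) < 2L) stop("need >= 2 hotspot sets", call. = FALSE)
  nms <- names(sets) %||% vapply(sets, `[[`, "", "metric")
  cells <- lapply(sets, `[[`, "cells")
  all_cells <- unique(unlist(cells))
  member <- vapply(cells, function(cl) all_cells %in% cl,
                   logical(length(all_cells)))
  member <- matrix(member, ncol = length(sets))
  k <- length(sets)
  out <- integer(2^k - 1L)
  labels <- character(2^k - 1L)
  for (code in seq_len(2^k - 1L)) {
    inset <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))
    labels[code] <- paste(nms[inset], collapse = "+")
    out[code] <- sum(apply(member, 1L, function(m) all(m == inset)))
  }
  stats::setNames(out, labels)
}

#' Union of hotspot sets with its cumulative area
#'
#' @param sets List of `"hotspot_set"` objects.
#' @param cell_area_km2 Nominal area per cell (default 10000 km2, i.e.
#'   100 x 100 km cells).
#' @param n_occupied Optional count of occupied grid cells, for the
#'   percent-of-occupied-cells figure.
#' @return List: `cells` (union), `n_cells`, `area_km2`, and
#'   `pct_of_occupied` when `n_occupied` is given.
#' @export
cumulative_hotspots <- function(sets, cell_area_km2 = 10000,
                                n_occupied = NULL) {
  if (!length(sets)) stop("need >= 1 hotspot set", call. = FALSE)
  u <- sort(unique(unlist(lapply(sets, `[[`, "cells"))))
  out <- list(cells = u, n_cells = length(u),
              area_km2 = length(u) * cell_area_km2)
  if (!is.null(n_occupied))
    out$pct_of_occupied <- 100 * length(u) / n_occupied
  out
}

#' Protected-area coverage of hotspot sets
#'
#' A cell counts as protected iff its protected fraction is at least 0.5
#' (strict 50-percent-overlap rule). Reports per-set and overall coverage and
#' flags sets not fully inside the protected network.
#'
#' @param sets Named list of `"hotspot_set"` objects.
#' @param mask Data frame `cell`, `protected_fraction` covering all member
#'   cells.
#' @param rule_threshold Protected-cell rule (default 0.5).
#' @return List of class `"protection_report"`: per-set data frame
#'   (`set`, `n_cells`, `n_protected`, `coverage`), `overall_coverage`,
#'   `fully_covered`, `gaps` (sets with coverage < 1), `rule_threshold`.
#' @export
protection_coverage <- function(sets, mask, rule_threshold = 0.5) {
  stopifnot(all(c("cell", "protected_fraction") %in% names(mask)))
  prot <- stats::setNames(mask$protected_fraction, mask$cell)
  nms <- names(sets) %||% vapply(sets, `[[`, "", "metric")
  all_cells <- unique(unlist(lapply(sets, `[[`, "cells")))
  missing <- setdiff(all_cells, mask$cell)
  if (length(missing))
    stop("mask missing cells: ", paste(utils::head(missing, 10),
                                       collapse = ", "), call. = FALSE)
  per <- do.call(rbind, lapply(seq_along(sets), function(i) {
    cl <- sets[[i]]$cells
    np <- sum(prot[as.character(cl)] >= rule_threshold)
    data.frame(set = nms[i], n_cells = length(cl), n_protected = np,
               coverage = np / length(cl), stringsAsFactors = FALSE)
  }))
  overall <- sum(prot[as.character(all_cells)] >= rule_threshold) /
    length(all_cells)
  structure(list(per_set = per, overall_coverage = overall,
                 fully_covered = all(per$coverage == 1),
                 gaps = per$set[per$coverage < 1],
                 rule_threshold = rule_threshold),
            class = "protection_report")
}

#' @export
print.protection_report <- function(x, ...) {
  print(x$per_set, row.names = FALSE)
  cat(sprintf("overall coverage %.3f (protected-cell rule: fraction >= %g)\n",
              x$overall_coverage, x$rule_threshold))
  if (x$fully_covered) cat("all hotspots fall within protected cells\n")
  else cat("coverage gaps in: ", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}
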