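#' Segment-level geometry of a single branch
#'
#' A branch segment is modelled as a cylinder of its basal diameter:
#' surface area \eqn{SA = \pi D L} and volume \eqn{V = \pi (D/2)^2 L}.
#' Length, mass and diameter are the measured values passed through.
#'
#' @param diameter Basal diameter (cm, > 0).
#' @param length Segment length (cm, >= 0).
#' @param mass Oven-dry mass (g) or `NA`.
#' @return One-row data frame with `diameter`, `length`, `mass`,
#'   `surface_area` (cm^2) and `volume` (cm^3).
#' @examples
#' segment_geometry(4, 10)  # D = 4 makes SA and V coincide at 40*pi
#' @export
segment_geometry <- function(diameter, length, mass = NA_real_) {
  stopifnot(all(diameter > 0), all(length >= 0))
  data.frame(diameter = diameter, length = length, mass = mass,
             surface_area = pi * diameter * length,
             volume = pi * (diameter / 2)^2 * length)
}

# Aggregate segment metrics over a tree in one post-order pass.
# Returns, per branch: path sums (length-maximal distal chain) and subtree
# sums. Twigs are dropped before aggregation unless include_twigs.
#' Morphological characteristics at the three branch classifications
#'
#' Computes, for every (non-twig, by default) branch of a tree, the
#' morphological characteristics used in branch-level allometry at the three
#' classification levels:
#' \describe{
#'   \item{segment}{the values measured or computed for the branch itself;}
#'   \item{path}{the branch plus the longest continuous chain of distal
#'     branches: at each node the child with maximal path length is
#'     followed, and length, mass, surface area and volume are summed along
#'     that chain;}
#'   \item{subtree}{the branch plus all distal branches, summed.}
#' }
#' Diameter at every level is the branch's own basal diameter: the
#' classifications re-aggregate the extensive quantities only. Terminal
#' branches have path = subtree = segment. Ties in path length are broken
#' toward the larger-diameter child, then the lexicographically smallest
#' branch id, so recomputation is deterministic. A missing mass anywhere in
#' an aggregate makes that aggregate's mass missing (never zero-filled).
#'
#' @param tree A [tree_architecture()].
#' @param levels Subset of `c("segment", "path", "subtree")`.
#' @param include_twigs Include twig records in the table and in path and
#'   subtree sums (the main analysis excludes them).
#' @return Data frame with one row per branch and level: `tree_id`,
#'   `branch_id`, `level`, `depth`, `n_branches` (branches aggregated),
#'   `diameter`, `length`, `mass`, `surface_area`, `volume`, plus any
#'   grouping columns (`species`, `rootstock`) present on the records.
#' @examples
#' rec <- data.frame(branch_id = c("r", "a", "b"),
#'                   parent_id = c(NA, "r", "r"),
#'                   diameter = c(5, 3, 2), length = c(10, 8, 5),
#'                   mass = c(100, 40, 10), is_twig = FALSE)
#' m <- branch_metrics(tree_architecture(rec))
#' subset(m, branch_id == "r" & level == "subtree")$length  # 23
#' @export
branch_metrics <- function(tree, levels = c("segment", "path", "subtree"),
                           include_twigs = FALSE) {
  stopifnot(inherits(tree, "tree_architecture"))
  levels <- match.arg(levels, several.ok = TRUE)
  rec <- tree$records
  if (!include_twigs) rec <- rec[!rec$is_twig, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop("no branches left after twig exclusion in tree '", tree$tree_id,
         "'", call. = FALSE)
  ids <- rec$branch_id
  if (!tree$root %in% ids)
    stop("root of tree '", tree$tree_id, "' is flagged as a twig; ",
         "aggregation undefined", call. = FALSE)
  seg <- segment_geometry(rec$diameter, rec$length, rec$mass)
  rownames(seg) <- ids
  kids_of <- lapply(stats::setNames(ids, ids), function(b)
    intersect(tree$children[[b]], ids))

  # post-order: children appear before parents
  order_post <- rev(ids[order(tree$depth[ids], ids)])
  agg_names <- c("length", "mass", "surface_area", "volume")
  path <- subtree <- as.matrix(seg[, agg_names])
  n_path <- n_sub <- stats::setNames(rep(1L, length(ids)), ids)
  for (b in order_post) {
    kids <- kids_of[[b]]
    if (length(kids) == 0L) next
    # path: follow the child of maximal path length; ties to the larger
    # diameter, then the smallest id (kids are pre-sorted lexicographically)
    o <- order(-path[kids, "length"], -seg[kids, "diameter"])
    best <- kids[o[1L]]
    path[b, ] <- path[b, ] + path[best, ]
    n_path[b] <- n_path[b] + n_path[best]
    subtree[b, ] <- subtree[b, ] +
      colSums(subtree[kids, , drop = FALSE])
    n_sub[b] <- n_sub[b] + sum(n_sub[kids])
  }

  lvl_tab <- function(level, m, n) {
    out <- data.frame(tree_id = tree$tree_id, branch_id = ids,
                      level = level, depth = unname(tree$depth[ids]),
                      n_branches = unname(n[ids]),
                      diameter = seg$diameter, as.data.frame(m),
                      stringsAsFactors = FALSE)
    for (g in intersect(c("species", "rootstock"), names(rec)))
      out[[g]] <- rec[[g]]
    out
  }
  tabs <- list(segment = function() lvl_tab("segment",
                                            as.matrix(seg[, agg_names]),
                                            stats::setNames(rep(1L,
                                              length(ids)), ids)),
               path = function() lvl_tab("path", path, n_path),
               subtree = function() lvl_tab("subtree", subtree, n_sub))
  out <- do.call(rbind, lapply(levels, function(l) tabs[[l]]()))
  rownames(out) <- NULL
  n_na <- sum(is.na(out$mass))
  if (n_na > 0L)
    attr(out, "mass_missing") <- n_na
  out
}

#' Metrics tables for a collection of trees
#'
#' @param trees List of [tree_architecture()] objects (as returned by
#'   [read_branch_table()]).
#' @inheritParams branch_metrics
#' @return Row-bound data frame of [branch_metrics()] results.
#' @export
metrics_table <- function(trees, levels = c("segment", "path", "subtree"),
                          include_twigs = FALSE) {
  if (inherits(trees, "tree_architecture")) trees <- list(trees)
  out <- do.call(rbind, lapply(trees, branch_metrics, levels = levels,
                               include_twigs = include_twigs))
  rownames(out) <- NULL
  out
}
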