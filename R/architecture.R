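#' Describe the column layout and policies of a branch measurement table
#'
#' A schema maps the columns of a delimited branch table onto the canonical
#' fields used throughout the package, declares unit conversions into the
#' canonical units (centimetres for diameter and length, grams for dry mass),
#' and sets the twig policy.
#'
#' A *twig* is a stem supporting only buds or short fruit-bearing spurs,
#' conventionally under 2 cm basal diameter. Twig status is partly
#' observational and cannot be inferred from geometry alone, so the default
#' rule flags a row as a twig only when a dedicated indicator column says so
#' AND its diameter falls below `twig_diameter_max`; with no indicator column
#' the twig flag defaults to `FALSE` for every row.
#'
#' @param tree_id,branch_id,parent_id,diameter,length,mass Column names in
#'   the input file holding, respectively, the tree identifier, the branch
#'   identifier (unique within a tree), the parent branch identifier (empty
#'   or `NA` marks the root), basal diameter, segment length, and oven-dry
#'   mass. `mass = NA` declares that no mass column exists.
#' @param species,rootstock Optional grouping-label columns (`NA` = absent).
#' @param twig Optional logical/0-1 column marking terminal fruiting stems
#'   (`NA` = absent, in which case no row is flagged as a twig).
#' @param twig_diameter_max Diameter ceiling (cm, after unit conversion) for
#'   the twig rule; rows marked in the `twig` column but at or above this
#'   diameter are not flagged.
#' @param diameter_scale,length_scale,mass_scale Multiplicative factors
#'   converting the file's units to cm, cm and g.
#' @param sep Field separator of the delimited file.
#' @return An object of class `branch_schema`.
#' @examples
#' sch <- branch_schema(mass = "dry_mass_g", species = "species")
#' @export
branch_schema <- function(tree_id = "tree_id", branch_id = "branch_id",
                          parent_id = "parent_id", diameter = "diameter",
                          length = "length", mass = "mass",
                          species = NA, rootstock = NA, twig = NA,
                          twig_diameter_max = 2,
                          diameter_scale = 1, length_scale = 1,
                          mass_scale = 1, sep = ",") {
  stopifnot(is.character(tree_id), is.character(branch_id),
            is.character(parent_id), is.character(diameter),
            is.character(length),
            is.numeric(twig_diameter_max), twig_diameter_max > 0,
            diameter_scale > 0, length_scale > 0, mass_scale > 0)
  structure(list(
    columns = list(tree_id = tree_id, branch_id = branch_id,
                   parent_id = parent_id, diameter = diameter,
                   length = length, mass = mass, species = species,
                   rootstock = rootstock, twig = twig),
    twig_diameter_max = twig_diameter_max,
    scales = c(diameter = diameter_scale, length = length_scale,
               mass = mass_scale),
    sep = sep), class = "branch_schema")
}

#' Construct a validated rooted tree from per-branch records
#'
#' Checks the topological invariants every downstream computation relies on:
#' branch ids unique, exactly one root (missing/empty `parent_id`), every
#' other `parent_id` resolving to an existing branch, and no cycles, so the
#' parent--child relation is a connected rooted tree.
#'
#' @param records Data frame with columns `branch_id`, `parent_id` (character;
#'   `NA` or `""` marks the root), `diameter` (cm, > 0), `length` (cm, >= 0),
#'   `mass` (g, >= 0 or `NA`), `is_twig` (logical), and optionally `species`,
#'   `rootstock`.
#' @param tree_id Identifier of the individual tree.
#' @return An object of class `tree_architecture`: a list with elements
#'   `tree_id`, `records` (the validated data frame), `root` (the root
#'   branch id), `children` (named list mapping each branch id to its
#'   children's ids) and `depth` (named integer vector, root = 0).
#' @seealso [read_branch_table()], [export_topology()]
#' @export
tree_architecture <- function(records, tree_id = "tree") {
  req <- c("branch_id", "parent_id", "diameter", "length", "mass", "is_twig")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L)
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records$branch_id <- as.character(records$branch_id)
  records$parent_id <- as.character(records$parent_id)
  records$parent_id[!is.na(records$parent_id) &
                      records$parent_id == ""] <- NA_character_

  if (anyDuplicated(records$branch_id))
    stop("validation error: duplicated branch_id within tree '", tree_id,
         "': ", paste(unique(records$branch_id[duplicated(records$branch_id)]),
                      collapse = ", "), call. = FALSE)
  bad_d <- which(!is.finite(records$diameter) | records$diameter <= 0)
  if (length(bad_d) > 0L)
    stop("validation error: non-positive diameter at row(s) ",
         paste(bad_d, collapse = ", "), " (branch ",
         paste(records$branch_id[bad_d], collapse = ", "), ")", call. = FALSE)
  bad_l <- which(!is.finite(records$length) | records$length < 0)
  if (length(bad_l) > 0L)
    stop("validation error: negative or non-finite length at row(s) ",
         paste(bad_l, collapse = ", "), call. = FALSE)
  bad_m <- which(!is.na(records$mass) & records$mass < 0)
  if (length(bad_m) > 0L)
    stop("validation error: negative mass at row(s) ",
         paste(bad_m, collapse = ", "), call. = FALSE)

  is_root <- is.na(records$parent_id)
  if (sum(is_root) != 1L)
    stop("topology error: tree '", tree_id, "' has ", sum(is_root),
         " root records (expected exactly 1)", call. = FALSE)
  root <- records$branch_id[is_root]

  unknown <- setdiff(records$parent_id[!is_root], records$branch_id)
  if (length(unknown) > 0L)
    stop("topology error: parent_id not found among branch ids: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  self_ref <- records$branch_id[!is_root &
                                  records$parent_id == records$branch_id]
  if (length(self_ref) > 0L)
    stop("topology error: branch references itself as parent: ",
         paste(self_ref, collapse = ", "), call. = FALSE)

  children <- split(records$branch_id[!is_root], records$parent_id[!is_root])
  children <- lapply(children, sort)
  # breadth-first reachability from the root both detects cycles (unreached
  # components) and yields depths
  depth <- stats::setNames(rep(NA_integer_, nrow(records)), records$branch_id)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier) > 0L) {
    nxt <- character(0)
    for (b in frontier) {
      kids <- children[[b]]
      if (length(kids) > 0L) {
        depth[kids] <- depth[b] + 1L
        nxt <- c(nxt, kids)
      }
    }
    frontier <- nxt
  }
  if (anyNA(depth))
    stop("topology error: cycle or disconnected branches: ",
         paste(names(depth)[is.na(depth)], collapse = ", "), call. = FALSE)

  structure(list(tree_id = tree_id, records = records, root = root,
                 children = children, depth = depth),
            class = "tree_architecture")
}

#' @export
print.tree_architecture <- function(x, ...) {
  cat("Tree architecture '", x$tree_id, "': ", nrow(x$records),
      " branches (", sum(x$records$is_twig), " twigs), max depth ",
      max(x$depth), ", root '", x$root, "'\n", sep = "")
  invisible(x)
}

#' Branch ids of terminal (childless) branches
#' @param tree A `tree_architecture`.
#' @param include_twigs Count twig records as branches; when `FALSE` twigs
#'   are ignored entirely, so a branch whose only children are twigs is
#'   terminal.
#' @return Character vector of branch ids.
#' @export
terminal_branches <- function(tree, include_twigs = FALSE) {
  rec <- tree$records
  keep <- if (include_twigs) rec$branch_id else rec$branch_id[!rec$is_twig]
  parents <- unique(rec$parent_id[rec$branch_id %in% keep])
  setdiff(keep, parents)
}

#' Read a delimited branch measurement table into tree architectures
#'
#' Parses a delimited text file with one row per measured branch, applies the
#' schema's column mapping and unit conversions, evaluates the twig rule, and
#' validates one rooted [tree_architecture()] per tree identifier. Rows
#' failing validation are reported with their file row numbers.
#'
#' @param path Path to the delimited file (header row required).
#' @param schema A [branch_schema()] describing the file.
#' @param quiet Suppress the per-tree ingest log.
#' @return Named list of `tree_architecture` objects (one per tree id), with
#'   attribute `"n_rows"` holding the accepted input row count.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("tree_id,branch_id,parent_id,diameter,length,mass",
#'              "t1,trunk,,10,50,900", "t1,a,trunk,4,30,120",
#'              "t1,b,trunk,3,20,60"), tf)
#' trees <- read_branch_table(tf)
#' trees[["t1"]]
#' @export
read_branch_table <- function(path, schema = branch_schema(), quiet = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(schema, "branch_schema"))
  raw <- utils::read.table(path, header = TRUE, sep = schema$sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, comment.char = "")
  cols <- schema$columns
  need <- unlist(cols[c("tree_id", "branch_id", "parent_id", "diameter",
                        "length")], use.names = FALSE)
  absent <- setdiff(need, names(raw))
  if (length(absent) > 0L)
    stop("schema error: column(s) not in file: ",
         paste(absent, collapse = ", "), call. = FALSE)

  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(
    tree_id   = raw[[cols$tree_id]],
    branch_id = raw[[cols$branch_id]],
    parent_id = raw[[cols$parent_id]],
    diameter  = num(raw[[cols$diameter]]) * schema$scales[["diameter"]],
    length    = num(raw[[cols$length]]) * schema$scales[["length"]],
    stringsAsFactors = FALSE)
  rec$mass <- if (!is.na(cols$mass) && cols$mass %in% names(raw))
    num(raw[[cols$mass]]) * schema$scales[["mass"]] else NA_real_
  rec$species <- if (!is.na(cols$species) && cols$species %in% names(raw))
    raw[[cols$species]] else NA_character_
  rec$rootstock <- if (!is.na(cols$rootstock) && cols$rootstock %in% names(raw))
    raw[[cols$rootstock]] else NA_character_
  twig_marked <- if (!is.na(cols$twig) && cols$twig %in% names(raw)) {
    v <- tolower(raw[[cols$twig]])
    v %in% c("true", "t", "1", "yes")
  } else rep(FALSE, nrow(rec))
  rec$is_twig <- twig_marked & rec$diameter < schema$twig_diameter_max

  trees <- lapply(split(seq_len(nrow(rec)), rec$tree_id), function(idx) {
    tree_architecture(rec[idx, , drop = FALSE], tree_id = rec$tree_id[idx[1]])
  })
  if (!quiet) {
    for (tid in names(trees))
      message("ingest: tree '", tid, "': ", nrow(trees[[tid]]$records),
              " branches, ", sum(trees[[tid]]$records$is_twig), " twigs, ",
              sum(is.na(trees[[tid]]$records$mass)), " missing mass")
  }
  attr(trees, "n_rows") <- nrow(rec)
  trees
}

#' Write a tree architecture back to the canonical branch-table layout
#'
#' @param trees A `tree_architecture` or a list of them.
#' @param path Output file path (comma-separated, header row).
#' @return `path`, invisibly.
#' @export
write_branch_table <- function(trees, path) {
  if (inherits(trees, "tree_architecture")) trees <- list(trees)
  tab <- do.call(rbind, lapply(trees, function(tr) {
    r <- tr$records
    r$tree_id <- tr$tree_id
    r[, c("tree_id", "branch_id", "parent_id", "diameter", "length",
          "mass", "is_twig",
          intersect(c("species", "rootstock"), names(r)))]
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Serialize a tree architecture as a Newick string
#'
#' Node labels are branch ids; branch lengths are segment lengths in cm. The
#' writer handles the degenerate cases a branch table produces that standard
#' phylogenetic containers do not: a single-record tree and internal nodes of
#' out-degree one.
#'
#' @param tree A `tree_architecture`.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string terminated by `;`.
#' @examples
#' rec <- data.frame(branch_id = c("r", "a", "b"),
#'                   parent_id = c(NA, "r", "r"),
#'                   diameter = c(5, 3, 2), length = c(10, 8, 5),
#'                   mass = NA_real_, is_twig = FALSE)
#' export_topology(tree_architecture(rec))
#' @export
export_topology <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "tree_architecture"))
  len <- stats::setNames(tree$records$length, tree$records$branch_id)
  fmt <- function(b) {
    kids <- tree$children[[b]]
    lab <- paste0(b, ":", format(len[[b]], digits = digits,
                                 scientific = FALSE, trim = TRUE))
    if (length(kids) == 0L) lab
    else paste0("(", paste(vapply(kids, fmt, character(1)), collapse = ","),
                ")", lab)
  }
  paste0(fmt(tree$root), ";")
}
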