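#' Configuration of an end-to-end allometry run
#'
#' Collects and fail-fast validates everything a run needs: the input (a
#' branch-table path plus [branch_schema()], or a [synth_config()] for a
#' simulated run), the variable pairs, classification levels, grouping,
#' confidence level, output directory and seed.
#'
#' @param input Path to a delimited branch table, or a [synth_config()].
#' @param schema [branch_schema()] for file input.
#' @param pairs `"y~x"` pairs to fit (see [allometry_pairs()]).
#' @param levels Classification levels.
#' @param grouping `"pooled"`, `"species"`, `"rootstock"` or
#'   `"individual"`.
#' @param conf Confidence level for SMA intervals.
#' @param include_twigs Include twigs in aggregates.
#' @param out_dir Directory for the report bundle.
#' @param seed Integer seed (applied to synthetic input generation).
#' @param n_synth_trees Number of trees to generate for synthetic input.
#' @return Object of class `run_config`.
#' @export
make_run_config <- function(input, schema = branch_schema(),
                            pairs = c("length~diameter", "mass~diameter"),
                            levels = c("segment", "path", "subtree"),
                            grouping = "pooled", conf = 0.95,
                            include_twigs = FALSE,
                            out_dir = tempfile("allom_run_"), seed = 1,
                            n_synth_trees = 1) {
  grouping <- match.arg(grouping, c("pooled", "species", "rootstock",
                                    "individual"))
  bad <- setdiff(levels, c("segment", "path", "subtree"))
  if (length(bad) > 0L)
    stop("configuration error: unknown level(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  lapply(pairs, parse_pair)
  stopifnot(conf > 0, conf < 1, n_synth_trees >= 1)
  if (!inherits(input, "synth_config") && !is.character(input))
    stop("configuration error: input must be a file path or synth_config",
         call. = FALSE)
  structure(list(input = input, schema = schema, pairs = pairs,
                 levels = levels, grouping = grouping, conf = conf,
                 include_twigs = include_twigs, out_dir = out_dir,
                 seed = seed, n_synth_trees = as.integer(n_synth_trees)),
            class = "run_config")
}

#' Run the full branch-allometry pipeline
#'
#' Orchestrates ingest (or synthesis) -> morphology -> SMA fitting ->
#' model-prediction comparison, and writes the report bundle to
#' `config$out_dir`:
#' \describe{
#'   \item{allometry_fits.csv}{one row per (pair, level, group): exponent,
#'     CI, multiplier, CI, r^2, n — the empirical allometry table;}
#'   \item{model_comparison.csv}{each fit against the FS range and/or WBE
#'     point prediction with its classification status, plus the
#'     across-level tendency direction per pair and group;}
#'   \item{aicc.csv}{linear vs quadratic log-log AICc per fit;}
#'   \item{predictions.csv}{the theoretical prediction table;}
#'   \item{manifest.json}{inputs, configuration, seed, package version and
#'     exclusion counts — sufficient to replay the run.}
#' }
#' Human-readable rounding is left to the reader; all tables carry full
#' precision. No multiple-comparison correction is applied to CI-overlap
#' interpretation.
#'
#' @param config A [make_run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with elements `trees`, `metrics`, `fits`,
#'   `comparison`, `aicc`, `manifest` (also written to disk).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (inherits(config$input, "synth_config")) {
    trees <- lapply(seq_len(config$n_synth_trees), function(i) {
      cfg <- config$input
      cfg$seed <- if (is.null(config$seed)) NULL else config$seed + i - 1L
      generate_tree(cfg, tree_id = sprintf("synth_%02d", i))$tree
    })
    names(trees) <- vapply(trees, `[[`, "", "tree_id")
    input_desc <- "synthetic"
  } else {
    trees <- read_branch_table(config$input, config$schema, quiet = quiet)
    input_desc <- normalizePath(config$input)
  }

  metrics <- metrics_table(trees, levels = config$levels,
                           include_twigs = config$include_twigs)
  fits <- fit_grid(metrics, pairs = config$pairs, levels = config$levels,
                   grouping = config$grouping, conf = config$conf)

  comparison <- compare_to_models(fits)
  aicc <- aicc_table(metrics, config)

  manifest <- list(
    package = "branchallom",
    version = as.character(utils::packageVersion("branchallom")),
    input = input_desc,
    synth_config = if (inherits(config$input, "synth_config"))
      unclass(config$input) else NULL,
    pairs = config$pairs, levels = config$levels,
    grouping = config$grouping, conf = config$conf,
    include_twigs = config$include_twigs, seed = config$seed,
    n_trees = length(trees),
    n_branches = sum(vapply(trees, function(t) nrow(t$records), 0)),
    n_failed_fits = sum(!fits$ok),
    note = "95% CI overlap interpreted without multiplicity correction")

  utils::write.csv(fits, file.path(config$out_dir, "allometry_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(comparison,
                   file.path(config$out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(aicc, file.path(config$out_dir, "aicc.csv"),
                   row.names = FALSE)
  utils::write.csv(prediction_table(),
                   file.path(config$out_dir, "predictions.csv"),
                   row.names = FALSE)
  # digits = I(17): doubles (e.g. irrational scaling ratios) must round-trip
  # bit-exactly for the manifest to replay the run byte-identically
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = I(17),
                       null = "null")
  if (!quiet)
    message("run: ", nrow(fits), " fits (", sum(!fits$ok), " failed), ",
            "bundle in ", config$out_dir)
  invisible(list(trees = trees, metrics = metrics, fits = fits,
                 comparison = comparison, aicc = aicc, manifest = manifest))
}

# One row per fit x applicable model, with classification status and the
# per-(pair, group) tendency direction attached to every level's row.
compare_to_models <- function(fits) {
  rows <- list()
  lvl_order <- c(segment = 1L, path = 2L, subtree = 3L)
  for (i in seq_len(nrow(fits))) {
    f <- fits[i, ]
    pair <- paste0(f$y_variable, "~", f$x_variable)
    preds <- list()
    if (pair %in% fs_pairs()) preds <- c(preds, list(fs_range(pair)))
    if (pair %in% c("mass~diameter", "length~diameter", "length~mass"))
      preds <- c(preds, list(wbe_prediction(pair)))
    if (length(preds) == 0L) next
    for (pr in preds) {
      status <- if (isTRUE(f$ok))
        classify_fit(list(a_ci = c(f$a_low, f$a_high)), pr)$status
      else NA_character_
      dir <- NA_character_
      if (pr$model == "FS") {
        same <- fits[fits$ok & fits$group == f$group &
                       fits$y_variable == f$y_variable &
                       fits$x_variable == f$x_variable, ]
        same <- same[order(lvl_order[same$level]), ]
        if (nrow(same) >= 2L)
          dir <- tendency(same$a_hat, pr)$direction
      }
      rows[[length(rows) + 1L]] <- data.frame(
        y_variable = f$y_variable, x_variable = f$x_variable,
        level = f$level, group = f$group, model = pr$model,
        a_hat = f$a_hat, a_low = f$a_low, a_high = f$a_high,
        pred_low = pr$range[1], pred_high = pr$range[2],
        status = status, tendency = dir,
        reconstructed = isTRUE(pr$reconstructed),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame()
  rownames(out) <- NULL
  out
}

aicc_table <- function(metrics, config) {
  group_col <- switch(config$grouping, pooled = NULL, species = "species",
                      rootstock = "rootstock", individual = "tree_id")
  groups <- if (is.null(group_col)) list(all = metrics)
  else split(metrics, metrics[[group_col]])
  rows <- list()
  for (g in names(groups)) for (lvl in config$levels)
    for (p in config$pairs) {
      yx <- parse_pair(p)
      sub <- groups[[g]][groups[[g]]$level == lvl, , drop = FALSE]
      res <- tryCatch(aicc_compare(sub[[yx[2]]], sub[[yx[1]]]),
                      error = function(e) list(aicc_linear = NA_real_,
                                               aicc_quadratic = NA_real_,
                                               delta = NA_real_,
                                               preferred = NA_character_))
      rows[[length(rows) + 1L]] <- data.frame(
        y_variable = yx[1], x_variable = yx[2], level = lvl, group = g,
        aicc_linear = res$aicc_linear, aicc_quadratic = res$aicc_quadratic,
        delta = res$delta, preferred = res$preferred,
        stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
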