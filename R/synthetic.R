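# Run expr with a private RNG stream seeded by `seed` (global .Random.seed
# restored afterwards); seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Parameters of the self-similar branching-tree generator
#'
#' The generator grows a full `n_children`-ary tree of `levels` depth
#' levels, scaling diameter by `beta` and length by `gamma` at each level.
#' For such a self-similar network the segment-level length--diameter
#' allometry is exactly \eqn{L \propto D^{a}} with
#' \eqn{a = \ln\gamma / \ln\beta}. Measurement error is multiplicative
#' lognormal (sd `noise_sigma` on the natural-log scale) applied
#' independently to diameter and length; mass is wood density times the
#' noised segment volume times its own lognormal noise, keeping log--log
#' residuals homoscedastic as the SMA error model assumes. Pruning
#' perturbations mimic orchard management: `prune_fraction` is the
#' probability that each non-root subtree at depth >= `prune_min_depth` is
#' removed outright (branch-removing cuts), `tip_trim` the fraction by
#' which terminal segment lengths (and proportionally their mass) are
#' shortened (length-reducing cuts).
#'
#' @param n_children Daughter branches per branch (>= 1).
#' @param levels Number of depth levels including the root (>= 2).
#' @param root_diameter,root_length Root segment dimensions (cm).
#' @param beta,gamma Per-level diameter and length scaling ratios in (0,1).
#' @param noise_sigma Lognormal sd of measurement noise (0 = deterministic).
#' @param wood_density Wood density (g/cm^3).
#' @param prune_fraction Subtree-removal probability in [0, 1]
#'   (1 removes every eligible subtree).
#' @param tip_trim Terminal-length shortening fraction in \[0, 1).
#' @param prune_min_depth Minimum depth eligible for subtree removal.
#' @param seed Integer seed; all randomness (noise then pruning) flows from
#'   one generator in documented order, so fixtures are bit-reproducible.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_children = 2, levels = 6, root_diameter = 10,
                         root_length = 100, beta = 2^(-1 / 2),
                         gamma = 2^(-1 / 3), noise_sigma = 0,
                         wood_density = 0.6, prune_fraction = 0,
                         tip_trim = 0, prune_min_depth = 1, seed = NULL) {
  if (!(beta > 0 && beta < 1) || !(gamma > 0 && gamma < 1))
    stop("configuration error: beta and gamma must lie in (0, 1)",
         call. = FALSE)
  stopifnot(n_children >= 1, levels >= 2, root_diameter > 0, root_length > 0,
            noise_sigma >= 0, wood_density > 0,
            prune_fraction >= 0, prune_fraction <= 1,
            tip_trim >= 0, tip_trim < 1, prune_min_depth >= 1)
  structure(list(n_children = as.integer(n_children),
                 levels = as.integer(levels),
                 root_diameter = root_diameter, root_length = root_length,
                 beta = beta, gamma = gamma, noise_sigma = noise_sigma,
                 wood_density = wood_density,
                 prune_fraction = prune_fraction, tip_trim = tip_trim,
                 prune_min_depth = as.integer(prune_min_depth), seed = seed),
            class = "synth_config")
}

#' Generate a self-similar branching tree with known allometric exponents
#'
#' Builds the deterministic geometry (level-\eqn{i} diameter
#' \eqn{D_0\beta^i}, length \eqn{L_0\gamma^i}), applies measurement noise
#' and mass assignment, then the pruning operators, per the
#' [synth_config()]. Branch ids encode the lineage (`R`, `R.1`, `R.1.2`,
#' ...), the root's parent id is `NA`.
#'
#' The random stream order is fixed: diameter noise for all branches in
#' breadth-first id order, then length noise, then mass noise, then
#' subtree-removal draws, so identical configs and seeds reproduce
#' identical record sets.
#'
#' @param config A [synth_config()].
#' @param tree_id Tree identifier for the generated architecture.
#' @return List of class `synth_tree`: `tree` (a [tree_architecture()]),
#'   `a_true` (the closed-form segment-level length~diameter exponent
#'   \eqn{\ln\gamma/\ln\beta}), `removed_mass_fraction` (from pruning) and
#'   `config`.
#' @examples
#' g <- generate_tree(synth_config(n_children = 2, levels = 3))
#' nrow(g$tree$records)  # 7
#' g$a_true              # 2/3 for the default WBE-like ratios
#' @export
generate_tree <- function(config = synth_config(), tree_id = "synth") {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    ids <- "R"; parents <- NA_character_; depths <- 0L
    frontier <- "R"
    for (lvl in seq_len(config$levels - 1L)) {
      kids <- unlist(lapply(frontier, function(p)
        paste0(p, ".", seq_len(config$n_children))))
      ids <- c(ids, kids)
      parents <- c(parents, rep(frontier, each = config$n_children))
      depths <- c(depths, rep(lvl, length(kids)))
      frontier <- kids
    }
    n <- length(ids)
    d <- config$root_diameter * config$beta^depths
    l <- config$root_length * config$gamma^depths
    noise <- function() if (config$noise_sigma > 0)
      exp(stats::rnorm(n, 0, config$noise_sigma)) else rep(1, n)
    d <- d * noise()
    l <- l * noise()
    m <- config$wood_density * pi * (d / 2)^2 * l * noise()

    rec <- data.frame(branch_id = ids, parent_id = parents, diameter = d,
                      length = l, mass = m, is_twig = FALSE,
                      stringsAsFactors = FALSE)
    tree <- tree_architecture(rec, tree_id = tree_id)
    pruned <- prune_tree(tree, prune_fraction = config$prune_fraction,
                         tip_trim = config$tip_trim,
                         prune_min_depth = config$prune_min_depth,
                         seed = NULL)
    structure(list(tree = pruned$tree,
                   a_true = log(config$gamma) / log(config$beta),
                   removed_mass_fraction = pruned$removed_mass_fraction,
                   config = config),
              class = "synth_tree")
  })
}

#' Generate a tree with the WBE branching geometry
#'
#' Convenience preset for [generate_tree()] with the area-preserving,
#' elastically similar ratios \eqn{\beta = n^{-1/2}},
#' \eqn{\gamma = n^{-1/3}}. In this geometry segment mass scales exactly as
#' \eqn{M \propto D^2 L \propto D^{8/3}} when noiseless, and segment length
#' as \eqn{L \propto D^{2/3}}.
#'
#' @param n_children Daughters per branch.
#' @param levels Depth levels.
#' @param root_diameter,root_length Root dimensions (cm).
#' @param wood_density Wood density (g/cm^3).
#' @param noise_sigma Lognormal measurement noise sd.
#' @param seed Integer seed.
#' @param tree_id Tree identifier.
#' @return A `synth_tree` (see [generate_tree()]).
#' @export
wbe_geometry <- function(n_children = 2, levels = 8, root_diameter = 10,
                         root_length = 100, wood_density = 0.6,
                         noise_sigma = 0, seed = NULL, tree_id = "wbe") {
  generate_tree(synth_config(n_children = n_children, levels = levels,
                             root_diameter = root_diameter,
                             root_length = root_length,
                             beta = n_children^(-1 / 2),
                             gamma = n_children^(-1 / 3),
                             noise_sigma = noise_sigma,
                             wood_density = wood_density, seed = seed),
                tree_id = tree_id)
}

#' Apply pruning perturbations to a tree architecture
#'
#' Two idealized operators mirror the two classes of orchard pruning cuts:
#' branch-removing cuts delete whole subtrees (each non-root branch at
#' depth >= `prune_min_depth` independently with probability
#' `prune_fraction`; removing a branch removes all its descendants), and
#' length-reducing cuts shorten every terminal segment's length — and
#' proportionally its mass, surface area and volume — by the factor
#' `(1 - tip_trim)`. The root is never removed.
#'
#' @param tree A [tree_architecture()].
#' @param prune_fraction Subtree-removal probability in [0, 1]
#'   (1 removes every eligible subtree).
#' @param tip_trim Terminal shortening fraction in \[0, 1).
#' @param prune_min_depth Minimum eligible depth for removal.
#' @param seed Integer seed (`NULL` = use the current RNG stream).
#' @return List: `tree` (pruned architecture) and `removed_mass_fraction`,
#'   the fraction of the original total mass removed by both operators
#'   (`NA` if any mass is missing).
#' @export
prune_tree <- function(tree, prune_fraction = 0, tip_trim = 0,
                       prune_min_depth = 1, seed = NULL) {
  stopifnot(inherits(tree, "tree_architecture"),
            prune_fraction >= 0, prune_fraction <= 1,
            tip_trim >= 0, tip_trim < 1)
  with_seed(seed, {
    rec <- tree$records
    total_mass <- sum(rec$mass)
    removed <- character(0)
    if (prune_fraction > 0) {
      # breadth-first order; descendants of an already-removed branch are
      # deleted with it and draw no random number
      ord <- rec$branch_id[order(tree$depth[rec$branch_id],
                                 rec$branch_id)]
      gone <- stats::setNames(rep(FALSE, nrow(rec)), rec$branch_id)
      for (b in ord) {
        if (b == tree$root) next
        p <- rec$parent_id[match(b, rec$branch_id)]
        if (gone[[p]]) { gone[[b]] <- TRUE; next }
        if (tree$depth[[b]] >= prune_min_depth &&
            stats::runif(1) < prune_fraction)
          gone[[b]] <- TRUE
      }
      removed <- names(gone)[gone]
      rec <- rec[!rec$branch_id %in% removed, , drop = FALSE]
    }
    removed_mass <- sum(tree$records$mass[tree$records$branch_id %in%
                                            removed])
    out <- tree_architecture(rec, tree_id = tree$tree_id)
    if (tip_trim > 0) {
      tips <- terminal_branches(out, include_twigs = TRUE)
      i <- match(tips, out$records$branch_id)
      removed_mass <- removed_mass + sum(out$records$mass[i]) * tip_trim
      out$records$length[i] <- out$records$length[i] * (1 - tip_trim)
      out$records$mass[i] <- out$records$mass[i] * (1 - tip_trim)
      out <- tree_architecture(out$records, tree_id = tree$tree_id)
    }
    list(tree = out,
         removed_mass_fraction = if (is.na(total_mass) || total_mass == 0)
           NA_real_ else removed_mass / total_mass)
  })
}

#' Simulate bivariate allometric data with a known exponent
#'
#' Draws `n` points from the errors-in-both-variables model under which the
#' SMA slope estimator is consistent: a latent log10 size
#' \eqn{t \sim N(0, spread^2)}, observed \eqn{\log_{10} x = t + \delta} with
#' \eqn{\delta \sim N(0, \sigma^2)} and
#' \eqn{\log_{10} y = b + a t + \epsilon} with
#' \eqn{\epsilon \sim N(0, (a\sigma)^2)} — the error-variance ratio equals
#' \eqn{a^2}, so \eqn{s_v/s_u = |a|} in expectation. Noise is therefore
#' multiplicative lognormal on the original scale.
#'
#' @param n Number of points.
#' @param slope True exponent a.
#' @param intercept True log10 multiplier b.
#' @param sigma Log10-scale noise sd on x (y receives `|slope| * sigma`).
#' @param spread Log10-scale sd of the latent size variable.
#' @param seed Integer seed (`NULL` = current stream).
#' @return Data frame with positive columns `x` and `y`.
#' @export
simulate_allometry_pairs <- function(n = 50, slope = 2, intercept = 0,
                                     sigma = 0.05, spread = 0.5,
                                     seed = NULL) {
  stopifnot(n >= 3, sigma >= 0, spread > 0, slope != 0)
  with_seed(seed, {
    t <- stats::rnorm(n, 0, spread)
    u <- t + stats::rnorm(n, 0, sigma)
    v <- intercept + slope * t + stats::rnorm(n, 0, abs(slope) * sigma)
    data.frame(x = 10^u, y = 10^v)
  })
}
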