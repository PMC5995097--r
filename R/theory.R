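# Minimal exact-rational helpers. Predictions are carried as integer
# numerator/denominator pairs and only converted to double at comparison
# time, so the emitted prediction table is exact.
gcd2 <- function(a, b) if (b == 0) abs(a) else gcd2(b, a %% b)

rational <- function(num, den = 1L) {
  stopifnot(den != 0)
  if (den < 0) { num <- -num; den <- -den }
  g <- gcd2(num, den)
  if (g == 0) g <- 1
  c(num = as.integer(num / g), den = as.integer(den / g))
}

rat_add <- function(a, b) rational(a["num"] * b["den"] + b["num"] * a["den"],
                                   a["den"] * b["den"])
rat_div <- function(a, b) rational(a["num"] * b["den"], a["den"] * b["num"])
rat_num <- function(a) unname(a["num"] / a["den"])
rat_str <- function(a) if (a["den"] == 1L) as.character(a["num"]) else
  paste0(a["num"], "/", a["den"])

#' Flow Similarity predicted exponent for a variable pair
#'
#' The Flow Similarity (FS) model parameterizes branch allometry by the
#' length--diameter exponent \eqn{\alpha_F}: hydraulic (area-preserving,
#' "flow similarity") branching corresponds to \eqn{\alpha_F = 2} and the
#' biomechanical buckling limit ("elastic similarity") to
#' \eqn{\alpha_F = 2/3}. All six pairwise exponents among length, diameter,
#' surface area and volume follow from \eqn{\alpha_F} via the cylinder
#' geometry:
#' \deqn{L \propto D^{\alpha_F},\; SA \propto V^{(\alpha_F+1)/(\alpha_F+2)},\;
#'   D \propto V^{1/(\alpha_F+2)},\; L \propto V^{\alpha_F/(\alpha_F+2)},\;
#'   D \propto SA^{1/(\alpha_F+1)},\; L \propto SA^{\alpha_F/(\alpha_F+1)}.}
#'
#' @param pair A `"y~x"` pair over `length`, `diameter`, `surface_area`,
#'   `volume`.
#' @param alpha_f The FS length--diameter exponent, given as `c(num, den)`
#'   integers (exact) or a single positive numeric.
#' @return The predicted exponent. Exact `c(num, den)` rational when
#'   `alpha_f` was given as one (attribute-free integer vector), numeric
#'   otherwise.
#' @examples
#' fs_exponent("surface_area~volume", 2)    # 0.75
#' fs_exponent("diameter~volume", c(2, 3))  # exact 3/8
#' @export
fs_exponent <- function(pair, alpha_f) {
  exact <- length(alpha_f) == 2L
  a <- if (exact) rational(alpha_f[1], alpha_f[2]) else {
    stopifnot(is.numeric(alpha_f), alpha_f > 0)
    NULL
  }
  if (exact && rat_num(a) <= 0)
    stop("alpha_f must be positive", call. = FALSE)
  one <- rational(1L); two <- rational(2L)
  expr <- switch(pair,
    "length~diameter"       = if (exact) a else alpha_f,
    "surface_area~volume"   = if (exact) rat_div(rat_add(a, one),
                                                 rat_add(a, two))
                              else (alpha_f + 1) / (alpha_f + 2),
    "diameter~volume"       = if (exact) rat_div(one, rat_add(a, two))
                              else 1 / (alpha_f + 2),
    "length~volume"         = if (exact) rat_div(a, rat_add(a, two))
                              else alpha_f / (alpha_f + 2),
    "diameter~surface_area" = if (exact) rat_div(one, rat_add(a, one))
                              else 1 / (alpha_f + 1),
    "length~surface_area"   = if (exact) rat_div(a, rat_add(a, one))
                              else alpha_f / (alpha_f + 1),
    stop("configuration error: no FS prediction for pair '", pair, "'",
         call. = FALSE))
  expr
}

fs_pairs <- function() c("length~diameter", "surface_area~volume",
                         "diameter~volume", "length~volume",
                         "diameter~surface_area", "length~surface_area")

#' Flow Similarity predicted exponent range for a pair
#'
#' Evaluates [fs_exponent()] at the flow endpoint (\eqn{\alpha_F = 2}) and
#' the elastic endpoint (\eqn{\alpha_F = 2/3}); the prediction is the closed
#' interval between them.
#'
#' @inheritParams fs_exponent
#' @return An `exponent_prediction`: list with `model = "FS"`, the pair,
#'   exact rationals `flow` and `elastic` (`c(num, den)`), their numeric
#'   values `flow_value`/`elastic_value`, and ordered numeric `range`.
#' @examples
#' fs_range("length~volume")$range  # 0.25 0.50
#' @export
fs_range <- function(pair) {
  flow <- fs_exponent(pair, c(2L, 1L))
  elastic <- fs_exponent(pair, c(2L, 3L))
  structure(list(model = "FS", pair = pair,
                 flow = flow, elastic = elastic,
                 flow_value = rat_num(flow), elastic_value = rat_num(elastic),
                 range = sort(c(rat_num(flow), rat_num(elastic))),
                 point_value = NA_real_),
            class = "exponent_prediction")
}

#' West-Brown-Enquist predicted exponent for a pair
#'
#' The WBE fractal branching model fixes the interaction of hydraulic and
#' biomechanical constraints and yields point predictions. The
#' mass~diameter exponent is 8/3. The length~diameter (2/3) and
#' length~mass (1/4) values follow from the standard WBE derivation
#' (area-preserving branching with elastically similar lengths,
#' \eqn{L \propto D^{2/3}}, \eqn{M \propto D^2 L \propto D^{8/3}}); they are
#' flagged `reconstructed` in the prediction table.
#'
#' @param pair One of `"mass~diameter"`, `"length~diameter"`,
#'   `"length~mass"`.
#' @return An `exponent_prediction` with `model = "WBE"`, exact rational
#'   `point` and numeric `point_value`, and `reconstructed` flag.
#' @examples
#' wbe_prediction("mass~diameter")$point_value  # 8/3
#' @export
wbe_prediction <- function(pair) {
  entry <- switch(pair,
    "mass~diameter"   = list(rational(8L, 3L), FALSE),
    "length~diameter" = list(rational(2L, 3L), TRUE),
    "length~mass"     = list(rational(1L, 4L), TRUE),
    stop("configuration error: no WBE prediction for pair '", pair, "'",
         call. = FALSE))
  structure(list(model = "WBE", pair = pair, point = entry[[1]],
                 point_value = rat_num(entry[[1]]),
                 reconstructed = entry[[2]],
                 range = rep(rat_num(entry[[1]]), 2)),
            class = "exponent_prediction")
}

#' @export
print.exponent_prediction <- function(x, ...) {
  if (x$model == "FS")
    cat(sprintf("FS prediction %s: flow %s, elastic %s (range [%g, %g])\n",
                x$pair, rat_str(x$flow), rat_str(x$elastic),
                x$range[1], x$range[2]))
  else
    cat(sprintf("WBE prediction %s: %s%s\n", x$pair, rat_str(x$point),
                if (x$reconstructed) " (reconstructed)" else ""))
  invisible(x)
}

#' Full table of theoretical exponent predictions
#'
#' One row per (model, pair): the six FS pairs with flow and elastic
#' endpoints as exact fractions, and the three WBE point predictions.
#'
#' @return Data frame with columns `model`, `y_variable`, `x_variable`,
#'   `flow`, `elastic`, `point` (fraction strings; `NA` where not
#'   applicable), numeric `range_low`, `range_high`, and `reconstructed`.
#' @export
prediction_table <- function() {
  fs <- do.call(rbind, lapply(fs_pairs(), function(p) {
    pr <- fs_range(p); yx <- parse_pair(p)
    data.frame(model = "FS", y_variable = yx[1], x_variable = yx[2],
               flow = rat_str(pr$flow), elastic = rat_str(pr$elastic),
               point = NA_character_, range_low = pr$range[1],
               range_high = pr$range[2], reconstructed = FALSE,
               stringsAsFactors = FALSE)
  }))
  wbe <- do.call(rbind, lapply(c("mass~diameter", "length~diameter",
                                 "length~mass"), function(p) {
    pr <- wbe_prediction(p); yx <- parse_pair(p)
    data.frame(model = "WBE", y_variable = yx[1], x_variable = yx[2],
               flow = NA_character_, elastic = NA_character_,
               point = rat_str(pr$point), range_low = pr$point_value,
               range_high = pr$point_value,
               reconstructed = pr$reconstructed, stringsAsFactors = FALSE)
  }))
  rbind(fs, wbe)
}

#' Classify an empirical exponent against a theoretical prediction
#'
#' For an FS range prediction the fit's confidence interval is compared to
#' the closed predicted interval: `within_range` when the CI lies entirely
#' inside, `overlaps_range` when they intersect without containment,
#' `outside_range` otherwise. For a WBE point prediction the status is
#' `consistent_with_point` iff the point lies in the closed CI.
#'
#' @param fit An `allometry_fit` (or any list with an `a_ci` element).
#' @param prediction An `exponent_prediction`.
#' @return List with `status` and the compared intervals.
#' @export
classify_fit <- function(fit, prediction) {
  ci <- if (inherits(fit, "allometry_fit") || is.list(fit)) fit$a_ci else fit
  stopifnot(length(ci) == 2L, ci[1] <= ci[2],
            inherits(prediction, "exponent_prediction"))
  if (prediction$model == "WBE") {
    p <- prediction$point_value
    status <- if (ci[1] <= p && p <= ci[2]) "consistent_with_point"
    else "inconsistent_with_point"
  } else {
    rng <- prediction$range
    status <- if (rng[1] <= ci[1] && ci[2] <= rng[2]) "within_range"
    else if (ci[1] <= rng[2] && rng[1] <= ci[2]) "overlaps_range"
    else "outside_range"
  }
  list(status = status, ci = ci, prediction = prediction$range)
}

#' Direction of exponent shift across branch classifications
#'
#' Branch classification forms a scale from segment through path to
#' subtree; the estimated exponent for a given pair typically shifts along
#' it. The shift is `toward_flow` when the distance of the estimates to the
#' flow-similarity endpoint is non-increasing over the ordered levels with
#' at least one strict decrease, `toward_elastic` for the mirror condition,
#' and `mixed` otherwise (including constant sequences).
#'
#' @param a_hats Numeric exponent estimates ordered segment, path, subtree
#'   (>= 2 values; missing levels simply omitted).
#' @param prediction An FS `exponent_prediction` supplying the endpoints.
#' @return List with `direction` and the two distance sequences.
#' @export
tendency <- function(a_hats, prediction) {
  stopifnot(length(a_hats) >= 2L, inherits(prediction, "exponent_prediction"),
            prediction$model == "FS")
  d_flow <- abs(a_hats - prediction$flow_value)
  d_elastic <- abs(a_hats - prediction$elastic_value)
  moves_to <- function(d) all(diff(d) <= 0) && any(diff(d) < 0)
  direction <- if (moves_to(d_flow)) "toward_flow"
  else if (moves_to(d_elastic)) "toward_elastic"
  else "mixed"
  list(direction = direction, dist_flow = d_flow, dist_elastic = d_elastic)
}
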