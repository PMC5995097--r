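#' Standardized (reduced) major axis fit of a power-law allometry
#'
#' Fits \eqn{y = b x^a} in log10--log10 space by standardized major axis
#' (SMA, also called reduced major axis) regression, which treats both
#' variables as measured with error: with \eqn{u = \log_{10} x},
#' \eqn{v = \log_{10} y}, the exponent estimate is
#' \eqn{\hat a = \mathrm{sign}(r)\, s_v / s_u} and the multiplier (log10
#' intercept) \eqn{\hat b = \bar v - \hat a \bar u}.
#'
#' The 95% confidence interval for the slope is the standard analytic SMA
#' construction: with \eqn{Q = F_{1-\alpha}(1, n-2)\,(1 - r^2)/(n - 2)}, the
#' interval is \eqn{\hat a\,(\sqrt{Q + 1} \mp \sqrt{Q})}, mirrored for
#' negative slopes so that the lower bound is always below the upper. The
#' intercept interval is obtained by re-evaluating the intercept at the
#' slope bounds — an approximation that ignores the sampling variation of
#' the means, adequate at the sample sizes of branch-level data.
#'
#' Pairs with missing or non-positive values are dropped (the log transform
#' requires positivity); the number dropped is recorded in `n_dropped`.
#'
#' @param x,y Positive numeric vectors of equal length.
#' @param conf Confidence level for the intervals.
#' @param y_variable,x_variable,level,group Optional labels carried into the
#'   result for bookkeeping in fit tables.
#' @return Object of class `allometry_fit`: list with `a_hat`, `a_ci`
#'   (length-2, low < high), `b_hat`, `b_ci`, `r_squared`, `n`,
#'   `n_dropped`, `conf` and the labels.
#' @examples
#' f <- rma_fit(c(1, 10, 100), c(1, 100, 10000))  # exact square law
#' f$a_hat  # 2
#' @export
rma_fit <- function(x, y, conf = 0.95, y_variable = "y", x_variable = "x",
                    level = NA_character_, group = NA_character_) {
  stopifnot(length(x) == length(y), conf > 0, conf < 1)
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n_dropped <- sum(!ok)
  u <- log10(x[ok]); v <- log10(y[ok])
  n <- length(u)
  if (n < 3L)
    stop("insufficient data: ", n, " usable pairs (need >= 3)",
         call. = FALSE)
  su <- stats::sd(u); sv <- stats::sd(v)
  if (su == 0 || sv == 0)
    stop("degenerate data: zero variance in log-",
         if (su == 0) x_variable else y_variable, call. = FALSE)
  r <- stats::cor(u, v)
  if (r == 0)
    stop("undefined slope sign: correlation is exactly zero", call. = FALSE)
  a <- sign(r) * sv / su
  b <- mean(v) - a * mean(u)
  Q <- stats::qf(conf, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- sort(a * (sqrt(Q + 1) + c(-1, 1) * sqrt(Q)))
  b_at <- mean(v) - ci * mean(u)
  structure(list(y_variable = y_variable, x_variable = x_variable,
                 level = level, group = group,
                 n = n, n_dropped = n_dropped,
                 a_hat = a, a_ci = ci,
                 b_hat = b, b_ci = sort(b_at),
                 r_squared = r^2, conf = conf),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, digits = 3, ...) {
  cat(sprintf("SMA fit %s ~ %s%s%s: a = %.*f [%.*f, %.*f], b = %.*f, r2 = %.*f, n = %d\n",
              x$y_variable, x$x_variable,
              if (is.na(x$level)) "" else paste0(", ", x$level),
              if (is.na(x$group)) "" else paste0(", ", x$group),
              digits, x$a_hat, digits, x$a_ci[1], digits, x$a_ci[2],
              digits, x$b_hat, digits, x$r_squared, x$n))
  invisible(x)
}

#' Coerce an allometry fit (or list of fits) to a one-row-per-fit data frame
#' @param x An `allometry_fit` or list of them/failure records.
#' @param ... Unused.
#' @export
as.data.frame.allometry_fit <- function(x, ...) {
  data.frame(y_variable = x$y_variable, x_variable = x$x_variable,
             level = x$level, group = x$group, ok = TRUE, n = x$n,
             n_dropped = x$n_dropped, a_hat = x$a_hat,
             a_low = x$a_ci[1], a_high = x$a_ci[2], b_hat = x$b_hat,
             b_low = x$b_ci[1], b_high = x$b_ci[2],
             r_squared = x$r_squared, error = NA_character_,
             stringsAsFactors = FALSE)
}

fit_failure_row <- function(y_variable, x_variable, level, group, msg) {
  data.frame(y_variable = y_variable, x_variable = x_variable, level = level,
             group = group, ok = FALSE, n = NA_integer_,
             n_dropped = NA_integer_, a_hat = NA_real_, a_low = NA_real_,
             a_high = NA_real_, b_hat = NA_real_, b_low = NA_real_,
             b_high = NA_real_, r_squared = NA_real_, error = msg,
             stringsAsFactors = FALSE)
}

#' The morphological variable pairs of the branch-level analysis
#'
#' The nine y~x pairs covered by the Flow Similarity and WBE predictions:
#' length~diameter, surface_area~volume, diameter~volume, length~volume,
#' diameter~surface_area, length~surface_area, mass~diameter, length~mass,
#' mass~volume.
#' @return Character vector of `"y~x"` formulas.
#' @export
allometry_pairs <- function() {
  c("length~diameter", "surface_area~volume", "diameter~volume",
    "length~volume", "diameter~surface_area", "length~surface_area",
    "mass~diameter", "length~mass", "mass~volume")
}

parse_pair <- function(pair) {
  parts <- strsplit(pair, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("configuration error: pair must be 'y~x', got '", pair, "'",
         call. = FALSE)
  trimws(parts)
}

#' Fit an allometry for every pair, level and group combination
#'
#' Runs [rma_fit()] over a metrics table for each requested variable pair,
#' branch classification level and group. Fits that fail (too few points,
#' degenerate data) are carried as explicit failure rows with the error
#' message, never dropped silently.
#'
#' @param metrics Data frame from [metrics_table()].
#' @param pairs Character vector of `"y~x"` pairs over the metric columns
#'   (`length`, `diameter`, `mass`, `surface_area`, `volume`).
#' @param levels Classification levels to fit.
#' @param grouping `"pooled"` (all branches together), `"species"`,
#'   `"rootstock"`, or `"individual"` (per tree id).
#' @param conf Confidence level.
#' @return Data frame with one row per (pair, level, group); columns as in
#'   [as.data.frame.allometry_fit()].
#' @export
fit_grid <- function(metrics, pairs = c("length~diameter", "mass~diameter"),
                     levels = c("segment", "path", "subtree"),
                     grouping = c("pooled", "species", "rootstock",
                                  "individual"),
                     conf = 0.95) {
  grouping <- match.arg(grouping)
  bad_lvl <- setdiff(levels, c("segment", "path", "subtree"))
  if (length(bad_lvl) > 0L)
    stop("configuration error: unknown level(s): ",
         paste(bad_lvl, collapse = ", "), call. = FALSE)
  metric_cols <- c("length", "diameter", "mass", "surface_area", "volume")
  parsed <- lapply(pairs, parse_pair)
  bad_var <- setdiff(unlist(parsed), metric_cols)
  if (length(bad_var) > 0L)
    stop("configuration error: unknown metric(s): ",
         paste(bad_var, collapse = ", "), call. = FALSE)

  group_col <- switch(grouping, pooled = NULL, species = "species",
                      rootstock = "rootstock", individual = "tree_id")
  groups <- if (is.null(group_col)) list(all = metrics)
  else split(metrics, metrics[[group_col]])

  rows <- list()
  for (g in names(groups)) {
    for (lvl in levels) {
      sub <- groups[[g]][groups[[g]]$level == lvl, , drop = FALSE]
      for (p in seq_along(pairs)) {
        yx <- parsed[[p]]
        fit <- tryCatch(
          as.data.frame(rma_fit(sub[[yx[2]]], sub[[yx[1]]], conf = conf,
                                y_variable = yx[1], x_variable = yx[2],
                                level = lvl, group = g)),
          error = function(e) fit_failure_row(yx[1], yx[2], lvl, g,
                                              conditionMessage(e)))
        rows[[length(rows) + 1L]] <- fit
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare linear and quadratic log-log fits by AICc
#'
#' Fits ordinary least squares of \eqn{v = \log_{10} y} on \eqn{u} (linear)
#' and on \eqn{(u, u^2)} (quadratic) and compares them by the small-sample
#' corrected Akaike information criterion,
#' \eqn{AICc = AIC + 2k(k+1)/(n-k-1)}, with \eqn{k} counting the regression
#' coefficients plus the residual variance. Allometric data that is truly a
#' power law should prefer the linear model; curvature on the log-log plot
#' flags departure from a single power law.
#'
#' @param x,y Positive numeric vectors.
#' @return List with `aicc_linear`, `aicc_quadratic`, `delta`
#'   (quadratic minus linear) and `preferred` (`"linear"` on ties within
#'   1e-9).
#' @export
aicc_compare <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  u <- log10(x[ok]); v <- log10(y[ok])
  n <- length(u)
  if (n < 6L)
    stop("insufficient data: ", n, " usable pairs (need >= 6 for AICc)",
         call. = FALSE)
  aicc <- function(fit) {
    ll <- stats::logLik(fit)
    k <- attr(ll, "df")                      # coefficients + sigma^2
    -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  }
  a1 <- aicc(stats::lm(v ~ u))
  a2 <- aicc(stats::lm(v ~ u + I(u^2)))
  list(aicc_linear = a1, aicc_quadratic = a2, delta = a2 - a1,
       preferred = if (a2 < a1 - 1e-9) "quadratic" else "linear")
}

#' Do two confidence intervals overlap?
#'
#' Closed-interval intersection, the criterion used to call two estimated
#' exponents statistically indistinguishable at the 95% level.
#'
#' @param ci1,ci2 Length-2 numeric vectors (low, high), or `allometry_fit`
#'   objects (their slope CIs are used).
#' @return `TRUE` iff the closed intervals intersect (shared endpoints
#'   count).
#' @export
ci_overlap <- function(ci1, ci2) {
  if (inherits(ci1, "allometry_fit")) ci1 <- ci1$a_ci
  if (inherits(ci2, "allometry_fit")) ci2 <- ci2$a_ci
  stopifnot(length(ci1) == 2L, length(ci2) == 2L,
            ci1[1] <= ci1[2], ci2[1] <= ci2[2])
  ci1[1] <= ci2[2] && ci2[1] <= ci1[2]
}
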