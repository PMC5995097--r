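test_that("exact power laws are recovered exactly", {
  f1 <- rma_fit(c(1, 10, 100), c(1, 10, 100))
  expect_equal(f1$a_hat, 1)
  expect_equal(f1$b_hat, 0)
  expect_equal(f1$r_squared, 1)
  f2 <- rma_fit(c(1, 10, 100), c(1, 100, 10000))
  expect_equal(f2$a_hat, 2)
  expect_equal(f2$b_hat, 0, tolerance = 1e-12)
  expect_equal(f2$r_squared, 1)
})

test_that("slope equals the sd-ratio oracle and CIs follow the SMA formula", {
  set.seed(90)
  u <- runif(20, 0, 2)
  v <- 2.5 * u + rnorm(20, 0, 0.1)
  f <- rma_fit(10^u, 10^v)
  r <- cor(u, v)
  expect_equal(f$a_hat, sign(r) * sd(v) / sd(u), tolerance = 1e-12)
  Q <- qf(0.95, 1, 18) * (1 - r^2) / 18
  expect_equal(f$a_ci,
               sort(f$a_hat * (sqrt(Q + 1) + c(-1, 1) * sqrt(Q))),
               tolerance = 1e-12)
  expect_true(f$a_ci[1] <= f$a_hat && f$a_hat <= f$a_ci[2])
  expect_true(f$b_ci[1] <= f$b_hat && f$b_hat <= f$b_ci[2])
})

test_that("negative allometries get the mirrored CI and correct sign", {
  set.seed(91)
  u <- runif(30, 0, 2)
  v <- 3 - 1.15 * u + rnorm(30, 0, 0.15)
  f <- rma_fit(10^u, 10^v)
  expect_lt(f$a_hat, 0)
  expect_equal(sign(f$a_hat), sign(cor(u, v)))
  expect_true(f$a_ci[1] < f$a_hat && f$a_hat < f$a_ci[2])
})

test_that("SMA symmetry, scale equivariance and OLS bracketing hold", {
  for (seed in 101:105) {
    set.seed(seed)
    n <- sample(10:60, 1)
    u <- rnorm(n, 0, 0.6)
    v <- 1 + runif(1, 0.5, 3) * u + rnorm(n, 0, 0.2)
    x <- 10^u; y <- 10^v
    f_yx <- rma_fit(x, y); f_xy <- rma_fit(y, x)
    expect_equal(f_yx$a_hat * f_xy$a_hat, 1, tolerance = 1e-9)
    f_scaled <- rma_fit(x, 100 * y)
    expect_equal(f_scaled$a_hat, f_yx$a_hat, tolerance = 1e-12)
    expect_equal(f_scaled$b_hat, f_yx$b_hat + 2, tolerance = 1e-12)
    ols <- unname(coef(lm(v ~ u))[2])
    expect_gte(abs(f_yx$a_hat) + 1e-12, abs(ols))
  }
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(rma_fit(c(1, 2), c(1, 2)), "insufficient data")
  expect_error(rma_fit(c(1, 1, 1), c(1, 2, 3)), "degenerate data")
  expect_error(rma_fit(c(1, 2, 3), c(5, 5, 5)), "degenerate data")
  # non-positive pairs are dropped before fitting
  f <- rma_fit(c(-1, 0, 1, 10, 100, NA), c(5, 5, 1, 10, 100, 7))
  expect_equal(f$n, 3)
  expect_equal(f$n_dropped, 3)
  expect_equal(f$a_hat, 1)
})

test_that("fit_grid covers the pair x level x group grid with failures kept", {
  g1 <- generate_tree(synth_config(levels = 5, noise_sigma = 0.1, seed = 1),
                      tree_id = "tr1")
  g2 <- generate_tree(synth_config(levels = 5, noise_sigma = 0.1, seed = 2),
                      tree_id = "tr2")
  m <- metrics_table(list(g1$tree, g2$tree))
  fits <- fit_grid(m, pairs = c("length~diameter", "mass~diameter"),
                   levels = c("segment", "path", "subtree"))
  expect_equal(nrow(fits), 6L)
  fits_i <- fit_grid(m, pairs = "length~diameter", levels = "segment",
                     grouping = "individual")
  expect_equal(nrow(fits_i), 2L)
  expect_setequal(fits_i$group, c("tr1", "tr2"))
  expect_equal(fits_i$n, rep(31L, 2))
  expect_error(fit_grid(m, pairs = "mass~girth"), "configuration error")
  expect_error(fit_grid(m, pairs = "mass~diameter", levels = "trunk"),
               "configuration error")
  # a group too small to fit yields an explicit failure row
  m_small <- m[m$tree_id == "tr1" & m$branch_id %in% c("R", "R.1"), ]
  fits_f <- fit_grid(rbind(m_small, m[m$tree_id == "tr2", ]),
                     pairs = "length~diameter", levels = "segment",
                     grouping = "individual")
  expect_false(fits_f$ok[fits_f$group == "tr1"])
  expect_match(fits_f$error[fits_f$group == "tr1"], "insufficient")
  expect_true(fits_f$ok[fits_f$group == "tr2"])
})

test_that("species-level fits on a two-species synthetic dataset recover each exponent", {
  mk <- function(seed, beta, gamma, sp, id) {
    g <- generate_tree(synth_config(levels = 7, beta = beta, gamma = gamma,
                                    noise_sigma = 0.05, seed = seed),
                       tree_id = id)
    g$tree$records$species <- sp
    list(tree = g$tree, a_true = g$a_true)
  }
  s1 <- mk(11, 2^(-1 / 2), 2^(-1 / 3), "sp1", "t1")   # a_true = 2/3
  s2 <- mk(12, 2^(-1 / 2), 2^(-1 / 2), "sp2", "t2")   # a_true = 1
  m <- metrics_table(list(s1$tree, s2$tree), levels = "segment")
  fits <- fit_grid(m, pairs = "length~diameter", levels = "segment",
                   grouping = "species")
  f1 <- fits[fits$group == "sp1", ]; f2 <- fits[fits$group == "sp2", ]
  expect_true(f1$a_low <= 2 / 3 && 2 / 3 <= f1$a_high)
  expect_true(f2$a_low <= 1 && 1 <= f2$a_high)
})

test_that("AICc comparison prefers the generating model", {
  u <- seq(0, 2, length.out = 30)
  expect_equal(aicc_compare(10^u, 10^(2 * u))$preferred, "linear")
  set.seed(7)
  v_curved <- u^2 + rnorm(30, 0, 0.05)
  res <- aicc_compare(10^u, 10^v_curved)
  expect_equal(res$preferred, "quadratic")
  # direct residual comparison confirms the curvature term dominates
  rss1 <- sum(resid(lm(v_curved ~ u))^2)
  rss2 <- sum(resid(lm(v_curved ~ u + I(u^2)))^2)
  expect_lt(rss2, rss1 / 10)
  expect_error(aicc_compare(10^u[1:5], 10^u[1:5]), "insufficient data")
})

test_that("AICc equals AIC plus the closed-form small-sample correction", {
  set.seed(8)
  u <- rnorm(10); v <- 1 + 2 * u + rnorm(10, 0, 0.1)
  res <- aicc_compare(10^u, 10^v)
  fit <- lm(v ~ u)
  n <- 10; k <- 3  # slope, intercept, residual variance
  ll <- as.numeric(logLik(fit))
  expect_equal(res$aicc_linear, -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1),
               tolerance = 1e-9)
})

test_that("aicc prefers linear for truly linear data in most replicates", {
  set.seed(303)
  n_rep <- 200
  pref <- vapply(seq_len(n_rep), function(i) {
    u <- rnorm(20, 0, 0.7)
    v <- 0.5 + 2 * u + rnorm(20, 0, 0.05)
    aicc_compare(10^u, 10^v)$preferred
  }, "")
  expect_gte(mean(pref == "linear"), 0.9)
})

test_that("confidence interval overlap uses closed intervals", {
  expect_true(ci_overlap(c(2.43, 2.55), c(2.49, 2.66)))
  expect_true(ci_overlap(c(1, 2), c(2, 3)))
  expect_false(ci_overlap(c(1, 2), c(2.01, 3)))
  f1 <- rma_fit(c(1, 10, 100), c(1, 10, 100))
  expect_true(ci_overlap(f1, f1))
})
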