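test_that("segment geometry follows the cylinder formulas", {
  s <- segment_geometry(4, 10)
  expect_equal(s$surface_area, 125.6637, tolerance = 1e-6)
  expect_equal(s$volume, 125.6637, tolerance = 1e-6)  # D = 4: SA == V
  expect_equal(segment_geometry(1, 0)$surface_area, 0)
  expect_equal(segment_geometry(1, 0)$volume, 0)
  s2 <- segment_geometry(2, 5)
  expect_equal(s2$surface_area, 10 * pi)
  expect_equal(s2$volume, 5 * pi)
})

test_that("path follows the longest continuous distal chain", {
  tr <- tree_architecture(make_records(c("r", "a", "b"), c(NA, "r", "r"),
                                       c(5, 3, 2), c(10, 8, 5),
                                       mass = c(100, 40, 10)))
  m <- branch_metrics(tr)
  root_path <- m[m$level == "path" & m$branch_id == "r", ]
  expect_equal(root_path$length, 18)
  expect_equal(root_path$mass, 140)
  # terminal branch: path == segment
  a_path <- m[m$level == "path" & m$branch_id == "a", ]
  a_seg <- m[m$level == "segment" & m$branch_id == "a", ]
  expect_equal(a_path$length, a_seg$length)
  expect_equal(a_path$mass, a_seg$mass)

  # chain r -> a -> a1 (10 + 8 + 4) beats r -> b (10 + 5)
  tr2 <- tree_architecture(make_records(
    c("r", "a", "a1", "b"), c(NA, "r", "a", "r"),
    c(5, 3, 1, 2), c(10, 8, 4, 5)))
  m2 <- branch_metrics(tr2)
  expect_equal(m2[m2$level == "path" & m2$branch_id == "r", "length"], 22)
})

test_that("subtree sums the whole distal set", {
  tr <- tree_architecture(make_records(c("r", "a", "b"), c(NA, "r", "r"),
                                       c(5, 3, 2), c(10, 8, 5),
                                       mass = c(100, 40, 10)))
  m <- branch_metrics(tr)
  rs <- m[m$level == "subtree" & m$branch_id == "r", ]
  expect_equal(rs$length, 23)
  expect_equal(rs$mass, 150)
  b <- m[m$branch_id == "b", ]
  expect_equal(b[b$level == "subtree", "mass"], b[b$level == "segment", "mass"])
})

test_that("aggregates on random trees match brute-force oracles", {
  for (seed in c(31, 32)) {
    rec <- random_records(50, seed = seed)
    tr <- tree_architecture(rec)
    m <- branch_metrics(tr)
    for (b in sample(rec$branch_id, 12)) {
      sub_ids <- c(b, oracle_descendants(rec, b))
      expected <- seg_row(rec, sub_ids)
      got <- m[m$level == "subtree" & m$branch_id == b, ]
      for (q in names(expected))
        expect_equal(got[[q]], expected[[q]], tolerance = 1e-12,
                     info = paste("subtree", q, b, seed))
      chain <- oracle_longest_chain(rec, b)
      expected_p <- seg_row(rec, chain)
      got_p <- m[m$level == "path" & m$branch_id == b, ]
      for (q in names(expected_p))
        expect_equal(got_p[[q]], expected_p[[q]], tolerance = 1e-12,
                     info = paste("path", q, b, seed))
    }
  }
})

test_that("subtree >= path >= segment for every branch and quantity", {
  rec <- random_records(80, seed = 41)
  m <- branch_metrics(tree_architecture(rec))
  wide <- reshape(m[, c("branch_id", "level", "length", "mass",
                        "surface_area", "volume")],
                  idvar = "branch_id", timevar = "level", direction = "wide")
  for (q in c("length", "mass", "surface_area", "volume")) {
    expect_true(all(wide[[paste0(q, ".subtree")]] >=
                      wide[[paste0(q, ".path")]] - 1e-9))
    expect_true(all(wide[[paste0(q, ".path")]] >=
                      wide[[paste0(q, ".segment")]] - 1e-9))
  }
  # equality exactly at terminal branches
  tips <- terminal_branches(tree_architecture(rec))
  tw <- wide[wide$branch_id %in% tips, ]
  expect_equal(tw$length.subtree, tw$length.segment)
  expect_equal(tw$mass.path, tw$mass.segment)
})

test_that("root subtree mass conserves the total segment mass", {
  rec <- random_records(60, seed = 51)
  tr <- tree_architecture(rec)
  m <- branch_metrics(tr)
  expect_equal(m[m$level == "subtree" & m$branch_id == tr$root, "mass"],
               sum(rec$mass), tolerance = 1e-9)
})

test_that("missing mass propagates into aggregates instead of zero-filling", {
  rec <- make_records(c("r", "a", "b"), c(NA, "r", "r"),
                      c(5, 3, 2), c(10, 8, 5), mass = c(100, NA, 10))
  m <- branch_metrics(tree_architecture(rec))
  expect_true(is.na(m[m$level == "subtree" & m$branch_id == "r", "mass"]))
  expect_equal(m[m$level == "subtree" & m$branch_id == "b", "mass"], 10)
  expect_false(anyNA(m$length))
})

test_that("path tie-breaking is deterministic: larger diameter, then id", {
  # both children have path length 8; the wider child carries more mass
  rec <- make_records(c("r", "thin", "wide"), c(NA, "r", "r"),
                      c(5, 1, 4), c(10, 8, 8), mass = c(100, 5, 50))
  m <- branch_metrics(tree_architecture(rec))
  expect_equal(m[m$level == "path" & m$branch_id == "r", "mass"], 150)
  # equal diameters too: lexicographically smallest id wins
  rec2 <- make_records(c("r", "aa", "ab"), c(NA, "r", "r"),
                       c(5, 2, 2), c(10, 8, 8), mass = c(100, 7, 9))
  m2 <- branch_metrics(tree_architecture(rec2))
  expect_equal(m2[m2$level == "path" & m2$branch_id == "r", "mass"], 107)
})

test_that("recomputation is deterministic and twigs are excluded by default", {
  rec <- random_records(40, seed = 61)
  rec$is_twig[rec$diameter < 2 & !is.na(rec$parent_id)] <- TRUE
  tr <- tree_architecture(rec)
  m1 <- branch_metrics(tr); m2 <- branch_metrics(tr)
  expect_identical(m1, m2)
  expect_false(any(m1$branch_id %in% rec$branch_id[rec$is_twig]))
  m_in <- branch_metrics(tr, include_twigs = TRUE)
  expect_equal(nrow(m_in), 3 * nrow(rec))
  root_sub <- function(m) m[m$level == "subtree" & m$branch_id == tr$root,
                            "mass"]
  expect_true(root_sub(m_in) >= root_sub(m1))
})
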