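# Fixture builders and brute-force oracles, written directly against the
# raw records table so they stay independent of the package's traversal
# code.

make_records <- function(branch_id, parent_id, diameter, length,
                         mass = NA_real_, is_twig = FALSE, ...) {
  data.frame(branch_id = branch_id, parent_id = parent_id,
             diameter = diameter, length = length, mass = mass,
             is_twig = is_twig, ..., stringsAsFactors = FALSE)
}

# random topology: each branch after the first attaches to a uniformly
# chosen earlier branch
random_records <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("b%03d", seq_len(n))
  parents <- c(NA_character_,
               vapply(2:n, function(i) ids[sample.int(i - 1L, 1L)], ""))
  make_records(ids, parents,
               diameter = stats::runif(n, 0.5, 12),
               length = stats::runif(n, 1, 80),
               mass = stats::runif(n, 1, 500))
}

# exhaustive reachability: descendants of b by repeated frontier expansion
oracle_descendants <- function(records, b) {
  out <- character(0); frontier <- b
  repeat {
    kids <- records$branch_id[!is.na(records$parent_id) &
                                records$parent_id %in% frontier]
    kids <- setdiff(kids, out)
    if (length(kids) == 0L) break
    out <- c(out, kids); frontier <- kids
  }
  out
}

# enumerate every chain from b to a tip; return the rows of the chain with
# maximal cumulative length
oracle_longest_chain <- function(records, b) {
  kids_of <- function(x) records$branch_id[!is.na(records$parent_id) &
                                             records$parent_id == x]
  chains <- function(x) {
    kids <- kids_of(x)
    if (length(kids) == 0L) return(list(x))
    unlist(lapply(kids, function(k)
      lapply(chains(k), function(ch) c(x, ch))), recursive = FALSE)
  }
  all_chains <- chains(b)
  lens <- vapply(all_chains, function(ch)
    sum(records$length[match(ch, records$branch_id)]), 0)
  all_chains[[which.max(lens)]]
}

seg_row <- function(records, ids) {
  i <- match(ids, records$branch_id)
  d <- records$diameter[i]; l <- records$length[i]
  list(length = sum(l), mass = sum(records$mass[i]),
       surface_area = sum(pi * d * l), volume = sum(pi * (d / 2)^2 * l))
}

write_branch_csv <- function(records, tree_id = "t1",
                             path = tempfile(fileext = ".csv")) {
  df <- cbind(tree_id = tree_id, records)
  write.csv(df, path, row.names = FALSE, na = "")
  path
}
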