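test_that("binary trees yield n-3 nontrivial splits", {
  set.seed(97)
  t4 <- ape::unroot(ape::rtree(4))
  expect_equal(cogevo:::n_splits(tree_to_splits(t4)), 1L)
  for (n in c(5, 8, 12)) {
    tr <- ape::unroot(ape::rtree(n))
    expect_equal(cogevo:::n_splits(tree_to_splits(tr)), n - 3L)
  }
  expect_error(tree_to_splits(ape::rtree(3)), "4 leaves")
})

test_that("tree splits equal the edge-removal bipartition oracle", {
  set.seed(101)
  tr <- ape::unroot(ape::rtree(12))
  ss <- tree_to_splits(tr)
  # oracle: clades from ape::prop.part on the rooted representation
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  oracle <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    other <- setdiff(labs, side)
    if (length(side) >= 2L && length(other) >= 2L)
      oracle <- c(oracle, cogevo:::split_key(
        cogevo:::canonical_split(side, other)))
  }
  expect_setequal(split_keys(ss), unique(oracle))
})

test_that("duplicate splits merge with summed weight and support", {
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:1,D:1):0.5);")
  ss <- collect_splits(list(tr, tr, tr))
  expect_equal(cogevo:::n_splits(ss), 1L)
  expect_equal(ss$splits[[1L]]$support, 3L)
  expect_equal(ss$splits[[1L]]$weight, 3 * 1.0)  # 0.5 + 0.5 per tree edge
  expect_equal(ss$n_trees, 3L)
})

test_that("z-closure is the identity on full split systems", {
  set.seed(103)
  tr <- ape::unroot(ape::rtree(7))
  ss <- tree_to_splits(tr)
  zc <- z_closure(ss)
  expect_identical(split_keys(zc), split_keys(ss))
})

test_that("z-closure extends partial splits and is idempotent", {
  ss <- split_set(as.character(1:5), list(
    cogevo:::canonical_split(c("1", "2"), c("3", "4")),
    cogevo:::canonical_split(c("1", "2", "5"), c("3"))))
  zc <- z_closure(ss)
  # every input split has an extension in the closure
  for (s in ss$splits) {
    ok <- any(vapply(zc$splits, function(z)
      (all(s$a %in% z$a) && all(s$b %in% z$b)) ||
        (all(s$a %in% z$b) && all(s$b %in% z$a)), logical(1L)))
    expect_true(ok, label = paste("extension of", cogevo:::split_key(s)))
  }
  expect_identical(split_keys(z_closure(zc)), split_keys(zc))
  # the fixpoint is among those reachable by exhaustive rule application
  fps <- closure_fixpoints(ss)
  expect_true(any(vapply(fps, identical, logical(1L), y = split_keys(zc))))
})

test_that("z-closure matches exhaustive enumeration on small systems", {
  set.seed(107)
  for (r in 1:5) {
    taxa <- as.character(1:5)
    make_partial <- function() {
      pick <- sample(taxa, sample(3:5, 1L))
      cut <- sample(seq_len(length(pick) - 1L), 1L)
      cogevo:::canonical_split(pick[seq_len(cut)], pick[-seq_len(cut)])
    }
    ss <- split_set(taxa, replicate(3, make_partial(), simplify = FALSE))
    zc <- z_closure(ss)
    fps <- closure_fixpoints(ss)
    expect_true(any(vapply(fps, identical, logical(1L),
                           y = split_keys(zc))),
                label = sprintf("replicate %d fixpoint reachable", r))
  }
})

test_that("full_splits drops unextendable partial leftovers only", {
  taxa <- as.character(1:6)
  ss <- split_set(taxa, list(
    cogevo:::canonical_split(c("1", "2", "3"), c("4", "5", "6")),
    cogevo:::canonical_split(c("1", "2"), c("4", "5"))))
  zc <- z_closure(ss)
  fs <- suppressMessages(full_splits(zc))
  expect_true(all(vapply(fs$splits, cogevo:::is_full_split, logical(1L),
                         universe = taxa)))
  expect_lte(cogevo:::n_splits(fs), cogevo:::n_splits(zc))
  # a system that is already full is untouched
  tr <- ape::unroot(ape::rtree(6))
  expect_identical(split_keys(full_splits(tree_to_splits(tr))),
                   split_keys(tree_to_splits(tr)))
})

test_that("support filtering retains splits by source-tree count", {
  set.seed(109)
  t1 <- ape::unroot(ape::rtree(6))
  t2 <- t1
  t3 <- ape::unroot(ape::rtree(6, tip.label = t1$tip.label))
  ss <- collect_splits(list(t1, t2, t3))
  expect_identical(split_keys(filter_supernetwork(ss, 1L)), split_keys(ss))
  f2 <- filter_supernetwork(ss, 2L)
  oracle <- vapply(ss$splits, function(s) s$support >= 2L, logical(1L))
  expect_setequal(split_keys(f2),
                  vapply(ss$splits[oracle], cogevo:::split_key, ""))
  # three identical trees at min_trees 3 give exactly that tree's splits
  same3 <- filter_supernetwork(collect_splits(list(t1, t1, t1)), 3L)
  expect_identical(split_keys(same3), split_keys(tree_to_splits(t1)))
})

test_that("compatibility counts agree with the quadratic oracle", {
  expect_true(compatibility_stats(
    tree_to_splits(ape::unroot(ape::rtree(9))))$is_tree_like)
  ss <- split_set(as.character(1:4), list(
    cogevo:::canonical_split(c("1", "2"), c("3", "4")),
    cogevo:::canonical_split(c("1", "3"), c("2", "4"))))
  expect_equal(compatibility_stats(ss)$n_pairs_incompatible, 1L)

  set.seed(113)
  trees <- lapply(1:4, function(i)
    ape::unroot(ape::rtree(6, tip.label = paste0("t", 1:6))))
  ss <- collect_splits(trees)
  st <- compatibility_stats(ss)
  n <- cogevo:::n_splits(ss)
  oracle <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (cogevo:::splits_incompatible(ss$splits[[i]], ss$splits[[j]]))
      oracle <- oracle + 1L
  expect_equal(st$n_pairs_incompatible, oracle)

  partial <- split_set(as.character(1:5), list(
    cogevo:::canonical_split("1", "2")))
  expect_error(compatibility_stats(partial), "full splits")
})

test_that("concordant trees add no reticulation; discordant trees only add", {
  set.seed(127)
  base <- ape::unroot(ape::rtree(8))
  conc <- filter_supernetwork(collect_splits(list(base, base, base)), 1L)
  expect_identical(split_keys(conc), split_keys(tree_to_splits(base)))
  expect_equal(compatibility_stats(conc)$n_pairs_incompatible, 0L)

  discord <- ape::unroot(ape::rtree(8, tip.label = base$tip.label))
  with_disc <- collect_splits(list(base, base, base, discord))
  n_before <- compatibility_stats(conc)$n_pairs_incompatible
  n_after <- compatibility_stats(with_disc)$n_pairs_incompatible
  expect_gte(n_after, n_before)
})

test_that("compatible split systems round-trip through a tree", {
  set.seed(131)
  tr <- ape::unroot(ape::rtree(10))
  ss <- tree_to_splits(tr)
  back <- splits_to_tree(ss)
  ss2 <- tree_to_splits(back)
  expect_identical(split_keys(ss2), split_keys(ss))
  # weights (branch lengths) survive the round trip
  w1 <- sort(vapply(ss$splits, function(s) s$weight, 0))
  w2 <- sort(vapply(ss2$splits, function(s) s$weight, 0))
  expect_equal(w1, w2, tolerance = 1e-12)
  incompat <- split_set(as.character(1:4), list(
    cogevo:::canonical_split(c("1", "2"), c("3", "4")),
    cogevo:::canonical_split(c("1", "3"), c("2", "4"))))
  expect_error(splits_to_tree(incompat), "not compatible")
})

test_that("NEXUS export writes a SplitsTree-readable splits block", {
  set.seed(137)
  tr <- ape::unroot(ape::rtree(6))
  ss <- tree_to_splits(tr, include_trivial = TRUE)
  path <- withr::local_tempfile(fileext = ".nex")
  write_splits_nexus(ss, path)
  txt <- toupper(readLines(path))
  expect_true(any(grepl("BEGIN SPLITS", txt)))
  expect_true(any(grepl("NTAX=6", gsub(" ", "", txt))))
})
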