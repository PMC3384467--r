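# ---- split systems and Z-closure supernetworks ----------------------------

# canonical orientation: the side holding the lexicographically smallest
# taxon of the split becomes side a; both sides kept sorted
canonical_split <- function(a, b, weight = 0, support = 1L) {
  a <- sort(unique(as.character(a)))
  b <- sort(unique(as.character(b)))
  if (!length(a) || !length(b)) stop("split sides must be non-empty")
  if (length(intersect(a, b))) stop("split sides must be disjoint")
  if (min(b) < min(a)) { tmp <- a; a <- b; b <- tmp }
  list(a = a, b = b, weight = weight, support = as.integer(support))
}

split_key <- function(s) paste(paste(s$a, collapse = ","),
                               paste(s$b, collapse = ","), sep = "|")

#' Construct a split set
#'
#' A weighted system of (possibly partial) splits over a taxon universe.
#' Duplicate splits merge: weights sum and supports (source-tree counts)
#' add.
#'
#' @param universe character vector of taxon labels.
#' @param splits list of splits as returned by internal constructors or
#'   [tree_to_splits()]; each a list with `a`, `b`, `weight`, `support`.
#' @param n_trees number of source trees represented.
#' @return An object of class `split_set`.
#' @export
split_set <- function(universe, splits = list(), n_trees = 0L) {
  universe <- sort(unique(as.character(universe)))
  merged <- list()
  for (s in splits) {
    s <- canonical_split(s$a, s$b, s$weight, s$support)
    if (!all(c(s$a, s$b) %in% universe))
      stop("split taxa outside the universe")
    k <- split_key(s)
    if (is.null(merged[[k]])) merged[[k]] <- s
    else {
      merged[[k]]$weight <- merged[[k]]$weight + s$weight
      merged[[k]]$support <- merged[[k]]$support + s$support
    }
  }
  structure(list(universe = universe, splits = unname(merged),
                 n_trees = as.integer(n_trees)),
            class = "split_set")
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("split_set: %d splits over %d taxa (%d source trees)\n",
              length(x$splits), length(x$universe), x$n_trees))
  invisible(x)
}

n_splits <- function(ss) length(ss$splits)

is_full_split <- function(s, universe)
  setequal(c(s$a, s$b), universe)

#' Decompose a tree into its splits
#'
#' One split per internal edge (the bipartition of the leaf set induced by
#' removing the edge), weighted by branch length. Trivial (pendant) splits
#' are excluded by default.
#'
#' @param tree a `phylo` with >= 4 leaves.
#' @param include_trivial also emit the pendant splits (default FALSE).
#' @return A `split_set` over the tree's leaves with `n_trees = 1`.
#' @export
tree_to_splits <- function(tree, include_trivial = FALSE) {
  labs <- tree$tip.label
  ntip <- length(labs)
  if (ntip < 4L) stop("tree must have at least 4 leaves")
  tree <- ape::unroot(tree)   # a root bifurcation would duplicate a split
  desc <- tip_descendants(tree)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    side <- labs[desc[[ch]]]
    other <- setdiff(labs, side)
    if (!length(other)) next                      # root edge artefact
    if (!include_trivial && (length(side) < 2L || length(other) < 2L))
      next
    w <- if (is.null(tree$edge.length)) 0 else tree$edge.length[e]
    out <- c(out, list(canonical_split(side, other, weight = w)))
  }
  split_set(labs, out, n_trees = 1L)
}

#' Pool the splits of several (possibly partial) trees
#'
#' @param trees list of `phylo` objects, leaf sets may differ.
#' @param include_trivial passed to [tree_to_splits()].
#' @return A `split_set` over the union of leaf sets; duplicate splits
#'   merge with summed weights and incremented support.
#' @export
collect_splits <- function(trees, include_trivial = FALSE) {
  universe <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  all_splits <- list()
  for (tr in trees) {
    ss <- tree_to_splits(tr, include_trivial = include_trivial)
    all_splits <- c(all_splits, ss$splits)
  }
  split_set(universe, all_splits, n_trees = length(trees))
}

# the Z-rule on an ordered, oriented pair: returns NULL or list(s1, s2)
z_rule <- function(s1, s2) {
  if (!length(intersect(s1$a, s2$a))) return(NULL)
  if (!length(intersect(s1$b, s2$b))) return(NULL)
  if (length(intersect(s1$a, s2$b))) return(NULL)
  n1 <- canonical_split(s1$a, union(s1$b, s2$b), s1$weight, s1$support)
  n2 <- canonical_split(union(s1$a, s2$a), s2$b, s2$weight, s2$support)
  o1 <- canonical_split(s1$a, s1$b)        # inputs may arrive re-oriented
  o2 <- canonical_split(s2$a, s2$b)
  if (identical(split_key(n1), split_key(o1)) &&
      identical(split_key(n2), split_key(o2))) return(NULL)
  list(s1 = n1, s2 = n2)
}

orientations <- function(s) list(
  s, list(a = s$b, b = s$a, weight = s$weight, support = s$support))

#' Z-closure of a partial split system
#'
#' Repeatedly applies the split extension rule — for partial splits
#' `A1|B1`, `A2|B2` with `A1` meeting `A2`, `B1` meeting `B2` and `A1`
#' disjoint from `B2`, replace the pair by `A1|(B1 u B2)` and
#' `(A1 u A2)|B2` — over all ordered, oriented pairs in a deterministic
#' lexicographic sweep until a fixpoint. The output is deduplicated,
#' contains an extension of every input split, and is idempotent under
#' re-application.
#'
#' @param ss a `split_set` (partial splits allowed).
#' @param max_passes iteration cap; exceeding it raises a diagnostic error.
#' @return The closed `split_set`.
#' @export
z_closure <- function(ss, max_passes = 10000L) {
  stopifnot(inherits(ss, "split_set"))
  splits <- ss$splits
  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (pass > max_passes)
      stop("z_closure: iteration cap (", max_passes, " passes) exceeded")
    changed <- FALSE
    n <- length(splits)
    if (n < 2L) break
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        done <- FALSE
        for (o1 in orientations(splits[[i]])) {
          for (o2 in orientations(splits[[j]])) {
            res <- z_rule(o1, o2)
            if (!is.null(res)) {
              splits[[i]] <- res$s1
              splits[[j]] <- res$s2
              changed <- TRUE; done <- TRUE; break
            }
          }
          if (done) break
        }
      }
    }
    # deduplicate between passes (merge weights/supports)
    splits <- split_set(ss$universe, splits)$splits
    if (!changed) break
  }
  split_set(ss$universe, splits, n_trees = ss$n_trees)
}

#' Select the full splits of a split system
#'
#' After [z_closure()], splits whose taxa could not be extended to the
#' whole universe (because no overlapping split informs the missing taxa)
#' remain partial; the supernetwork itself is assembled from the full
#' splits. Partial leftovers are dropped with a message.
#'
#' @param ss a `split_set`.
#' @return The `split_set` restricted to splits covering the universe.
#' @export
full_splits <- function(ss) {
  stopifnot(inherits(ss, "split_set"))
  full <- vapply(ss$splits, is_full_split, logical(1L),
                 universe = ss$universe)
  if (!all(full))
    message(sum(!full), " split(s) could not be extended to all taxa ",
            "and were dropped")
  out <- ss
  out$splits <- ss$splits[full]
  out
}

#' Filter a supernetwork by split support
#'
#' Retains splits induced by at least `min_trees` source trees; the weight
#' of a retained (merged) split becomes the mean of its contributing
#' weights.
#'
#' @param ss a `split_set`.
#' @param min_trees minimum support (>= 1); 1 keeps everything.
#' @return The filtered `split_set` with mean weights.
#' @export
filter_supernetwork <- function(ss, min_trees = 1L) {
  stopifnot(inherits(ss, "split_set"), min_trees >= 1L)
  kept <- Filter(function(s) s$support >= min_trees, ss$splits)
  kept <- lapply(kept, function(s) {
    s$weight <- s$weight / s$support
    s
  })
  out <- split_set(ss$universe, kept, n_trees = ss$n_trees)
  # split_set() re-merges; weights were already averaged, supports restored
  out$splits <- kept
  out
}

splits_incompatible <- function(s1, s2) {
  length(intersect(s1$a, s2$a)) > 0L &&
    length(intersect(s1$a, s2$b)) > 0L &&
    length(intersect(s1$b, s2$a)) > 0L &&
    length(intersect(s1$b, s2$b)) > 0L
}

#' Compatibility diagnostics of a full split system
#'
#' Two full splits are incompatible iff all four pairwise side
#' intersections are non-empty; a split system is tree-like iff no pair is
#' incompatible. Reticulation in a supernetwork is quantified by the number
#' of incompatible pairs.
#'
#' @param ss a `split_set` of full splits (apply [z_closure()] first);
#'   partial splits are rejected.
#' @return List with `n_pairs_incompatible` and `is_tree_like`.
#' @export
compatibility_stats <- function(ss) {
  stopifnot(inherits(ss, "split_set"))
  full <- vapply(ss$splits, is_full_split, logical(1L),
                 universe = ss$universe)
  if (!all(full))
    stop("compatibility_stats requires full splits; apply z_closure first")
  n <- length(ss$splits)
  bad <- 0L
  if (n >= 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (splits_incompatible(ss$splits[[i]], ss$splits[[j]]))
        bad <- bad + 1L
  list(n_pairs_incompatible = bad, is_tree_like = bad == 0L)
}

#' Reassemble a tree from a compatible full split system
#'
#' Inverse of [tree_to_splits()] for pairwise-compatible full splits: each
#' split becomes an internal edge (weight = mean split weight), pendant
#' edges get length zero. Polytomies arise where splits are absent.
#'
#' @param ss a `split_set` of pairwise-compatible full splits.
#' @return A `phylo` over the universe.
#' @export
splits_to_tree <- function(ss) {
  stopifnot(inherits(ss, "split_set"))
  if (!compatibility_stats(ss)$is_tree_like)
    stop("split system is not compatible; no tree realises it")
  taxa <- ss$universe
  o <- taxa[1L]
  clades <- lapply(ss$splits, function(s) if (o %in% s$a) s$b else s$a)
  weights <- vapply(ss$splits, function(s) s$weight / s$support, 0)
  ord <- order(vapply(clades, length, 1L), decreasing = TRUE)
  clades <- clades[ord]; weights <- weights[ord]

  ntip <- length(taxa)
  n_int <- 1L + length(clades)              # root + one node per clade
  root <- ntip + 1L
  clade_node <- if (length(clades)) ntip + 1L + seq_along(clades)
                else integer(0)

  parent_of <- function(members) {
    # smallest clade strictly containing `members`; else the root
    best <- 0L; best_size <- Inf
    for (k in seq_along(clades)) {
      ck <- clades[[k]]
      if (length(ck) > length(members) && all(members %in% ck) &&
          length(ck) < best_size) {
        best <- k; best_size <- length(ck)
      }
    }
    if (best == 0L) root else clade_node[best]
  }

  edges <- NULL; lens <- NULL
  for (k in seq_along(clades)) {
    edges <- rbind(edges, c(parent_of(clades[[k]]), clade_node[k]))
    lens <- c(lens, weights[k])
  }
  for (i in seq_len(ntip)) {
    edges <- rbind(edges, c(parent_of(taxa[i]), i))
    lens <- c(lens, 0)
  }
  tr <- structure(list(edge = edges, edge.length = lens,
                       tip.label = taxa, Nnode = n_int),
                  class = "phylo")
  ape::reorder.phylo(tr, "postorder")
}

#' Export a split system as a SplitsTree-readable NEXUS file
#'
#' Writes TAXA and SPLITS blocks (weights included, cycle omitted) through
#' phangorn's splits writer.
#'
#' @param ss a `split_set` of full splits.
#' @param path output path.
#' @export
write_splits_nexus <- function(ss, path) {
  if (!requireNamespace("phangorn", quietly = TRUE))
    stop("phangorn is required for NEXUS splits export")
  full <- vapply(ss$splits, is_full_split, logical(1L),
                 universe = ss$universe)
  if (!all(full))
    stop("NEXUS export requires full splits; apply z_closure first")
  idx <- lapply(ss$splits, function(s) match(s$a, ss$universe))
  obj <- structure(idx, labels = ss$universe,
                   weights = vapply(ss$splits,
                                    function(s) s$weight / s$support, 0),
                   class = "splits")
  phangorn::write.nexus.splits(obj, file = path)
  invisible(path)
}
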