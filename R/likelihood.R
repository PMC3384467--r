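# Site-pattern compression: integer tip-state matrix -> unique columns
# with multiplicities. NA encodes gap/missing (treated as uninformative).
compress_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  list(states = states[, first, drop = FALSE], weights = weights)
}

# align alignment rows to tree tip labels; error on mismatch
match_tips <- function(tree, aln) {
  labs <- tree$tip.label
  if (!setequal(labs, rownames(aln$mat)))
    stop("tree leaves and alignment members differ for COG ", aln$cog_id)
  encode_alignment(aln)[labs, , drop = FALSE]
}

# one-hot partial for a tip pattern vector (NA -> all ones)
tip_partial <- function(st, npat) {
  L <- matrix(0, npat, 20L)
  ok <- !is.na(st)
  L[cbind(which(ok), st[ok])] <- 1
  L[!ok, ] <- 1
  L
}

#' Felsenstein pruning log-likelihood of a tree
#'
#' Computes the log-likelihood of an unrooted, branch-length-weighted tree
#' for a gap-filtered protein alignment under a reversible substitution
#' model, by the pruning algorithm with per-pattern rescaling to prevent
#' underflow. The virtual root is placed at an internal node; by
#' reversibility the value is invariant to that placement.
#'
#' @param tree a `phylo`; leaf labels must equal the alignment members.
#' @param aln a `cog_aln` (apply [complete_deletion()] first; any remaining
#'   gap/missing cells are treated as uninformative).
#' @param model a `subst_model`.
#' @return Log-likelihood (numeric scalar).
#' @export
tree_log_likelihood <- function(tree, aln, model) {
  stopifnot(inherits(aln, "cog_aln"), inherits(model, "subst_model"))
  states <- match_tips(tree, aln)
  pat <- compress_patterns(states)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  npat <- ncol(pat$states)

  partial <- vector("list", nnode)
  logscale <- matrix(0, nnode, npat)
  for (i in seq_len(ntip))
    partial[[i]] <- tip_partial(pat$states[i, ], npat)

  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    P <- prob_matrix(model, tr$edge.length[i])
    msg <- partial[[ch]] %*% t(P)
    if (is.null(partial[[p]])) {
      partial[[p]] <- msg
      logscale[p, ] <- logscale[ch, ]
    } else {
      partial[[p]] <- partial[[p]] * msg
      logscale[p, ] <- logscale[p, ] + logscale[ch, ]
    }
    # rescale to the row maximum once the node is (possibly partially)
    # combined; harmless to do per incoming edge
    mx <- pmax(apply(partial[[p]], 1L, max), 1e-300)
    partial[[p]] <- partial[[p]] / mx
    logscale[p, ] <- logscale[p, ] + log(mx)
  }

  root <- tr$edge[nrow(tr$edge), 1L]
  site_l <- as.vector(partial[[root]] %*% model$pi)
  sum(pat$weights * (log(site_l) + logscale[root, ]))
}
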