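# ---- directed-message likelihood engine -----------------------------------
#
# For branch-length optimisation and NNI scoring the pruning recursion is
# factored into directed per-edge messages: for edge e = (p, c),
#   down(e)  = L_down(c) %*% t(P_e)   (subtree below c, pushed into p)
#   ctx(e)   = product of the messages entering p other than down(e)
#   up(c)    = ctx(e) %*% t(P_e)      (rest of the tree, pushed into c;
#                                      valid under reversibility)
# so that for any t,
#   logL(t) = sum_pat w * log rowSums( ((ctx(e) * pi) %*% P(t)) * L_down(c) )
# plus the accumulated per-pattern log scale factors. Messages are rescaled
# to a row maximum of 1 to prevent underflow.

new_engine <- function(tree, aln, model) {
  states <- match_tips(tree, aln)
  pat <- compress_patterns(states)
  npat <- ncol(pat$states)
  list(model = model, states = pat$states, weights = pat$weights,
       npat = npat, pimat = matrix(model$pi, npat, 20L, byrow = TRUE))
}

# rescale a message matrix; returns list(m, ls_add)
.rescale <- function(m) {
  mx <- pmax(.rowMaxs(m), 1e-300)
  list(m = m / mx, ls = log(mx))
}

.rowMaxs <- function(m) {
  out <- m[, 1L]
  for (j in 2L:ncol(m)) out <- pmax(out, m[, j])
  out
}

# compute all messages for the current tree (tip labels must match the
# engine's state matrix rows by name)
engine_messages <- function(eng, tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nE <- nrow(tr$edge)
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- tr$edge[nE, 1L]
  npat <- eng$npat
  ord <- match(tr$tip.label, rownames(eng$states))

  P <- vector("list", nE)
  for (e in seq_len(nE)) P[[e]] <- prob_matrix(eng$model, tr$edge.length[e])

  parent_edge <- integer(nnode)           # 0 for root
  child_edges <- vector("list", nnode)
  for (e in seq_len(nE)) {
    parent_edge[tr$edge[e, 2L]] <- e
    child_edges[[tr$edge[e, 1L]]] <- c(child_edges[[tr$edge[e, 1L]]], e)
  }

  Ldown <- vector("list", nnode); lsdown <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    Ldown[[i]] <- tip_partial(eng$states[ord[i], ], npat)
    lsdown[[i]] <- numeric(npat)
  }
  down <- vector("list", nE); lsmsg <- vector("list", nE)
  for (e in seq_len(nE)) {                 # postorder: children first
    ch <- tr$edge[e, 2L]; p <- tr$edge[e, 1L]
    down[[e]] <- Ldown[[ch]] %*% t(P[[e]])
    lsmsg[[e]] <- lsdown[[ch]]
    if (is.null(Ldown[[p]])) {
      Ldown[[p]] <- down[[e]]; lsdown[[p]] <- lsmsg[[e]]
    } else {
      r <- .rescale(Ldown[[p]] * down[[e]])
      Ldown[[p]] <- r$m
      lsdown[[p]] <- lsdown[[p]] + lsmsg[[e]] + r$ls
    }
  }

  ctx <- vector("list", nE); lsctx <- vector("list", nE)
  up <- vector("list", nnode); lsup <- vector("list", nnode)
  for (e in rev(seq_len(nE))) {            # preorder: parents first
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    pieces_m <- list(); pieces_ls <- numeric(npat)
    for (e2 in child_edges[[p]]) if (e2 != e) {
      pieces_m <- c(pieces_m, list(down[[e2]]))
      pieces_ls <- pieces_ls + lsmsg[[e2]]
    }
    if (p != root) {
      pieces_m <- c(pieces_m, list(up[[p]]))
      pieces_ls <- pieces_ls + lsup[[p]]
    }
    m <- pieces_m[[1L]]
    if (length(pieces_m) > 1L)
      for (k in 2L:length(pieces_m)) m <- m * pieces_m[[k]]
    r <- .rescale(m)
    ctx[[e]] <- r$m; lsctx[[e]] <- pieces_ls + r$ls
    if (ch > ntip) {                       # tips never feed an up message
      u <- .rescale(ctx[[e]] %*% t(P[[e]]))
      up[[ch]] <- u$m; lsup[[ch]] <- lsctx[[e]] + u$ls
    }
  }

  list(tr = tr, nE = nE, ntip = ntip, root = root, P = P,
       parent_edge = parent_edge, child_edges = child_edges,
       Ldown = Ldown, lsdown = lsdown, down = down, lsmsg = lsmsg,
       ctx = ctx, lsctx = lsctx, up = up, lsup = lsup)
}

msg_loglik <- function(eng, M) {
  site <- as.vector(M$Ldown[[M$root]] %*% eng$model$pi)
  sum(eng$weights * (log(site) + M$lsdown[[M$root]]))
}

# log-likelihood as a function of the length of edge e, given messages
edge_loglik_fun <- function(eng, M, e) {
  ch <- M$tr$edge[e, 2L]
  Fm <- M$ctx[[e]] * eng$pimat
  G <- M$Ldown[[ch]]
  base <- eng$weights * (M$lsctx[[e]] + M$lsdown[[ch]])
  function(t) {
    P <- prob_matrix(eng$model, t)
    s <- rowSums((Fm %*% P) * G)
    sum(eng$weights * log(s)) + sum(base)
  }
}

# generic combined-context Brent step used by edge and NNI scoring
brent_edge <- function(f, lower = 1e-9, upper = 10, tol = 1e-8) {
  opt <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = tol)
  fl <- f(lower)
  if (fl > opt$objective) list(t = lower, logl = fl)
  else list(t = opt$maximum, logl = opt$objective)
}

#' Optimise branch lengths by coordinate-wise scalar search
#'
#' Iteratively maximises the pruning log-likelihood over one branch length
#' at a time (Brent search on `[1e-9, t_max]`), sweeping all edges per pass,
#' until the log-likelihood improves by less than `tol` or `max_passes` is
#' reached. The returned log-likelihood is never below the starting value.
#'
#' @param tree a `phylo` with branch lengths.
#' @param aln gap-filtered `cog_aln` whose members equal the tree's leaves.
#' @param model a `subst_model`.
#' @param max_passes maximum sweeps over all edges (default 3).
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param t_max upper bracket for any branch length (default 10).
#' @return The tree with optimised `edge.length` and attribute `logLik`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, max_passes = 3L,
                                    tol = 1e-6, t_max = 10) {
  eng <- new_engine(tree, aln, model)
  M <- engine_messages(eng, tree)
  cur <- msg_loglik(eng, M)
  tr <- M$tr
  for (pass in seq_len(max_passes)) {
    for (e in seq_len(M$nE)) {
      f <- edge_loglik_fun(eng, M, e)
      opt <- brent_edge(f, upper = t_max)
      tr$edge.length[e] <- opt$t
    }
    M <- engine_messages(eng, tr)
    tr <- M$tr
    new <- msg_loglik(eng, M)
    if (new < cur - 1e-8) {
      # a sweep against stale messages regressed (rare); redo this pass
      # with messages refreshed after every accepted edge
      for (e in seq_len(M$nE)) {
        f <- edge_loglik_fun(eng, M, e)
        opt <- brent_edge(f, upper = t_max)
        if (opt$logl > msg_loglik(eng, M) + 1e-12) {
          tr$edge.length[e] <- opt$t
          M <- engine_messages(eng, tr)
          tr <- M$tr
        }
      }
      new <- msg_loglik(eng, M)
    }
    if (new - cur < tol) { cur <- max(cur, new); break }
    cur <- new
  }
  attr(tr, "logLik") <- cur
  tr
}

# exchange child subtree x (child of u) with child subtree y (child of v)
apply_nni_swap <- function(tree, x, y, u, v) {
  ex <- which(tree$edge[, 2L] == x)
  ey <- which(tree$edge[, 2L] == y)
  stopifnot(tree$edge[ex, 1L] == u, tree$edge[ey, 1L] == v)
  tree$edge[ex, 1L] <- v
  tree$edge[ey, 1L] <- u
  attr(tree, "order") <- NULL      # edge matrix no longer in stored order
  ape::reorder.phylo(tree, "postorder")
}

#' NNI hill-climbing search for the maximum-likelihood topology
#'
#' Starting from a binary tree (typically the neighbor-joining tree on ML
#' pairwise distances), evaluates both nearest-neighbor-interchange
#' rearrangements of every internal edge, with the central branch length
#' re-optimised for each candidate from cached subtree messages, accepts the
#' best strict improvement per round, re-optimises all branch lengths, and
#' stops at a local optimum or after `max_rounds` rounds. With
#' `max_rounds = 0` the start tree is returned unchanged.
#'
#' @param start binary `phylo` with branch lengths.
#' @param aln gap-filtered `cog_aln`.
#' @param model a `subst_model`.
#' @param max_rounds maximum accepted rearrangement rounds (default 10).
#' @param tol minimum log-likelihood gain to accept a rearrangement.
#' @return The locally optimal tree, attribute `logLik` attached; its
#'   log-likelihood is >= that of `start`.
#' @export
nni_search <- function(start, aln, model, max_rounds = 10L, tol = 1e-5) {
  if (max_rounds == 0L) return(start)
  start <- ape::unroot(start)    # NNI edges are defined on unrooted trees
  eng <- new_engine(start, aln, model)
  tr <- optimize_branch_lengths(start, aln, model, max_passes = 2L)
  cur <- attr(tr, "logLik")
  for (round in seq_len(max_rounds)) {
    M <- engine_messages(eng, tr)
    tr <- M$tr
    ntip <- M$ntip
    best <- list(gain = tol, swap = NULL)
    internal <- which(M$tr$edge[, 2L] > ntip)
    for (e in internal) {
      u <- M$tr$edge[e, 1L]; v <- M$tr$edge[e, 2L]
      vkids <- M$child_edges[[v]]
      if (length(vkids) != 2L) next
      e1 <- vkids[1L]; e2 <- vkids[2L]
      X1 <- M$down[[e1]]; ls1 <- M$lsmsg[[e1]]
      X2 <- M$down[[e2]]; ls2 <- M$lsmsg[[e2]]
      ukids <- setdiff(M$child_edges[[u]], e)
      if (u == M$root) {
        if (length(ukids) < 2L) next
        ea <- ukids[1L]; eb <- ukids[2L]
        XA <- M$down[[ea]]; lsA <- M$lsmsg[[ea]]
        XB <- M$down[[eb]]; lsB <- M$lsmsg[[eb]]
        swapA <- M$tr$edge[ea, 2L]
      } else {
        if (length(ukids) != 1L) next
        ea <- ukids[1L]
        XA <- M$down[[ea]]; lsA <- M$lsmsg[[ea]]
        XB <- M$up[[u]];    lsB <- M$lsup[[u]]
        swapA <- M$tr$edge[ea, 2L]
      }
      c1 <- M$tr$edge[e1, 2L]; c2 <- M$tr$edge[e2, 2L]

      score <- function(Fm, lsF, G, lsG) {
        base <- sum(eng$weights * (lsF + lsG))
        Fp <- Fm * eng$pimat
        f <- function(t) {
          P <- prob_matrix(eng$model, t)
          sum(eng$weights * log(rowSums((Fp %*% P) * G))) + base
        }
        brent_edge(f)
      }
      s0 <- score(XA * XB, lsA + lsB, X1 * X2, ls1 + ls2)
      s1 <- score(X1 * XB, ls1 + lsB, XA * X2, lsA + ls2)  # swap A <-> c1
      s2 <- score(X2 * XB, ls2 + lsB, X1 * XA, ls1 + lsA)  # swap A <-> c2
      if (s1$logl - s0$logl > best$gain)
        best <- list(gain = s1$logl - s0$logl,
                     swap = list(x = swapA, y = c1, u = u, v = v,
                                 e = e, t = s1$t))
      if (s2$logl - s0$logl > best$gain)
        best <- list(gain = s2$logl - s0$logl,
                     swap = list(x = swapA, y = c2, u = u, v = v,
                                 e = e, t = s2$t))
    }
    if (is.null(best$swap)) break
    sw <- best$swap
    tr$edge.length[sw$e] <- sw$t
    tr <- apply_nni_swap(tr, sw$x, sw$y, sw$u, sw$v)
    tr <- optimize_branch_lengths(tr, aln, model, max_passes = 1L)
    new <- attr(tr, "logLik")
    if (new <= cur + tol) { cur <- max(cur, new); break }
    cur <- new
  }
  attr(tr, "logLik") <- cur
  tr
}
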