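as_residue_int <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(toupper(x), "")[[1L]]
  if (is.character(x)) x <- match(x, AMINO_ACIDS)
  as.integer(x)
}

#' Maximum-likelihood pairwise distance between two protein sequences
#'
#' Maximises the pairwise likelihood
#' `sum over sites of log( pi[x] * P(t)[x, y] )` over the branch length
#' `t >= 0` by bracketed scalar (Brent) optimisation on `[0, t_max]`. Sites
#' where either sequence has a gap/missing symbol are excluded.
#'
#' @param seq_i,seq_j aligned residue strings (or single-character vectors)
#'   of equal length.
#' @param model a `subst_model`.
#' @param t_max upper bracket (default 10); if the optimum hits the bound
#'   the result carries attribute `saturated = TRUE`.
#' @return Distance in expected substitutions per site, with attribute
#'   `saturated`.
#' @export
ml_pairwise_distance <- function(seq_i, seq_j, model, t_max = 10) {
  xi <- as_residue_int(seq_i)
  xj <- as_residue_int(seq_j)
  if (length(xi) != length(xj)) stop("sequences must have equal length")
  ok <- !is.na(xi) & !is.na(xj)
  if (!any(ok)) stop("no comparable sites between the two sequences")
  N <- matrix(tabulate(20L * (xi[ok] - 1L) + xj[ok], nbins = 400L), 20L, 20L,
              byrow = TRUE)
  d <- ml_distance_from_counts(N, model, t_max)
  d
}

# shared optimiser over a 20x20 site-pair count matrix
ml_distance_from_counts <- function(N, model, t_max = 10) {
  pos <- N > 0
  f <- function(t) {
    J <- model$pi * prob_matrix(model, t)   # pi_i * P_ij, row-scaled
    sum(N[pos] * log(pmax(J[pos], 1e-300)))
  }
  if (sum(N[!diag(20L) & pos]) == 0L) {     # identical where comparable
    out <- 0
    attr(out, "saturated") <- FALSE
    return(out)
  }
  opt <- stats::optimize(f, c(0, t_max), maximum = TRUE, tol = 1e-9)
  d <- opt$maximum
  if (f(0) >= opt$objective) d <- 0
  saturated <- (t_max - d) < 1e-4
  if (saturated) d <- t_max
  attr(d, "saturated") <- saturated
  d
}

#' ML pairwise distance matrix of an alignment
#'
#' @param aln gap-filtered `cog_aln`.
#' @param model a `subst_model`.
#' @param t_max passed to [ml_pairwise_distance()].
#' @return Symmetric numeric matrix (zero diagonal) over the alignment
#'   members, attribute `saturated` holding a logical matrix.
#' @export
ml_distance_matrix <- function(aln, model, t_max = 10) {
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  D <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  Sat <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    xi <- enc[i, ]; xj <- enc[j, ]
    ok <- !is.na(xi) & !is.na(xj)
    if (!any(ok))
      stop("no comparable sites between ", rownames(enc)[i], " and ",
           rownames(enc)[j])
    N <- matrix(tabulate(20L * (xi[ok] - 1L) + xj[ok], nbins = 400L),
                20L, 20L, byrow = TRUE)
    d <- ml_distance_from_counts(N, model, t_max)
    D[i, j] <- D[j, i] <- as.numeric(d)
    Sat[i, j] <- Sat[j, i] <- attr(d, "saturated")
  }
  attr(D, "saturated") <- Sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (delegated to [ape::nj()] for
#' four or more leaves; the three-leaf star is solved directly from the
#' three-point formulas). Negative estimated branch lengths are clamped
#' to zero.
#'
#' @param D symmetric distance matrix with zero diagonal and >= 3 leaves,
#'   dimnames labelling the taxa.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (any(is.na(D)) || any(!is.finite(D)))
    stop("distance matrix contains NA/NaN/Inf")
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be 0")
  n <- nrow(D)
  if (n < 3L) stop("at least 3 leaves required")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", 1:n)
  if (n == 3L) {
    a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    c <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    tr <- structure(list(
      edge = matrix(c(4L, 1L, 4L, 2L, 4L, 3L), 3L, 2L, byrow = TRUE),
      edge.length = pmax(c(a, b, c), 0),
      tip.label = rownames(D), Nnode = 1L), class = "phylo")
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Infer one COG tree: complete deletion, +F frequencies, distances, NJ, NNI
#'
#' The standard inference path used by the pipeline: filter columns by
#' [complete_deletion()], estimate empirical frequencies (the `+F` step),
#' build the WAG+F model, compute ML pairwise distances, construct the
#' neighbor-joining start tree and refine it by [nni_search()].
#'
#' @param aln a `cog_aln`.
#' @param nni_rounds maximum NNI rounds (default 2; 0 = NJ tree with
#'   ML-optimised branch lengths only).
#' @param freq `"empirical"` (+F, default) or `"model"` (published WAG
#'   frequencies).
#' @return The inferred `phylo` with attribute `logLik`.
#' @export
infer_cog_tree <- function(aln, nni_rounds = 2L,
                           freq = c("empirical", "model")) {
  freq <- match.arg(freq)
  aln <- complete_deletion(aln)
  model <- if (freq == "empirical") wag_model(empirical_frequencies(aln))
           else wag_model()
  D <- ml_distance_matrix(aln, model)
  tr <- nj_tree(D)
  if (nni_rounds > 0L) {
    tr <- nni_search(tr, aln, model, max_rounds = nni_rounds)
  } else {
    tr <- optimize_branch_lengths(tr, aln, model)
  }
  tr
}
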