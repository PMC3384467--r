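GAP_CHARS <- c("-", "?")

#' Construct a COG protein alignment
#'
#' A `cog_aln` holds one cluster of orthologous proteins (COG): an aligned
#' set of reference sequences plus zero or more focal-organism alleles, with
#' the mapping from sequence id to taxon id used for donor attribution.
#'
#' @param cog_id character scalar.
#' @param seqs named character vector of aligned residue strings (equal
#'   lengths; alphabet: 20 amino acids plus `-` and `?`), or a character
#'   matrix (rows = sequences, single characters).
#' @param taxon_map named character vector mapping sequence id to taxon id;
#'   defaults to the identity mapping.
#' @return An object of class `cog_aln`: list with `cog_id`, `mat` (character
#'   matrix, rownames = sequence ids), `taxon_map`.
#' @export
cog_alignment <- function(cog_id, seqs, taxon_map = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    stopifnot(!is.null(names(seqs)))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("aligned sequences must have equal length in COG ", cog_id)
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat))) stop("sequence ids required")
  if (anyDuplicated(rownames(mat))) stop("duplicate sequence ids")
  bad <- setdiff(unique(as.vector(mat)), c(AMINO_ACIDS, GAP_CHARS))
  if (length(bad))
    stop("unexpected residue symbol(s): ", paste(bad, collapse = " "))
  if (is.null(taxon_map)) {
    taxon_map <- stats::setNames(rownames(mat), rownames(mat))
  }
  structure(list(cog_id = cog_id, mat = mat, taxon_map = taxon_map),
            class = "cog_aln")
}

#' @export
print.cog_aln <- function(x, ...) {
  cat(sprintf("COG alignment %s: %d sequences x %d columns\n",
              x$cog_id, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Number of sequences / columns of an alignment
#' @param aln a `cog_aln`.
#' @return integer.
#' @export
n_sequences <- function(aln) nrow(aln$mat)

#' @rdname n_sequences
#' @export
n_columns <- function(aln) ncol(aln$mat)

#' Complete deletion of gapped and missing columns
#'
#' Removes every alignment column that contains a gap (`-`) or missing (`?`)
#' symbol in any member, the column filter applied before model-based
#' inference. Member order is preserved; the operation is idempotent.
#'
#' @param aln a `cog_aln`.
#' @return The filtered `cog_aln`.
#' @export
complete_deletion <- function(aln) {
  stopifnot(inherits(aln, "cog_aln"))
  if (ncol(aln$mat) == 0L)
    stop("no columns survive complete deletion in COG ", aln$cog_id)
  keep <- colSums(matrix(aln$mat %in% GAP_CHARS, nrow = nrow(aln$mat))) == 0L
  if (!any(keep))
    stop("no columns survive complete deletion in COG ", aln$cog_id)
  out <- aln
  out$mat <- aln$mat[, keep, drop = FALSE]
  out
}

#' Empirical amino-acid frequencies of an alignment
#'
#' The "+F" component of tree inference: per-residue frequencies counted
#' over all cells of a (gap-filtered) alignment. Zero counts are floored at
#' `1e-6` before renormalisation so that the resulting model assigns no
#' residue probability exactly zero.
#'
#' @param aln a `cog_aln` (gap/missing symbols, if present, are ignored in
#'   the counts).
#' @return Named numeric vector of length 20 summing to 1.
#' @export
empirical_frequencies <- function(aln) {
  stopifnot(inherits(aln, "cog_aln"))
  cells <- as.vector(aln$mat)
  cells <- cells[!(cells %in% GAP_CHARS)]
  if (!length(cells)) stop("empty alignment: no residues to count")
  counts <- table(factor(cells, levels = AMINO_ACIDS))
  f <- as.numeric(counts) / sum(counts)
  f[f < 1e-6] <- 1e-6
  f <- f / sum(f)
  names(f) <- AMINO_ACIDS
  f
}

#' Read / write aligned protein FASTA
#'
#' Thin wrappers over Biostrings FASTA IO returning/accepting `cog_aln`
#' objects. Gaps are written as `-`.
#'
#' @param path file path.
#' @param cog_id id recorded on the alignment; default the file base name.
#' @param taxon_map optional sequence-id to taxon-id mapping.
#' @return `read_cog_fasta`: a `cog_aln`. `write_cog_fasta`: `path`,
#'   invisibly.
#' @export
read_cog_fasta <- function(path, cog_id = NULL, taxon_map = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- stats::setNames(as.character(ss), names(ss))
  if (is.null(cog_id))
    cog_id <- sub("\\.[^.]*$", "", basename(path))
  cog_alignment(cog_id, seqs, taxon_map = taxon_map)
}

#' @rdname read_cog_fasta
#' @param aln a `cog_aln` to write.
#' @export
write_cog_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "cog_aln"))
  ss <- Biostrings::AAStringSet(apply(aln$mat, 1L, paste, collapse = ""))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# integer-encode alignment rows (1..20; NA for gap/missing)
encode_alignment <- function(aln) {
  m <- matrix(match(aln$mat, AMINO_ACIDS), nrow = nrow(aln$mat),
              dimnames = dimnames(aln$mat))
  m
}
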