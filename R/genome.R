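# ---- synthetic genome + occupancy / G+C statistics ------------------------

#' Simulate a genome sequence with annotated genes
#'
#' Draws a random DNA sequence at a target G+C content and places
#' `n_genes` non-overlapping genes (1-based inclusive coordinates, random
#' strand) along it.
#'
#' @param length chromosome length in bp (> 0).
#' @param n_genes number of genes; must fit without mandatory overlap.
#' @param gc_target target G+C fraction in (0, 1); the realised content is
#'   binomial around it.
#' @param seed integer seed.
#' @param gene_length_range min/max gene length in bp.
#' @return List with `sequence` (character scalar) and `annotation` (a
#'   `genome_annotation`: list with `contig_id`, `contig_length`, `genes`
#'   data.frame `gene_id`, `start`, `end`, `strand`).
#' @export
simulate_genome <- function(length, n_genes, gc_target = 0.5, seed = 1L,
                            gene_length_range = c(300L, 1500L)) {
  stopifnot(length > 0, n_genes >= 0, gc_target > 0, gc_target < 1)
  with_seed(seed, {
    p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
           G = gc_target / 2, T = (1 - gc_target) / 2)
    seq <- paste(sample(names(p), length, replace = TRUE, prob = p),
                 collapse = "")
    genes <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
    if (n_genes > 0) {
      glen <- sample(gene_length_range[1L]:gene_length_range[2L], n_genes,
                     replace = TRUE)
      if (sum(glen) > length) {
        # shrink uniformly; reject only if even minimal genes cannot fit
        if (n_genes * gene_length_range[1L] > length)
          stop("infeasible n_genes for genome length")
        glen <- rep(gene_length_range[1L], n_genes)
      }
      slack <- length - sum(glen)
      # random non-overlapping placement: distribute slack between genes
      cuts <- sort(sample.int(slack + n_genes, n_genes))
      gaps <- diff(c(0L, cuts)) - 1L
      starts <- cumsum(gaps + c(1L, glen[-n_genes]))
      genes <- data.frame(
        gene_id = sprintf("gene%04d", seq_len(n_genes)),
        start = as.integer(starts),
        end = as.integer(starts + glen - 1L),
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    ann <- genome_annotation("contig1", length, genes)
    list(sequence = seq, annotation = ann)
  })
}

#' Construct a genome annotation
#'
#' @param contig_id contig name.
#' @param contig_length contig length in bp.
#' @param genes data.frame with `gene_id`, `start`, `end` (1-based
#'   inclusive), `strand` (`+`/`-`).
#' @return A `genome_annotation`.
#' @export
genome_annotation <- function(contig_id, contig_length, genes) {
  stopifnot(contig_length >= 1)
  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id)) stop("gene_ids must be unique")
    if (any(genes$start < 1L) || any(genes$end > contig_length) ||
        any(genes$start > genes$end))
      stop("gene interval out of bounds")
    if (!all(genes$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  structure(list(contig_id = contig_id,
                 contig_length = as.integer(contig_length),
                 genes = genes),
            class = "genome_annotation")
}

#' G+C content of a DNA sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; `N` bases are excluded from the
#' denominator. Full precision is kept; rounding is a presentation concern.
#'
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N`.
#' @return Percent G+C (numeric scalar).
#' @export
gc_content <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  dna <- Biostrings::DNAString(toupper(sequence))
  counts <- Biostrings::alphabetFrequency(dna)[c("A", "C", "G", "T", "N")]
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) stop("sequence has no A/C/G/T bases")
  100 * sum(counts[c("G", "C")]) / denom
}

#' Genome occupancy summary statistics
#'
#' Computes the genome-composition summary: total bases, overall G+C,
#' number of genes, length occupied by genes (union of gene intervals,
#' overlaps merged, strand ignored), intergenic length (their exact
#' complement, so gene + intergenic = total always), and the G+C content
#' and percent-of-chromosome of each part.
#'
#' @param annotation a `genome_annotation`.
#' @param sequence the contig DNA string (length must match).
#' @return A `genome_stats`: list with `total_bases`, `gc_percent`,
#'   `n_genes`, `gene_length`, `gene_gc_percent`, `gene_fraction_percent`,
#'   `intergenic_length`, `intergenic_gc_percent`,
#'   `intergenic_fraction_percent`.
#' @export
occupancy <- function(annotation, sequence) {
  stopifnot(inherits(annotation, "genome_annotation"))
  total <- nchar(sequence)
  if (total != annotation$contig_length)
    stop("sequence length does not match annotation contig_length")
  genes <- annotation$genes
  if (nrow(genes) && (any(genes$end > total) || any(genes$start < 1L)))
    stop("gene interval out of bounds")

  if (nrow(genes)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = genes$start,
                                           end = genes$end))
    gene_len <- sum(IRanges::width(ir))
    gene_seq <- paste(substring(sequence, IRanges::start(ir),
                                IRanges::end(ir)), collapse = "")
  } else {
    ir <- IRanges::IRanges()
    gene_len <- 0L
    gene_seq <- ""
  }
  inter_ir <- IRanges::gaps(ir, start = 1L, end = total)
  inter_len <- total - gene_len
  inter_seq <- if (length(inter_ir))
    paste(substring(sequence, IRanges::start(inter_ir),
                    IRanges::end(inter_ir)), collapse = "") else ""

  structure(list(
    total_bases = as.integer(total),
    gc_percent = gc_content(sequence),
    n_genes = nrow(genes),
    gene_length = as.integer(gene_len),
    gene_gc_percent = if (nzchar(gene_seq)) gc_content(gene_seq)
                      else NA_real_,
    gene_fraction_percent = 100 * gene_len / total,
    intergenic_length = as.integer(inter_len),
    intergenic_gc_percent = if (nzchar(inter_seq)) gc_content(inter_seq)
                            else NA_real_,
    intergenic_fraction_percent = 100 * inter_len / total
  ), class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat("Genome summary\n")
  cat(sprintf("  total bases          %12d   %%G+C %s\n", x$total_bases,
              format_percent(x$gc_percent)))
  cat(sprintf("  genes                %12d\n", x$n_genes))
  cat(sprintf("  gene length (bp)     %12d   %%G+C %s   %%of chromosome %s\n",
              x$gene_length, format_percent(x$gene_gc_percent),
              format_percent(x$gene_fraction_percent)))
  cat(sprintf("  intergenic (bp)      %12d   %%G+C %s   %%of chromosome %s\n",
              x$intergenic_length, format_percent(x$intergenic_gc_percent),
              format_percent(x$intergenic_fraction_percent)))
  invisible(x)
}

# 2-decimal, round-half-away-from-zero presentation
format_percent <- function(x, digits = 2L) {
  if (is.na(x)) return("NA")
  m <- 10^digits
  sprintf(paste0("%.", digits, "f"), sign(x) * floor(abs(x) * m + 0.5) / m)
}

#' Genome FASTA / gene-coordinate IO
#'
#' Reads a single-contig FASTA (Biostrings) and a tab-separated gene table
#' (`gene_id`, `start`, `end`, `strand`; 1-based inclusive). A minimal GFF3
#' (seqid, source, type, start, end, score, strand, phase, attributes) is
#' accepted for coordinates as well.
#'
#' @param fasta_path FASTA path.
#' @return `read_genome_fasta`: character scalar sequence.
#' @export
read_genome_fasta <- function(fasta_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(ss) != 1L) stop("expected a single-contig FASTA")
  as.character(ss[[1L]])
}

#' @rdname read_genome_fasta
#' @param sequence DNA string to write.
#' @param path output path.
#' @param contig_id FASTA header.
#' @export
write_genome_fasta <- function(sequence, path, contig_id = "contig1") {
  ss <- Biostrings::DNAStringSet(sequence)
  names(ss) <- contig_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname read_genome_fasta
#' @param coord_path gene coordinate table path (TSV or GFF3 by extension).
#' @param contig_length contig length for the annotation.
#' @export
read_gene_table <- function(coord_path, contig_length) {
  if (grepl("\\.gff3?$", coord_path, ignore.case = TRUE)) {
    df <- utils::read.delim(coord_path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = sprintf("gene%04d", seq_len(nrow(df))),
                        start = as.integer(df[[4L]]),
                        end = as.integer(df[[5L]]),
                        strand = df[[7L]], stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.delim(coord_path, stringsAsFactors = FALSE)
  }
  genome_annotation("contig1", contig_length, genes)
}

#' @rdname read_genome_fasta
#' @param annotation a `genome_annotation` to write as TSV.
#' @export
write_gene_table <- function(annotation, path) {
  utils::write.table(annotation$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_genome_fasta
#' @param stats a `genome_stats` to write as a one-row CSV (percentages at
#'   2 decimals, round half away from zero).
#' @export
write_genome_stats <- function(stats, path) {
  df <- data.frame(
    total_bases = stats$total_bases,
    gc_percent = format_percent(stats$gc_percent),
    n_genes = stats$n_genes,
    gene_length = stats$gene_length,
    gene_gc_percent = format_percent(stats$gene_gc_percent),
    gene_fraction_percent = format_percent(stats$gene_fraction_percent),
    intergenic_length = stats$intergenic_length,
    intergenic_gc_percent = format_percent(stats$intergenic_gc_percent),
    intergenic_fraction_percent =
      format_percent(stats$intergenic_fraction_percent))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
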