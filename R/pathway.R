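# ---- pathway polymorphism annotation --------------------------------------

#' Construct pathway step definitions
#'
#' A pathway step is one enzymatic reaction (EC number) of the starch and
#' sucrose, upper-glycolysis or lower-glycolysis maps, backed by one or
#' more COGs whose donor calls are aggregated into the step's allele
#' annotation.
#'
#' @param steps data.frame with columns `step_id`, `pathway`, `ec_number`,
#'   `cog_ids` (semicolon-joined), `description`.
#' @return A validated `pathway_steps` data.frame.
#' @export
pathway_steps <- function(steps) {
  need <- c("step_id", "pathway", "ec_number", "cog_ids", "description")
  if (!all(need %in% names(steps)))
    stop("pathway table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(steps$step_id)) stop("duplicate step_ids")
  ok <- grepl("^\\d+\\.\\d+\\.\\d+\\.(\\d+|-)$", steps$ec_number)
  if (!all(ok))
    stop("malformed EC number(s): ",
         paste(steps$ec_number[!ok], collapse = " "))
  if (any(!nzchar(steps$cog_ids))) stop("cog_ids must be non-empty")
  out <- steps[, need]
  rownames(out) <- NULL
  structure(out, class = c("pathway_steps", "data.frame"))
}

#' Read / write pathway step tables
#'
#' Tab-separated with columns `step_id`, `pathway`, `ec_number`, `cog_ids`
#' (semicolon-joined), `description`.
#'
#' @param path file path.
#' @return `read_pathway_steps`: a `pathway_steps` data.frame.
#' @export
read_pathway_steps <- function(path) {
  pathway_steps(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_pathway_steps
#' @param steps a `pathway_steps` table.
#' @export
write_pathway_steps <- function(steps, path) {
  utils::write.table(as.data.frame(steps), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate pathway steps with allele counts and donor codes
#'
#' Joins donor calls onto step definitions: for each step, all alleles of
#' its COGs are counted and their donor codes collected (sorted), rendered
#' in the map style `"n: code1,code2,..."`. Steps with no matching calls
#' are annotated `"0:"` with a warning. Output preserves the input step
#' order; the join is deterministic.
#'
#' @param steps a `pathway_steps` table.
#' @param calls data.frame of donor calls (`cog_id`, `allele_id`, `code`).
#' @return data.frame (`step_id`, `pathway`, `ec_number`, `n_alleles`,
#'   `codes`, `annotation`).
#' @export
annotate_pathway <- function(steps, calls) {
  steps <- pathway_steps(as.data.frame(steps))
  out <- do.call(rbind, lapply(seq_len(nrow(steps)), function(i) {
    cogs <- strsplit(steps$cog_ids[i], ";", fixed = TRUE)[[1L]]
    hit <- calls[calls$cog_id %in% cogs, , drop = FALSE]
    hit <- hit[order(hit$cog_id, hit$allele_id), , drop = FALSE]
    n <- nrow(hit)
    codes <- paste(sort(hit$code), collapse = ",")
    if (n == 0L)
      warning("no donor calls for step ", steps$step_id[i],
              " (COGs: ", steps$cog_ids[i], ")", call. = FALSE)
    data.frame(step_id = steps$step_id[i],
               pathway = steps$pathway[i],
               ec_number = steps$ec_number[i],
               n_alleles = n,
               codes = codes,
               annotation = sprintf("%d: %s", n, codes),
               stringsAsFactors = FALSE)
  }))
  out$annotation <- sub(": $", ":", out$annotation)
  rownames(out) <- NULL
  out
}

#' @rdname annotate_pathway
#' @param annotation result of [annotate_pathway()].
#' @param path output TSV path.
#' @export
write_pathway_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Illustrative pathway step fixture over simulated COG ids
#'
#' Builds a small three-pathway step table (starch-sucrose, upper and
#' lower glycolysis) mapping steps to the given COG ids round-robin — a
#' stand-in for a curated EC-to-COG resource, sufficient to exercise the
#' annotation join.
#'
#' @param cog_ids character vector of COG ids to distribute over steps.
#' @param n_steps number of steps (default 12).
#' @return A `pathway_steps` table.
#' @export
example_pathway_steps <- function(cog_ids, n_steps = 12L) {
  n_steps <- min(n_steps, length(cog_ids))
  ecs <- c("3.2.1.26", "2.7.1.1", "5.3.1.9", "2.7.1.11", "4.1.2.13",
           "5.3.1.1", "1.2.1.12", "2.7.2.3", "5.4.2.11", "4.2.1.11",
           "2.7.1.40", "1.2.4.1")
  pw <- rep(c("starch-sucrose", "glycolysis-upper", "glycolysis-lower"),
            length.out = n_steps)
  groups <- split(cog_ids, rep_len(seq_len(n_steps), length(cog_ids)))
  pathway_steps(data.frame(
    step_id = sprintf("S%02d", seq_len(n_steps)),
    pathway = pw,
    ec_number = rep_len(ecs, n_steps),
    cog_ids = vapply(groups, paste, "", collapse = ";"),
    description = sprintf("enzymatic step %d", seq_len(n_steps)),
    stringsAsFactors = FALSE))
}
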