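#' Donor category codes
#'
#' Clade categories of the reference panel and the short codes used in
#' donor attribution: `P` Proteobacteria (vertical inheritance), `B` other
#' bacteria, `T` thermophilic archaea, `HA` halophilic archaea, `A` other
#' (non-halophilic, non-thermophilic) archaea. `NC` marks alleles that form
#' no cluster with any reference clade.
#'
#' @export
CATEGORIES <- c(PROTEO = "P", OTHER_BACT = "B", THERMO_ARCH = "T",
                HALO_ARCH = "HA", OTHER_ARCH = "A")

#' @rdname CATEGORIES
#' @export
CATEGORY_DOMAIN <- c(PROTEO = "Bacteria", OTHER_BACT = "Bacteria",
                     THERMO_ARCH = "Archaea", HALO_ARCH = "Archaea",
                     OTHER_ARCH = "Archaea")

# evaluate expr under a local RNG state seeded with `seed`; global RNG
# stream untouched (all randomness in the package flows through this)
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic child seeds below 2^31, derived from one master seed
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a reference taxonomy
#'
#' Builds a reference panel of taxa partitioned into the five clade
#' categories (Proteobacteria, other Bacteria, thermophilic Archaea,
#' halophilic Archaea, other Archaea). Taxon ids are unique short tokens;
#' the result is deterministic for a fixed seed.
#'
#' @param n_per_category named integer vector with entries for each of
#'   `names(CATEGORIES)`; all counts must be >= 1.
#' @param seed integer seed.
#' @return A `taxon_set`: data.frame with columns `taxon_id`, `name`,
#'   `domain`, `category`.
#' @examples
#' tax <- simulate_taxonomy(c(PROTEO = 2, OTHER_BACT = 2, THERMO_ARCH = 2,
#'                            HALO_ARCH = 2, OTHER_ARCH = 2), seed = 1)
#' table(tax$category)
#' @export
simulate_taxonomy <- function(n_per_category, seed = 1L) {
  cats <- names(CATEGORIES)
  if (is.null(names(n_per_category)) ||
      !all(cats %in% names(n_per_category)))
    stop("n_per_category must be named with all of: ",
         paste(cats, collapse = ", "))
  n <- as.integer(n_per_category[cats])
  if (any(is.na(n)) || any(n < 1L))
    stop("all category counts must be positive integers")
  prefix <- c(PROTEO = "PRO", OTHER_BACT = "BAC", THERMO_ARCH = "THA",
              HALO_ARCH = "HAR", OTHER_ARCH = "ARC")
  rows <- do.call(rbind, lapply(seq_along(cats), function(i) {
    cat_i <- cats[i]
    ids <- sprintf("%s%02d", prefix[cat_i], seq_len(n[i]))
    data.frame(taxon_id = ids,
               name = sprintf("%s reference strain %d", tolower(cat_i),
                              seq_len(n[i])),
               domain = unname(CATEGORY_DOMAIN[cat_i]),
               category = cat_i,
               stringsAsFactors = FALSE)
  }))
  # seed reserved for future stochastic naming; ids themselves are
  # deterministic so identical calls give identical panels
  rownames(rows) <- NULL
  structure(rows, class = c("taxon_set", "data.frame"), seed = seed)
}

#' Read / write a taxonomy table
#'
#' Tab-separated with columns `taxon_id`, `name`, `domain`, `category`.
#'
#' @param path file path.
#' @return `read_taxonomy`: a `taxon_set`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "domain", "category")
  if (!all(need %in% names(df)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (!"name" %in% names(df)) df$name <- df$taxon_id
  validate_taxonomy(df)
  structure(df[, c("taxon_id", "name", "domain", "category")],
            class = c("taxon_set", "data.frame"))
}

#' @rdname read_taxonomy
#' @param taxa a `taxon_set` to write.
#' @export
write_taxonomy <- function(taxa, path) {
  utils::write.table(as.data.frame(taxa), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_taxonomy <- function(df) {
  if (anyDuplicated(df$taxon_id)) stop("taxon_id values must be unique")
  known <- c(names(CATEGORIES), "FOCAL")
  bad <- setdiff(unique(df$category), known)
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = " "))
  ref <- df[df$category != "FOCAL", ]
  exp_dom <- CATEGORY_DOMAIN[ref$category]
  if (any(ref$domain != exp_dom))
    stop("category/domain mismatch for: ",
         paste(ref$taxon_id[ref$domain != exp_dom], collapse = " "))
  invisible(df)
}

# named category -> code lookup with FOCAL passthrough
category_code <- function(category) unname(CATEGORIES[category])
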