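#' Default thresholds for donor attribution
#'
#' `tau`: minimum neighbor-category share for a singleton code (0.75);
#' `k`: neighbor cap, nearest leaves by path distance (10);
#' `delta_mult`: multiple of the tree's median non-focal pendant branch
#' length above which the nearest neighbor is considered too distant and
#' the allele is called `NC` (5); `combo_min`: minimum share for a category
#' to enter a combination code (0.25); `nc_diameter_frac`: floor on the NC
#' cutoff as a fraction of the reference-leaf tree diameter (0.3), which
#' keeps the cutoff meaningful when many pendant branches collapse to
#' near-zero length.
#'
#' @return Named list of thresholds.
#' @export
donor_params <- function(tau = 0.75, k = 10L, delta_mult = 5,
                         combo_min = 0.25, nc_diameter_frac = 0.3) {
  stopifnot(tau > 0, tau <= 1, k >= 1L, delta_mult > 0,
            combo_min > 0, combo_min <= 1,
            nc_diameter_frac > 0, nc_diameter_frac < 1)
  list(tau = tau, k = k, delta_mult = delta_mult, combo_min = combo_min,
       nc_diameter_frac = nc_diameter_frac)
}

# leaf -> category lookup; FOCAL for focal alleles; error on unlabeled
leaf_categories <- function(tree, taxonomy, taxon_map = NULL) {
  labs <- tree$tip.label
  tax <- if (is.null(taxon_map)) labs else {
    mapped <- taxon_map[labs]
    ifelse(is.na(mapped), labs, mapped)
  }
  cat <- stats::setNames(taxonomy$category[match(tax, taxonomy$taxon_id)],
                         labs)
  cat[tax == "FOCAL"] <- "FOCAL"
  if (any(is.na(cat)))
    stop("unlabeled leaf (no taxonomy category): ",
         paste(labs[is.na(cat)], collapse = " "))
  cat
}

#' Attribute the donor category of one focal allele from its gene tree
#'
#' Implements the sister-clade attribution rule: (1) locate the focal
#' allele's pendant edge and attachment node; (2) among the subtrees
#' adjacent to the attachment node, select the one with the smallest mean
#' path distance to the focal leaf; (3) take that subtree's leaves (capped
#' at the `k` nearest by path distance, other focal alleles excluded) as
#' the neighbor set; (4) if the largest category share (purity) reaches
#' `tau`, emit that category's code, else the comma-joined combination of
#' all categories with share >= `combo_min` (alphabetical); (5) if even the
#' nearest neighbor lies further than `delta_mult` times the tree's median
#' pendant branch length, the allele forms no cluster and the call is `NC`,
#' overriding all else.
#'
#' @param tree inferred `phylo` for one COG.
#' @param taxonomy a `taxon_set` labelling every non-focal leaf.
#' @param focal_leaf leaf label of the allele to classify.
#' @param params thresholds from [donor_params()].
#' @param taxon_map optional leaf-label to taxon-id mapping (focal alleles
#'   map to `"FOCAL"`).
#' @param cog_id recorded in the output (default `NA`).
#' @return One-row data.frame (`cog_id`, `allele_id`, `code`,
#'   `neighbor_taxa`, `neighbor_purity`, `min_neighbor_distance`,
#'   `bacterial_share`, `archaeal_share`) with attribute `shares` (named
#'   per-category share vector).
#' @export
assign_donor <- function(tree, taxonomy, focal_leaf,
                         params = donor_params(), taxon_map = NULL,
                         cog_id = NA_character_) {
  labs <- tree$tip.label
  tipn <- match(focal_leaf, labs)
  if (is.na(tipn)) stop("focal leaf absent from tree: ", focal_leaf)
  cats <- leaf_categories(tree, taxonomy, taxon_map)
  ntip <- length(labs)

  dm <- ape::dist.nodes(tree)
  att <- tree$edge[tree$edge[, 2L] == tipn, 1L]
  desc <- tip_descendants(tree)

  # subtrees adjacent to the attachment node
  kid_edges <- which(tree$edge[, 1L] == att & tree$edge[, 2L] != tipn)
  subtrees <- lapply(tree$edge[kid_edges, 2L], function(nd) desc[[nd]])
  up <- setdiff(seq_len(ntip), c(desc[[att]], tipn))
  if (length(up)) subtrees <- c(subtrees, list(up))

  eligible <- lapply(subtrees, function(tips)
    tips[cats[labs[tips]] != "FOCAL"])
  eligible <- eligible[vapply(eligible, length, 1L) > 0L]
  if (!length(eligible))
    stop("no non-focal neighbors adjacent to ", focal_leaf)

  means <- vapply(eligible, function(tips) mean(dm[tipn, tips]), 0)
  sel <- eligible[[which.min(means)]]
  sel <- sel[order(dm[tipn, sel])]
  neigh <- sel[seq_len(min(params$k, length(sel)))]

  shares <- prop.table(table(factor(cats[labs[neigh]],
                                    levels = names(CATEGORIES))))
  shares <- stats::setNames(as.numeric(shares), names(CATEGORIES))
  purity <- max(shares)
  min_dist <- min(dm[tipn, neigh])

  # NC cutoff: multiple of the median reference pendant length, floored at
  # a fraction of the reference-leaf diameter (robust to collapsed
  # pendants)
  ref_tips <- which(cats[labs] != "FOCAL")
  pend_edges <- tree$edge[, 2L] %in% ref_tips
  pend <- tree$edge.length[pend_edges]
  diam <- max(dm[ref_tips, ref_tips])
  delta <- max(params$delta_mult * stats::median(pend),
               params$nc_diameter_frac * diam)

  if (min_dist > delta) {
    code <- "NC"
  } else if (purity >= params$tau) {
    code <- CATEGORIES[names(which.max(shares))]
  } else {
    in_combo <- names(shares)[shares >= params$combo_min]
    if (!length(in_combo)) in_combo <- names(which.max(shares))
    code <- paste(sort(unname(CATEGORIES[in_combo])), collapse = ",")
  }

  bact <- sum(shares[c("PROTEO", "OTHER_BACT")])
  arch <- sum(shares[c("THERMO_ARCH", "HALO_ARCH", "OTHER_ARCH")])
  out <- data.frame(
    cog_id = cog_id, allele_id = focal_leaf, code = unname(code),
    neighbor_taxa = paste(labs[neigh], collapse = ";"),
    neighbor_purity = purity, min_neighbor_distance = min_dist,
    bacterial_share = bact, archaeal_share = arch,
    stringsAsFactors = FALSE)
  attr(out, "shares") <- shares
  out
}

#' Attribute every focal allele of a COG tree
#'
#' @param tree inferred `phylo`.
#' @param taxonomy a `taxon_set`.
#' @param taxon_map leaf to taxon mapping (focal alleles map to `"FOCAL"`).
#' @param params thresholds from [donor_params()].
#' @param cog_id recorded on each call.
#' @return data.frame of [assign_donor()] rows, one per focal allele.
#' @export
assign_donors <- function(tree, taxonomy, taxon_map,
                          params = donor_params(),
                          cog_id = NA_character_) {
  cats <- leaf_categories(tree, taxonomy, taxon_map)
  focal <- names(cats)[cats == "FOCAL"]
  if (!length(focal)) stop("tree contains no focal alleles")
  do.call(rbind, lapply(focal, function(f)
    assign_donor(tree, taxonomy, f, params = params,
                 taxon_map = taxon_map, cog_id = cog_id)))
}

# summary class of one code string ("P", "B,T", "NC", ...)
summary_class <- function(code, bacterial_share = NA_real_,
                          archaeal_share = NA_real_) {
  if (code == "NC") return("no_cluster")
  parts <- strsplit(code, ",", fixed = TRUE)[[1L]]
  if (identical(parts, "P")) return("proteobacteria_vertical")
  bact <- parts %in% c("P", "B")
  arch <- parts %in% c("T", "HA", "A")
  if (any(!bact & !arch)) stop("unknown donor code: ", code)
  if (all(bact)) return("other_bacteria_hgt")
  if (all(arch)) return("archaea_hgt")
  # mixed bacterial-archaeal combination: majority neighbor share decides,
  # ties go to other-bacteria
  if (!is.na(bacterial_share) && !is.na(archaeal_share) &&
      archaeal_share > bacterial_share) return("archaea_hgt")
  if (is.na(bacterial_share) && sum(arch) > sum(bact)) return("archaea_hgt")
  "other_bacteria_hgt"
}

SUMMARY_CLASSES <- c("other_bacteria_hgt", "proteobacteria_vertical",
                     "archaea_hgt", "no_cluster")

#' Tally donor calls into summary classes
#'
#' Maps each call's code to one of four summary classes — other-bacteria
#' HGT (`B` and bacterial combinations), Proteobacteria vertical (`P`),
#' archaeal HGT (`T`/`HA`/`A` and archaeal combinations; mixed
#' bacterial-archaeal combinations go to the majority neighbor share, ties
#' to other-bacteria), and no cluster (`NC`) — and reports counts and
#' fractions.
#'
#' @param calls data.frame of donor calls with at least a `code` column
#'   (shares used when present).
#' @return A `category_tally`: data.frame (`class`, `count`, `fraction`)
#'   over the four classes, attribute `n_total`.
#' @export
tally_categories <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) stop("no donor calls to tally")
  bs <- if ("bacterial_share" %in% names(calls)) calls$bacterial_share
        else rep(NA_real_, nrow(calls))
  as_ <- if ("archaeal_share" %in% names(calls)) calls$archaeal_share
         else rep(NA_real_, nrow(calls))
  cls <- vapply(seq_len(nrow(calls)), function(i)
    summary_class(calls$code[i], bs[i], as_[i]), character(1L))
  counts <- table(factor(cls, levels = SUMMARY_CLASSES))
  out <- data.frame(class = SUMMARY_CLASSES,
                    count = as.integer(counts),
                    fraction = as.numeric(counts) / nrow(calls),
                    stringsAsFactors = FALSE)
  structure(out, class = c("category_tally", "data.frame"),
            n_total = nrow(calls))
}

#' Write donor calls / tallies
#'
#' Calls go to a tab-separated per-allele table (`cog_id`, `allele_id`,
#' `code`, `neighbor_purity`, `min_neighbor_distance`, `neighbor_taxa`);
#' tallies to CSV or JSON.
#'
#' @param calls data.frame of donor calls.
#' @param path output path.
#' @export
write_donor_calls <- function(calls, path) {
  cols <- c("cog_id", "allele_id", "code", "neighbor_purity",
            "min_neighbor_distance", "neighbor_taxa")
  utils::write.table(calls[, intersect(cols, names(calls))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_donor_calls
#' @param tally a `category_tally`.
#' @param format `"csv"` or `"json"`.
#' @export
write_tally <- function(tally, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(tally), path, row.names = FALSE)
  } else {
    obj <- list(n_total = attr(tally, "n_total"),
                counts = stats::setNames(as.list(tally$count), tally$class),
                fractions = stats::setNames(as.list(tally$fraction),
                                            tally$class))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
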