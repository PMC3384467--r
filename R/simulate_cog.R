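FOCAL_PREFIX <- "HBOL"

# largest-remainder allocation of n items to fractions (sums to n exactly)
allocate_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

# pure-birth clade over the given tip labels, scaled to the given depth
pb_clade <- function(tips, depth) {
  k <- length(tips)
  if (k == 1L) return(NULL)  # single tip: no subtree to graft
  tr <- ape::rphylo(k, birth = 1, death = 0)
  tr$tip.label <- tips
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (depth / h)
  tr
}

#' Simulate a clade-respecting reference species tree
#'
#' Taxa of each clade category form a monophyletic group, grafted as a
#' pure-birth (Yule) subtree onto a fixed backbone separating the bacterial
#' (Proteobacteria, other Bacteria) and archaeal (thermophilic, halophilic,
#' other) categories. Branch lengths are in expected substitutions per site.
#'
#' @param taxa a `taxon_set` (reference taxa only; `FOCAL` rows ignored).
#' @param seed integer seed.
#' @param clade_depth height of each within-category subtree (default 0.25).
#' @return An unrooted-interpretable `phylo` whose tips are taxon ids.
#' @export
simulate_species_tree <- function(taxa, seed = 1L, clade_depth = 0.25) {
  taxa <- taxa[taxa$category != "FOCAL", ]
  with_seed(seed, {
    backbone <- ape::read.tree(text = paste0(
      "((PROTEO:0.15,OTHER_BACT:0.15):0.3,",
      "(THERMO_ARCH:0.15,(HALO_ARCH:0.12,OTHER_ARCH:0.12):0.08):0.3);"))
    tr <- backbone
    for (cat_i in names(CATEGORIES)) {
      tips <- taxa$taxon_id[taxa$category == cat_i]
      if (!length(tips))
        stop("no taxa in category ", cat_i)
      clade <- pb_clade(tips, clade_depth)
      where <- which(tr$tip.label == cat_i)
      if (is.null(clade)) {
        tr$tip.label[where] <- tips
      } else {
        tr <- ape::bind.tree(tr, clade, where = where)
      }
    }
    tr
  })
}

# candidate attachment edges: edges whose descendant tips all belong to
# `category` (clade-internal, pendant and stem edges)
category_edges <- function(tree, taxa, category) {
  tipcat <- stats::setNames(taxa$category, taxa$taxon_id)
  ntip <- length(tree$tip.label)
  desc <- tip_descendants(tree)
  keep <- vapply(seq_len(nrow(tree$edge)), function(i) {
    tips <- desc[[tree$edge[i, 2L]]]
    isTRUE(all(tipcat[tree$tip.label[tips]] == category))
  }, logical(1L))
  which(keep)
}

# list: node -> integer vector of descendant tip indices
tip_descendants <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  tr <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; c <- tr$edge[i, 2L]
    out[[p]] <- c(out[[p]], out[[c]])
  }
  out
}

# attach a new pendant tip of length `len` at `position` along the edge
# subtending node `where` (position measured rootward from `where`)
bind_tip <- function(tree, label, len, where, position = 0) {
  tip <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                        tip.label = label, edge.length = len,
                        Nnode = 1L), class = "phylo")
  ape::bind.tree(tree, tip, where = where, position = position)
}

#' Simulate one COG alignment with planted ground truth
#'
#' Builds a clade-respecting species tree over the reference taxa, attaches
#' each focal allele either inside its planted donor clade (codes `P`, `B`,
#' `T`, `HA`, `A`) or, for `NC`, on a deliberately long pendant branch
#' (`orphan_mult` times the tree's median pendant length), evolves a root
#' sequence drawn from the model's equilibrium frequencies down the tree
#' site-independently via transition matrices `exp(Q t)`, and finally masks
#' a fraction of columns with gap symbols in randomly chosen sequences.
#'
#' @param taxa reference `taxon_set`; at least 4 taxa are required in each
#'   planted donor category.
#' @param cog_id identifier for the simulated COG.
#' @param planted_codes character vector of donor codes, one per focal
#'   allele (over `P`, `B`, `T`, `HA`, `A`, `NC`).
#' @param n_sites alignment length before masking (>= 1).
#' @param model a `subst_model` (default WAG with published frequencies).
#' @param gap_fraction fraction of columns receiving gap symbols, in `[0, 1)`.
#' @param seed integer seed; all randomness in the call flows from it.
#' @param clade_depth,pendant_range,orphan_mult tree-shape controls: height
#'   of within-category subtrees; range of the focal pendant branch length
#'   for planted HGT/vertical alleles; multiple of the median pendant length
#'   used for `NC` orphans.
#' @param taxon_dropout fraction of reference taxa randomly omitted from
#'   this COG (emulates partial taxon coverage across COGs), default 0.
#' @return List with elements `alignment` (a `cog_aln`), `tree` (the true
#'   `phylo`, including focal tips), and `truth` (data.frame: `cog_id`,
#'   `allele_id`, `planted_category`, `donor_taxon_ids`, `seed`).
#' @export
simulate_cog <- function(taxa, cog_id, planted_codes = "B", n_sites = 300L,
                         model = wag_model(), gap_fraction = 0.1, seed = 1L,
                         clade_depth = 0.25, pendant_range = c(0.02, 0.08),
                         orphan_mult = 6, taxon_dropout = 0) {
  stopifnot(n_sites >= 1L, gap_fraction >= 0, gap_fraction < 1,
            orphan_mult > 0, taxon_dropout >= 0, taxon_dropout < 1)
  taxa <- taxa[taxa$category != "FOCAL", ]
  code2cat <- stats::setNames(names(CATEGORIES), unname(CATEGORIES))
  bad <- setdiff(planted_codes, c(names(code2cat), "NC"))
  if (length(bad)) stop("unknown planted code: ", paste(bad, collapse = " "))

  with_seed(seed, {
    if (taxon_dropout > 0) {
      n_drop <- floor(taxon_dropout * nrow(taxa))
      if (n_drop > 0) {
        # never drop a donor category below 4 members
        drop_pool <- taxa$taxon_id
        dropped <- character(0)
        for (id in sample(drop_pool, n_drop)) {
          cat_i <- taxa$category[taxa$taxon_id == id]
          left <- sum(!taxa$taxon_id[taxa$category == cat_i] %in%
                        c(dropped, id))
          if (left >= 4L) dropped <- c(dropped, id)
        }
        taxa <- taxa[!taxa$taxon_id %in% dropped, ]
      }
    }
    for (code in setdiff(planted_codes, "NC")) {
      if (sum(taxa$category == code2cat[code]) < 4L)
        stop("fewer than 4 donor-clade taxa for planted code ", code)
    }

    tree <- simulate_species_tree(taxa, seed = sample.int(2^30, 1L),
                                  clade_depth = clade_depth)
    truth <- NULL
    for (a in seq_along(planted_codes)) {
      code <- planted_codes[a]
      allele_id <- sprintf("%s_A%d", FOCAL_PREFIX, a)
      if (code == "NC") {
        pend <- tree$edge.length[tree$edge[, 2L] <=
                                   length(tree$tip.label)]
        diam <- max(ape::dist.nodes(tree)[seq_along(tree$tip.label),
                                          seq_along(tree$tip.label)])
        # long enough to be unambiguous whatever the pendant distribution
        len <- max(orphan_mult * stats::median(pend), 0.5 * diam)
        e <- sample.int(nrow(tree$edge), 1L)
        pos <- stats::runif(1L, 0, tree$edge.length[e])
        donors <- NA_character_
      } else {
        cand <- category_edges(tree, taxa, code2cat[code])
        e <- if (length(cand) == 1L) cand else sample(cand, 1L)
        len <- stats::runif(1L, pendant_range[1L], pendant_range[2L])
        # attach near the lower end of the edge so the allele sits close
        # to an extant donor lineage
        pos <- stats::runif(1L, 0, 0.3 * tree$edge.length[e])
        donors <- paste(taxa$taxon_id[taxa$category == code2cat[code]],
                        collapse = ";")
      }
      where <- tree$edge[e, 2L]
      tree <- bind_tip(tree, allele_id, len, where, pos)
      truth <- rbind(truth, data.frame(
        cog_id = cog_id, allele_id = allele_id, planted_category = code,
        donor_taxon_ids = donors, seed = seed, stringsAsFactors = FALSE))
    }

    states <- evolve_sequences(tree, model, n_sites)
    mat <- matrix(AMINO_ACIDS[states], nrow = nrow(states),
                  dimnames = list(rownames(states), NULL))
    if (gap_fraction > 0) {
      n_mask <- floor(gap_fraction * n_sites)
      if (n_mask > 0) {
        cols <- sample.int(n_sites, n_mask)
        for (j in cols) {
          k <- sample.int(nrow(mat) - 1L, 1L)
          mat[sample.int(nrow(mat), k), j] <- "-"
        }
      }
    }
    tmap <- stats::setNames(rownames(mat), rownames(mat))
    tmap[truth$allele_id] <- "FOCAL"
    list(alignment = cog_alignment(cog_id, mat, taxon_map = tmap),
         tree = tree, truth = truth)
  })
}

# evolve integer state matrix (tips x sites) down a rooted phylo
evolve_sequences <- function(tree, model, n_sites) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  root <- ntip + 1L
  states <- matrix(NA_integer_, nnode, n_sites)
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = model$pi)
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; ch <- tr$edge[i, 2L]
    P <- prob_matrix(model, tr$edge.length[i])
    ps <- states[p, ]
    out <- integer(n_sites)
    for (s in unique(ps)) {
      idx <- which(ps == s)
      out[idx] <- sample.int(20L, length(idx), replace = TRUE,
                             prob = P[s, ])
    }
    states[ch, ] <- out
  }
  tips <- states[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- tr$tip.label
  tips
}

#' Simulate a batch of COGs with planted summary-class fractions
#'
#' Plants each COG's focal allele(s) according to a vector of summary-class
#' fractions (`proteobacteria` vertical, `other_bacteria` HGT, `archaea` HGT
#' split uniformly over the three archaeal categories, `no_cluster`).
#' Planting is either `"multinomial"` (classes drawn per allele) or
#' `"proportional"` (deterministic largest-remainder allocation of the exact
#' configured fractions, shuffled across COGs).
#'
#' @param taxa reference `taxon_set`.
#' @param n_cogs number of COGs.
#' @param class_fractions named fractions summing to 1 over
#'   `proteobacteria`, `other_bacteria`, `archaea`, `no_cluster`.
#' @param alleles_per_cog focal alleles per COG (default 1).
#' @param plant `"proportional"` or `"multinomial"`.
#' @param seed integer master seed; per-COG seeds are derived from it.
#' @param ... passed to [simulate_cog()].
#' @return List with `cogs` (list of [simulate_cog()] results) and `truth`
#'   (row-bound truth table).
#' @export
simulate_cog_set <- function(taxa, n_cogs,
                             class_fractions = c(proteobacteria = 0.34,
                                                 other_bacteria = 0.44,
                                                 archaea = 0.13,
                                                 no_cluster = 0.09),
                             alleles_per_cog = 1L,
                             plant = c("proportional", "multinomial"),
                             seed = 1L, ...) {
  plant <- match.arg(plant)
  need <- c("proteobacteria", "other_bacteria", "archaea", "no_cluster")
  if (!all(need %in% names(class_fractions)))
    stop("class_fractions must be named: ", paste(need, collapse = ", "))
  class_fractions <- class_fractions[need]
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  n_alleles <- n_cogs * alleles_per_cog
  class2code <- list(proteobacteria = "P", other_bacteria = "B",
                     archaea = c("T", "HA", "A"), no_cluster = "NC")
  codes <- with_seed(seed, {
    cls <- if (plant == "multinomial") {
      sample(need, n_alleles, replace = TRUE, prob = class_fractions)
    } else {
      sample(rep(need, allocate_counts(class_fractions, n_alleles)))
    }
    vapply(cls, function(cl) {
      pool <- class2code[[cl]]
      if (length(pool) == 1L) pool else sample(pool, 1L)
    }, character(1L))
  })
  seeds <- derive_seeds(seed, n_cogs)
  cogs <- vector("list", n_cogs)
  for (i in seq_len(n_cogs)) {
    idx <- ((i - 1L) * alleles_per_cog + 1L):(i * alleles_per_cog)
    cogs[[i]] <- simulate_cog(taxa, cog_id = sprintf("COG%04d", i),
                              planted_codes = codes[idx],
                              seed = seeds[i], ...)
  }
  truth <- do.call(rbind, lapply(cogs, `[[`, "truth"))
  list(cogs = cogs, truth = truth)
}

#' Write / read a simulation truth table
#'
#' Tab-separated: `cog_id`, `allele_id`, `planted_category`,
#' `donor_taxon_ids`, `seed`.
#'
#' @param truth truth data.frame as returned by [simulate_cog()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
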