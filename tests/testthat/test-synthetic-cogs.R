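test_that("taxonomy simulation honours requested counts and is deterministic", {
  req <- c(PROTEO = 2, OTHER_BACT = 2, THERMO_ARCH = 2, HALO_ARCH = 2,
           OTHER_ARCH = 2)
  tax <- simulate_taxonomy(req, seed = 1)
  expect_equal(nrow(tax), 10L)
  expect_equal(as.vector(table(tax$category)[names(req)]),
               unname(as.integer(req)))
  expect_false(anyDuplicated(tax$taxon_id) > 0)
  expect_identical(tax, simulate_taxonomy(req, seed = 1))
  # the reference panel scale: 59 bacteria + 41 archaea = 100 organisms
  panel <- simulate_taxonomy(c(PROTEO = 30, OTHER_BACT = 29,
                               THERMO_ARCH = 14, HALO_ARCH = 14,
                               OTHER_ARCH = 13), seed = 1)
  expect_equal(nrow(panel), 100L)
  expect_equal(sum(panel$domain == "Bacteria"), 59L)
  expect_equal(sum(panel$domain == "Archaea"), 41L)
  expect_error(simulate_taxonomy(c(PROTEO = 0, OTHER_BACT = 2,
                                   THERMO_ARCH = 2, HALO_ARCH = 2,
                                   OTHER_ARCH = 2)), "positive")
})

test_that("category/domain consistency is enforced on taxonomy IO", {
  tax <- small_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, path)
  back <- read_taxonomy(path)
  expect_equal(as.data.frame(back), as.data.frame(tax),
               ignore_attr = TRUE)
  bad <- tax; bad$domain[bad$category == "HALO_ARCH"] <- "Bacteria"
  write_taxonomy(bad, path)
  expect_error(read_taxonomy(path), "mismatch")
})

test_that("zero branch lengths give identical sequences", {
  tax <- small_panel()
  sim <- simulate_cog(tax, "C0", planted_codes = "B", n_sites = 50,
                      seed = 3, gap_fraction = 0)
  tr <- sim$tree
  tr$edge.length[] <- 0
  states <- cogevo:::evolve_sequences(tr, wag_model(), 40L)
  expect_true(all(apply(states, 2L, function(col) length(unique(col)) == 1L)))
})

test_that("planted donor clade contains the focal leaf's sisters", {
  tax <- small_panel()
  for (code in c("P", "B", "HA")) {
    sim <- simulate_cog(tax, "C1", planted_codes = code, n_sites = 10,
                        seed = 7, gap_fraction = 0)
    tr <- sim$tree
    tip <- which(tr$tip.label == "HBOL_A1")
    att <- tr$edge[tr$edge[, 2L] == tip, 1L]
    sisters <- setdiff(ape::extract.clade(tr, att)$tip.label, "HBOL_A1")
    cat_of <- stats::setNames(tax$category, tax$taxon_id)
    expect_true(all(cat_of[sisters] ==
                      names(which(CATEGORIES == code))),
                label = paste("sisters pure for code", code))
  }
})

test_that("NC alleles sit on a long pendant branch", {
  tax <- small_panel()
  sim <- simulate_cog(tax, "C2", planted_codes = "NC", n_sites = 10,
                      seed = 9, gap_fraction = 0, orphan_mult = 6)
  tr <- sim$tree
  tip <- which(tr$tip.label == "HBOL_A1")
  pend <- tr$edge.length[tr$edge[, 2L] <= length(tr$tip.label)]
  focal_len <- tr$edge.length[tr$edge[, 2L] == tip]
  expect_gte(focal_len, 5 * stats::median(pend[-tip]))
})

test_that("one-branch substitution fraction matches the analytic oracle", {
  model <- wag_model()
  t <- 1.0
  n_sites <- 10000L
  P <- prob_matrix(model, t)
  p_ident <- sum(model$pi * diag(P))      # analytic identity probability
  tr <- ape::read.tree(text = sprintf("(child:%g);", t))
  # evolve parent -> child directly
  set.seed(11)
  parent <- sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
  child <- vapply(parent, function(s)
    sample.int(20L, 1L, prob = P[s, ]), 1L)
  obs <- mean(parent == child)
  se <- sqrt(p_ident * (1 - p_ident) / n_sites)
  expect_lt(abs(obs - p_ident), 3 * se)
})

test_that("leaf state frequencies converge to pi on long branches", {
  model <- wag_model()
  P <- prob_matrix(model, 50)
  set.seed(13)
  n_sites <- 10000L
  root <- sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
  leaf <- vapply(root, function(s) sample.int(20L, 1L, prob = P[s, ]), 1L)
  counts <- tabulate(leaf, nbins = 20L)
  chi <- suppressWarnings(stats::chisq.test(counts, p = model$pi))
  expect_gt(chi$p.value, 0.01)
})

test_that("multinomial planting matches configured fractions within 3 SE", {
  tax <- small_panel()
  fr <- c(proteobacteria = 0.34, other_bacteria = 0.44, archaea = 0.13,
          no_cluster = 0.09)
  n <- 400L
  sim <- simulate_cog_set(tax, n, class_fractions = fr,
                          plant = "multinomial", seed = 5, n_sites = 5,
                          gap_fraction = 0)
  cls <- vapply(sim$truth$planted_category, cogevo:::planted_class, "")
  obs <- table(factor(cls, levels = c("proteobacteria_vertical",
                                      "other_bacteria_hgt", "archaea_hgt",
                                      "no_cluster"))) / n
  exp_fr <- fr[c("proteobacteria", "other_bacteria", "archaea",
                 "no_cluster")]
  se <- sqrt(exp_fr * (1 - exp_fr) / n)
  expect_true(all(abs(as.numeric(obs) - exp_fr) < 3 * se))
})

test_that("simulator rejects invalid inputs and is seed-deterministic", {
  tax <- small_panel()
  small <- tax[tax$category != "HALO_ARCH" |
                 tax$taxon_id %in% c("HAR01", "HAR02", "HAR03"), ]
  expect_error(simulate_cog(small, "C", planted_codes = "HA"),
               "fewer than 4")
  expect_error(simulate_cog(tax, "C", gap_fraction = 1), "gap_fraction")
  s1 <- simulate_cog(tax, "C", planted_codes = "T", n_sites = 60, seed = 21)
  s2 <- simulate_cog(tax, "C", planted_codes = "T", n_sites = 60, seed = 21)
  expect_identical(s1$alignment$mat, s2$alignment$mat)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("gap masking hits the configured fraction of columns", {
  tax <- small_panel()
  sim <- simulate_cog(tax, "C", planted_codes = "B", n_sites = 200,
                      seed = 2, gap_fraction = 0.25)
  gapped <- sum(apply(sim$alignment$mat, 2L, function(col) any(col == "-")))
  expect_equal(gapped, floor(0.25 * 200))
  expect_equal(n_columns(complete_deletion(sim$alignment)), 150L)
})
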