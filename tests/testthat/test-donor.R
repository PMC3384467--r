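toy_taxonomy <- function() {
  structure(data.frame(
    taxon_id = c("PRO01", "PRO02", "BAC01", "HAR01", "HAR02", "THA01"),
    name = "toy", domain = c("Bacteria", "Bacteria", "Bacteria",
                             "Archaea", "Archaea", "Archaea"),
    category = c("PROTEO", "PROTEO", "OTHER_BACT", "HALO_ARCH",
                 "HALO_ARCH", "THERMO_ARCH"),
    stringsAsFactors = FALSE), class = c("taxon_set", "data.frame"))
}

test_that("a focal allele sister to halophilic archaea is coded HA", {
  tax <- toy_taxonomy()
  tr <- ape::read.tree(text = paste0(
    "((PRO01:0.1,PRO02:0.1):0.2,(BAC01:0.15,THA01:0.2):0.1,",
    "((HAR01:0.05,HBOL_A1:0.05):0.05,HAR02:0.08):0.2);"))
  call <- assign_donor(tr, tax, "HBOL_A1",
                       taxon_map = c(HBOL_A1 = "FOCAL"))
  expect_equal(call$code, "HA")
  expect_equal(call$neighbor_purity, 1)
})

test_that("an over-long focal pendant triggers NC whatever the neighbors", {
  tax <- toy_taxonomy()
  tr <- ape::read.tree(text = paste0(
    "((PRO01:0.1,PRO02:0.1):0.2,(BAC01:0.15,THA01:0.2):0.1,",
    "((HAR01:0.05,HBOL_A1:1.5):0.05,HAR02:0.08):0.2);"))
  call <- assign_donor(tr, tax, "HBOL_A1",
                       taxon_map = c(HBOL_A1 = "FOCAL"))
  expect_equal(call$code, "NC")
})

test_that("mixed neighborhoods yield sorted combination codes", {
  tax <- toy_taxonomy()
  # focal sister subtree holds one bacterium and one thermophilic archaeon
  tr <- ape::read.tree(text = paste0(
    "((PRO01:0.1,PRO02:0.1):0.3,(HAR01:0.1,HAR02:0.1):0.3,",
    "((BAC01:0.05,THA01:0.05):0.02,HBOL_A1:0.05):0.3);"))
  call <- assign_donor(tr, tax, "HBOL_A1",
                       taxon_map = c(HBOL_A1 = "FOCAL"))
  expect_equal(call$code, "B,T")
  expect_equal(call$neighbor_purity, 0.5)
})

test_that("other focal alleles never vote as neighbors", {
  tax <- toy_taxonomy()
  # allele 1 nests in the halophilic clade, allele 2 in the Proteobacteria
  tr <- ape::read.tree(text = paste0(
    "((PRO01:0.1,(PRO02:0.08,HBOL_A2:0.08):0.04):0.2,",
    "(BAC01:0.15,THA01:0.2):0.1,",
    "(HBOL_A1:0.05,(HAR01:0.05,HAR02:0.05):0.03):0.2);"))
  tmap <- c(HBOL_A1 = "FOCAL", HBOL_A2 = "FOCAL")
  both <- assign_donors(tr, tax, tmap, cog_id = "C1")
  expect_equal(nrow(both), 2L)
  expect_equal(sort(both$code), c("HA", "P"))
  expect_false(any(grepl("HBOL", both$neighbor_taxa)))
  # a pure-focal sister subtree is skipped rather than voting
  tr2 <- ape::read.tree(text = paste0(
    "((PRO01:0.1,PRO02:0.1):0.2,(BAC01:0.15,THA01:0.2):0.1,",
    "((HBOL_A2:0.03,HBOL_A1:0.03):0.02,(HAR01:0.05,HAR02:0.05):0.03):0.2);"))
  call <- assign_donor(tr2, tax, "HBOL_A1", taxon_map = tmap)
  expect_false(grepl("HBOL_A2", call$neighbor_taxa))
})

test_that("unlabeled or absent leaves raise errors", {
  tax <- toy_taxonomy()
  tr <- ape::read.tree(
    text = "((PRO01:1,XX:1):1,(HAR01:1,HBOL_A1:1):1);")
  expect_error(assign_donor(tr, tax, "HBOL_A1",
                            taxon_map = c(HBOL_A1 = "FOCAL")),
               "unlabeled")
  tr2 <- ape::read.tree(
    text = "((PRO01:1,PRO02:1):1,(HAR01:1,HAR02:1):1);")
  expect_error(assign_donor(tr2, tax, "HBOL_A1"), "absent")
})

test_that("tallies map codes to the four summary classes", {
  calls <- data.frame(code = c("B", "P", "HA", "NC"))
  tl <- tally_categories(calls)
  expect_equal(tl$fraction, rep(0.25, 4))
  expect_equal(sum(tl$count), attr(tl, "n_total"))

  allp <- tally_categories(data.frame(code = rep("P", 7)))
  expect_equal(allp$fraction[allp$class == "proteobacteria_vertical"], 1)

  # combinations: bacterial, archaeal, and share-resolved mixed codes
  combo <- data.frame(code = c("B,P", "A,HA", "B,T", "B,T"),
                      bacterial_share = c(NA, NA, 0.3, 0.6),
                      archaeal_share = c(NA, NA, 0.7, 0.4))
  tc <- tally_categories(combo)
  expect_equal(tc$count[tc$class == "other_bacteria_hgt"], 2L)
  expect_equal(tc$count[tc$class == "archaea_hgt"], 2L)
})

test_that("random code tallies equal a counting oracle and sum to one", {
  set.seed(89)
  pool <- c("P", "B", "T", "HA", "A", "NC", "B,P", "A,T", "HA,T")
  codes <- sample(pool, 1000L, replace = TRUE)
  tl <- tally_categories(data.frame(code = codes))
  oracle <- table(vapply(codes, cogevo:::summary_class, ""))
  for (cl in tl$class)
    expect_equal(tl$count[tl$class == cl],
                 as.integer(oracle[cl]),
                 label = paste("count for", cl))
  expect_lt(abs(sum(tl$fraction) - 1), 1e-12)
  expect_error(tally_categories(data.frame(code = character(0))), "no donor")
})
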