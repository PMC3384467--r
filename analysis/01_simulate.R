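#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with planted ground truth —
# a 30-taxon reference panel (6 organisms per clade category), 160
# single-allele COG alignments with donor classes planted at the study
# fractions (44% other bacteria, 34% Proteobacteria, 13% archaea, 9% no
# cluster), plus three partial-coverage COG sets for the supernetwork
# escalation. Large artifacts go to scratch/analysis; a compact summary
# goes to results/.

suppressMessages(library(cogevo))
seed <- 11L
data_dir <- "scratch/analysis"
dir.create(file.path(data_dir, "alignments"), recursive = TRUE,
           showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

taxa <- simulate_taxonomy(c(PROTEO = 6, OTHER_BACT = 6, THERMO_ARCH = 6,
                            HALO_ARCH = 6, OTHER_ARCH = 6), seed = seed)
write_taxonomy(taxa, file.path(data_dir, "taxonomy.tsv"))
message("reference panel: ", nrow(taxa), " taxa in ",
        length(unique(taxa$category)), " clade categories")

sim <- simulate_cog_set(taxa, n_cogs = 160,
                        class_fractions = c(proteobacteria = 0.34,
                                            other_bacteria = 0.44,
                                            archaea = 0.13,
                                            no_cluster = 0.09),
                        plant = "proportional", seed = seed,
                        n_sites = 300, gap_fraction = 0.1)
write_truth(sim$truth, file.path(data_dir, "truth.tsv"))
for (cg in sim$cogs) {
  write_cog_fasta(cg$alignment, file.path(
    data_dir, "alignments", paste0(cg$alignment$cog_id, ".fasta")))
  ape::write.tree(cg$tree, file.path(
    data_dir, "alignments", paste0(cg$alignment$cog_id, ".true.nwk")))
}
planted <- table(sim$truth$planted_category)
message("planted donor codes: ",
        paste(names(planted), planted, sep = "=", collapse = " "))

# partial-coverage COG sets for the supernetwork escalation (3/6/22 trees),
# mirroring gene sets with incomplete taxon sampling
dir.create(file.path(data_dir, "supernet"), showWarnings = FALSE)
sn_seeds <- 9000L + seq_len(22L)
for (i in seq_len(22L)) {
  cg <- simulate_cog(taxa, cog_id = sprintf("SN%02d", i),
                     planted_codes = sample(c("P", "B", "T", "HA", "A"),
                                            1L),
                     n_sites = 300, seed = sn_seeds[i],
                     gap_fraction = 0.1, taxon_dropout = 0.2)
  write_cog_fasta(cg$alignment, file.path(
    data_dir, "supernet", paste0("SN", sprintf("%02d", i), ".fasta")))
}

utils::write.csv(data.frame(
  n_taxa = nrow(taxa), n_cogs = 160, n_sites = 300,
  n_supernet_cogs = 22,
  planted_other_bacteria = sum(sim$truth$planted_category == "B"),
  planted_proteobacteria = sum(sim$truth$planted_category == "P"),
  planted_archaea = sum(sim$truth$planted_category %in%
                          c("T", "HA", "A")),
  planted_no_cluster = sum(sim$truth$planted_category == "NC")),
  "results/simulation_summary.csv", row.names = FALSE)
message("wrote results/simulation_summary.csv")
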