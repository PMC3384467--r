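#!/usr/bin/env Rscript
# Stage 6: genome summary statistics of a synthetic chromosome drawn at
# the study organism's scale (G+C target 54.69%), and the acidic/basic
# residue screen over proteins emulating halophilic composition.

suppressMessages(library(cogevo))
data_dir <- "scratch/analysis"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

# a scaled-down chromosome (400 kb) at the published G+C content
g <- simulate_genome(400000L, 360L, gc_target = 0.5469, seed = 11)
write_genome_fasta(g$sequence, file.path(data_dir, "genome.fasta"))
write_gene_table(g$annotation, file.path(data_dir, "genes.tsv"))
st <- occupancy(g$annotation, g$sequence)
print(st)
write_genome_stats(st, "results/genome_stats.csv")

# composition screen: one acidic-enriched allele (halophilic signature),
# one moderate allele, one neutral reference
fa <- file.path(data_dir, "proteins.fasta")
ss <- Biostrings::AAStringSet(c(
  allele1_halophilic = simulate_halophilic_protein(
    1000L, acidic_percent = 10.1, basic_percent = 3.5, seed = 21),
  allele2_moderate = simulate_halophilic_protein(
    1000L, acidic_percent = 9.4, basic_percent = 5.5, seed = 22),
  reference_neutral = simulate_halophilic_protein(
    1000L, acidic_percent = 5.9, basic_percent = 5.9, seed = 23)))
Biostrings::writeXStringSet(ss, fa)
comp <- composition_screen(fa, out_csv = "results/composition.csv")
message("acidic/basic ratios:")
for (i in seq_len(nrow(comp)))
  message(sprintf("  %-20s acidic %.1f%%  basic %.1f%%  ratio %.1f",
                  comp$id[i], comp$acidic_percent[i],
                  comp$basic_percent[i], comp$ratio[i]))
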