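# cogevo

Evolutionary attribution of carbohydrate transport and metabolism genes
in a halophilic, PHB-producing bacterium — as a tested, reproducible R
pipeline.

## The problem

Comparative analyses of halophile genomes repeatedly find that large
parts of the carbohydrate uptake and metabolism repertoire were not
inherited vertically but acquired by horizontal gene transfer (HGT) from
other bacteria and, strikingly, from thermophilic and halophilic archaea
sharing the same habitats. The published evidence for such claims is a
collection of per-gene-family (COG) protein trees in which the study
organism's alleles nest inside foreign clades — read by eye. `cogevo`
turns that reading into an explicit algorithm and measures how well it
works on data with planted ground truth:

* **WAG+F maximum-likelihood protein phylogenetics** — complete deletion
  of gapped/missing columns, empirical amino-acid frequencies, ML
  pairwise distances, neighbor-joining start trees, NNI hill-climbing
  under a Felsenstein pruning likelihood with per-pattern rescaling.
* **Sister-clade donor attribution** — for each focal allele, the
  adjacent subtree with the smallest mean path distance votes; purity
  `tau = 0.75` yields a singleton category code (`P` Proteobacteria,
  `B` other bacteria, `T` thermophilic, `HA` halophilic, `A` other
  archaea), mixed neighborhoods yield combination codes, and alleles
  whose nearest neighbor exceeds a no-cluster cutoff are `NC`.
* **Category tallies and pathway polymorphism** — the fraction of genes
  per summary class (other-bacteria HGT / Proteobacteria vertical /
  archaeal HGT / no cluster) and per-enzymatic-step allele annotations
  (`"2: B,P"`) for the starch-sucrose and glycolysis maps.
* **Z-closure split supernetworks** — partial splits harvested from gene
  trees, extended to the full taxon set by the Z-closure rule,
  compatibility diagnostics (incompatible split pairs = reticulation),
  NEXUS export for split-network viewers.
* **Genome statistics, composition screen, fermentation metrics** —
  occupancy/G+C summaries with exact gene + intergenic conservation, the
  acidic:basic residue ratio used to argue halophilic protein character,
  and batch-culture PHB metrics (RCM = CDW − PHB, content wt%,
  volumetric productivity) over a two-substrate diauxic culture model.
* **A synthetic-data generator** — clade-respecting species trees,
  planted HGT donors or deliberately unattached (`NC`) alleles, sequence
  evolution under the exact inference model, gap masking, taxon dropout,
  synthetic genomes and culture series. Every benchmark number the
  package reports is measured against what the generator planted.

## Worked example

```r
library(cogevo)

# a 30-taxon reference panel, 6 organisms per clade category
taxa <- simulate_taxonomy(c(PROTEO = 6, OTHER_BACT = 6, THERMO_ARCH = 6,
                            HALO_ARCH = 6, OTHER_ARCH = 6), seed = 1)

# one COG whose focal allele was planted inside the halophilic archaea
sim <- simulate_cog(taxa, "COG0001", planted_codes = "HA",
                    n_sites = 300, seed = 42)
aln <- complete_deletion(sim$alignment)   # 270 of 300 columns survive

# infer the WAG+F tree and attribute the allele
tree <- infer_cog_tree(aln, nni_rounds = 1)
assign_donor(tree, taxa, "HBOL_A1", taxon_map = aln$taxon_map,
             cog_id = "COG0001")
#>    cog_id allele_id code ... neighbor_purity min_neighbor_distance
#> 1 COG0001   HBOL_A1   HA               1.00                 0.300
```

The allele is recovered as halophilic-archaeal HGT: its neighbor set is
purely `HALO_ARCH` (purity 1.00) at a path distance far below the
no-cluster cutoff. The same machinery scaled up (`run_pipeline()`, 160
COGs planted at 44% other-bacteria / 34% Proteobacteria / 13% archaea /
9% no-cluster) recovers each summary-class fraction within ±0.08 and
reports per-allele accuracy against the planted truth.

The fermentation side in one line:

```r
compute_metrics(simulate_batch_culture())
#> PHB max 4.36 g/L, max content 48.7 wt%, productivity 0.132 g/L/h
```

## Analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the full
study on synthetic data, writing compact tables to `results/` and bulky
artifacts to `scratch/` (not part of the deliverable):

| script | what it does |
|---|---|
| `01_simulate.R` | reference panel, 160 planted COG alignments, supernetwork gene sets |
| `02_infer_trees.R` | WAG+F trees for every COG |
| `03_donor_attribution.R` | donor calls, summary tally, accuracy vs truth |
| `04_pathway_polymorphism.R` | per-step allele counts and donor codes |
| `05_supernetworks.R` | Z-closure supernetworks from 3 / 6 / 22 trees |
| `06_genome_composition.R` | genome occupancy/G+C table, acid:base screen |
| `07_fermentation.R` | batch-culture series and PHB metrics |

Run them in order from the package root:
`Rscript analysis/01_simulate.R`, etc.

## Vignette

`vignettes/cog-hgt-attribution.Rmd` documents the model and search
strategy, every attribution threshold and its default, what the
synthetic generator does and does not emulate (and hence what passing
benchmarks do and do not show about real data), the numerical safeguards,
and known limitations.
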