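#!/usr/bin/env Rscript
## Build the synthetic study world: a growth-capable toy pan metabolic
## network, a species tree, and a gene existence matrix with planted
## trait gains/losses and a downstream-pathway deletion.  All later
## steps consume the artefacts written here.

library(gemevo)
seed <- 1
out <- "results/world"

world <- generate_pan_network(n_substrates = 3, n_species = 16,
                              complex_fraction = 0.3,
                              isozyme_fraction = 0.3, seed = seed)
write_world(world, out)

cat("pan-network:", length(world$pan$reactions), "reactions,",
    nrow(world$pan$metabolites), "metabolites,",
    length(world$pan$gene_ids), "ortholog groups\n")
cat("species:", nrow(world$existence),
    "| complete:", world$truth$complete_species,
    "| downstream-gap species:", world$truth$dgap_species, "\n")
cat("planted per-trait causal reactions:",
    paste(names(world$truth$trait_causal_reaction),
          world$truth$trait_causal_reaction, sep = "=", collapse = ", "),
    "\n")
cat("artefacts written to", out, "\n")
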