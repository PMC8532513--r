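#!/usr/bin/env Rscript
## Derive species-specific models (ssGEMs) from the pan-model via GPR
## evaluation, classify core/accessory reactions, compute model
## similarity (Hamming), and score substrate-utilization predictions
## against a noisy "experimental" trait table.

library(gemevo)
seed <- 1

world <- generate_pan_network(3, 16, 0.3, 0.3, seed = seed)
models <- derive_world_models(world)
media <- minimal_media(world$pan)

rxn_exist <- reaction_existence_matrix(models, world$pan)
write_matrix_tsv(rxn_exist, "results/reaction_existence.tsv")

cc <- classify_core_accessory(models)
cat("core reactions:", length(cc$core),
    "| accessory:", length(cc$accessory), "\n")

D <- reaction_hamming(rxn_exist)
write_matrix_tsv(D, "results/model_hamming.tsv")
cat("max pairwise Hamming distance:", max(D), "\n")

pred <- generate_trait_table(world, 0, 0, seed = seed + 1,
                             models = models)
obs <- generate_trait_table(world, 0.05, 0.02, seed = seed + 2,
                            models = models)
write_matrix_tsv(pred, "results/traits_predicted.tsv")
write_matrix_tsv(obs, "results/traits_observed.tsv")

keep <- !is.na(obs)
ct <- list(TP = sum(pred == 1 & obs == 1, na.rm = TRUE),
           TN = sum(pred == 0 & obs == 0, na.rm = TRUE),
           FP = sum(pred == 1 & obs == 0, na.rm = TRUE),
           FN = sum(pred == 0 & obs == 1, na.rm = TRUE))
m <- confusion_metrics(ct)
cat(sprintf("substrate prediction vs noisy observations: accuracy %.3f over %d cells\n",
            m[["accuracy"]], sum(keep)))

ess <- single_gene_deletions(models[[world$truth$complete_species]],
                             media)
cat("essential genes in the complete species:",
    paste(names(ess)[ess == "essential"], collapse = ", "), "\n")
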