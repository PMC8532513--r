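#!/usr/bin/env Rscript
## Horizontal gene transfer screening: Alien Index + out-group
## percentage for distant (non-fungal) donors, and the three-filter
## bitscore screen for close (fungal) donors, on a hit table with
## planted transfers.

library(gemevo)
seed <- 1

ht <- generate_hit_table(n_genes = 60, n_hgt_distant = 6,
                         n_hgt_close = 6, seed = seed)
write_hit_table(ht$table, "results/blast_hits.tsv")

dist <- screen_distant(ht$table)
close <- screen_close(ht$table)
write.table(dist, "results/hgt_distant.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(close, "results/hgt_close.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

called_d <- dist$gene_id[dist$screen == "distant"]
called_c <- close$gene_id[close$screen == "close"]
cat("distant screen: called", length(called_d), "of",
    length(ht$distant_genes), "planted;",
    "exact recovery:", setequal(called_d, ht$distant_genes), "\n")
cat("close screen: called", length(called_c), "of",
    length(ht$close_genes), "planted;",
    "exact recovery:", setequal(called_c, ht$close_genes), "\n")
cat(sprintf("analytic check: AI(1e-10, 1e-50) = %.3f (40 ln 10 = %.3f)\n",
            alien_index(1e-10, 1e-50), 40 * log(10)))
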