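test_that("generator parameters are validated", {
  expect_error(generate_pan_network(2, 8), "n_substrates")
  expect_error(generate_pan_network(3, 2), "n_species")
  expect_error(generate_pan_network(3, 8, 1.5, 0), "fractions")
  expect_error(generate_trait_table(world_fixture()$world, 0.7),
               "flip_rate")
  expect_error(generate_hit_table(3, 2, 2), "exceed")
  expect_error(generate_sequences(5, 20, 0.1), "length")
  expect_error(generate_sequences(5, 100, 0.5), "shift")
  expect_error(generate_structure_alignment(6, 40, 3), "length")
  expect_error(generate_structure_alignment(6, 60, 20), "length/4")
})

test_that("worlds carry the promised network motifs", {
  w <- world_fixture()$world
  pan <- w$pan
  ## an AND-complex of >= 3 subunits
  cx <- Filter(function(r) !is.null(r$gpr) && r$gpr$kind == "and" &&
                 length(gpr_genes(r$gpr)) >= 3, pan$reactions)
  expect_gte(length(cx), 1)
  ## an OR-isozyme reaction
  iso <- Filter(function(r) !is.null(r$gpr) && r$gpr$kind == "or",
                pan$reactions)
  expect_gte(length(iso), 1)
  ## a promiscuous ortholog in >= 2 GPRs
  expect_true(w$truth$promiscuous_gene %in% promiscuous_orthologs(pan))
  ## exchanges for substrates, oxygen analogue and biomass
  for (ex in c("EX_S1", "EX_S2", "EX_S3", "EX_O2", "EX_BIO"))
    expect_true(ex %in% reaction_ids(pan))
  ## every existence-matrix ortholog appears in some GPR
  expect_true(all(colnames(w$existence) %in% model_genes(pan)))
  ## tree tips match species
  expect_setequal(w$tree$tip.label, rownames(w$existence))
})

test_that("the complete species grows on every substrate", {
  w <- world_fixture()
  full <- w$models[[w$world$truth$complete_species]]
  for (ex in w$world$truth$trait_substrate_exchange)
    expect_true(test_substrate_utilization(full, ex))
})

test_that("downstream knockout removes exactly the dependent traits", {
  w <- world_fixture()
  full <- w$models[[w$world$truth$complete_species]]
  ko <- drop_reactions(full, w$world$truth$downstream_reaction)
  lost <- names(Filter(isFALSE, sapply(
    w$world$truth$trait_substrate_exchange,
    function(ex) test_substrate_utilization(ko, ex))))
  expect_setequal(lost, w$world$truth$downstream_dependent_traits)
})

test_that("every trait has both gain and loss events on the tree", {
  w <- world_fixture()
  for (tr in colnames(w$traits)) {
    anc_p <- w$world$truth$ancestral_posterior[[tr]]
    root_state <- as.integer(anc_p >= 0.5)
    vals <- w$traits[, tr]
    ## both states realised among extant species, and at least one
    ## species differs from the root state in each direction across
    ## the trait's history (gain clade + loss clade by construction)
    expect_setequal(unique(vals), c(0L, 1L))
    changes <- classify_trait_changes(w$traits,
                                      w$world$truth$ancestral_posterior)
    if (root_state == 1) expect_true(any(changes[, tr] == "loss"))
    else expect_true(any(changes[, tr] == "gain"))
  }
})

test_that("regeneration under the same seed is byte-identical", {
  w1 <- generate_pan_network(3, 12, 0.3, 0.3, seed = 5)
  w2 <- generate_pan_network(3, 12, 0.3, 0.3, seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  write_world(w1, d1); write_world(w2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  w3 <- generate_pan_network(3, 12, 0.3, 0.3, seed = 6)
  expect_false(identical(w1$existence, w3$existence))
})

test_that("noiseless trait tables equal the simulated ground truth", {
  w <- world_fixture()
  expect_identical(w$traits + 0L,
                   w$world$truth$expected_traits + 0L)
})

test_that("flip rates land within binomial error", {
  w <- world_fixture()
  clean <- w$traits
  flipped <- generate_trait_table(w$world, flip_rate = 0.1, seed = 7,
                                  models = w$models)
  n <- length(clean)
  obs <- mean(flipped != clean)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(obs - 0.1), 3 * se)
  ## NA masking
  masked <- generate_trait_table(w$world, 0, na_rate = 0.25, seed = 8,
                                 models = w$models)
  expect_gt(mean(is.na(masked)), 0.1)
  expect_lt(mean(is.na(masked)), 0.4)
})

test_that("hit tables are deterministic and honour their contracts", {
  h1 <- generate_hit_table(30, 3, 3, seed = 9)
  h2 <- generate_hit_table(30, 3, 3, seed = 9)
  expect_identical(h1, h2)
  tab <- h1$table
  ## no-hit lineages are absent rows, not sentinels
  expect_true(all(tab$evalue > 0))
  ## distant plants: outside best at least e^45 below any group hit
  for (g in h1$distant_genes) {
    h <- tab[tab$gene_id == g, ]
    bbhG <- min(h$evalue[h$taxonomy_class == "group_lineage"])
    bbhO <- min(h$evalue[h$taxonomy_class == "outside_group"])
    expect_gte(log(bbhG) - log(bbhO), 45)
    nonrec <- h[h$taxonomy_class != "recipient_subphylum", ]
    expect_gte(mean(nonrec$taxonomy_class == "outside_group"), 0.9)
  }
  for (g in h1$close_genes) {
    h <- tab[tab$gene_id == g, ]
    bg <- max(h$bitscore[h$taxonomy_class == "group_lineage"])
    br <- max(h$bitscore[h$taxonomy_class == "recipient_subphylum"])
    expect_gte(bg, 100)
    expect_gte(bg / br, 0.5)
  }
})

test_that("sequence records stay on the ACGT alphabet", {
  gs <- generate_sequences(20, 90, 0.2, seed = 10)
  expect_true(all(grepl("^[ACGT]+$", gs$sequences)))
  expect_true(all(nchar(gs$sequences) == 90))
  expect_identical(gs$sequences,
                   generate_sequences(20, 90, 0.2, seed = 10)$sequences)
  ## planted class gap in evolution features survives extraction
  expect_lt(mean(gs$evo$dn_ds[gs$labels == 1]),
            mean(gs$evo$dn_ds[gs$labels == 0]))
})

test_that("zero shift carries no sequence signal", {
  gs <- generate_sequences(150, 150, 0, seed = 11)
  X <- t(vapply(gs$sequences, kmer3, numeric(64)))
  auc <- ml_evaluate(X, gs$labels, "rf", seed = 12)$auc
  n_test <- ml_evaluate(X, gs$labels, "rf", seed = 12)$n_test
  se <- sqrt((n_test + 1) / (12 * (n_test / 2)^2))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("structures separate the planted cluster from function", {
  st <- generate_structure_alignment(10, 80, 4, seed = 13)
  X <- st$structure$coords
  ## consecutive Calpha spacing matches the helix geometry (~3.8 A),
  ## except at the segment boundary
  half <- floor(80 / 2)
  d <- sqrt(rowSums((X[-1, ] - X[-nrow(X), ])^2))
  expect_true(all(abs(d[-half] - d[1]) < 1e-6))
  ## every cluster site has a cluster neighbour within 6 A
  for (s in st$fast_sites) {
    others <- setdiff(st$fast_sites, s)
    dd <- sqrt(colSums((t(X[others, , drop = FALSE]) - X[s, ])^2))
    expect_lt(min(dd), 6)
  }
  ## the cluster spans sequence-distant residues
  expect_gte(max(st$fast_sites) - min(st$fast_sites), 10)
  ## functional sites are >= 10 A away from every cluster site
  dd <- distance_to_functional_sites(st$fast_sites, st$structure)
  expect_true(all(dd$min_distance >= 10))
  ## functional columns are invariant in the alignment
  M <- do.call(rbind, strsplit(st$block$seqs, ""))
  for (j in st$functional_sites)
    expect_length(unique(M[, j]), 1)
  ## planted dN/dS marks exactly the fast sites above 1
  expect_setequal(st$dnds$ref_pos[st$dnds$dn_ds > 1], st$fast_sites)
})
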