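#' @title Synthetic pan-network worlds with planted ground truth
#' @description
#' Generates a growth-capable toy pan metabolic network plus a species
#' tree and a gene existence matrix in which every downstream analysis
#' has a known answer: per-trait causal transporter genes gained and
#' lost on tree clades, a "downstream pathway" reaction (gluconeogenesis
#' analogue) whose loss removes several substrate traits at once, an
#' enzyme complex, an isozyme pair, a promiscuous ortholog, and
#' enzyme-constraint parameter sets for flux-control analyses.
#' @name synthetic_world
NULL

#' Generate a synthetic pan-network world
#'
#' The network has one catabolic branch per substrate (transporter
#' `T<i>` gated by the trait-causal ortholog `OGT<i>`, catabolic step
#' `B<i>`) feeding a shared central chain (glycolysis analogue `GLY`
#' with an isozyme pair, precursor syntheses, a three-subunit complex on
#' `PGS`, respiration/fermentation ATP branches) that ends in a biomass
#' reaction.  Substrate 1 enters above the `GLY` node; all other
#' substrates enter below it and additionally require the
#' gluconeogenesis-analogue `GNG` ("downstream pathway" reaction, gene
#' `OGD`), which sits on no catabolic branch.  The existence matrix is
#' built by gaining/losing each trait-causal ortholog on nested tree
#' clades (one gain and one loss event per trait), one designated
#' species loses only `GNG`, and one species is complete.
#'
#' @param n_substrates number of substrates/traits (>= 3).
#' @param n_species number of species (>= 4; >= 8 recommended so that
#'   planted correlations separate cleanly).
#' @param complex_fraction,isozyme_fraction fractions in [0,1] of the
#'   decorable catabolic steps that receive an AND-complex / an
#'   OR-isozyme rule.
#' @param seed integer seed; everything is deterministic given it.
#' @return object of class `synthetic_world`: `pan` (a `gem`),
#'   `existence` (species x ortholog 0/1 matrix), `tree` (ape phylo),
#'   `ec` and `ec_single` (kcat/mw/pool parameter sets), and `truth`
#'   (planted answer key).
#' @export
generate_pan_network <- function(n_substrates = 3, n_species = 16,
                                 complex_fraction = 0.3,
                                 isozyme_fraction = 0.3, seed = 1) {
  if (n_substrates < 3) stop("generate_pan_network: n_substrates must be >= 3")
  if (n_species < 4) stop("generate_pan_network: n_species must be >= 4")
  if (complex_fraction < 0 || complex_fraction > 1 ||
      isozyme_fraction < 0 || isozyme_fraction > 1)
    stop("generate_pan_network: fractions must lie in [0, 1]")

  .with_seed(seed, {
    pan <- .build_pan(n_substrates, complex_fraction, isozyme_fraction)
    sol <- .plant_existence(pan, n_substrates, n_species, seed)
    .assemble_world(pan, sol, n_substrates)
  })
}

## ---------------------------------------------------------------- network

.build_pan <- function(k, complex_fraction, isozyme_fraction) {
  met <- function(id, name, comp) data.frame(id = id, name = name,
                                             compartment = comp)
  mets <- rbind(
    do.call(rbind, lapply(seq_len(k), function(i) rbind(
      met(sprintf("S%d_e", i), sprintf("substrate %d (external)", i), "e"),
      met(sprintf("S%d_c", i), sprintf("substrate %d", i), "c")))),
    met("O2_e", "oxygen analogue (external)", "e"),
    met("O2_c", "oxygen analogue", "c"),
    met("NH4_e", "ammonia analogue (external)", "e"),
    met("NH4_c", "ammonia analogue", "c"),
    met("ETH_e", "fermentation product (external)", "e"),
    met("ETH_c", "fermentation product", "c"),
    met("G_c", "hexose phosphate analogue", "c"),
    met("C_c", "central carbon intermediate", "c"),
    met("ATP_c", "energy carrier", "c"),
    met("PG_c", "G-derived biomass precursor", "c"),
    met("PC_c", "C-derived biomass precursor", "c"),
    met("PN_c", "N-containing biomass precursor", "c"),
    met("BIO_c", "biomass", "c"))

  rxn <- function(id, stoich, lb, ub, gpr = NULL, subsystem = "") {
    list(id = id, stoich = stoich, lb = lb, ub = ub,
         gpr = if (is.character(gpr)) parse_gpr(gpr) else gpr,
         subsystem = subsystem)
  }
  rxns <- list()
  add <- function(r) rxns[[r$id]] <<- r

  for (i in seq_len(k)) {
    se <- sprintf("S%d_e", i); sc <- sprintf("S%d_c", i)
    add(rxn(sprintf("EX_S%d", i), stats::setNames(-1, se),
            0, 1000, subsystem = "exchange"))
    add(rxn(sprintf("T%d", i),
            stats::setNames(c(-1, 1), c(se, sc)),
            0, 1000, sprintf("OGT%d", i), "transport"))
  }
  ## catabolic steps; substrate 1 enters above GLY, the rest below it.
  ## B2/B3 share the promiscuous ortholog OGPROM; remaining steps are
  ## decorated as complexes/isozymes according to the fractions.
  decorable <- setdiff(seq_len(k), c(2L, 3L))
  n_cx <- round(complex_fraction * length(decorable))
  n_iso <- min(round(isozyme_fraction * length(decorable)),
               length(decorable) - n_cx)
  deco <- rep("single", length(decorable))
  if (length(decorable)) {
    pick <- sample(seq_along(decorable))
    if (n_cx > 0) deco[pick[seq_len(n_cx)]] <- "complex"
    if (n_iso > 0) deco[pick[n_cx + seq_len(n_iso)]] <- "isozyme"
  }
  for (t in seq_along(decorable)) {
    i <- decorable[t]
    gpr <- switch(deco[t],
      single = sprintf("OGB%d", i),
      complex = sprintf("OGB%da and OGB%db and OGB%dc", i, i, i),
      isozyme = sprintf("OGB%d or OGB%dalt", i, i))
    prod <- if (i == 1) "G_c" else "C_c"
    add(rxn(sprintf("B%d", i),
            stats::setNames(c(-1, 1), c(sprintf("S%d_c", i), prod)),
            0, 1000, gpr, "catabolism"))
  }
  for (i in intersect(c(2L, 3L), seq_len(k))) {
    add(rxn(sprintf("B%d", i),
            stats::setNames(c(-1, 1), c(sprintf("S%d_c", i), "C_c")),
            0, 1000, "OGPROM", "catabolism"))
  }

  add(rxn("EX_O2", stats::setNames(-1, "O2_e"), 0, 1000,
          subsystem = "exchange"))
  add(rxn("TO2", stats::setNames(c(-1, 1), c("O2_e", "O2_c")),
          0, 1000, subsystem = "transport"))
  add(rxn("EX_NH4", stats::setNames(-1, "NH4_e"), 0, 1000,
          subsystem = "exchange"))
  add(rxn("TNH4", stats::setNames(c(-1, 1), c("NH4_e", "NH4_c")),
          0, 1000, subsystem = "transport"))
  add(rxn("EX_ETH", stats::setNames(-1, "ETH_e"), 0, 1000,
          subsystem = "exchange"))
  add(rxn("TETH", stats::setNames(c(-1, 1), c("ETH_c", "ETH_e")),
          0, 1000, subsystem = "transport"))

  ## central chain
  add(rxn("GLY", stats::setNames(c(-1, 1, 1), c("G_c", "C_c", "ATP_c")),
          0, 1000, "OGI1 or OGI2", "glycolysis"))
  add(rxn("GNG", stats::setNames(c(-1, -1, 1), c("C_c", "ATP_c", "G_c")),
          0, 1000, "OGD", "gluconeogenesis"))
  add(rxn("RESP", stats::setNames(c(-1, -1, 3), c("C_c", "O2_c", "ATP_c")),
          0, 1000, "OGR", "respiration"))
  add(rxn("FERM", stats::setNames(c(-1, 1, 1), c("C_c", "ETH_c", "ATP_c")),
          0, 1000, "OGF", "fermentation"))
  add(rxn("PGS", stats::setNames(c(-1, 1), c("G_c", "PG_c")),
          0, 1000, "OGPGa and OGPGb and OGPGc", "precursor synthesis"))
  add(rxn("PCS", stats::setNames(c(-1, 1), c("C_c", "PC_c")),
          0, 1000, "OGPC", "precursor synthesis"))
  add(rxn("PNS", stats::setNames(c(-1, -1, 1), c("C_c", "NH4_c", "PN_c")),
          0, 1000, "OGPN", "precursor synthesis"))
  add(rxn("BIOMASS",
          stats::setNames(c(-1, -1, -1, -6, 1),
                          c("PG_c", "PC_c", "PN_c", "ATP_c", "BIO_c")),
          0, 1000, subsystem = "biomass"))
  add(rxn("EX_BIO", stats::setNames(-1, "BIO_c"), 0, 1000,
          subsystem = "exchange"))

  pan <- new_model(mets, rxns, "BIOMASS", id = "pan")
  pan$media_defaults <- list(carbon = "EX_S1",
                             free = c("EX_O2", "EX_NH4"),
                             nitrogen = "EX_NH4")
  pan
}

## ------------------------------------------------------- existence matrix

## tip sets of all internal clades (excluding the root) and all tips
.clades <- function(tree) {
  nt <- length(tree$tip.label)
  nodes <- (nt + 2L):(nt + tree$Nnode)         # internal, non-root
  cl <- lapply(nodes, function(nd) {
    tips <- .desc_tips(tree, nd, nt)
    tree$tip.label[tips]
  })
  c(cl, as.list(tree$tip.label))               # terminal edges too
}

.desc_tips <- function(tree, node, nt) {
  if (node <= nt) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .desc_tips, tree = tree, nt = nt))
}

## choose, per trait, a (gain, loss) clade pair so that the planted
## causal ortholog is the unique high-correlated reaction for its trait
.plant_existence <- function(pan, k, n, seed) {
  for (attempt in 0:49) {
    tree <- .with_seed(seed + 7919L * attempt, {
      tr <- ape::rcoal(n, tip.label = sprintf("sp%02d", seq_len(n)))
      tr
    })
    sol <- .with_seed(seed + 7919L * attempt + 1L,
                      .try_plant(tree, k, n))
    if (!is.null(sol)) { sol$tree <- tree; return(sol) }
  }
  stop("generate_pan_network: could not place trait events on any tree; ",
       "increase n_species")
}

.try_plant <- function(tree, k, n) {
  tips <- tree$tip.label
  complete_sp <- tips[1]; dgap_sp <- tips[2]
  reserved <- c(complete_sp, dgap_sp)
  clades <- .clades(tree)
  sizes <- lengths(clades)
  big <- which(sizes >= 3 & sizes <= n - 2)   # candidate outer clades
  if (!length(big)) return(NULL)

  max_ones <- floor(0.83 * n) - 1
  for (restart in seq_len(60)) {
    P <- list(); ok <- TRUE
    for (i in seq_len(k)) {
      root_present <- (i %% 2L == 1L)
      found <- FALSE
      for (c1 in sample(big)) {
        A <- clades[[c1]]
        inner <- which(vapply(clades, function(B)
          length(B) < length(A) && all(B %in% A), logical(1)))
        if (!length(inner)) next
        for (c2 in sample(inner, min(8, length(inner)))) {
          B <- clades[[c2]]
          Pset <- if (root_present) union(setdiff(tips, A), B)
                  else setdiff(A, B)
          Pset <- union(Pset, reserved)
          ones <- if (i == 1) Pset else setdiff(Pset, dgap_sp)
          if (length(ones) < 3 || length(ones) > max_ones) next
          ## cross-trait separation vs already chosen traits
          sep <- TRUE
          for (j in seq_along(P)) {
            Zj <- setdiff(tips, P[[j]])
            ones_j <- if (j == 1) P[[j]] else setdiff(P[[j]], dgap_sp)
            Zi <- setdiff(tips, Pset)
            if (length(intersect(ones, Zj)) < 2 ||
                length(intersect(ones_j, Zi)) < 2) { sep <- FALSE; break }
          }
          if (!sep) next
          P[[i]] <- Pset; found <- TRUE; break
        }
        if (found) break
      }
      if (!found) { ok <- FALSE; break }
    }
    if (ok) return(list(present = P, complete = complete_sp,
                        dgap = dgap_sp))
  }
  NULL
}

## ------------------------------------------------------------ assembly

.assemble_world <- function(pan, sol, k) {
  tree <- sol$tree
  tips <- tree$tip.label
  genes <- pan$gene_ids
  M <- matrix(1L, length(tips), length(genes),
              dimnames = list(tips, genes))
  for (i in seq_len(k)) {
    g <- sprintf("OGT%d", i)
    M[, g] <- as.integer(tips %in% sol$present[[i]])
  }
  M[, "OGD"] <- 1L
  M[sol$dgap, ] <- 1L
  M[sol$dgap, "OGD"] <- 0L
  M[sol$complete, ] <- 1L

  dependent <- sprintf("trait%d", 2:k)
  anc <- stats::setNames(ifelse(seq_len(k) %% 2 == 1, 0.95, 0.05),
                         sprintf("trait%d", seq_len(k)))
  expected <- sapply(seq_len(k), function(i) {
    as.integer(M[, sprintf("OGT%d", i)] == 1L &
                 (i == 1 | M[, "OGD"] == 1L))
  })
  dimnames(expected) <- list(tips, sprintf("trait%d", seq_len(k)))

  truth <- list(
    complete_species = sol$complete,
    dgap_species = sol$dgap,
    downstream_reaction = "GNG",
    downstream_gene = "OGD",
    downstream_dependent_traits = dependent,
    trait_substrate_exchange = stats::setNames(
      sprintf("EX_S%d", seq_len(k)), sprintf("trait%d", seq_len(k))),
    trait_causal_gene = stats::setNames(
      sprintf("OGT%d", seq_len(k)), sprintf("trait%d", seq_len(k))),
    trait_causal_reaction = stats::setNames(
      sprintf("T%d", seq_len(k)), sprintf("trait%d", seq_len(k))),
    direct_pathway = stats::setNames(
      lapply(seq_len(k), function(i) c(sprintf("T%d", i),
                                       sprintf("B%d", i))),
      sprintf("trait%d", seq_len(k))),
    ancestral_posterior = anc,
    expected_traits = expected,
    promiscuous_gene = "OGPROM",
    limiting_enzyme = "OGPGa")

  ## enzyme parameter sets: a multi-enzyme overflow-capable set for
  ## Crabtree-style scans, and a single-constraint set in which the
  ## planted limiting enzyme carries the only kcat (flux control 1)
  ## kinetic economics: respiration saves carbon (3 ATP per C) while
  ## fermentation saves protein (higher kcat per enzyme mass); with the
  ## base glycolytic kcat the respiro-fermentative switch sits near
  ## threefold, so kcat scans reproduce overflow metabolism
  ec <- list(
    kcat = data.frame(
      enzyme_id = c("OGI1", "OGI2", "OGR", "OGF"),
      reaction_id = c("GLY", "GLY", "RESP", "FERM"),
      kcat = c(4, 3.5, 6, 25)),
    mw = data.frame(enzyme_id = c("OGI1", "OGI2", "OGR", "OGF"),
                    mw = c(1, 1.1, 1, 1)),
    pool = 0.3)
  ec_single <- list(
    kcat = data.frame(enzyme_id = "OGPGa", reaction_id = "PGS",
                      kcat = 50),
    mw = data.frame(enzyme_id = "OGPGa", mw = 1),
    pool = 0.04)

  structure(list(pan = pan, existence = M, tree = tree,
                 ec = ec, ec_single = ec_single, truth = truth),
            class = "synthetic_world")
}

#' Derive all species models of a world
#' @param world a `synthetic_world`.
#' @return named list of species `gem`s.
#' @export
derive_world_models <- function(world) {
  sp <- rownames(world$existence)
  stats::setNames(lapply(sp, function(s)
    derive_species_model(world$pan, world$existence[s, ], s)), sp)
}

#' Simulate the trait table of a world
#'
#' Traits equal FBA-simulated substrate utilization per species model;
#' each value is independently flipped with probability `flip_rate` and
#' masked to NA with probability `na_rate`.
#' @param world a `synthetic_world`.
#' @param flip_rate in [0, 0.5).
#' @param na_rate fraction masked to NA.
#' @param seed integer seed.
#' @param models optional pre-derived model list (speeds up repeated calls).
#' @return species x trait integer matrix with NA holes.
#' @export
generate_trait_table <- function(world, flip_rate = 0, na_rate = 0,
                                 seed = 1, models = NULL) {
  if (flip_rate < 0 || flip_rate >= 0.5)
    stop("generate_trait_table: flip_rate must lie in [0, 0.5)")
  if (na_rate < 0 || na_rate > 1)
    stop("generate_trait_table: na_rate must lie in [0, 1]")
  if (is.null(models)) models <- derive_world_models(world)
  exch <- world$truth$trait_substrate_exchange
  M <- matrix(NA_integer_, length(models), length(exch),
              dimnames = list(names(models), names(exch)))
  for (s in names(models)) {
    for (tr in names(exch)) {
      M[s, tr] <- as.integer(
        test_substrate_utilization(models[[s]], exch[[tr]]))
    }
  }
  .with_seed(seed, {
    flip <- matrix(stats::runif(length(M)) < flip_rate, nrow(M))
    M[flip] <- 1L - M[flip]
    hole <- matrix(stats::runif(length(M)) < na_rate, nrow(M))
    M[hole] <- NA_integer_
  })
  M
}
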