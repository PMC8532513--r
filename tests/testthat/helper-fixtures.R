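## Shared fixtures: tiny hand-built models, independent oracles and
## random-case generators used across the suite.

## linear chain: EX_S (uptake) -> S, S -> P, biomass consumes 2 P.
## With uptake 10 the hand-solved optimum is 5.0.
chain_model <- function(uptake = 10) {
  mets <- data.frame(id = c("S_e", "S_c", "P_c"),
                     name = c("s", "s", "p"),
                     compartment = c("e", "c", "c"))
  rxns <- list(
    list(id = "EX_S", stoich = c(S_e = -1), lb = -uptake, ub = 1000,
         gpr = NULL, subsystem = "exchange"),
    list(id = "T_S", stoich = c(S_e = -1, S_c = 1), lb = 0, ub = 1000,
         gpr = parse_gpr("gT"), subsystem = ""),
    list(id = "CONV", stoich = c(S_c = -1, P_c = 1), lb = 0, ub = 1000,
         gpr = parse_gpr("gC"), subsystem = ""),
    list(id = "BIOMASS", stoich = c(P_c = -2), lb = 0, ub = 1000,
         gpr = NULL, subsystem = "biomass"))
  new_model(mets, rxns, "BIOMASS", id = "chain")
}

## independent recursive GPR evaluator used as the truth-table oracle
## (same majority-subunit semantics, separate implementation)
oracle_gpr_active <- function(node, present) {
  if (is.null(node)) return(TRUE)
  if (node$kind == "gene") return(node$gene %in% present)
  vals <- vapply(node$children, oracle_gpr_active, logical(1),
                 present = present)
  if (node$kind == "or") return(any(vals))
  sum(vals) > length(vals) / 2
}

## random normalized GPR tree over the given genes
random_gpr <- function(genes, depth = 2) {
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.4)
      return(gemevo:::gpr_gene(sample(genes, 1)))
    kind <- sample(c("and", "or"), 1)
    n <- sample(2:3, 1)
    list(kind = kind, children = lapply(seq_len(n), function(i)
      build(d - 1)))
  }
  normalize_gpr(build(depth))
}

## small branched network for gap-fill cases: a main route plus
## alternative routes and dead-end decoys; removing reactions from the
## main route creates gaps fillable from the rest.
gapfill_pan <- function(n_chain = 5, n_alt = 4, n_decoy = 4, seed = 1) {
  set.seed(seed)
  mets <- data.frame(
    id = c("S_e", paste0("M", seq_len(n_chain)), "X1", "X2"),
    name = "m", compartment = c("e", rep("c", n_chain + 2)))
  rxns <- list(
    list(id = "EX_S", stoich = c(S_e = -1), lb = -10, ub = 1000,
         gpr = NULL, subsystem = "exchange"),
    list(id = "R00", stoich = c(S_e = -1, M1 = 1), lb = 0, ub = 1000,
         gpr = NULL, subsystem = ""))
  for (i in seq_len(n_chain - 1)) {
    st <- stats::setNames(c(-1, 1), paste0("M", c(i, i + 1)))
    rxns[[length(rxns) + 1]] <- list(id = sprintf("R%02d", i),
                                     stoich = st, lb = 0, ub = 1000,
                                     gpr = NULL, subsystem = "")
  }
  ## alternative two-step bypasses M_i -> X -> M_j (i < j)
  for (a in seq_len(n_alt)) {
    ij <- sort(sample(n_chain, 2))
    x <- sample(c("X1", "X2"), 1)
    rxns[[length(rxns) + 1]] <- list(
      id = sprintf("A%02da", a),
      stoich = stats::setNames(c(-1, 1), c(paste0("M", ij[1]), x)),
      lb = 0, ub = 1000, gpr = NULL, subsystem = "")
    rxns[[length(rxns) + 1]] <- list(
      id = sprintf("A%02db", a),
      stoich = stats::setNames(c(-1, 1), c(x, paste0("M", ij[2]))),
      lb = 0, ub = 1000, gpr = NULL, subsystem = "")
  }
  for (d in seq_len(n_decoy)) {
    ij <- sample(n_chain, 2)
    rxns[[length(rxns) + 1]] <- list(
      id = sprintf("D%02d", d),
      stoich = stats::setNames(c(-1, 1),
                               paste0("M", c(ij[1], ij[2]))),
      lb = 0, ub = 1000, gpr = NULL, subsystem = "")
  }
  rxns[[length(rxns) + 1]] <- list(
    id = "BIOMASS", stoich = stats::setNames(-1, paste0("M", n_chain)),
    lb = 0, ub = 1000, gpr = NULL, subsystem = "biomass")
  m <- new_model(mets, rxns, "BIOMASS", id = "gf")
  m$media_defaults <- list(carbon = "EX_S", free = character(0))
  m
}

## drop reactions from a model
drop_reactions <- function(model, ids) {
  model$reactions[ids] <- NULL
  model
}

## exhaustive ascending-cardinality search for the minimal fill set
oracle_gapfill_cardinality <- function(model, pan, media,
                                       threshold = 1e-6) {
  cand <- sort(setdiff(reaction_ids(pan), reaction_ids(model)))
  grows <- function(ids) {
    m <- model
    for (id in ids) m$reactions[[id]] <- pan$reactions[[id]]
    r <- solve_fba(m, media)
    r$status == "optimal" && r$objective >= threshold
  }
  if (grows(character(0))) return(0L)
  for (size in seq_along(cand)) {
    sets <- utils::combn(cand, size, simplify = FALSE)
    for (s in sets) if (grows(s)) return(size)
  }
  Inf
}

## cache one default world + derived models for the whole suite
world_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- generate_pan_network(3, 16, 0.3, 0.3, seed = 1)
      models <- derive_world_models(w)
      traits <- generate_trait_table(w, 0, 0, seed = 2, models = models)
      cache <<- list(world = w, models = models, traits = traits,
                     media = minimal_media(w$pan),
                     rxn_exist = reaction_existence_matrix(models, w$pan))
    }
    cache
  }
})
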