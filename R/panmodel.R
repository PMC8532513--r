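#' @title Metabolic model container
#' @description
#' A `gem` object holds a (pan or species) metabolic network: a metabolite
#' table, a named list of reactions (stoichiometry as a named coefficient
#' vector, flux bounds in mmol/gDW/h, an optional GPR tree, a subsystem
#' label), the id of the biomass pseudo-reaction and the declared gene
#' universe.  Exchange reactions touch exactly one metabolite and carry no
#' GPR.
#' @name gem
NULL

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions named list; each element a list with `id`, `stoich`
#'   (named numeric, metabolite id -> signed coefficient), `lb`, `ub`,
#'   `gpr` (GPR tree or `NULL`), `subsystem` (optional).
#' @param biomass_id id of the biomass reaction (must exist).
#' @param gene_ids optional declared gene universe; defaults to the union
#'   of genes in all GPRs.
#' @param id optional model identifier.
#' @return object of class `gem`.
#' @export
new_model <- function(metabolites, reactions, biomass_id,
                      gene_ids = NULL, id = "model") {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  model <- structure(
    list(id = id,
         metabolites = metabolites,
         reactions = reactions,
         biomass_id = biomass_id,
         gene_ids = gene_ids %||% model_genes_raw(reactions)),
    class = "gem")
  validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

model_genes_raw <- function(reactions) {
  sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr)))))
}

#' Genes appearing in any GPR of a model
#' @param model a `gem`.
#' @return sorted character vector.
#' @export
model_genes <- function(model) model_genes_raw(model$reactions)

#' Reaction ids of a model
#' @param model a `gem`.
#' @return character vector in model order.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Validate model invariants
#'
#' Checks unique ids, bound ordering, stoichiometry referencing declared
#' metabolites, exchange shape (single metabolite, no GPR requirement is
#' not enforced), presence of the biomass reaction, and GPR genes being in
#' the declared gene universe.
#' @param model a `gem`.
#' @return the model, invisibly; stops on violation.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  stopifnot(is.data.frame(mets),
            all(c("id", "name", "compartment") %in% names(mets)))
  if (anyDuplicated(mets$id))
    stop("validate_model: duplicate metabolite ids")
  if (any(!nzchar(mets$compartment)))
    stop("validate_model: empty compartment")
  rids <- names(model$reactions)
  if (anyDuplicated(rids)) stop("validate_model: duplicate reaction ids")
  if (!model$biomass_id %in% rids)
    stop("validate_model: biomass reaction '", model$biomass_id,
         "' not in model")
  for (r in model$reactions) {
    if (r$lb > r$ub)
      stop("validate_model: lb > ub for reaction '", r$id, "'")
    bad <- setdiff(names(r$stoich), mets$id)
    if (length(bad))
      stop("validate_model: reaction '", r$id,
           "' references undeclared metabolite(s): ",
           paste(bad, collapse = ", "))
    extra <- setdiff(gpr_genes(r$gpr), model$gene_ids)
    if (length(extra))
      stop("validate_model: reaction '", r$id,
           "' uses undeclared gene(s): ", paste(extra, collapse = ", "))
  }
  invisible(model)
}

#' Is a reaction an exchange reaction?
#' @param rxn a reaction element of a `gem`.
#' @return logical.
#' @export
is_exchange <- function(rxn) length(rxn$stoich) == 1L

#' Stoichiometric matrix of a model
#' @param model a `gem`.
#' @return dense numeric matrix, metabolites x reactions, dimnames set.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, length(mets), length(rids), dimnames = list(mets, rids))
  for (j in seq_along(rids)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Write a pan-model to JSON
#'
#' Schema: top-level `metabolites` (id, name, compartment), `reactions`
#' (id, stoichiometry mapping, lb, ub, gpr string, subsystem) and
#' `biomass_id`.
#' @param model a `gem`.
#' @param path output path.
#' @export
write_pan_json <- function(model, path) {
  obj <- list(
    metabolites = model$metabolites[, c("id", "name", "compartment")],
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id,
           stoichiometry = as.list(r$stoich),
           lb = r$lb, ub = r$ub,
           gpr = write_gpr(r$gpr),
           subsystem = r$subsystem %||% "")
    }),
    biomass_id = model$biomass_id)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE),
             path)
  invisible(path)
}

#' Read a pan-model from JSON
#' @param path path written by [write_pan_json()].
#' @return a `gem`.
#' @export
read_pan_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id, name = m$name, compartment = m$compartment,
               stringsAsFactors = FALSE)))
  reactions <- lapply(obj$reactions, function(r) {
    list(id = r$id,
         stoich = unlist(r$stoichiometry),
         lb = r$lb, ub = r$ub,
         gpr = parse_gpr(r$gpr),
         subsystem = r$subsystem)
  })
  new_model(mets, reactions, obj$biomass_id)
}

#' Core and accessory reactions across species models
#'
#' Core reactions exist in all sampled species; accessory reactions exist
#' in only part of them.
#' @param models list of `gem` objects or of reaction-id character vectors.
#' @return list with sorted character vectors `core` and `accessory`.
#' @export
classify_core_accessory <- function(models) {
  if (!length(models)) stop("classify_core_accessory: empty model list")
  sets <- lapply(models, function(m)
    if (inherits(m, "gem")) reaction_ids(m) else as.character(m))
  core <- Reduce(intersect, sets)
  pan <- Reduce(union, sets)
  list(core = sort(core), accessory = sort(setdiff(pan, core)))
}

#' Pairwise Hamming distance between binary reaction-existence rows
#'
#' @param matrix binary species x reaction matrix (0/1).
#' @return symmetric integer distance matrix with zero diagonal.
#' @export
reaction_hamming <- function(matrix) {
  M <- as.matrix(matrix)
  bad <- which(!(M %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(M)) + 1
    j <- ((bad[1] - 1) %/% nrow(M)) + 1
    stop("reaction_hamming: non-binary cell at row ", i, ", column ", j)
  }
  storage.mode(M) <- "double"
  ## hamming = manhattan on 0/1 rows
  D <- as.matrix(stats::dist(M, method = "manhattan"))
  storage.mode(D) <- "integer"
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

#' Binary species x reaction existence matrix from species models
#' @param models named list of species `gem`s.
#' @param pan optional pan-model fixing the reaction universe/order.
#' @return 0/1 integer matrix, species x reactions.
#' @export
reaction_existence_matrix <- function(models, pan = NULL) {
  univ <- if (!is.null(pan)) reaction_ids(pan)
          else sort(unique(unlist(lapply(models, reaction_ids))))
  M <- t(vapply(models, function(m) as.integer(univ %in% reaction_ids(m)),
                integer(length(univ))))
  dimnames(M) <- list(names(models), univ)
  M
}
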