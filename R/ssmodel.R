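#' @title Species-specific model derivation and gap-filling
#' @description
#' Derives a species model from the pan-model and a binary gene-existence
#' row by evaluating every GPR against the species' gene content, and
#' restores in-silico growth by adding a minimum-cardinality set of
#' pan-model reactions (exact branch-and-bound over binary reaction
#' indicators).
#' @name ssmodel
NULL

#' Derive a species model from the pan-model
#'
#' A reaction is retained iff its GPR evaluates active for the species'
#' genes (with complexes pruned to present subunits and missing isozymes
#' dropped), or it has no GPR (spontaneous/exchange reactions are always
#' kept).  The biomass reaction is always retained.
#'
#' @param pan the pan-model (`gem`).
#' @param existence_row named 0/1 vector over ortholog-group ids; genes of
#'   the pan-model missing from the row are treated as absent (logged).
#' @param species_id identifier for the derived model.
#' @return a `gem` with `species`, pruned GPRs and per-reaction
#'   `provenance` ("derived" or "no_gpr_kept").
#' @export
derive_species_model <- function(pan, existence_row,
                                 species_id = "species") {
  missing <- setdiff(pan$gene_ids, names(existence_row))
  if (length(missing))
    message("derive_species_model: ", length(missing),
            " pan gene(s) missing from existence row, treated as absent")
  present <- names(existence_row)[existence_row == 1]

  keep <- list()
  provenance <- character(0)
  for (r in pan$reactions) {
    if (is.null(r$gpr)) {
      tag <- "no_gpr_kept"
    } else {
      ev <- evaluate_gpr(r$gpr, present)
      if (!ev$active && r$id != pan$biomass_id) next
      r$gpr <- ev$pruned
      tag <- "derived"
    }
    keep[[r$id]] <- r
    provenance[r$id] <- tag
  }
  if (!pan$biomass_id %in% names(keep)) {
    keep[[pan$biomass_id]] <- pan$reactions[[pan$biomass_id]]
    provenance[pan$biomass_id] <- "derived"
  }
  m <- new_model(pan$metabolites, keep, pan$biomass_id,
                 gene_ids = pan$gene_ids, id = species_id)
  m$species <- species_id
  m$provenance <- provenance
  m$media_defaults <- pan$media_defaults
  m
}

#' Can the model produce a metabolite?
#'
#' Adds a temporary demand reaction for the metabolite, maximizes its
#' flux under the media, and reports whether the optimum exceeds 1e-6.
#' @param model a `gem`.
#' @param metabolite_id metabolite to test.
#' @param media a [media_spec()].
#' @return logical.
#' @export
check_producibility <- function(model, metabolite_id, media) {
  if (!metabolite_id %in% model$metabolites$id)
    stop("check_producibility: unknown metabolite '", metabolite_id, "'")
  dm <- paste0(".DM_", metabolite_id)
  model$reactions[[dm]] <- list(id = dm,
                                stoich = stats::setNames(-1, metabolite_id),
                                lb = 0, ub = 1000, gpr = NULL,
                                subsystem = "demand")
  res <- solve_fba(model, media, objective_reaction = dm)
  res$status == "optimal" && res$objective > 1e-6
}

#' Minimal gap-filling against the pan-model
#'
#' Finds a minimum-cardinality subset of pan-model reactions absent from
#' the species model whose addition restores biomass flux to at least
#' `growth_threshold` under the media.  Solved exactly: binary indicator
#' per candidate reaction coupled to its flux bounds, LP-relaxation
#' branch-and-bound on the indicator count, then lexicographic
#' tie-breaking among equal-cardinality optima by sequentially fixing
#' candidates in reaction-id order.  An optional `preferred` candidate
#' list is tried on its own first.
#'
#' @param model species `gem` (a subset of `pan`).
#' @param pan the pan-model.
#' @param media a [media_spec()].
#' @param growth_threshold minimal biomass flux, default 1e-6.
#' @param preferred optional character vector of candidate reaction ids to
#'   try before the full pan candidate pool.
#' @return sorted character vector of added reaction ids (empty when the
#'   model already grows); errors with "unfillable" when no pan subset
#'   restores growth.
#' @export
gap_fill <- function(model, pan, media, growth_threshold = 1e-6,
                     preferred = NULL) {
  base <- solve_fba(model, media)
  if (base$status == "optimal" && base$objective >= growth_threshold)
    return(character(0))

  candidates <- sort(setdiff(reaction_ids(pan), reaction_ids(model)))
  if (!is.null(preferred)) {
    pref <- sort(intersect(preferred, candidates))
    if (length(pref)) {
      got <- tryCatch(
        .gapfill_search(model, pan, media, growth_threshold, pref),
        error = function(e) NULL)
      if (!is.null(got)) return(got)
    }
  }
  .gapfill_search(model, pan, media, growth_threshold, candidates)
}

.gapfill_search <- function(model, pan, media, growth_threshold,
                            candidates) {
  ## assemble the relaxation system once: pan reactions restricted to
  ## model + candidates, media applied to the combined model
  ids <- c(reaction_ids(model), candidates)
  rxns <- c(model$reactions, pan$reactions[candidates])
  comb <- new_model(pan$metabolites, rxns, pan$biomass_id,
                    gene_ids = pan$gene_ids, id = model$id)
  comb$media_defaults <- model$media_defaults
  comb <- apply_media(comb, media)

  n <- length(comb$reactions)
  k <- length(candidates)
  if (k == 0) stop("gap_fill: unfillable (no candidate reactions)")
  lb <- vapply(comb$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(comb$reactions, `[[`, numeric(1), "ub")
  S <- stoich_matrix(comb)
  bi <- match(comb$biomass_id, names(comb$reactions))
  ci <- match(candidates, names(comb$reactions))

  ## variables: v (n) then y (k).  Rows: S v = 0; biomass >= threshold;
  ## v_c - ub_c y_c <= 0; v_c - lb_c y_c >= 0.
  obj <- c(rep(0, n), rep(1, k))
  bio_row <- c(as.numeric(seq_len(n) == bi), rep(0, k))
  up_rows <- matrix(0, k, n + k)
  lo_rows <- matrix(0, k, n + k)
  for (j in seq_len(k)) {
    up_rows[j, ci[j]] <- 1; up_rows[j, n + j] <- -ub[ci[j]]
    lo_rows[j, ci[j]] <- 1; lo_rows[j, n + j] <- -lb[ci[j]]
  }
  A <- rbind(cbind(S, matrix(0, nrow(S), k)), bio_row, up_rows, lo_rows)
  rhs <- c(rep(0, nrow(S)), growth_threshold, rep(0, 2 * k))
  sense <- c(rep("=", nrow(S)), ">=", rep("<=", k), rep(">=", k))
  lov <- c(lb, rep(0, k)); hiv <- c(ub, rep(1, k))

  relax <- function(fix0, fix1) {
    lo2 <- lov; hi2 <- hiv
    lo2[n + fix1] <- 1
    hi2[n + fix0] <- 0
    lp_solve(obj, A, rhs, sense, lo2, hi2, maximize = FALSE)
  }

  all_open <- relax(integer(0), integer(0))
  if (all_open$status != "optimal")
    stop("gap_fill: unfillable (no pan subset restores growth)")

  solve_milp <- function(fix0, fix1, cutoff = Inf) {
    ## returns minimal cardinality (Inf if infeasible or above cutoff)
    best <- Inf
    recurse <- function(fix0, fix1) {
      r <- relax(fix0, fix1)
      if (r$status != "optimal") return()
      bound <- r$objective
      if (bound >= best - 1e-6 || bound > cutoff + 1e-6) return()
      yv <- r$x[n + seq_len(k)]
      ## indicators rest at v/M under the relaxation, so any support
      ## above solver noise counts as fractional
      frac <- setdiff(which(yv > 1e-10 & yv < 1 - 1e-9),
                      c(fix0, fix1))
      if (!length(frac)) {
        card <- sum(yv > 0.5)
        if (card < best) best <<- card
        return()
      }
      b <- frac[which.max(yv[frac])]
      recurse(fix0, c(fix1, b))       # include first: finds incumbents fast
      recurse(c(fix0, b), fix1)
    }
    recurse(fix0, fix1)
    best
  }

  kstar <- solve_milp(integer(0), integer(0))
  if (!is.finite(kstar)) stop("gap_fill: unfillable")

  ## lexicographically smallest optimal set (candidates are sorted):
  ## greedily include the smallest id that still admits a completion of
  ## cardinality kstar, else exclude it
  fix0 <- integer(0); fix1 <- integer(0)
  for (j in seq_len(k)) {
    if (length(fix1) == kstar) break
    with_j <- solve_milp(fix0, c(fix1, j), cutoff = kstar)
    if (with_j <= kstar + 1e-9) fix1 <- c(fix1, j)
    else fix0 <- c(fix0, j)
  }
  added <- sort(candidates[fix1])

  ## post-check: adding the set restores growth
  check <- model
  for (id in added) check$reactions[[id]] <- pan$reactions[[id]]
  res <- solve_fba(check, media)
  if (!(res$status == "optimal" && res$objective >= growth_threshold))
    stop("gap_fill: internal error, fill set does not restore growth")
  added
}
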