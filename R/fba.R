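#' @title Flux balance analysis
#' @description
#' Linear-programming simulation of metabolic models: growth maximisation
#' (FBA), parsimonious FBA, substrate-utilization tests, single-gene
#' deletion essentiality, and confusion-matrix metrics used to score
#' predictions against experimental trait tables.
#' @name fba
NULL

#' Media specification
#'
#' A media is a table of exchange-reaction bounds (mmol/gDW/h); uptake is
#' a negative lower bound.  Exchanges not listed are closed to uptake
#' (lb = 0) when the media is applied.
#' @param reaction exchange reaction ids.
#' @param lb,ub bounds, recycled to length.
#' @return data.frame of class `media_spec`.
#' @export
media_spec <- function(reaction, lb, ub = 1000) {
  df <- data.frame(reaction = as.character(reaction),
                   lb = as.numeric(lb), ub = as.numeric(ub),
                   stringsAsFactors = FALSE)
  if (any(df$lb > df$ub)) stop("media_spec: lb > ub")
  class(df) <- c("media_spec", "data.frame")
  df
}

#' Minimal media for a model
#'
#' Free uptake of the model's inorganic exchanges (oxygen-, ammonia-,
#' phosphate-, sulfate-analogues, as declared in `model$media_defaults$free`)
#' and a constrained uptake of the default carbon source.
#' @param model a `gem` whose `media_defaults` declare `carbon` and `free`.
#' @param carbon_uptake uptake rate for the carbon source (positive number,
#'   applied as a negative lower bound), default 10.
#' @return a [media_spec()].
#' @export
minimal_media <- function(model, carbon_uptake = 10) {
  md <- model$media_defaults
  if (is.null(md))
    stop("minimal_media: model carries no media defaults")
  media_spec(c(md$carbon, md$free),
             lb = c(-carbon_uptake, rep(-1000, length(md$free))))
}

#' Apply a media to a model
#'
#' All exchange reactions are first closed to uptake (lb = 0); listed
#' exchanges then receive the media bounds.
#' @param model a `gem`.
#' @param media a [media_spec()] (or NULL to leave bounds untouched).
#' @return modified `gem`.
#' @export
apply_media <- function(model, media) {
  if (is.null(media)) return(model)
  for (id in names(model$reactions)) {
    if (is_exchange(model$reactions[[id]]))
      model$reactions[[id]]$lb <- max(model$reactions[[id]]$lb, 0)
  }
  for (i in seq_len(nrow(media))) {
    id <- media$reaction[i]
    if (!id %in% names(model$reactions)) next
    model$reactions[[id]]$lb <- media$lb[i]
    model$reactions[[id]]$ub <- media$ub[i]
  }
  model
}

#' Flux balance analysis
#'
#' Maximizes the flux of `objective_reaction` subject to steady state
#' (S v = 0) and flux bounds.
#' @param model a `gem`.
#' @param media a [media_spec()] or NULL (use the model's current bounds).
#' @param objective_reaction reaction id; defaults to the biomass reaction.
#' @return list with `status`, `objective` (h^-1 for biomass) and `fluxes`
#'   (named vector, solver noise below 1e-10 rounded away).
#' @export
solve_fba <- function(model, media = NULL,
                      objective_reaction = model$biomass_id) {
  model <- apply_media(model, media)
  if (!objective_reaction %in% names(model$reactions))
    stop("solve_fba: unknown objective reaction '", objective_reaction, "'")
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  if (any(lb > ub))
    stop("solve_fba: lb > ub for reaction(s) ",
         paste(names(model$reactions)[lb > ub], collapse = ", "))
  S <- stoich_matrix(model)
  obj <- as.numeric(names(model$reactions) == objective_reaction)
  res <- lp_solve(obj, S, rhs = rep(0, nrow(S)),
                  sense = rep("=", nrow(S)), lower = lb, upper = ub)
  fluxes <- if (res$status == "optimal") {
    v <- round(res$x, 10)
    stats::setNames(v, names(model$reactions))
  } else NULL
  list(status = res$status,
       objective = if (res$status == "optimal") round(res$objective, 10)
                   else NA_real_,
       fluxes = fluxes)
}

#' Parsimonious FBA
#'
#' Fixes the objective at its FBA optimum (within 1e-9 relative), then
#' minimizes the total absolute flux by splitting each reaction into
#' non-negative forward/reverse parts.
#' @inheritParams solve_fba
#' @return as [solve_fba()]; `total_flux` additionally reports the
#'   minimized sum of absolute fluxes.
#' @export
pfba <- function(model, media = NULL,
                 objective_reaction = model$biomass_id) {
  model <- apply_media(model, media)
  stage1 <- solve_fba(model, NULL, objective_reaction)
  if (stage1$status != "optimal") return(stage1)
  vstar <- stage1$objective

  rids <- names(model$reactions)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  oi <- match(objective_reaction, rids)
  lb[oi] <- max(lb[oi], vstar - abs(vstar) * 1e-9 - 1e-12)

  S <- stoich_matrix(model)
  n <- length(rids)
  ## v = f - r, f,r >= 0
  A <- cbind(S, -S)
  lof <- rep(0, 2 * n)
  hif <- c(pmax(ub, 0), pmax(-lb, 0))
  ## keep v within [lb, ub]: f - r in [lb, ub]
  Abox <- cbind(diag(1, n), -diag(1, n))
  A2 <- rbind(A, Abox, Abox)
  rhs <- c(rep(0, nrow(S)), ub, lb)
  sense <- c(rep("=", nrow(S)), rep("<=", n), rep(">=", n))
  res <- lp_solve(rep(1, 2 * n), A2, rhs, sense, lof, hif,
                  maximize = FALSE)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, fluxes = NULL))
  v <- round(res$x[seq_len(n)] - res$x[n + seq_len(n)], 10)
  list(status = "optimal",
       objective = v[oi],
       fluxes = stats::setNames(v, rids),
       total_flux = round(res$objective, 10))
}

#' Test substrate utilization in silico
#'
#' Builds minimal media with the default carbon (or nitrogen) source's
#' exchange closed and the test substrate's exchange opened at the given
#' uptake rate ("replacing" the default source), then checks whether the
#' maximal growth rate reaches the threshold (inclusive).
#' @param model a `gem` with media defaults.
#' @param substrate_exchange_id exchange reaction of the test substrate.
#' @param uptake_rate uptake allowance, default 10 mmol/gDW/h.
#' @param growth_threshold growth classified at >= this rate (default 1e-6).
#' @param nitrogen if TRUE, replace the ammonia-analogue source instead of
#'   the carbon source.
#' @return logical; FALSE (with a message) when the substrate exchange is
#'   absent from the model.
#' @export
test_substrate_utilization <- function(model, substrate_exchange_id,
                                       uptake_rate = 10,
                                       growth_threshold = 1e-6,
                                       nitrogen = FALSE) {
  if (!substrate_exchange_id %in% names(model$reactions)) {
    message("substrate exchange '", substrate_exchange_id,
            "' absent from model '", model$id, "': non-utilizer")
    return(FALSE)
  }
  md <- model$media_defaults
  if (is.null(md)) stop("test_substrate_utilization: no media defaults")
  closed <- if (nitrogen) md$nitrogen %||% md$free[1] else md$carbon
  free <- setdiff(md$free, substrate_exchange_id)
  keep_carbon <- if (nitrogen && md$carbon != substrate_exchange_id)
    md$carbon else NULL
  rxn <- c(substrate_exchange_id, setdiff(free, closed), keep_carbon)
  lbv <- c(-uptake_rate, rep(-1000, length(setdiff(free, closed))),
           if (!is.null(keep_carbon)) -10)
  media <- media_spec(rxn, lbv)
  res <- solve_fba(model, media)
  res$status == "optimal" && res$objective >= growth_threshold
}

#' Single-gene deletion essentiality
#'
#' For each gene of the model, re-evaluates every GPR with the gene
#' removed, closes reactions whose rule becomes inactive, and classifies
#' the gene essential iff the maximal growth rate falls below the
#' threshold.
#' @param model a `gem`.
#' @param media a [media_spec()].
#' @param growth_threshold default 1e-6 h^-1.
#' @return named character vector, "essential"/"non_essential" per gene.
#' @export
single_gene_deletions <- function(model, media,
                                  growth_threshold = 1e-6) {
  model <- apply_media(model, media)
  wt <- solve_fba(model)
  if (wt$status != "optimal" || wt$objective < growth_threshold)
    stop("single_gene_deletions: model does not grow on the given media")
  genes <- model_genes(model)
  out <- stats::setNames(character(length(genes)), genes)
  for (g in genes) {
    present <- setdiff(genes, g)
    mut <- model
    for (id in names(mut$reactions)) {
      gpr <- mut$reactions[[id]]$gpr
      if (is.null(gpr)) next
      if (!g %in% gpr_genes(gpr)) next
      if (!evaluate_gpr(gpr, present)$active) {
        mut$reactions[[id]]$lb <- 0
        mut$reactions[[id]]$ub <- 0
      }
    }
    res <- solve_fba(mut)
    grows <- res$status == "optimal" && res$objective >= growth_threshold
    out[g] <- if (grows) "non_essential" else "essential"
  }
  out
}

#' Confusion-matrix metrics
#'
#' Computes accuracy, sensitivity (recall), specificity, precision, F1 and
#' false-positive rate from TP/TN/FP/FN counts.  Ratios with a zero
#' denominator are returned as `NaN`, never silently as 0.
#' @param counts named list or vector with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector.
#' @export
confusion_metrics <- function(counts) {
  cts <- unlist(counts)[c("TP", "TN", "FP", "FN")]
  if (any(is.na(cts))) stop("confusion_metrics: need TP, TN, FP, FN")
  if (any(cts < 0)) stop("confusion_metrics: negative count")
  if (sum(cts) == 0) stop("confusion_metrics: all counts zero")
  TP <- cts["TP"]; TN <- cts["TN"]; FP <- cts["FP"]; FN <- cts["FN"]
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sens <- ratio(TP, TP + FN)
  spec <- ratio(TN, TN + FP)
  prec <- ratio(TP, TP + FP)
  f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) NaN
        else 2 * prec * sens / (prec + sens)
  c(accuracy = as.numeric((TP + TN) / sum(cts)),
    sensitivity = as.numeric(sens),
    specificity = as.numeric(spec),
    precision = as.numeric(prec),
    F1 = as.numeric(f1),
    FPR = as.numeric(if (is.nan(spec)) NaN else 1 - spec))
}
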