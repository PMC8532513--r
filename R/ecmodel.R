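#' @title Enzyme-constrained models and flux control
#' @description
#' Extends a species model with enzyme usage variables: each catalysed
#' reaction flux is capped by the summed catalytic capacity of its
#' enzymes (`v_j <= sum_i kcat_ij e_i`, isozymes additive) and total
#' enzyme mass draws on a shared protein pool (`sum_i MW_i e_i <= P`).
#' Flux control coefficients are obtained by finite kcat perturbation,
#' and kcat fold-change scans drive overflow-metabolism (Crabtree-style)
#' analyses.
#' @name ecmodel
NULL

#' Build an enzyme-constrained model
#'
#' Reversible reactions are split into irreversible forward/reverse parts
#' before kcat coupling.  A model without any kcat entry reduces exactly
#' to the base model.
#'
#' @param model a `gem`.
#' @param kcat data.frame with `enzyme_id`, `reaction_id`, `kcat`
#'   (turnovers per hour, > 0).
#' @param mw data.frame with `enzyme_id`, `mw` (g/mmol); every enzyme with
#'   a kcat needs a molecular weight.
#' @param pool total protein budget P (g/gDW); `Inf` disables the pool
#'   constraint.
#' @return object of class `ecgem`.
#' @export
build_ec_model <- function(model, kcat, mw, pool) {
  kcat <- as.data.frame(kcat)
  mw <- as.data.frame(mw)
  stopifnot(all(c("enzyme_id", "reaction_id", "kcat") %in% names(kcat)),
            all(c("enzyme_id", "mw") %in% names(mw)))
  bad <- kcat$kcat <= 0
  if (any(bad))
    stop("build_ec_model: non-positive kcat for ",
         paste(kcat$enzyme_id[bad], kcat$reaction_id[bad],
               sep = "/", collapse = ", "))
  unknown_rxn <- setdiff(kcat$reaction_id, reaction_ids(model))
  if (length(unknown_rxn))
    stop("build_ec_model: kcat references unknown reaction(s): ",
         paste(unknown_rxn, collapse = ", "))
  mwv <- stats::setNames(mw$mw, mw$enzyme_id)
  nomw <- setdiff(unique(kcat$enzyme_id), names(mwv))
  if (length(nomw))
    stop("build_ec_model: missing molecular weight for enzyme(s): ",
         paste(nomw, collapse = ", "))
  if (any(mwv <= 0)) stop("build_ec_model: non-positive molecular weight")
  structure(list(base = model, kcat = kcat, mw = mwv, pool = pool),
            class = "ecgem")
}

## Split reversible reactions of a bounds-resolved model into forward and
## reverse irreversible parts; returns the split system.
.ec_split <- function(model) {
  ids <- character(0); orig <- character(0); dirn <- numeric(0)
  lo <- numeric(0); hi <- numeric(0)
  stoich <- list()
  for (r in model$reactions) {
    fwd_hi <- max(r$ub, 0); rev_hi <- max(-r$lb, 0)
    if (fwd_hi > 0 || (r$lb >= 0 && r$ub >= 0)) {
      ids <- c(ids, r$id); orig <- c(orig, r$id); dirn <- c(dirn, 1)
      lo <- c(lo, max(r$lb, 0)); hi <- c(hi, fwd_hi)
      stoich[[length(stoich) + 1L]] <- r$stoich
    }
    if (rev_hi > 0) {
      ids <- c(ids, paste0(r$id, "__rev"))
      orig <- c(orig, r$id); dirn <- c(dirn, -1)
      lo <- c(lo, 0); hi <- c(hi, rev_hi)
      stoich[[length(stoich) + 1L]] <- -r$stoich
    }
  }
  list(ids = ids, orig = orig, dirn = dirn, lo = lo, hi = hi,
       stoich = stoich)
}

#' Solve an enzyme-constrained model
#'
#' FBA (optionally ec-pFBA: growth maximisation followed by minimisation
#' of protein-pool usage at the fixed optimum) over the split irreversible
#' system with kcat coupling and the shared pool constraint.
#'
#' @param ec an `ecgem`.
#' @param media a [media_spec()] or NULL.
#' @param objective_reaction reaction id of the base model.
#' @param parsimonious if TRUE run the two-stage ec-pFBA.
#' @return list with `status`, `objective`, `fluxes` (net flux per base
#'   reaction), `enzyme_usage` (mmol/gDW) and `pool_usage` (g/gDW).
#' @export
solve_ec <- function(ec, media = NULL,
                     objective_reaction = ec$base$biomass_id,
                     parsimonious = FALSE) {
  model <- apply_media(ec$base, media)
  sp <- .ec_split(model)
  n <- length(sp$ids)
  enzymes <- sort(unique(ec$kcat$enzyme_id))
  q <- length(enzymes)

  mets <- model$metabolites$id
  S <- matrix(0, length(mets), n, dimnames = list(mets, sp$ids))
  for (j in seq_len(n)) S[names(sp$stoich[[j]]), j] <- sp$stoich[[j]]

  ## capacity rows: v_j - sum_i kcat_ij e_i <= 0 per catalysed split rxn
  cap_rxns <- unique(ec$kcat$reaction_id)
  cap_rows <- list()
  for (rid in cap_rxns) {
    for (j in which(sp$orig == rid)) {
      row <- numeric(n + q); row[j] <- 1
      tab <- ec$kcat[ec$kcat$reaction_id == rid, ]
      for (t in seq_len(nrow(tab))) {
        ei <- match(tab$enzyme_id[t], enzymes)
        row[n + ei] <- row[n + ei] - tab$kcat[t]
      }
      cap_rows[[length(cap_rows) + 1L]] <- row
    }
  }
  pool_row <- c(rep(0, n), ec$mw[enzymes])
  pool_row[is.na(pool_row)] <- 0

  A <- rbind(cbind(S, matrix(0, nrow(S), q)),
             do.call(rbind, cap_rows))
  rhs <- c(rep(0, nrow(S)), rep(0, length(cap_rows)))
  sense <- c(rep("=", nrow(S)), rep("<=", length(cap_rows)))
  if (is.finite(ec$pool) && q > 0) {
    A <- rbind(A, pool_row)
    rhs <- c(rhs, ec$pool)
    sense <- c(sense, "<=")
  }
  lov <- c(sp$lo, rep(0, q))
  hiv <- c(sp$hi, rep(Inf, q))

  if (!objective_reaction %in% sp$orig)
    stop("solve_ec: unknown objective reaction '", objective_reaction, "'")
  obj <- c(as.numeric(sp$orig == objective_reaction) * sp$dirn, rep(0, q))

  res <- lp_solve(obj, A, rhs, sense, lov, hiv, maximize = TRUE)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, fluxes = NULL,
                enzyme_usage = NULL, pool_usage = NA_real_))

  if (parsimonious && q > 0) {
    vstar <- res$objective
    A2 <- rbind(A, obj)
    rhs2 <- c(rhs, vstar - abs(vstar) * 1e-9 - 1e-12)
    sense2 <- c(sense, ">=")
    obj2 <- c(rep(0, n), ec$mw[enzymes])
    res2 <- lp_solve(obj2, A2, rhs2, sense2, lov, hiv, maximize = FALSE)
    if (res2$status == "optimal") res <- res2
  }

  v_split <- res$x[seq_len(n)]
  eu <- if (q > 0) stats::setNames(res$x[n + seq_len(q)], enzymes)
        else numeric(0)
  net <- stats::setNames(numeric(length(model$reactions)),
                         names(model$reactions))
  for (j in seq_len(n)) net[sp$orig[j]] <- net[sp$orig[j]] +
      sp$dirn[j] * v_split[j]
  bio <- sum(obj[seq_len(n)] * v_split)
  list(status = "optimal",
       objective = round(bio, 10),
       fluxes = round(net, 10),
       enzyme_usage = eu,
       pool_usage = if (q > 0) sum(ec$mw[enzymes] * eu) else 0)
}

#' Flux control coefficient of an enzyme
#'
#' Scaled finite difference: all kcats of the enzyme are multiplied by
#' `1 + relative_perturbation` (default 0.1%) and the fractional response
#' of the target flux is divided by the fractional perturbation,
#' \deqn{FCC_i = \frac{(v_j^* - v_j)/v_j}{\Delta k/k}.}
#' The unperturbed flux normalizes the difference by default; set
#' `denominator = "perturbed"` for the alternative reading.
#'
#' @param ec an `ecgem`.
#' @param enzyme_id enzyme to perturb (must carry at least one kcat).
#' @param target_reaction flux whose control is measured (default biomass).
#' @param relative_perturbation default 0.001.
#' @param media optional [media_spec()].
#' @param denominator "reference" (v_j) or "perturbed" (v_j*).
#' @return dimensionless control coefficient.
#' @export
compute_fcc <- function(ec, enzyme_id,
                        target_reaction = ec$base$biomass_id,
                        relative_perturbation = 0.001,
                        media = NULL,
                        denominator = c("reference", "perturbed")) {
  denominator <- match.arg(denominator)
  if (!enzyme_id %in% ec$kcat$enzyme_id)
    stop("compute_fcc: enzyme '", enzyme_id, "' has no kcat entry")
  ref <- solve_ec(ec, media, target_reaction)
  if (ref$status != "optimal")
    stop("compute_fcc: reference model does not solve")
  vj <- ref$objective
  if (vj == 0)
    stop("compute_fcc: control coefficient undefined at zero flux")
  ec2 <- ec
  sel <- ec2$kcat$enzyme_id == enzyme_id
  ec2$kcat$kcat[sel] <- ec2$kcat$kcat[sel] * (1 + relative_perturbation)
  per <- solve_ec(ec2, media, target_reaction)
  if (per$status != "optimal")
    stop("compute_fcc: perturbed model does not solve")
  vs <- per$objective
  if (vs == vj) return(0)
  den <- if (denominator == "reference") vj else vs
  ((vs - vj) / den) / relative_perturbation
}

#' kcat fold-change scan
#'
#' Multiplies the kcats of the targeted enzymes by each fold in the grid,
#' runs ec-pFBA (growth maximisation then pool-usage minimisation), and
#' reports the growth rate and requested exchange fluxes, each also
#' normalized per gram of consumed carbon substrate.
#'
#' @param ec an `ecgem`.
#' @param enzyme_ids enzymes whose kcats are scaled.
#' @param folds ascending grid starting at 1 (e.g. `seq(1, 10, by = 1)`).
#' @param report_reactions exchange reaction ids to report.
#' @param carbon_exchange exchange reaction of the consumed carbon source.
#' @param carbon_mw molecular weight of the carbon substrate, g/mmol
#'   (0.18 for a glucose-like hexose).
#' @param media optional [media_spec()].
#' @return data.frame: one row per fold with growth, per-reaction fluxes
#'   and `_yield` columns (per gram consumed substrate).
#' @export
kcat_scan <- function(ec, enzyme_ids, folds, report_reactions,
                      carbon_exchange, carbon_mw = 0.18, media = NULL) {
  folds <- as.numeric(folds)
  if (any(folds <= 0)) stop("kcat_scan: folds must be positive")
  if (is.unsorted(folds)) stop("kcat_scan: folds must be ascending")
  if (abs(folds[1] - 1) > 1e-12) stop("kcat_scan: grid must start at 1")
  rows <- list()
  for (f in folds) {
    ecf <- ec
    sel <- ecf$kcat$enzyme_id %in% enzyme_ids
    ecf$kcat$kcat[sel] <- ecf$kcat$kcat[sel] * f
    res <- solve_ec(ecf, media, parsimonious = TRUE)
    uptake <- if (res$status == "optimal")
      max(-res$fluxes[carbon_exchange], 0) else NA_real_
    grams <- uptake * carbon_mw
    row <- list(fold = f,
                growth = res$objective,
                growth_yield = if (isTRUE(grams > 0))
                  res$objective / grams else NA_real_)
    for (rid in report_reactions) {
      v <- if (res$status == "optimal") res$fluxes[rid] else NA_real_
      row[[rid]] <- as.numeric(v)
      row[[paste0(rid, "_yield")]] <- if (isTRUE(grams > 0))
        as.numeric(v) / grams else NA_real_
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, lapply(rows, as.data.frame))
}
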