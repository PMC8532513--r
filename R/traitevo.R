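#' @title Reaction-trait correlation and trait gain/loss analysis
#' @description
#' Connects reaction content to metabolic traits: accuracy/sensitivity of
#' reaction presence as a predictor of substrate utilization,
#' high-correlated reaction detection at the galactose-calibrated
#' thresholds, gain/loss classification against ancestral-state
#' posteriors, and mechanistic attribution of simulated trait losses
#' (including downstream-pathway gaps found by gap-filling).
#' @name traitevo
NULL

#' Accuracy and sensitivity of reaction presence vs a trait
#'
#' Treats presence as the predictor: TP = present & trait 1,
#' FP = present & trait 0, FN = absent & trait 1, TN = absent & trait 0.
#' Species with NA trait values are excluded.
#' @param presence binary vector over species.
#' @param trait vector over species with values 1/0/NA.
#' @return named numeric: `accuracy`, `sensitivity`.
#' @export
reaction_trait_metrics <- function(presence, trait) {
  stopifnot(length(presence) == length(trait))
  keep <- !is.na(trait)
  if (!any(keep))
    stop("reaction_trait_metrics: trait is all NA")
  p <- as.numeric(presence[keep]); tr <- as.numeric(trait[keep])
  if (!all(p %in% c(0, 1)) || !all(tr %in% c(0, 1)))
    stop("reaction_trait_metrics: non-binary values")
  TP <- sum(p == 1 & tr == 1); FP <- sum(p == 1 & tr == 0)
  FN <- sum(p == 0 & tr == 1); TN <- sum(p == 0 & tr == 0)
  acc <- (TP + TN) / (TP + TN + FP + FN)
  sens <- if (TP + FN == 0) NaN else TP / (TP + FN)
  c(accuracy = acc, sensitivity = sens)
}

#' High-correlated reactions for a trait
#'
#' Returns reactions whose presence predicts the trait with
#' accuracy > `accuracy_threshold` AND sensitivity > `sensitivity_threshold`
#' (both strict).  Default thresholds 0.83/0.92 are the
#' galactose-pathway calibration.
#' @param existence binary species x reaction matrix.
#' @param trait vector over species (1/0/NA), aligned with rows.
#' @param accuracy_threshold,sensitivity_threshold strict cutoffs.
#' @return sorted character vector of reaction ids.
#' @export
find_correlated_reactions <- function(existence, trait,
                                      accuracy_threshold = 0.83,
                                      sensitivity_threshold = 0.92) {
  M <- as.matrix(existence)
  stopifnot(nrow(M) == length(trait))
  hits <- character(0)
  for (j in seq_len(ncol(M))) {
    met <- reaction_trait_metrics(M[, j], trait)
    if (!is.nan(met["sensitivity"]) &&
        met["accuracy"] > accuracy_threshold &&
        met["sensitivity"] > sensitivity_threshold)
      hits <- c(hits, colnames(M)[j])
  }
  sort(hits)
}

#' Classify trait changes against the ancestral state
#'
#' The ancestor (BYCA) is taken to possess a trait at posterior
#' probability >= `present_cutoff` (0.85) and to lack it below
#' `absent_cutoff` (0.15); intermediate posteriors, and NA species
#' values, yield "undetermined".
#' @param traits species x trait matrix/data.frame with 1/0/NA cells.
#' @param ancestor named numeric vector of posterior probabilities per
#'   trait.
#' @param present_cutoff,absent_cutoff posterior cutoffs.
#' @return character matrix (species x trait) with labels `gain`, `loss`,
#'   `retained_present`, `retained_absent`, `undetermined`.
#' @export
classify_trait_changes <- function(traits, ancestor,
                                   present_cutoff = 0.85,
                                   absent_cutoff = 0.15) {
  if (absent_cutoff >= present_cutoff)
    stop("classify_trait_changes: absent_cutoff must be < present_cutoff")
  M <- as.matrix(traits)
  out <- matrix("undetermined", nrow(M), ncol(M),
                dimnames = dimnames(M))
  for (tr in colnames(M)) {
    p <- ancestor[[tr]]
    if (is.null(p) || is.na(p)) next
    anc <- if (p >= present_cutoff) 1L
           else if (p < absent_cutoff) 0L
           else NA_integer_
    if (is.na(anc)) next
    sp <- M[, tr]
    out[, tr] <- ifelse(is.na(sp), "undetermined",
                 ifelse(sp == anc,
                        if (anc == 1) "retained_present" else "retained_absent",
                 ifelse(anc == 1, "loss", "gain")))
  }
  out
}

#' Attribute the mechanism of a simulated trait loss
#'
#' For a species that cannot utilize a substrate which the complete
#' (pan) network can, reports, in order: loss of a trait-correlated
#' reaction; loss of a reaction on the direct catabolic pathway; a
#' downstream-pathway gap (all direct-pathway reactions present, and
#' gap-filling restores utilization using only reactions outside the
#' direct pathway); otherwise unexplained.
#'
#' @param species_model species `gem`.
#' @param pan pan-model.
#' @param direct_pathway_reactions reaction ids of the substrate's direct
#'   catabolic pathway.
#' @param correlated reaction ids flagged as trait-correlated.
#' @param media a [media_spec()] used for gap-filling.
#' @param substrate_exchange_id exchange reaction of the substrate.
#' @param uptake_rate uptake allowance for the utilization test.
#' @return one of "correlated_reaction_loss", "noncorrelated_pathway_loss",
#'   "downstream_pathway_gap", "unexplained".
#' @export
attribute_loss_mechanism <- function(species_model, pan,
                                     direct_pathway_reactions,
                                     correlated, media,
                                     substrate_exchange_id,
                                     uptake_rate = 10) {
  if (test_substrate_utilization(species_model, substrate_exchange_id,
                                 uptake_rate))
    stop("attribute_loss_mechanism: species utilizes the substrate; ",
         "no loss to attribute")
  have <- reaction_ids(species_model)
  if (length(setdiff(correlated, have)) > 0)
    return("correlated_reaction_loss")
  if (length(setdiff(direct_pathway_reactions, have)) > 0)
    return("noncorrelated_pathway_loss")
  ## all direct-pathway reactions present: is there a gap elsewhere?
  sub_media <- .substrate_media(species_model, substrate_exchange_id,
                                uptake_rate)
  fill <- tryCatch(
    gap_fill(species_model, pan, sub_media),
    error = function(e) NULL)
  if (!is.null(fill) && length(fill) > 0 &&
      !any(fill %in% direct_pathway_reactions))
    return("downstream_pathway_gap")
  "unexplained"
}

## media with the default carbon source replaced by the given substrate
.substrate_media <- function(model, substrate_exchange_id, uptake_rate) {
  md <- model$media_defaults
  if (is.null(md)) stop("no media defaults on model")
  free <- setdiff(md$free, substrate_exchange_id)
  media_spec(c(substrate_exchange_id, free),
             lb = c(-uptake_rate, rep(-1000, length(free))))
}

#' Tally gain-of-function mechanisms per species
#'
#' Pure aggregation over gained traits: for each gain event, counts
#' whether the trait's direct-pathway genes intersect the
#' horizontally-transferred gene set, the expanded-family set, or the
#' promiscuous-enzyme set.  Categories are not mutually exclusive.
#'
#' @param changes species x trait label matrix from
#'   [classify_trait_changes()].
#' @param pathway_genes named list: trait id -> character vector of
#'   direct-pathway gene ids.
#' @param hgt_genes character vector of HGT-called gene ids.
#' @param expanded_genes character vector of expanded-family gene ids.
#' @param promiscuous_genes character vector of promiscuous ortholog ids
#'   (orthologs appearing in >= 2 reactions' GPRs; see
#'   [promiscuous_orthologs()]).
#' @return data.frame per species: `n_gains`, `hgt`, `expanded`,
#'   `promiscuity`.
#' @export
gain_mechanism_tally <- function(changes, pathway_genes,
                                 hgt_genes = character(0),
                                 expanded_genes = character(0),
                                 promiscuous_genes = character(0)) {
  M <- as.matrix(changes)
  if (is.null(rownames(M)))
    stop("gain_mechanism_tally: changes must have species rownames")
  out <- data.frame(species = rownames(M),
                    n_gains = 0L, hgt = 0L, expanded = 0L,
                    promiscuity = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(M))) {
    for (tr in colnames(M)) {
      if (M[i, tr] != "gain") next
      out$n_gains[i] <- out$n_gains[i] + 1L
      genes <- pathway_genes[[tr]] %||% character(0)
      if (length(intersect(genes, hgt_genes)))
        out$hgt[i] <- out$hgt[i] + 1L
      if (length(intersect(genes, expanded_genes)))
        out$expanded[i] <- out$expanded[i] + 1L
      if (length(intersect(genes, promiscuous_genes)))
        out$promiscuity[i] <- out$promiscuity[i] + 1L
    }
  }
  out
}

#' Promiscuous orthologs of a pan-model
#'
#' Orthologs appearing in the GPRs of at least `min_reactions` reactions.
#' @param pan a `gem`.
#' @param min_reactions default 2.
#' @return sorted character vector of gene ids.
#' @export
promiscuous_orthologs <- function(pan, min_reactions = 2) {
  counts <- table(unlist(lapply(pan$reactions,
                                function(r) gpr_genes(r$gpr))))
  sort(names(counts)[counts >= min_reactions])
}
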