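#' @title Horizontal gene transfer screening
#' @description
#' Screens per-gene BLAST hit tables for horizontal transfer.  Distant
#' (non-fungal donor) candidates are flagged by the Alien Index,
#' \deqn{AI = \ln(bbhG + 10^{-200}) - \ln(bbhO + 10^{-200}),}
#' where `bbhG`/`bbhO` are the best (smallest) E-values among
#' group-lineage and outside-group hits, combined with the out-group hit
#' percentage.  Close (fungal donor) candidates pass three sequential
#' bitscore filters.  Hit tables carry one row per hit with a taxonomy
#' class in `recipient_subphylum`, `group_lineage`, `outside_group`;
#' a gene with no hit in a lineage simply has no row for it.
#' @name hgt
NULL

#' Alien Index
#'
#' Natural-log ratio of best-hit E-values with a 1e-200 pseudo-count;
#' positive when the outside-group hit is stronger (smaller E-value).
#' A lineage with no hit is conventionally encoded as E-value 1.0 before
#' the call.
#' @param bbhG_evalue best group-lineage E-value (>= 0).
#' @param bbhO_evalue best outside-group E-value (>= 0).
#' @return the AI score.
#' @export
alien_index <- function(bbhG_evalue, bbhO_evalue) {
  if (any(c(bbhG_evalue, bbhO_evalue) < 0))
    stop("alien_index: E-values must be non-negative")
  log(bbhG_evalue + 1e-200) - log(bbhO_evalue + 1e-200)
}

.validate_hits <- function(hits) {
  hits <- as.data.frame(hits)
  need <- c("gene_id", "taxonomy_class", "evalue", "bitscore")
  if (!all(need %in% names(hits)))
    stop("hit table needs columns: ", paste(need, collapse = ", "))
  ok <- c("recipient_subphylum", "group_lineage", "outside_group")
  if (!all(hits$taxonomy_class %in% ok))
    stop("hit table: unknown taxonomy class ",
         paste(setdiff(unique(hits$taxonomy_class), ok), collapse = ", "))
  if (any(hits$evalue <= 0, na.rm = TRUE))
    stop("hit table: E-values must be positive")
  hits
}

## one hit-species unit per row unless a species column deduplicates
.hit_units <- function(h) {
  if ("species" %in% names(h)) h[!duplicated(h$species), ] else h
}

#' Out-group percentage of a gene's hits
#'
#' Fraction of (deduplicated) non-recipient hit species classed
#' `outside_group`.
#' @param hits hit rows for one gene.
#' @return fraction in [0, 1].
#' @export
out_group_percentage <- function(hits) {
  h <- .validate_hits(hits)
  if (!nrow(h)) stop("out_group_percentage: empty hit list")
  u <- .hit_units(h)
  denom <- sum(u$taxonomy_class != "recipient_subphylum")
  if (denom == 0) return(0)
  sum(u$taxonomy_class == "outside_group") / denom
}

#' Screen for distant (non-fungal donor) HGT candidates
#'
#' Flags a gene iff AI >= `ai_threshold` (default 45) and out-group
#' percentage >= `out_pct_threshold` (default 0.90), both inclusive.  A
#' lineage without a hit enters the AI as E-value 1.0.
#' @param table a hit table (all genes).
#' @param ai_threshold,out_pct_threshold inclusive thresholds.
#' @param absent_evalue E-value standing in for "no hit" (default 1.0).
#' @return data.frame per gene: `gene_id`, `AI`, `out_pct`, `screen`
#'   ("distant"/"none"), sorted by gene id.
#' @export
screen_distant <- function(table, ai_threshold = 45,
                           out_pct_threshold = 0.90,
                           absent_evalue = 1.0) {
  hits <- .validate_hits(table)
  genes <- sort(unique(hits$gene_id))
  res <- lapply(genes, function(g) {
    h <- hits[hits$gene_id == g, ]
    bbhG <- suppressWarnings(
      min(h$evalue[h$taxonomy_class == "group_lineage"]))
    bbhO <- suppressWarnings(
      min(h$evalue[h$taxonomy_class == "outside_group"]))
    if (!is.finite(bbhG)) bbhG <- absent_evalue
    if (!is.finite(bbhO)) bbhO <- absent_evalue
    ai <- alien_index(bbhG, bbhO)
    op <- out_group_percentage(h)
    data.frame(gene_id = g, AI = ai, out_pct = op,
               screen = if (ai >= ai_threshold && op >= out_pct_threshold)
                 "distant" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Screen for close (fungal donor) HGT candidates
#'
#' Three sequential filters: (1) the best non-recipient hit lies in the
#' group lineage with bitscore >= `bitscore_threshold` (100); (2) the
#' fraction of group-lineage hits among non-recipient hits is
#' >= `pct_threshold` (0.90); (3) the HGT index — best group-lineage
#' bitscore over best recipient bitscore — is >= `index_threshold` (0.5).
#' Genes without a recipient hit are skipped with a warning (index
#' undefined).
#' @param table a hit table (all genes).
#' @param bitscore_threshold,pct_threshold,index_threshold thresholds.
#' @return data.frame per gene: `gene_id`, `best_group_bitscore`,
#'   `group_pct`, `hgt_index`, `screen` ("close"/"none").
#' @export
screen_close <- function(table, bitscore_threshold = 100,
                         pct_threshold = 0.90,
                         index_threshold = 0.50) {
  hits <- .validate_hits(table)
  genes <- sort(unique(hits$gene_id))
  res <- lapply(genes, function(g) {
    h <- hits[hits$gene_id == g, ]
    grp <- h[h$taxonomy_class == "group_lineage", ]
    rec <- h[h$taxonomy_class == "recipient_subphylum", ]
    nonrec <- h[h$taxonomy_class != "recipient_subphylum", ]
    bg <- if (nrow(grp)) max(grp$bitscore) else NA_real_
    u <- .hit_units(nonrec)
    gp <- if (nrow(u)) sum(u$taxonomy_class == "group_lineage") / nrow(u)
          else NA_real_
    if (!nrow(rec)) {
      warning("screen_close: gene '", g,
              "' has no recipient hit; index undefined, skipped")
      return(data.frame(gene_id = g, best_group_bitscore = bg,
                        group_pct = gp, hgt_index = NA_real_,
                        screen = "none", stringsAsFactors = FALSE))
    }
    idx <- if (is.na(bg)) NA_real_ else bg / max(rec$bitscore)
    best_nonrec_in_group <- nrow(nonrec) > 0 &&
      nonrec$taxonomy_class[which.max(nonrec$bitscore)] == "group_lineage"
    pass <- !is.na(bg) && best_nonrec_in_group &&
      bg >= bitscore_threshold &&
      !is.na(gp) && gp >= pct_threshold &&
      !is.na(idx) && idx >= index_threshold
    data.frame(gene_id = g, best_group_bitscore = bg, group_pct = gp,
               hgt_index = idx, screen = if (pass) "close" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read / write hit tables
#'
#' TSV with columns `gene_id`, `taxonomy_class`, `evalue`, `bitscore`
#' (optional `species` for deduplication).
#' @param path file path.
#' @return data.frame.
#' @export
read_hit_table <- function(path) {
  .validate_hits(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_hit_table
#' @param hits a hit table.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
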