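#' @title Residue-level evolution on alignments and structures
#' @description
#' Column conservation by Jensen-Shannon divergence against a background
#' residue distribution, unique-mutation detection between trait groups
#' (heat-tolerance style), Calpha distances from candidate sites to
#' annotated functional sites, and a CLUMPS-style permutation test for
#' spatial clustering of selected sites on a 3D structure.
#' @name siteevo
NULL

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Alignment block
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (gap character "-").
#' @param reference name of the reference species; its sequence defines
#'   the ungapped 1-based position mapping.
#' @return list of class `alignment_block` with `seqs`, `reference`,
#'   `ref_pos` (per column: reference position or NA at reference gaps).
#' @export
alignment_block <- function(seqs, reference) {
  if (length(unique(nchar(seqs))) != 1)
    stop("alignment_block: unequal aligned lengths")
  if (!reference %in% names(seqs))
    stop("alignment_block: reference species not in alignment")
  refchars <- strsplit(seqs[[reference]], "")[[1]]
  ref_pos <- rep(NA_integer_, length(refchars))
  ref_pos[refchars != "-"] <- seq_len(sum(refchars != "-"))
  structure(list(seqs = seqs, reference = reference, ref_pos = ref_pos),
            class = "alignment_block")
}

.aln_matrix <- function(block) {
  do.call(rbind, strsplit(toupper(block$seqs), ""))
}

#' Jensen-Shannon divergence conservation scores
#'
#' Per alignment column: the observed residue distribution (gaps
#' excluded) is compared to the background by base-2 JSD with equal
#' weights, then linearly penalized by the gap fraction
#' (`score * (1 - gap_fraction)`).  Columns with gap fraction above the
#' cutoff are flagged low-confidence but still scored; all-gap columns
#' score 0.
#'
#' @param block an [alignment_block()].
#' @param background length-20 named frequency vector over the amino
#'   acids (default uniform); must sum to 1.
#' @param gap_cutoff flag columns with gap fraction above this (0.3).
#' @return data.frame: `column`, `ref_pos`, `score`, `gap_fraction`,
#'   `low_confidence`.
#' @export
jsd_conservation <- function(block,
                             background = stats::setNames(
                               rep(1 / 20, 20), AA20),
                             gap_cutoff = 0.3) {
  if (abs(sum(background) - 1) > 1e-9)
    stop("jsd_conservation: background must sum to 1")
  background <- background[AA20]
  M <- .aln_matrix(block)
  ncols <- ncol(M)
  score <- numeric(ncols); gapf <- numeric(ncols)
  for (j in seq_len(ncols)) {
    col <- M[, j]
    gaps <- col %in% c("-", ".")
    gapf[j] <- mean(gaps)
    res <- col[!gaps & col %in% AA20]
    if (!length(res)) { score[j] <- 0; next }
    p <- as.numeric(table(factor(res, levels = AA20))) / length(res)
    score[j] <- .jsd2(p, as.numeric(background)) * (1 - gapf[j])
  }
  data.frame(column = seq_len(ncols), ref_pos = block$ref_pos,
             score = score, gap_fraction = gapf,
             low_confidence = gapf > gap_cutoff | gapf == 1)
}

## base-2 Jensen-Shannon divergence with lambda = 0.5
.jsd2 <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Unique mutations associated with a trait group
#'
#' A residue is reported at a reference position iff its frequency among
#' the tolerant species exceeds `conserved_threshold` (0.80) and it is
#' not in the reference residue set (residues at frequency above
#' `reference_threshold`, 0.20, among the non-tolerant species).  Gaps
#' are not residues; frequencies are computed over species with a
#' non-gap character at the column (set `count_gaps = TRUE` to keep gaps
#' in the denominator).  Only columns mappable to the reference sequence
#' are reported.
#'
#' @param block an [alignment_block()].
#' @param tolerant_species,non_tolerant_species disjoint, non-empty
#'   species sets present in the block.
#' @param conserved_threshold,reference_threshold strict frequency
#'   thresholds.
#' @param count_gaps include gapped species in the denominators.
#' @return data.frame: `ref_pos`, `residue`, `tolerant_freq`.
#' @export
unique_mutations <- function(block, tolerant_species,
                             non_tolerant_species,
                             conserved_threshold = 0.80,
                             reference_threshold = 0.20,
                             count_gaps = FALSE) {
  if (!length(tolerant_species) || !length(non_tolerant_species))
    stop("unique_mutations: species sets must be non-empty")
  if (length(intersect(tolerant_species, non_tolerant_species)))
    stop("unique_mutations: species sets overlap")
  if (!all(c(tolerant_species, non_tolerant_species) %in%
           names(block$seqs)))
    stop("unique_mutations: species missing from alignment")
  M <- .aln_matrix(block)
  rownames(M) <- names(block$seqs)
  freq_of <- function(colv, group) {
    v <- colv[group]
    if (!count_gaps) v <- v[v != "-"]
    if (!length(v)) return(stats::setNames(numeric(0), character(0)))
    n <- if (count_gaps) length(colv[group]) else length(v)
    table(v[v != "-"]) / n
  }
  out <- list()
  for (j in which(!is.na(block$ref_pos))) {
    ft <- freq_of(M[, j], tolerant_species)
    fn <- freq_of(M[, j], non_tolerant_species)
    refset <- names(fn)[fn > reference_threshold]
    hits <- names(ft)[ft > conserved_threshold]
    for (r in setdiff(hits, refset)) {
      out[[length(out) + 1L]] <- data.frame(
        ref_pos = block$ref_pos[j], residue = r,
        tolerant_freq = as.numeric(ft[r]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(ref_pos = integer(0), residue = character(0),
                      tolerant_freq = numeric(0)))
  do.call(rbind, out)
}

#' Structure model
#'
#' @param coords numeric n x 3 matrix of Calpha coordinates (Angstrom),
#'   row i = residue i (1-based).
#' @param sites named list: category -> integer vector of annotated
#'   residue indices.
#' @return list of class `structure_model`.
#' @export
structure_model <- function(coords, sites = list()) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  for (cat in names(sites)) {
    if (any(sites[[cat]] < 1 | sites[[cat]] > nrow(coords)))
      stop("structure_model: annotated index outside structure (", cat, ")")
  }
  structure(list(coords = coords, sites = sites),
            class = "structure_model")
}

#' Distance from candidate sites to annotated functional sites
#'
#' Minimum Calpha-Calpha Euclidean distance from each site to any
#' annotated residue of the selected categories; a site is "adjacent"
#' iff that distance is <= `adjacency` (10 Angstrom).
#' @param sites integer vector of residue positions.
#' @param structure a [structure_model()].
#' @param categories annotation categories to use (default all).
#' @param adjacency distance cutoff, Angstrom.
#' @return data.frame: `site`, `min_distance`, `adjacent`.
#' @export
distance_to_functional_sites <- function(sites, structure,
                                         categories = names(structure$sites),
                                         adjacency = 10) {
  idx <- sort(unique(unlist(structure$sites[categories])))
  if (!length(idx))
    stop("distance_to_functional_sites: no annotated residues in the ",
         "selected categories")
  if (any(sites < 1 | sites > nrow(structure$coords)))
    stop("distance_to_functional_sites: site outside structure")
  X <- structure$coords
  d <- vapply(sites, function(s) {
    min(sqrt(colSums((t(X[idx, , drop = FALSE]) - X[s, ])^2)))
  }, numeric(1))
  data.frame(site = sites, min_distance = d, adjacent = d <= adjacency)
}

#' CLUMPS-style spatial clustering test
#'
#' Observed score: sum over site pairs of
#' \eqn{\exp(-d_{ij}^2 / (2 t^2))} with Calpha distances and bandwidth
#' t (6 Angstrom).  The null distribution redraws the same number of
#' residue positions uniformly without replacement `n_permutations`
#' times; \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n)}.
#' @param sites >= 2 residue positions.
#' @param structure a [structure_model()].
#' @param n_permutations >= 100.
#' @param seed integer seed for the permutation draws.
#' @param bandwidth Gaussian bandwidth t, Angstrom.
#' @return list: `score`, `p_value`, `n_permutations`.
#' @export
clumps_test <- function(sites, structure, n_permutations = 10000,
                        seed = 1, bandwidth = 6) {
  if (length(sites) < 2)
    stop("clumps_test: cluster undefined for fewer than 2 sites")
  if (n_permutations < 100)
    stop("clumps_test: need at least 100 permutations")
  X <- structure$coords
  n_res <- nrow(X)
  if (any(sites < 1 | sites > n_res))
    stop("clumps_test: site outside structure")
  D2 <- as.matrix(stats::dist(X))^2
  K <- exp(-D2 / (2 * bandwidth^2))
  pair_score <- function(ix) {
    sub <- K[ix, ix]
    (sum(sub) - length(ix)) / 2
  }
  obs <- pair_score(sites)
  null <- .with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      pair_score(sample.int(n_res, length(sites)))
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + n_permutations)
  list(score = obs, p_value = p, n_permutations = n_permutations)
}

## run code under a temporary RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Read Calpha coordinates from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb` extracting Calpha atoms of one
#' chain into a [structure_model()].
#' @param path PDB file.
#' @param chain chain identifier (default first chain found).
#' @return a [structure_model()].
#' @export
read_ca_pdb <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$elety == "CA", ]
  if (!is.null(chain)) at <- at[at$chain == chain, ]
  if (!nrow(at)) stop("read_ca_pdb: no Calpha atoms found")
  coords <- as.matrix(at[, c("x", "y", "z")])
  rownames(coords) <- at$resno
  structure_model(coords)
}

#' Write Calpha-only PDB ATOM records
#' @param coords n x 3 coordinate matrix (residue per row).
#' @param path output path.
#' @export
write_ca_pdb <- function(coords, path) {
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, coords[i, 1], coords[i, 2], coords[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
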