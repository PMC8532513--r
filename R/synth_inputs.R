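#' @title Synthetic HGT hit tables, labelled sequences and structures
#' @description
#' Seeded generators for the remaining pipeline inputs: per-gene BLAST
#' hit tables with planted distant/close HGT signatures, two-class
#' nucleotide sequence sets with class-separated trinucleotide profiles
#' and class-conditional evolution features, and alignment + helical
#' structure pairs with a planted spatial cluster of fast-evolving
#' sites.
#' @name synthetic_inputs
NULL

#' Generate a BLAST hit table with planted HGT genes
#'
#' Non-HGT genes have their best hits in the recipient subphylum with
#' group-lineage hits dominating the remainder.  Planted distant-HGT
#' genes carry outside-group best hits at least e^45 stronger (smaller
#' E-value) than any group-lineage hit with >= 90% outside-group hit
#' rows; planted close-HGT genes carry group-lineage best hits with
#' bitscore >= 100, >= 90% group-lineage hit rows, and an HGT index
#' >= 0.5.  A lineage without a hit simply has no row.
#'
#' @param n_genes total genes.
#' @param n_hgt_distant,n_hgt_close planted counts
#'   (`n_hgt_distant + n_hgt_close <= n_genes`).
#' @param seed integer seed.
#' @return list: `table` (hit data.frame), `distant_genes`,
#'   `close_genes`.
#' @export
generate_hit_table <- function(n_genes, n_hgt_distant, n_hgt_close,
                               seed = 1) {
  if (n_hgt_distant + n_hgt_close > n_genes)
    stop("generate_hit_table: planted counts exceed n_genes")
  .with_seed(seed, {
    ids <- sprintf("gene%04d", seq_len(n_genes))
    distant <- if (n_hgt_distant) ids[seq_len(n_hgt_distant)]
               else character(0)
    close <- if (n_hgt_close)
      ids[n_hgt_distant + seq_len(n_hgt_close)] else character(0)
    loge <- function(n, lo, hi) 10^stats::runif(n, lo, hi)
    rows <- list()
    emit <- function(g, cls, ev, bs) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = g, taxonomy_class = cls, evalue = ev, bitscore = bs,
        stringsAsFactors = FALSE)
    }
    for (g in ids) {
      if (g %in% distant) {
        ## strong outside-group hits, one weak group hit, one recipient hit
        bbhG <- loge(1, -28, -15)
        emit(g, "group_lineage", bbhG, stats::runif(1, 60, 90))
        bbhO <- bbhG * exp(-stats::runif(1, 50, 70))
        emit(g, "outside_group", bbhO, stats::runif(1, 300, 600))
        emit(g, "outside_group", bbhO * 10^stats::runif(9, 0, 8),
             stats::runif(9, 150, 300))
        emit(g, "recipient_subphylum", loge(1, -40, -20),
             stats::runif(1, 80, 120))
      } else if (g %in% close) {
        ## recipient best, strong group-lineage block, no outside hits
        rec_bs <- stats::runif(1, 180, 260)
        emit(g, "recipient_subphylum", loge(1, -120, -80), rec_bs)
        grp_best <- rec_bs * stats::runif(1, 0.6, 0.95)
        emit(g, "group_lineage", loge(1, -90, -60), max(grp_best, 110))
        emit(g, "group_lineage", loge(10, -60, -30),
             stats::runif(10, 60, grp_best))
        emit(g, "outside_group", loge(1, -8, -2),
             stats::runif(1, 30, 50))
      } else {
        ## vertical gene: recipient dominates, group beats outside
        rec_bs <- stats::runif(1, 400, 900)
        rec_ev <- loge(1, -180, -120)
        emit(g, "recipient_subphylum", rec_ev, rec_bs)
        emit(g, "recipient_subphylum", loge(4, -120, -60),
             stats::runif(4, 200, 400))
        bbhG <- loge(1, -60, -30)
        emit(g, "group_lineage", bbhG, rec_bs * stats::runif(1, 0.2, 0.4))
        emit(g, "group_lineage", bbhG * 10^stats::runif(2, 0, 10),
             stats::runif(2, 60, 120))
        emit(g, "outside_group", bbhG * 10^stats::runif(1, 3, 10),
             stats::runif(1, 40, 80))
      }
    }
    list(table = do.call(rbind, rows),
         distant_genes = distant, close_genes = close)
  })
}

#' Generate labelled nucleotide sequences with evolution features
#'
#' Two classes ("essential"/"non-essential") are drawn codon-wise from
#' trinucleotide profiles separated by `shift` (per-codon probability
#' multipliers `1 +/- shift` on complementary halves of the 64 codons),
#' plus class-conditional evolution features: essential genes carry
#' higher conservation and occurrence and lower dN/dS and paralog
#' counts.
#'
#' @param n_per_class records per class.
#' @param length nucleotide length (>= 30).
#' @param shift profile separation in [0, 0.3].
#' @param seed integer seed.
#' @return list: `sequences` (named character vector), `labels`
#'   (1 = essential), `evo` (per-record evolution feature data.frame),
#'   `profiles` (the two trinucleotide profiles).
#' @export
generate_sequences <- function(n_per_class, length, shift, seed = 1) {
  if (length < 30) stop("generate_sequences: length must be >= 30")
  if (shift < 0 || shift > 0.3)
    stop("generate_sequences: shift must lie in [0, 0.3]")
  nuc <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(nuc, nuc, paste0), nuc, paste0))
  codons <- codons[order(codons)]
  sgn <- rep(c(1, -1), 32)               # alternating codon halves
  p1 <- (1 + shift * sgn) / 64; p1 <- p1 / sum(p1)   # essential
  p0 <- (1 - shift * sgn) / 64; p0 <- p0 / sum(p0)
  n_codon <- ceiling(length / 3)
  .with_seed(seed, {
    draw <- function(p) {
      s <- paste(sample(codons, n_codon, replace = TRUE, prob = p),
                 collapse = "")
      substr(s, 1, length)
    }
    seqs <- c(vapply(seq_len(n_per_class), function(i) draw(p1),
                     character(1)),
              vapply(seq_len(n_per_class), function(i) draw(p0),
                     character(1)))
    labels <- rep(c(1L, 0L), each = n_per_class)
    names(seqs) <- sprintf("%s%04d",
                           ifelse(labels == 1, "ess", "non"),
                           seq_along(seqs))
    n <- 2 * n_per_class
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    evo <- data.frame(
      gene_id = names(seqs),
      conservation_score = clamp(
        stats::rnorm(n, ifelse(labels == 1, 0.80, 0.60), 0.08), 0, 1),
      dn_ds = clamp(
        stats::rlnorm(n, log(ifelse(labels == 1, 0.08, 0.30)), 0.4),
        0, 5),
      occurrence_count = stats::rbinom(n, 100,
                                       ifelse(labels == 1, 0.9, 0.6)),
      avg_paralog_number = 1 + stats::rexp(
        n, rate = ifelse(labels == 1, 20, 4)),
      stringsAsFactors = FALSE)
    list(sequences = seqs, labels = labels, evo = evo,
         profiles = list(essential = stats::setNames(p1, codons),
                         non_essential = stats::setNames(p0, codons)))
  })
}

#' Generate an alignment + structure with a planted spatial cluster
#'
#' Builds a hairpin of two ideal helical segments (1.5 Angstrom rise and
#' 100 degree turn per residue, 2.3 Angstrom radius) packed antiparallel
#' ~5 Angstrom apart, so that residues near the hairpin are
#' sequence-distant yet spatially adjacent.  The planted fast-evolving
#' sites alternate between the two segments at matched heights (all
#' within < 6 Angstrom of another cluster member); invariant
#' "functional" columns are annotated at least 10 Angstrom from every
#' cluster site.  The alignment keeps the reference ungapped; cluster
#' columns mutate fast, functional columns never, the rest slowly.
#'
#' @param n_species aligned species (>= 4).
#' @param length residues (>= 50).
#' @param n_cluster_sites planted fast sites (>= 3, <= length/4).
#' @param seed integer seed.
#' @return list: `block` ([alignment_block()]), `structure`
#'   ([structure_model()] with a `functional` annotation), `fast_sites`,
#'   `functional_sites`, `dnds` (per-site data.frame).
#' @export
generate_structure_alignment <- function(n_species = 12, length = 80,
                                         n_cluster_sites = 4, seed = 1) {
  if (length < 50) stop("generate_structure_alignment: length must be >= 50")
  if (n_cluster_sites < 3)
    stop("generate_structure_alignment: need >= 3 cluster sites")
  if (n_cluster_sites > length / 4)
    stop("generate_structure_alignment: n_cluster_sites exceeds length/4")

  half <- floor(length / 2)
  rise <- 1.5; turn <- 100 * pi / 180; radius <- 2.3
  coords <- matrix(NA_real_, length, 3)
  for (i in seq_len(half)) {                      # helix A, ascending z
    coords[i, ] <- c(radius * cos(turn * i), radius * sin(turn * i),
                     rise * i)
  }
  sep <- 5.0                                      # inter-helix packing
  for (i in (half + 1):length) {                  # helix B, descending z
    j <- i - half
    coords[i, ] <- c(sep + radius * cos(-turn * j),
                     radius * sin(-turn * j),
                     rise * (half - j + 1))
  }

  ## anchor the cluster on the closest cross-segment residue pair with a
  ## sequence gap of at least 5, then extend along each helix (3.8 A
  ## consecutive Calpha steps keep every site within 6 A of a neighbour)
  js <- 3:(half - 3)
  cross_d <- vapply(js, function(j) {
    sqrt(sum((coords[half - j + 1, ] - coords[half + j, ])^2))
  }, numeric(1))
  jstar <- js[which.min(cross_d)]
  if (min(cross_d) >= 6)
    stop("generate_structure_alignment: no adjacent cross-segment pair")
  a <- half - jstar + 1L; b <- half + jstar
  nA <- ceiling(n_cluster_sites / 2); nB <- n_cluster_sites - nA
  fast <- sort(c(a - seq_len(nA) + 1L, if (nB) b + seq_len(nB) - 1L))

  ## functional sites: far end of helix A, >= 10 A from every fast site
  d_to_fast <- vapply(seq_len(length), function(i)
    min(sqrt(colSums((t(coords[fast, , drop = FALSE]) - coords[i, ])^2))),
    numeric(1))
  cand <- setdiff(which(d_to_fast >= 10), fast)
  if (length(cand) < 3)
    stop("generate_structure_alignment: structure too small to separate ",
         "functional sites from the cluster")
  functional <- sort(cand[seq_len(3)])

  aa_pool <- c("A","C","D","E","F","G","H","I","K","L",
               "M","N","P","Q","R","S","T","V","W","Y")
  .with_seed(seed, {
    ref <- sample(aa_pool, length, replace = TRUE)
    seqs <- character(n_species)
    species <- sprintf("sp%02d", seq_len(n_species))
    for (s in seq_len(n_species)) {
      if (s == 1) { seqs[s] <- paste(ref, collapse = ""); next }
      chars <- ref
      for (j in seq_len(length)) {
        if (j %in% functional) next                     # invariant
        rate <- if (j %in% fast) 0.8 else 0.08
        if (stats::runif(1) < rate)
          chars[j] <- sample(aa_pool, 1)
        else if (stats::runif(1) < 0.02)
          chars[j] <- "-"
      }
      seqs[s] <- paste(chars, collapse = "")
    }
    names(seqs) <- species
    block <- alignment_block(seqs, reference = species[1])
    dnds <- data.frame(
      ref_pos = seq_len(length),
      dn_ds = ifelse(seq_len(length) %in% fast,
                     stats::runif(length, 1.3, 3.0),
                     stats::runif(length, 0.02, 0.6)))
    structure <- structure_model(coords,
                                 sites = list(functional = functional))
    list(block = block, structure = structure,
         fast_sites = fast, functional_sites = functional,
         dnds = dnds)
  })
}
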