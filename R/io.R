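#' @title Plain-text serialization of synthetic worlds
#' @description
#' Writers for every artefact a synthetic world feeds downstream:
#' pan-model JSON, existence/trait/kcat/MW TSVs, newick tree, FASTA,
#' Calpha-only PDB and the planted-truth JSON.  All writers are
#' deterministic: regenerating a world from the same seed and re-writing
#' it yields byte-identical files.
#' @name world_io
NULL

#' Write a FASTA file
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a FASTA file
#' @param path input path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  nm <- sub("^>", "", lines[hdr])
  body <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(as.character(body), nm)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a binary matrix (existence or trait table) as TSV
#' @param M matrix with dimnames.
#' @param path output path.
#' @param id_col name of the first (row-id) column.
#' @export
write_matrix_tsv <- function(M, path, id_col = "species") {
  df <- data.frame(rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  .write_tsv(df, path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#' @param path input path.
#' @return matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}

#' Write every artefact of a synthetic world to a directory
#'
#' Emits `pan.json`, `existence.tsv`, `tree.nwk`, `kcat.tsv`, `mw.tsv`
#' (the overflow parameter set), and `truth.json`.
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pan_json(world$pan, file.path(dir, "pan.json"))
  write_matrix_tsv(world$existence, file.path(dir, "existence.tsv"))
  ape::write.tree(world$tree, file.path(dir, "tree.nwk"))
  .write_tsv(world$ec$kcat, file.path(dir, "kcat.tsv"))
  .write_tsv(world$ec$mw, file.path(dir, "mw.tsv"))
  truth <- world$truth
  truth$expected_traits <- as.data.frame(truth$expected_traits)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}
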