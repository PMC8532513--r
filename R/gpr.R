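#' @title Gene-protein-reaction (GPR) boolean logic
#' @description
#' GPR rules gate a reaction's availability on gene content: `and` joins the
#' subunits of an enzyme complex, `or` joins isozymes.  Trees are plain
#' lists: `list(kind = "gene", gene = id)` or
#' `list(kind = "and"/"or", children = list(...))`; `NULL` means "no rule"
#' (spontaneous/exchange reactions, always available).
#' @name gpr
NULL

gpr_gene <- function(id) list(kind = "gene", gene = id)
gpr_and <- function(...) list(kind = "and", children = list(...))
gpr_or  <- function(...) list(kind = "or",  children = list(...))

#' Parse a GPR rule string
#'
#' Grammar: identifiers, `and`, `or` (case-insensitive) and parentheses;
#' `and` binds tighter than `or`.  The returned tree is normalized: nested
#' nodes of the same kind are flattened, duplicate children merged, and
#' single-child nodes collapsed.
#'
#' @param text GPR string; empty or all-whitespace yields `NULL`.
#' @return a GPR tree (or `NULL`).
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text)) return(NULL)
  text <- as.character(text)
  if (!nzchar(trimws(text))) return(NULL)

  ## tokenize, tracking character offsets for error messages
  toks <- list(); pos <- 1L; nch <- nchar(text)
  while (pos <= nch) {
    ch <- substr(text, pos, pos)
    if (grepl("^\\s$", ch)) { pos <- pos + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, at = pos)
      pos <- pos + 1L
      next
    }
    mt <- regmatches(substr(text, pos, nch),
                     regexpr("^[A-Za-z0-9_.:-]+", substr(text, pos, nch)))
    if (!length(mt))
      stop("parse_gpr: unexpected character '", ch, "' at offset ", pos)
    word <- mt[[1]]
    lw <- tolower(word)
    type <- if (lw == "and") "and" else if (lw == "or") "or" else "id"
    toks[[length(toks) + 1L]] <- list(type = type, value = word, at = pos)
    pos <- pos + nchar(word)
  }
  if (!length(toks)) return(NULL)

  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() { tk <- toks[[i]]; i <<- i + 1L; tk }

  parse_factor <- function() {
    tk <- peek()
    if (is.null(tk))
      stop("parse_gpr: dangling operator at offset ", nch + 1L)
    if (tk$type == "(") {
      advance()
      node <- parse_expr()
      cl <- peek()
      if (is.null(cl) || cl$type != ")")
        stop("parse_gpr: unbalanced parentheses at offset ", tk$at)
      advance()
      return(node)
    }
    if (tk$type == "id") {
      advance()
      return(gpr_gene(tk$value))
    }
    stop("parse_gpr: unexpected token '",
         if (is.null(tk$value)) tk$type else tk$value,
         "' at offset ", tk$at)
  }
  parse_term <- function() {
    kids <- list(parse_factor())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      kids[[length(kids) + 1L]] <- parse_factor()
    }
    if (length(kids) == 1L) kids[[1L]] else list(kind = "and", children = kids)
  }
  parse_expr <- function() {
    kids <- list(parse_term())
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      kids[[length(kids) + 1L]] <- parse_term()
    }
    if (length(kids) == 1L) kids[[1L]] else list(kind = "or", children = kids)
  }

  tree <- parse_expr()
  if (!is.null(peek()))
    stop("parse_gpr: unexpected token at offset ", peek()$at)
  normalize_gpr(tree)
}

#' Normalize a GPR tree
#'
#' Flattens nested same-kind nodes, removes duplicate children (by
#' serialized form) and collapses single-child nodes.
#' @param gpr a GPR tree or `NULL`.
#' @return normalized tree (or `NULL`).
#' @export
normalize_gpr <- function(gpr) {
  if (is.null(gpr)) return(NULL)
  if (gpr$kind == "gene") return(gpr)
  kids <- list()
  for (ch in gpr$children) {
    ch <- normalize_gpr(ch)
    if (is.null(ch)) next
    if (ch$kind == gpr$kind) kids <- c(kids, ch$children)
    else kids[[length(kids) + 1L]] <- ch
  }
  if (!length(kids)) return(NULL)
  keys <- vapply(kids, write_gpr, character(1))
  kids <- kids[!duplicated(keys)]
  if (length(kids) == 1L) return(kids[[1L]])
  list(kind = gpr$kind, children = kids)
}

#' Serialize a GPR tree to its string form
#'
#' Inverse of [parse_gpr()] up to normalization; `and` groups under `or`
#' need no parentheses (precedence), `or` groups under `and` are
#' parenthesized.
#' @param gpr GPR tree or `NULL`.
#' @return single string ("" for `NULL`).
#' @export
write_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  if (gpr$kind == "gene") return(gpr$gene)
  parts <- vapply(gpr$children, function(ch) {
    s <- write_gpr(ch)
    if (gpr$kind == "and" && ch$kind == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", gpr$kind, " "))
}

#' Gene identifiers appearing in a GPR tree
#' @param gpr GPR tree or `NULL`.
#' @return character vector (possibly empty), unique, in first-appearance order.
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (gpr$kind == "gene") return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}

#' Evaluate a GPR rule against a gene set
#'
#' Complex (`and`) semantics follow the majority-subunit rule: an `and` node
#' is active iff strictly more than 50% of its child subunits are satisfied,
#' and its pruned form drops the missing subunits.  An `or` node (isozymes)
#' is active iff at least one child is active; inactive children are
#' dropped.  An empty rule (`NULL`) is always active.
#'
#' @param gpr GPR tree or `NULL`.
#' @param present_genes character vector of present gene ids.
#' @return list with `active` (logical) and `pruned` (GPR tree or `NULL`;
#'   `NULL` whenever `active` is `FALSE`).
#' @export
evaluate_gpr <- function(gpr, present_genes) {
  gpr <- normalize_gpr(gpr)
  if (is.null(gpr)) return(list(active = TRUE, pruned = NULL))
  res <- .eval_gpr_node(gpr, present_genes)
  if (!res$active) return(list(active = FALSE, pruned = NULL))
  list(active = TRUE, pruned = normalize_gpr(res$pruned))
}

.eval_gpr_node <- function(node, present) {
  if (node$kind == "gene") {
    ok <- node$gene %in% present
    return(list(active = ok, pruned = if (ok) node else NULL))
  }
  kid_res <- lapply(node$children, .eval_gpr_node, present = present)
  act <- vapply(kid_res, `[[`, logical(1), "active")
  if (node$kind == "or") {
    if (!any(act)) return(list(active = FALSE, pruned = NULL))
    keep <- lapply(kid_res[act], `[[`, "pruned")
    return(list(active = TRUE, pruned = list(kind = "or", children = keep)))
  }
  ## and: strictly more than half of the subunit slots must be satisfied
  if (sum(act) * 2L <= length(act))
    return(list(active = FALSE, pruned = NULL))
  keep <- lapply(kid_res[act], `[[`, "pruned")
  list(active = TRUE, pruned = list(kind = "and", children = keep))
}

#' Integrate a homolog gene into a GPR rule
#'
#' Adds `homolog_gene` wherever `reference_gene` participates: a bare
#' reference leaf (at the root or under an `or`) gains the homolog as an
#' `or`-sibling ("A or B" becomes "A or B or C"); each maximal `and` term
#' containing the reference is duplicated with the reference replaced by
#' the homolog ("A and B" becomes "(A and B) or (C and B)").
#'
#' @param gpr GPR tree.
#' @param reference_gene gene id already present in `gpr`.
#' @param homolog_gene gene id to integrate.
#' @return normalized GPR tree; if the reference does not occur the rule is
#'   returned unchanged with a warning.
#' @export
integrate_homolog <- function(gpr, reference_gene, homolog_gene) {
  gpr <- normalize_gpr(gpr)
  if (is.null(gpr) || !(reference_gene %in% gpr_genes(gpr))) {
    warning("integrate_homolog: reference gene '", reference_gene,
            "' not found; rule unchanged")
    return(gpr)
  }
  normalize_gpr(.integrate_node(gpr, reference_gene, homolog_gene))
}

.integrate_node <- function(node, ref, hom) {
  if (node$kind == "gene") {
    if (identical(node$gene, ref))
      return(list(kind = "or", children = list(node, gpr_gene(hom))))
    return(node)
  }
  if (node$kind == "or") {
    kids <- list(); saw_ref_leaf <- FALSE
    for (ch in node$children) {
      if (ch$kind == "gene" && identical(ch$gene, ref)) {
        saw_ref_leaf <- TRUE
        kids[[length(kids) + 1L]] <- ch
      } else {
        kids[[length(kids) + 1L]] <- .integrate_node(ch, ref, hom)
      }
    }
    if (saw_ref_leaf) kids[[length(kids) + 1L]] <- gpr_gene(hom)
    return(list(kind = "or", children = kids))
  }
  ## maximal and-term: duplicate with the reference swapped for the homolog
  if (ref %in% gpr_genes(node)) {
    dup <- .swap_gene(node, ref, hom)
    return(list(kind = "or", children = list(node, dup)))
  }
  node
}

.swap_gene <- function(node, ref, hom) {
  if (node$kind == "gene") {
    if (identical(node$gene, ref)) return(gpr_gene(hom))
    return(node)
  }
  node$children <- lapply(node$children, .swap_gene, ref = ref, hom = hom)
  node
}
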