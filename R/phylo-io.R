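#' Read a rooted tree from a newick file or string
#'
#' Parses a newick tree (via \pkg{ape}) after a light structural scan that
#' reports the character offset of unbalanced parentheses or stray
#' characters. Trees are treated as rooted as written; every branch must
#' carry a length (no silent defaults).
#'
#' @param source Path to a newick file, or a string containing a newick
#'   description (anything ending in `;`).
#' @return A `phylo` object. The rooting convention (rooted-as-written) is
#'   recorded in attribute `"rooted_as_written"`.
#' @examples
#' tr <- read_master_tree("((A:1,B:1):1,C:2);")
#' branch_table(tr)
#' @export
read_master_tree <- function(source) {
  txt <- if (length(source) == 1 && !grepl(";", source) && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "")
  } else {
    paste(source, collapse = "")
  }
  txt <- trimws(txt)
  if (!nzchar(txt)) abort("empty newick input")
  scan_newick(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) abort("newick parse failed")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("newick tree has branches without lengths; lengths are required")
  }
  if (any(tree$edge.length < 0)) abort("negative branch length in newick input")
  if (anyDuplicated(tree$tip.label)) abort("duplicated taxon labels in tree")
  attr(tree, "rooted_as_written") <- TRUE
  tree
}

# Structural pre-scan: balanced parentheses, legal characters, terminating
# semicolon. Errors name the 1-based character offset, which ape does not.
scan_newick <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("malformed newick: unmatched ')' at character %d", i))
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf(
      "malformed newick: %d unclosed '(' (last opened at character %d)",
      depth, max(which(chars == "("))
    ))
  }
  semi <- which(chars == ";")
  if (length(semi) == 0) abort("malformed newick: missing terminating ';'")
  invisible(TRUE)
}

#' Tabulate the branches of a tree by bipartition
#'
#' Every branch of a rooted tree is identified by the set of terminal taxa
#' descending from it (its bipartition), not by newick position, so branches
#' of different trees over shared taxa can be matched unambiguously. The
#' root's two child branches are kept distinct.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A tibble with one row per branch: `branch_id` (sorted descendant
#'   taxa joined by `|`), `parent` and `child` node numbers, `length`,
#'   `n_tips`, and `is_terminal`.
#' @export
branch_table <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  sets <- node_tip_sets(tree)
  n_tip <- length(tree$tip.label)
  child <- tree$edge[, 2L]
  tips <- lapply(sets[child], function(i) tree$tip.label[i])
  tibble(
    branch_id = make_branch_id(tips),
    parent = tree$edge[, 1L],
    child = child,
    length = tree$edge.length,
    n_tips = lengths(tips),
    is_terminal = child <= n_tip
  )
}

#' Filter alignment species by gap content
#'
#' Species whose aligned sequence is more than `max_gap_frac` gaps are
#' removed before tree-based analyses; the default threshold removes
#' sequences with strictly more than 30% gaps. Only `-` counts as a gap;
#' ambiguity characters (`N`, `X`) do not.
#'
#' @param alignment Path to an aligned FASTA file, or a named character
#'   vector of equal-length aligned sequences.
#' @param max_gap_frac Largest tolerated gap fraction; strictly exceeding it
#'   removes the species. Default 0.30.
#' @return A tibble with `species`, `n_gaps`, `width`, `gap_frac`, and
#'   logical `retained`.
#' @export
filter_alignment_species <- function(alignment, max_gap_frac = 0.30) {
  if (is.character(alignment) && length(alignment) == 1 && file.exists(alignment)) {
    seqs <- Biostrings::readBStringSet(alignment)
    species <- names(seqs)
    widths <- Biostrings::width(seqs)
    n_gaps <- as.integer(Biostrings::letterFrequency(seqs, letters = "-"))
  } else {
    if (length(alignment) == 0) abort("empty alignment")
    species <- names(alignment) %||% as.character(seq_along(alignment))
    widths <- nchar(alignment)
    n_gaps <- vapply(
      strsplit(alignment, ""),
      function(ch) sum(ch == "-"), integer(1)
    )
  }
  if (length(species) == 0) abort("empty alignment")
  if (length(unique(widths)) != 1) {
    abort("aligned sequences must have equal length")
  }
  widths <- unname(widths)
  n_gaps <- unname(n_gaps)
  tibble(
    species = species,
    n_gaps = n_gaps,
    width = widths,
    gap_frac = n_gaps / widths,
    retained = n_gaps / widths <= max_gap_frac
  )
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then member gene ids.
#' Duplicate members within a line are deduplicated; duplicate set names or
#' memberless lines are errors.
#'
#' @param path Path to a GMT file.
#' @return A tibble with `set_name`, `description`, and a list-column
#'   `genes` of unique member ids.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has no members", bad[1]))
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    abort(sprintf(
      "duplicate gene-set name(s): %s",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  tibble(
    set_name = nm,
    description = vapply(parts, `[[`, character(1), 2L),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets A tibble as returned by [read_gene_sets()].
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- purrr::pmap_chr(
    list(sets$set_name, sets$description, sets$genes),
    function(nm, d, g) paste(c(nm, d, g), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a species trait table
#'
#' A TSV whose first column (`species`) names species; remaining columns are
#' binary (0/1) or continuous traits. Species absent from the master tree
#' are excluded with a warning (exact string matching only).
#'
#' @param path Path to a TSV file.
#' @param master Optional `phylo`; when given, rows for unknown species are
#'   dropped with a warning.
#' @return A tibble, one row per species.
#' @export
read_trait_table <- function(path, master = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"species" %in% names(tab)) {
    names(tab)[1] <- "species"
  }
  tab$species <- as.character(tab$species)
  if (!is.null(master)) {
    unknown <- setdiff(tab$species, master$tip.label)
    if (length(unknown) > 0) {
      warn(sprintf(
        "dropping %d species absent from the master tree: %s",
        length(unknown), paste(unknown, collapse = ", ")
      ))
      tab <- tab[tab$species %in% master$tip.label, , drop = FALSE]
    }
  }
  tab
}

#' Write a result table as TSV
#'
#' Numeric fields round-trip losslessly (full double precision).
#'
#' @param results A data frame.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}

#' Read gene trees from a two-column TSV (gene id, newick)
#'
#' Plain newick carries no gene identifiers, so gene-tree collections are
#' stored one gene per line as `gene_id<TAB>newick` (the convention of
#' RER-style tooling).
#'
#' @param path Path to the gene-trees TSV.
#' @return A named list of `phylo` objects.
#' @export
read_gene_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort("gene-tree file must have exactly two tab-separated columns")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) abort("duplicated gene ids in gene-tree file")
  trees <- lapply(parts, function(p) read_master_tree(p[[2]]))
  setNames(trees, ids)
}

#' Write gene trees to a two-column TSV (gene id, newick)
#'
#' @param gene_trees Named list of `phylo` objects.
#' @param path Output path.
#' @param digits Significant digits for branch lengths (default 12).
#' @export
write_gene_trees <- function(gene_trees, path, digits = 12) {
  stopifnot(!is.null(names(gene_trees)))
  lines <- vapply(seq_along(gene_trees), function(i) {
    paste(
      names(gene_trees)[i],
      ape::write.tree(gene_trees[[i]], digits = digits),
      sep = "\t"
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
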