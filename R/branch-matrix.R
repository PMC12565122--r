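#' Build the genes-by-branches branch-length matrix
#'
#' Each master branch is identified by its bipartition (set of descendant
#' taxa). For every gene, the master bipartitions are restricted to the
#' gene's taxon set; a branch contributes an entry iff its restriction is a
#' non-trivial, *unique* bipartition of the gene tree. Master branches that
#' become trivial or collapse onto one another after taxon removal are
#' missing for that gene (no path-summing reallocation), so the branch
#' correspondence stays one-to-one.
#'
#' @param gene_trees Named list of `phylo` objects (taxa must be subsets of
#'   the master taxa, topology compatible with the restricted master).
#' @param master Master `phylo` tree.
#' @param min_taxa Minimum taxa a gene tree must retain (default 3).
#' @return A tibble in long form (`gene_id`, `branch_id`, `length`); absent
#'   rows are the missing entries. Skipped genes are recorded in attribute
#'   `"dropped"` with their reason.
#' @export
build_branch_matrix <- function(gene_trees, master, min_taxa = 3) {
  stopifnot(inherits(master, "phylo"), !is.null(names(gene_trees)))
  mtab <- branch_table(master)
  msets <- node_tip_sets(master)
  mtips <- lapply(msets[mtab$child], function(i) master$tip.label[i])

  rows <- vector("list", length(gene_trees))
  dropped <- list()
  for (g in seq_along(gene_trees)) {
    gid <- names(gene_trees)[g]
    gt <- gene_trees[[g]]
    gtaxa <- gt$tip.label
    if (length(gtaxa) < min_taxa) {
      dropped[[gid]] <- "too_few_taxa"
      next
    }
    if (!all(gtaxa %in% master$tip.label)) {
      dropped[[gid]] <- "taxa_not_in_master"
      next
    }
    restr <- lapply(mtips, intersect, gtaxa)
    sizes <- lengths(restr)
    nontrivial <- sizes > 0 & sizes < length(gtaxa)
    keys <- rep(NA_character_, length(restr))
    keys[nontrivial] <- make_branch_id(restr[nontrivial])
    dupkeys <- keys[nontrivial][duplicated(keys[nontrivial])]
    usable <- nontrivial & !(keys %in% dupkeys)

    gtab <- branch_table(gt)
    idx <- match(keys[usable], gtab$branch_id)
    if (anyNA(idx)) {
      dropped[[gid]] <- "incompatible_topology"
      next
    }
    rows[[g]] <- tibble(
      gene_id = gid,
      branch_id = mtab$branch_id[usable],
      length = gtab$length[idx]
    )
  }
  out <- bind_rows(rows)
  if (length(dropped) > 0) {
    inform(sprintf(
      "build_branch_matrix: skipped %d gene(s) (%s)",
      length(dropped), paste(unique(unlist(dropped)), collapse = ", ")
    ))
  }
  attr(out, "dropped") <- drop_record(
    names(dropped), unlist(dropped, use.names = FALSE) %||% character(),
    stage = "branch_matrix"
  )
  attr(out, "master_branches") <- mtab$branch_id
  out
}

#' Consensus branch lengths by averaging over genes
#'
#' The consensus length of a branch is the arithmetic mean of that branch's
#' length over all genes with a present entry; missing entries are ignored.
#'
#' @param branch_matrix Long tibble from [build_branch_matrix()].
#' @return A tibble with `branch_id`, `mean_length`, and `support` (number
#'   of genes contributing).
#' @export
consensus_lengths <- function(branch_matrix) {
  branch_matrix |>
    group_by(.data$branch_id) |>
    summarise(
      mean_length = mean(.data$length),
      support = dplyr::n(),
      .groups = "drop"
    )
}

#' Use a reference tree's branch lengths as the consensus
#'
#' Instead of averaging the analyzed gene trees, the consensus predictor can
#' be taken from an independently estimated genome-wide tree (as when a
#' reference species tree with ML branch lengths is available). This keeps
#' the consensus free of contamination when a large fraction of the analyzed
#' genes share convergent rate shifts.
#'
#' @param tree A `phylo` with branch lengths (the reference tree).
#' @return A consensus tibble (`branch_id`, `mean_length`, `support`)
#'   usable as the `consensus` argument of [compute_rers()].
#' @export
consensus_from_tree <- function(tree) {
  bt <- branch_table(tree)
  tibble(branch_id = bt$branch_id, mean_length = bt$length, support = 1L)
}

#' Variance-stabilizing transform for branch lengths
#'
#' The square root is applied to both gene and consensus branch lengths
#' before the RER regression: branch-length variance grows with the mean,
#' and the square root is the standard stabilizer for non-negative lengths.
#' Monotone, with 0 mapped to 0.
#'
#' @param x Non-negative numeric vector (substitutions/site).
#' @return `sqrt(x)`.
#' @export
transform_lengths <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("branch lengths must be non-negative")
  sqrt(x)
}

#' Export a long branch matrix as a wide genes-by-branches TSV
#'
#' @param branch_matrix Long tibble (`gene_id`, `branch_id`, value column).
#' @param path Output path.
#' @param value Name of the value column to spread (default `"length"`).
#' @export
write_branch_matrix <- function(branch_matrix, path, value = "length") {
  wide <- tidyr::pivot_wider(
    branch_matrix[, c("gene_id", "branch_id", value)],
    names_from = "branch_id", values_from = dplyr::all_of(value)
  )
  readr::write_tsv(wide, path, na = "NA", progress = FALSE)
  invisible(path)
}
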