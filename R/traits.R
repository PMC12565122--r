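#' Label branches as foreground or background for a binary trait
#'
#' Builds the per-branch binary design for the association scan. A branch is
#' identified with its child endpoint (the branch "leads to" that node);
#' trait states at internal nodes come from Fitch maximum parsimony.
#'
#' Modes:
#' \describe{
#'   \item{`clade`}{branch is foreground iff its child node's resolved
#'     parsimony state is 1 — all terminal and internal branches of every
#'     trait clade, including independent origins.}
#'   \item{`ancestral`}{only the stem branch(es) into each maximal trait
#'     clade (child resolved 1, parent resolved 0) — the trait's origin
#'     branches.}
#'   \item{`terminal`}{only the terminal branches of trait-bearing species.}
#' }
#'
#' @param tree Master `phylo`.
#' @param trait_species Character vector of trait-bearing species; must be a
#'   non-empty proper subset of the taxa (all taxa would leave no
#'   background).
#' @param mode One of `"clade"`, `"ancestral"`, `"terminal"`.
#' @param trait_name Label carried into results (default `"trait"`).
#' @return A tibble of class `trait_design` with one row per branch:
#'   `branch_id`, `label` (1 = foreground). Attributes: `mode`,
#'   `trait_name`, `trait_species`, `n_origins` (parsimony origins),
#'   `changes` (parsimony change count).
#' @examples
#' tr <- read_master_tree("((A:1,B:1):1,C:2);")
#' assign_foreground(tr, c("A", "B"), mode = "clade")
#' @export
assign_foreground <- function(tree, trait_species,
                              mode = c("clade", "ancestral", "terminal"),
                              trait_name = "trait") {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (length(trait_species) == 0) abort("trait_species is empty")
  unknown <- setdiff(trait_species, tree$tip.label)
  if (length(unknown) > 0) {
    abort(sprintf(
      "trait species not in tree: %s", paste(unknown, collapse = ", ")
    ))
  }
  if (setequal(trait_species, tree$tip.label)) {
    abort("all taxa carry the trait: no background branches remain")
  }

  states <- setNames(
    as.integer(tree$tip.label %in% trait_species), tree$tip.label
  )
  fp <- fitch_parsimony(tree, states)
  res <- fp$node_states$resolved
  btab <- branch_table(tree)
  n_tip <- length(tree$tip.label)

  label <- switch(mode,
    clade = res[btab$child],
    ancestral = as.integer(res[btab$child] == 1L & res[btab$parent] == 0L),
    terminal = {
      lab <- integer(nrow(btab))
      term <- which(btab$is_terminal)
      lab[term] <- as.integer(
        tree$tip.label[btab$child[term]] %in% trait_species
      )
      lab
    }
  )
  root <- n_tip + 1L
  n_origins <- sum(res[btab$child] == 1L & res[btab$parent] == 0L) +
    as.integer(res[root] == 1L)

  out <- tibble(branch_id = btab$branch_id, label = as.integer(label))
  class(out) <- c("trait_design", class(out))
  attr(out, "mode") <- mode
  attr(out, "trait_name") <- trait_name
  attr(out, "trait_species") <- sort(trait_species)
  attr(out, "n_origins") <- n_origins
  attr(out, "changes") <- fp$changes
  out
}

#' High body mass / long lifespan species under fixed thresholds
#'
#' The binary "large, long-lived" trait: a species qualifies iff body mass
#' strictly exceeds `mass_min` (kg) and lifespan strictly exceeds
#' `lifespan_min` (years). Species with a missing value in either column
#' are excluded with a message.
#'
#' @param traits Trait tibble with a `species` column.
#' @param mass_col,lifespan_col Column names (defaults `"mass_kg"`,
#'   `"lifespan_y"`).
#' @param mass_min,lifespan_min Strict thresholds; defaults 40 kg and 10
#'   years.
#' @return Character vector of qualifying species.
#' @export
binarize_mass_lifespan <- function(traits, mass_col = "mass_kg",
                                   lifespan_col = "lifespan_y",
                                   mass_min = 40, lifespan_min = 10) {
  stopifnot(all(c("species", mass_col, lifespan_col) %in% names(traits)))
  mass <- traits[[mass_col]]
  life <- traits[[lifespan_col]]
  incomplete <- is.na(mass) | is.na(life)
  if (any(incomplete)) {
    inform(sprintf(
      "excluding %d species with missing mass/lifespan: %s",
      sum(incomplete), paste(traits$species[incomplete], collapse = ", ")
    ))
  }
  keep <- !incomplete & mass > mass_min & life > lifespan_min
  traits$species[keep]
}

#' Top-k species jointly ranked by body mass and lifespan
#'
#' Species are scored by the product of their within-table rank of mass and
#' rank of lifespan (average ranks for ties; higher product = jointly larger
#' and longer-lived); the top `k` are returned. Score ties are broken
#' lexicographically by species id, with a message.
#'
#' @inheritParams binarize_mass_lifespan
#' @param k Number of species to select (default 4, the "4 longest-lived,
#'   highest-body-mass" design).
#' @return Character vector of `k` species.
#' @export
select_top_k <- function(traits, k = 4, mass_col = "mass_kg",
                         lifespan_col = "lifespan_y") {
  stopifnot(all(c("species", mass_col, lifespan_col) %in% names(traits)))
  if (k < 1) abort("k must be >= 1")
  if (k > nrow(traits)) {
    abort(sprintf("k = %d exceeds the %d species available", k, nrow(traits)))
  }
  score <- rank(traits[[mass_col]]) * rank(traits[[lifespan_col]])
  ord <- order(-score, traits$species)
  cutoff <- score[ord][k]
  if (sum(score == cutoff) > 1 && k < nrow(traits) &&
    score[ord][k + 1] == cutoff) {
    inform("rank-product tie at the selection boundary; broke lexicographically")
  }
  sort(traits$species[ord[seq_len(k)]])
}

#' Natural-log transform for positive continuous traits
#'
#' Continuous traits (body mass, lifespan) are log-transformed to
#' approximate normality and damp extreme values before Pearson
#' correlation; the correlation is invariant to the log base.
#'
#' @param values Positive numeric vector, optionally named by species.
#' @return `log(values)`, with the pre-transform `mean` and `sd` recorded
#'   as attributes.
#' @export
log_normalize <- function(values) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad) > 0) {
    who <- if (!is.null(names(values))) {
      paste(names(values)[bad], collapse = ", ")
    } else {
      paste("position", paste(bad, collapse = ", "))
    }
    abort(sprintf("log_normalize requires positive values; offending: %s", who))
  }
  out <- log(values)
  attr(out, "raw_mean") <- mean(values, na.rm = TRUE)
  attr(out, "raw_sd") <- sd(values, na.rm = TRUE)
  out
}
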