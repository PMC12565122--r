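# End-to-end orchestration: branch matrix -> consensus -> RER ->
# foreground design -> per-gene association -> BH/classes -> class tests
# -> FAS -> set enrichment -> Jaccard clustering, with a run manifest
# that accounts for every dropped gene.

#' Run the binary-trait RER analysis end to end
#'
#' @param master Master `phylo`.
#' @param gene_trees Named list of gene `phylo` objects.
#' @param trait_species Trait-bearing species (foreground definition).
#' @param gene_sets Optional gene-set tibble ([read_gene_sets()]); when
#'   `NULL` the enrichment stage is skipped.
#' @param mode Foreground mode: `"clade"` (default), `"ancestral"`, or
#'   `"terminal"`; see [assign_foreground()].
#' @param class_members Optional gene-id vector of a focal class (e.g.
#'   tumor suppressors) for the overrepresentation / sign-bias tests.
#' @param alpha Significance level (default 0.05).
#' @param min_taxa Minimum taxa per gene tree (default 3).
#' @param min_branches Minimum present branches per gene (default 3).
#' @param min_set_size Minimum scored members per gene set (default 10).
#' @param jaccard_threshold Strict Jaccard threshold for pathway
#'   clustering (default 0.5).
#' @param raw_p_filter Restrict enrichment to genes with raw `p < alpha`
#'   (default `FALSE`).
#' @param consensus Optional precomputed consensus ([consensus_lengths()]
#'   output); by default the consensus is averaged from the gene set under
#'   analysis.
#' @param trait_name Label for the manifest and result tables.
#' @param out_dir Optional output directory; when given, all result TSVs
#'   and the JSON manifest are written there (deterministically — two runs
#'   with identical inputs give byte-identical files).
#' @return A list of class `rer_run`: `branch_matrix`, `consensus`, `fit`,
#'   `design`, `assoc`, `class_tests`, `enrichment`, `clusters`,
#'   `manifest`.
#' @export
run_binary_analysis <- function(master, gene_trees, trait_species,
                                gene_sets = NULL,
                                mode = c("clade", "ancestral", "terminal"),
                                class_members = NULL,
                                alpha = 0.05, min_taxa = 3, min_branches = 3,
                                min_set_size = 10, jaccard_threshold = 0.5,
                                raw_p_filter = FALSE, consensus = NULL,
                                trait_name = "trait", out_dir = NULL) {
  mode <- match.arg(mode)
  design <- assign_foreground(master, trait_species,
    mode = mode,
    trait_name = trait_name
  )
  run_core(
    master = master, gene_trees = gene_trees, design = design,
    trait = NULL, gene_sets = gene_sets, class_members = class_members,
    alpha = alpha, min_taxa = min_taxa, min_branches = min_branches,
    min_set_size = min_set_size, jaccard_threshold = jaccard_threshold,
    raw_p_filter = raw_p_filter, consensus = consensus,
    trait_name = trait_name, kind = "binary", mode = mode,
    out_dir = out_dir
  )
}

#' Run the continuous-trait RER analysis end to end
#'
#' Terminal-branch RERs are correlated (Pearson) with the log-normalized
#' trait; no foreground/background division is made.
#'
#' @inheritParams run_binary_analysis
#' @param trait Named numeric vector (names = species) or a two-column
#'   data frame (`species`, value) of positive trait values.
#' @param log_transform Apply [log_normalize()] first (default `TRUE`).
#' @param min_n Minimum species per gene (default 4).
#' @return A list of class `rer_run` (as [run_binary_analysis()], without
#'   `design`).
#' @export
run_continuous_analysis <- function(master, gene_trees, trait,
                                    gene_sets = NULL, class_members = NULL,
                                    log_transform = TRUE,
                                    alpha = 0.05, min_taxa = 3,
                                    min_branches = 3, min_n = 4,
                                    min_set_size = 10,
                                    jaccard_threshold = 0.5,
                                    raw_p_filter = FALSE, consensus = NULL,
                                    trait_name = "trait", out_dir = NULL) {
  if (is.data.frame(trait)) {
    trait <- setNames(trait[[2]], trait[[1]])
  }
  trait <- trait[!is.na(trait)]
  if (length(trait) == 0 || sd(trait) == 0) {
    abort("trait is constant or empty; aborting before the RER stage")
  }
  unknown <- setdiff(names(trait), master$tip.label)
  if (length(unknown) > 0) {
    warn(sprintf(
      "dropping %d trait species absent from the master tree",
      length(unknown)
    ))
    trait <- trait[setdiff(names(trait), unknown)]
  }
  if (log_transform) trait <- log_normalize(trait)
  run_core(
    master = master, gene_trees = gene_trees, design = NULL,
    trait = trait, gene_sets = gene_sets, class_members = class_members,
    alpha = alpha, min_taxa = min_taxa, min_branches = min_branches,
    min_set_size = min_set_size, jaccard_threshold = jaccard_threshold,
    raw_p_filter = raw_p_filter, consensus = consensus,
    trait_name = trait_name, kind = "continuous", mode = "continuous",
    out_dir = out_dir, min_n = min_n
  )
}

run_core <- function(master, gene_trees, design, trait, gene_sets,
                     class_members, alpha, min_taxa, min_branches,
                     min_set_size, jaccard_threshold, raw_p_filter,
                     consensus, trait_name, kind, mode, out_dir,
                     min_n = 4) {
  bm <- build_branch_matrix(gene_trees, master, min_taxa = min_taxa)
  fit <- compute_rers(bm, consensus = consensus, min_branches = min_branches)
  assoc <- if (kind == "binary") {
    associate_binary(fit, design, alpha = alpha)
  } else {
    associate_continuous(fit, master, trait, alpha = alpha, min_n = min_n)
  }

  class_tests <- list()
  if (!is.null(class_members)) {
    sig <- assoc$gene_id[assoc$class != "ns"]
    class_tests$overrepresentation <- fisher_overrepresentation(
      class_members, sig, assoc$gene_id
    )
    n_in <- length(intersect(sig, class_members))
    if (n_in > 0 && n_in < length(sig)) {
      class_tests$sign_bias <- sign_bias_test(assoc, class_members,
        alpha = alpha
      )
    }
  }

  enrichment <- NULL
  clusters <- NULL
  if (!is.null(gene_sets)) {
    enrichment <- enrich_sets(assoc, gene_sets,
      alpha = alpha,
      min_set_size = min_set_size, raw_p_filter = raw_p_filter
    )
    sig_sets <- gene_sets[
      gene_sets$set_name %in% enrichment$set_name[enrichment$significant], ,
      drop = FALSE
    ]
    clusters <- cluster_pathways(sig_sets, threshold = jaccard_threshold)
  }

  dropped <- attr(assoc, "dropped")
  manifest <- list(
    package = "rerscan",
    version = as.character(utils::packageVersion("rerscan")),
    trait_name = trait_name,
    kind = kind,
    mode = mode,
    thresholds = list(
      alpha = alpha, min_taxa = min_taxa, min_branches = min_branches,
      min_set_size = min_set_size, jaccard_threshold = jaccard_threshold,
      raw_p_filter = raw_p_filter
    ),
    n_genes_in = length(gene_trees),
    n_genes_analyzed = nrow(assoc),
    drops = as.list(table(paste(dropped$stage, dropped$reason, sep = ":"))),
    n_fast = sum(assoc$class == "fast"),
    n_slow = sum(assoc$class == "slow"),
    config_hash = rlang::hash(list(
      trait_name, kind, mode, alpha, min_taxa, min_branches,
      min_set_size, jaccard_threshold, raw_p_filter
    ))
  )

  run <- structure(
    list(
      branch_matrix = bm, consensus = fit$consensus, fit = fit,
      design = design, assoc = assoc, class_tests = class_tests,
      enrichment = enrichment, clusters = clusters, manifest = manifest
    ),
    class = "rer_run"
  )
  if (!is.null(out_dir)) write_run_bundle(run, out_dir)
  run
}

#' Write a pipeline run's result tables and manifest
#'
#' Writes `gene_association.tsv`, `set_enrichment.tsv`,
#' `pathway_clusters.tsv`, `class_tests.tsv` (as available) and
#' `manifest.json` into `dir`. Output is deterministic.
#'
#' @param run An `rer_run`.
#' @param dir Output directory (created if needed).
#' @export
write_run_bundle <- function(run, dir) {
  stopifnot(inherits(run, "rer_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results(as_tibble(run$assoc), file.path(dir, "gene_association.tsv"))
  if (!is.null(run$enrichment)) {
    write_results(
      as_tibble(run$enrichment),
      file.path(dir, "set_enrichment.tsv")
    )
    write_results(run$clusters, file.path(dir, "pathway_clusters.tsv"))
  }
  if (length(run$class_tests) > 0) {
    write_results(
      bind_rows(lapply(run$class_tests, tidy)),
      file.path(dir, "class_tests.tsv")
    )
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Run an analysis described by a YAML or JSON config file
#'
#' The config mirrors the function arguments: a `paths` block
#' (`master_tree`, `gene_trees`, `traits` or `trait_table`, optional
#' `gene_sets`, `out_dir`), a `trait` block (`name`, `kind` =
#' binary/continuous, `mode`, and either `species` or `column`), and an
#' optional `thresholds` block (`alpha`, `min_taxa`, `min_branches`,
#' `min_set_size`, `jaccard_threshold`). Missing files are reported by
#' path before any work starts.
#'
#' @param config Path to a YAML/JSON file, or an equivalent nested list.
#' @return An `rer_run`.
#' @export
run_from_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  paths <- config$paths %||% abort("config needs a 'paths' block")
  for (key in c("master_tree", "gene_trees")) {
    if (is.null(paths[[key]])) abort(sprintf("config paths$%s is missing", key))
    if (!file.exists(paths[[key]])) {
      abort(sprintf("input file not found: %s", paths[[key]]))
    }
  }
  trait_cfg <- config$trait %||% abort("config needs a 'trait' block")
  th <- config$thresholds %||% list()

  master <- read_master_tree(paths$master_tree)
  gene_trees <- read_gene_trees(paths$gene_trees)
  gene_sets <- NULL
  if (!is.null(paths$gene_sets)) {
    if (!file.exists(paths$gene_sets)) {
      abort(sprintf("input file not found: %s", paths$gene_sets))
    }
    gene_sets <- read_gene_sets(paths$gene_sets)
  }

  kind <- trait_cfg$kind %||% "binary"
  shared <- list(
    master = master, gene_trees = gene_trees, gene_sets = gene_sets,
    alpha = th$alpha %||% 0.05,
    min_taxa = th$min_taxa %||% 3,
    min_branches = th$min_branches %||% 3,
    min_set_size = th$min_set_size %||% 10,
    jaccard_threshold = th$jaccard_threshold %||% 0.5,
    raw_p_filter = th$raw_p_filter %||% FALSE,
    trait_name = trait_cfg$name %||% "trait",
    out_dir = paths$out_dir
  )

  if (kind == "binary") {
    trait_species <- trait_cfg$species
    if (is.null(trait_species)) {
      tab <- read_trait_table(paths$traits %||% paths$trait_table, master)
      col <- trait_cfg$column %||% abort("binary trait needs species or column")
      trait_species <- tab$species[tab[[col]] == 1]
    }
    do.call(run_binary_analysis, c(
      shared,
      list(trait_species = trait_species, mode = trait_cfg$mode %||% "clade")
    ))
  } else {
    tab <- read_trait_table(paths$traits %||% paths$trait_table, master)
    col <- trait_cfg$column %||% abort("continuous trait needs a column")
    do.call(run_continuous_analysis, c(
      shared,
      list(
        trait = setNames(tab[[col]], tab$species),
        log_transform = trait_cfg$log_transform %||% TRUE
      )
    ))
  }
}

#' @export
print.rer_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<rer_run> %s (%s, %s): %d/%d genes analyzed, %d fast, %d slow\n",
    m$trait_name, m$kind, m$mode, m$n_genes_analyzed, m$n_genes_in,
    m$n_fast, m$n_slow
  ))
  if (!is.null(x$enrichment)) {
    cat(sprintf(
      "  %d gene sets tested, %d significant\n",
      nrow(x$enrichment), sum(x$enrichment$significant)
    ))
  }
  invisible(x)
}

#' Per-gene results of a pipeline run
#'
#' @param x An `rer_run`.
#' @param ... Unused.
#' @return The `rer_assoc` tibble.
#' @method tidy rer_run
#' @export
tidy.rer_run <- function(x, ...) as_tibble(x$assoc)

#' One-row summary of a pipeline run
#'
#' @param x An `rer_run`.
#' @param ... Unused.
#' @method glance rer_run
#' @export
glance.rer_run <- function(x, ...) {
  m <- x$manifest
  tibble(
    trait_name = m$trait_name, kind = m$kind, mode = m$mode,
    n_genes_in = m$n_genes_in, n_genes_analyzed = m$n_genes_analyzed,
    n_fast = m$n_fast, n_slow = m$n_slow,
    n_sets_tested = if (is.null(x$enrichment)) NA_integer_ else nrow(x$enrichment),
    n_sets_significant = if (is.null(x$enrichment)) {
      NA_integer_
    } else {
      sum(x$enrichment$significant)
    }
  )
}
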