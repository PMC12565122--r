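# Synthetic-data generator: master trees, gene trees with planted rate
# shifts, traits and gene sets with known ground truth. All randomness
# flows from one root seed through fixed per-stage offsets (see
# SEED_STREAM in utils.R): master tree = seed+0, gene trees = seed+1,
# traits = seed+2, gene sets = seed+3, so any stage can be regenerated
# independently of the others.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: 40 taxa, 500
#' genes of which 10% carry a planted acceleration and 10% a planted
#' deceleration (multiplier 3 and 1/3 on the foreground branches of a
#' 10-species foreground clade), lognormal gene-specific rate scalars,
#' multiplicative gamma branch noise with coefficient of variation 0.2,
#' 5% per-species-per-gene missingness, and 20 gene sets of which one is
#' enriched (80% of its 30 members drawn from the accelerated genes).
#'
#' @param n_taxa Number of species (>= 4).
#' @param n_genes Number of genes.
#' @param fraction_fast,fraction_slow Fractions of genes with planted
#'   acceleration/deceleration; counts are `floor(fraction * n_genes)`.
#' @param fg_clade_size Size of the foreground clade (resolved on the
#'   simulated tree; see `clade_strategy`).
#' @param fg_species Optional explicit foreground species (overrides
#'   `fg_clade_size`).
#' @param m_fg Foreground rate multiplier (> 0); slow genes use `1/m_fg`
#'   so fast and slow effects are symmetric on the log scale.
#' @param scalar_meanlog,scalar_sdlog Lognormal parameters of the
#'   gene-specific rate scalar.
#' @param noise_cv Coefficient of variation of the multiplicative gamma
#'   branch noise (mean 1); 0 disables noise.
#' @param p_missing Probability each species is missing from each gene.
#' @param min_taxa Minimum taxa a gene tree may be reduced to; missingness
#'   is redrawn (with a counted retry) below this.
#' @param brlen_mean Mean of the exponential master branch lengths
#'   (substitutions/site).
#' @param n_sets,n_enriched_sets Total and enriched gene-set counts.
#' @param enriched_fraction Fraction of an enriched set drawn from fast
#'   genes.
#' @param enriched_set_size Size of each enriched set.
#' @param set_size_range Inclusive size range for null sets.
#' @param bm_sigma Brownian-motion standard deviation per unit branch
#'   length for continuous traits.
#' @param trait_offset Offset added to the continuous trait on foreground
#'   species (plants a true RER-trait correlation when non-zero).
#' @param clade_strategy `"nearest"` (default) picks the clade closest in
#'   size to `fg_clade_size`; `"exact"` errors when no clade of exactly
#'   that size exists.
#' @param seed Root seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 40, n_genes = 500,
                       fraction_fast = 0.1, fraction_slow = 0.1,
                       fg_clade_size = 10, fg_species = NULL,
                       m_fg = 3, scalar_meanlog = 0, scalar_sdlog = 0.5,
                       noise_cv = 0.2, p_missing = 0.05, min_taxa = 3,
                       brlen_mean = 0.1,
                       n_sets = 20, n_enriched_sets = 1,
                       enriched_fraction = 0.8, enriched_set_size = 30,
                       set_size_range = c(10, 200),
                       bm_sigma = 0.5, trait_offset = 0,
                       clade_strategy = c("nearest", "exact"),
                       seed = 1) {
  cfg <- list(
    n_taxa = n_taxa, n_genes = n_genes,
    fraction_fast = fraction_fast, fraction_slow = fraction_slow,
    fg_clade_size = fg_clade_size, fg_species = fg_species,
    m_fg = m_fg, scalar_meanlog = scalar_meanlog,
    scalar_sdlog = scalar_sdlog, noise_cv = noise_cv,
    p_missing = p_missing, min_taxa = min_taxa, brlen_mean = brlen_mean,
    n_sets = n_sets, n_enriched_sets = n_enriched_sets,
    enriched_fraction = enriched_fraction,
    enriched_set_size = enriched_set_size,
    set_size_range = set_size_range,
    bm_sigma = bm_sigma, trait_offset = trait_offset,
    clade_strategy = match.arg(clade_strategy),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_taxa >= 4, cfg$n_genes >= 1,
    cfg$fraction_fast >= 0, cfg$fraction_slow >= 0,
    cfg$fraction_fast + cfg$fraction_slow <= 1,
    cfg$m_fg > 0, cfg$noise_cv >= 0,
    cfg$p_missing >= 0, cfg$p_missing < 1,
    cfg$n_sets >= 1, cfg$n_enriched_sets >= 0,
    cfg$enriched_fraction >= 0, cfg$enriched_fraction <= 1,
    length(cfg$set_size_range) == 2,
    cfg$set_size_range[1] >= 1,
    cfg$set_size_range[1] <= cfg$set_size_range[2]
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a master tree
#'
#' Yule (pure-birth) topology with iid exponential branch lengths; tips
#' are relabeled `sp01`, `sp02`, ... Deterministic under the seed.
#'
#' @param n_taxa Number of tips (>= 4).
#' @param seed Root seed (master-tree stream).
#' @param brlen_mean Mean branch length (substitutions/site).
#' @return A `phylo`.
#' @export
simulate_master_tree <- function(n_taxa, seed = 1, brlen_mean = 0.1) {
  if (n_taxa < 4) abort("n_taxa must be >= 4")
  withr::with_seed(stream_seed(seed, "master_tree"), {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1 / brlen_mean)
    tree$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
    tree
  })
}

#' Pick a foreground clade of (approximately) a given size
#'
#' @param master Master `phylo`.
#' @param size Requested clade size (2 <= size < n_taxa).
#' @param strategy `"exact"` errors when no clade of that size exists
#'   (listing the available sizes); `"nearest"` takes the closest size
#'   (smaller node number on ties) with a message.
#' @return Character vector of clade species.
#' @export
pick_clade <- function(master, size, strategy = c("exact", "nearest")) {
  strategy <- match.arg(strategy)
  n_tip <- length(master$tip.label)
  sets <- node_tip_sets(master)
  internal <- seq(n_tip + 2L, n_tip + master$Nnode) # all but the root
  sizes <- lengths(sets[internal])
  if (strategy == "exact") {
    hit <- internal[sizes == size]
    if (length(hit) == 0) {
      abort(sprintf(
        "no clade of size %d; available clade sizes: %s",
        size, paste(sort(unique(sizes)), collapse = ", ")
      ))
    }
    node <- hit[1]
  } else {
    node <- internal[order(abs(sizes - size), internal)][1]
    if (lengths(sets[node]) != size) {
      inform(sprintf(
        "no clade of size %d; using nearest available size %d",
        size, length(sets[[node]])
      ))
    }
  }
  sort(master$tip.label[sets[[node]]])
}

#' Simulate gene trees with planted rate shifts
#'
#' Gene `g`'s length on master branch `b` is
#' `r_g * m_gb * B_b * eps_gb`: a lognormal gene scalar, the foreground
#' multiplier (`m_fg` for fast genes, `1/m_fg` for slow genes, 1
#' elsewhere), the master length, and mean-1 gamma noise. Each species is
#' then dropped independently with probability `p_missing` (pruning the
#' tree; draws reducing a gene below `min_taxa` are redone with a counted
#' retry). Deterministic under the seed.
#'
#' @param master Master `phylo`.
#' @param config A [sim_config()].
#' @param fg_species Foreground species (a clade of the master).
#' @return List with `trees` (named list of `phylo`), `truth` (tibble
#'   `gene_id`, `scalar`, `status`, `retries`), and the foreground
#'   `design` used.
#' @export
simulate_gene_trees <- function(master, config, fg_species) {
  stopifnot(inherits(config, "sim_config"))
  design <- assign_foreground(master, fg_species, mode = "clade")
  # branch_table rows are in master$edge order, so design$label indexes edges
  fg_edge <- design$label == 1L
  n_edge <- nrow(master$edge)
  n_genes <- config$n_genes
  n_fast <- floor(config$fraction_fast * n_genes)
  n_slow <- floor(config$fraction_slow * n_genes)

  withr::with_seed(stream_seed(config$seed, "gene_trees"), {
    ord <- sample.int(n_genes)
    status <- rep("null", n_genes)
    status[ord[seq_len(n_fast)]] <- "fast"
    if (n_slow > 0) status[ord[n_fast + seq_len(n_slow)]] <- "slow"
    scalar <- stats::rlnorm(n_genes, config$scalar_meanlog, config$scalar_sdlog)
    shape <- if (config$noise_cv > 0) 1 / config$noise_cv^2 else Inf

    trees <- vector("list", n_genes)
    retries <- integer(n_genes)
    for (g in seq_len(n_genes)) {
      mult <- rep(1, n_edge)
      if (status[g] == "fast") mult[fg_edge] <- config$m_fg
      if (status[g] == "slow") mult[fg_edge] <- 1 / config$m_fg
      eps <- if (is.finite(shape)) {
        stats::rgamma(n_edge, shape = shape, rate = shape)
      } else {
        rep(1, n_edge)
      }
      gt <- master
      gt$edge.length <- scalar[g] * mult * master$edge.length * eps

      repeat {
        drop <- master$tip.label[
          stats::runif(config$n_taxa) < config$p_missing
        ]
        if (config$n_taxa - length(drop) >= config$min_taxa) break
        retries[g] <- retries[g] + 1L
      }
      trees[[g]] <- if (length(drop) > 0) ape::drop.tip(gt, drop) else gt
    }
    names(trees) <- sprintf("g%04d", seq_len(n_genes))
    list(
      trees = trees,
      truth = tibble(
        gene_id = names(trees), scalar = scalar,
        status = status, retries = retries
      ),
      design = design
    )
  })
}

#' Simulate species traits on the master tree
#'
#' Binary trait: membership of the foreground clade. Continuous traits:
#' body mass and lifespan as geometric Brownian motion (exponentiated BM,
#' so values are positive and log-normalization applies), plus a generic
#' continuous trait `cont_trait` (plain BM) shifted by `trait_offset` on
#' foreground species to plant a true RER-trait correlation.
#'
#' @param master Master `phylo`.
#' @param fg Foreground species (character vector), or a clade size to be
#'   resolved with [pick_clade()] (strict `"exact"` strategy).
#' @param seed Root seed (traits stream).
#' @param bm_sigma BM standard deviation per unit branch length.
#' @param trait_offset Continuous-trait offset on foreground species.
#' @return Tibble: `species`, `trait_bin`, `mass_kg`, `lifespan_y`,
#'   `cont_trait`.
#' @export
simulate_traits <- function(master, fg, seed = 1, bm_sigma = 0.5,
                            trait_offset = 0) {
  fg_species <- if (is.numeric(fg)) {
    pick_clade(master, fg, strategy = "exact")
  } else {
    fg
  }
  stopifnot(all(fg_species %in% master$tip.label))
  withr::with_seed(stream_seed(seed, "traits"), {
    bm_mass <- ape::rTraitCont(master, model = "BM", sigma = bm_sigma)
    bm_life <- ape::rTraitCont(master, model = "BM", sigma = bm_sigma)
    bm_cont <- ape::rTraitCont(master, model = "BM", sigma = bm_sigma)
    sp <- master$tip.label
    is_fg <- sp %in% fg_species
    tibble(
      species = sp,
      trait_bin = as.integer(is_fg),
      mass_kg = 30 * exp(bm_mass[sp]),
      lifespan_y = 8 * exp(bm_life[sp]),
      cont_trait = bm_cont[sp] + trait_offset * is_fg
    )
  })
}

#' Simulate gene sets with planted enrichment
#'
#' Enriched sets draw `enriched_fraction` of their members from the fast
#' genes and the rest uniformly from the remainder; null sets are uniform
#' draws with sizes in `set_size_range`. Deterministic under the seed.
#'
#' @param gene_ids All gene ids.
#' @param truth Gene truth tibble (needs `gene_id`, `status`).
#' @param config A [sim_config()].
#' @return List with `sets` (gene-set tibble) and `set_truth` (tibble
#'   `set_name`, `enriched`).
#' @export
simulate_gene_sets <- function(gene_ids, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  fast <- truth$gene_id[truth$status == "fast"]
  other <- setdiff(gene_ids, fast)
  n_from_fast <- round(config$enriched_fraction * config$enriched_set_size)
  if (config$n_enriched_sets > 0 && n_from_fast > length(fast)) {
    abort(sprintf(
      "enriched sets need %d fast genes but only %d exist",
      n_from_fast, length(fast)
    ))
  }
  withr::with_seed(stream_seed(config$seed, "gene_sets"), {
    n_sets <- config$n_sets
    sets <- vector("list", n_sets)
    enriched <- c(
      rep(TRUE, config$n_enriched_sets),
      rep(FALSE, n_sets - config$n_enriched_sets)
    )
    lo <- config$set_size_range[1]
    hi <- min(config$set_size_range[2], length(gene_ids))
    for (i in seq_len(n_sets)) {
      sets[[i]] <- if (enriched[i]) {
        c(
          sample(fast, n_from_fast),
          sample(other, config$enriched_set_size - n_from_fast)
        )
      } else {
        # guard against base R's scalar-sample surprise when lo == hi
        size_i <- seq(lo, hi)[sample.int(hi - lo + 1L, 1L)]
        sample(gene_ids, size_i)
      }
    }
    nm <- sprintf("SET%03d", seq_len(n_sets))
    list(
      sets = tibble(
        set_name = nm,
        description = "simulated gene set",
        genes = sets
      ),
      set_truth = tibble(set_name = nm, enriched = enriched)
    )
  })
}

#' Simulate a complete study bundle
#'
#' Master tree, foreground clade, gene trees with planted shifts, traits,
#' and gene sets, all from one root seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `rer_sim`: `master`, `fg_species`,
#'   `gene_trees`, `gene_truth`, `design`, `traits`, `sets`, `set_truth`,
#'   `config`.
#' @examples
#' sim <- simulate_rer_study(sim_config(n_taxa = 12, n_genes = 30, seed = 7))
#' sim$gene_truth
#' @export
simulate_rer_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  master <- simulate_master_tree(
    config$n_taxa,
    seed = config$seed, brlen_mean = config$brlen_mean
  )
  fg_species <- config$fg_species %||%
    pick_clade(master, config$fg_clade_size, strategy = config$clade_strategy)
  genes <- simulate_gene_trees(master, config, fg_species)
  traits <- simulate_traits(
    master, fg_species,
    seed = config$seed,
    bm_sigma = config$bm_sigma, trait_offset = config$trait_offset
  )
  gs <- simulate_gene_sets(names(genes$trees), genes$truth, config)
  structure(
    list(
      master = master, fg_species = fg_species,
      gene_trees = genes$trees, gene_truth = genes$truth,
      design = genes$design,
      traits = traits, sets = gs$sets, set_truth = gs$set_truth,
      config = config
    ),
    class = "rer_sim"
  )
}

#' @export
print.rer_sim <- function(x, ...) {
  cat(sprintf(
    "<rer_sim> %d taxa, %d genes (%d fast / %d slow), fg clade of %d, %d sets\n",
    x$config$n_taxa, x$config$n_genes,
    sum(x$gene_truth$status == "fast"), sum(x$gene_truth$status == "slow"),
    length(x$fg_species), nrow(x$sets)
  ))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Writes `master.nwk`, `gene_trees.tsv`, `traits.tsv`, `gene_sets.gmt`,
#' `gene_truth.tsv`, `set_truth.tsv`, and `config.json` into `dir`.
#' Deterministic: identical configs give byte-identical files.
#'
#' @param sim An `rer_sim` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "rer_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(
    ape::write.tree(sim$master, digits = 12),
    file.path(dir, "master.nwk")
  )
  write_gene_trees(sim$gene_trees, file.path(dir, "gene_trees.tsv"))
  write_results(sim$traits, file.path(dir, "traits.tsv"))
  write_gene_sets(sim$sets, file.path(dir, "gene_sets.gmt"))
  write_results(sim$gene_truth, file.path(dir, "gene_truth.tsv"))
  write_results(sim$set_truth, file.path(dir, "set_truth.tsv"))
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
    auto_unbox = TRUE, null = "null", digits = NA
  )
  invisible(dir)
}
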