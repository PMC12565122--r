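# The simulator: tree shapes, planted shifts, traits, gene sets,
# determinism, and ground-truth bookkeeping.

test_that("master trees have the right size and are seed-deterministic", {
  tr4 <- simulate_master_tree(4, seed = 1)
  expect_equal(nrow(branch_table(tr4)), 6) # 2n - 2
  expect_error(simulate_master_tree(3), ">= 4")

  a <- ape::write.tree(simulate_master_tree(12, seed = 9))
  b <- ape::write.tree(simulate_master_tree(12, seed = 9))
  c <- ape::write.tree(simulate_master_tree(12, seed = 10))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("cherry counts match the Yule expectation n/3", {
  # mean cherries of a Yule tree is n/3, variance 2n/45 (McKenzie & Steel)
  n <- 12
  reps <- 600
  cherries <- vapply(seq_len(reps), function(i) {
    tr <- simulate_master_tree(n, seed = 5000 + i)
    bt <- branch_table(tr)
    sum(table(bt$parent[bt$is_terminal]) == 2)
  }, numeric(1))
  se <- sqrt(2 * n / 45 / reps)
  expect_lt(abs(mean(cherries) - n / 3), 3 * se)
})

test_that("degenerate noise gives gene trees exactly proportional to master", {
  cfg <- sim_config(
    n_taxa = 10, n_genes = 5, fraction_fast = 0, fraction_slow = 0,
    noise_cv = 0, p_missing = 0, fg_clade_size = 3, seed = 2
  )
  master <- simulate_master_tree(10, seed = 2)
  fg <- pick_clade(master, 3, strategy = "nearest")
  g <- simulate_gene_trees(master, cfg, fg)
  for (i in seq_along(g$trees)) {
    ratio <- g$trees[[i]]$edge.length / master$edge.length
    expect_equal(ratio, rep(g$truth$scalar[i], length(ratio)), tolerance = 1e-12)
  }
  # and downstream RERs vanish identically
  fit <- compute_rers(
    build_branch_matrix(g$trees, master),
    consensus = consensus_from_tree(master)
  )
  expect_lt(max(abs(fit$rer$rer)), 1e-10)
})

test_that("planted multipliers act on the designated foreground branches", {
  cfg <- sim_config(
    n_taxa = 10, n_genes = 300, fraction_fast = 0.5, fraction_slow = 0.5,
    noise_cv = 0, p_missing = 0, scalar_sdlog = 0, m_fg = 3,
    fg_clade_size = 3, seed = 6
  )
  master <- simulate_master_tree(10, seed = 6)
  fg <- pick_clade(master, 3, strategy = "nearest")
  g <- simulate_gene_trees(master, cfg, fg)
  fg_edges <- g$design$label == 1
  for (i in c(1, 50, 200)) {
    st <- g$truth$status[i]
    m <- if (st == "fast") 3 else if (st == "slow") 1 / 3 else 1
    ratio <- g$trees[[i]]$edge.length / master$edge.length
    expect_equal(unique(round(ratio[fg_edges], 10)), round(m, 10))
    expect_equal(unique(round(ratio[!fg_edges], 10)), 1)
  }
})

test_that("branch noise has the configured mean and dispersion", {
  cfg <- sim_config(
    n_taxa = 8, n_genes = 2000, fraction_fast = 0, fraction_slow = 0,
    noise_cv = 0.2, p_missing = 0, scalar_sdlog = 0, fg_clade_size = 3,
    seed = 8
  )
  master <- simulate_master_tree(8, seed = 8)
  fg <- pick_clade(master, 3, strategy = "nearest")
  g <- simulate_gene_trees(master, cfg, fg)
  # pooled multiplicative noise across genes and branches: mean 1, cv 0.2
  ratios <- unlist(lapply(g$trees, function(t) t$edge.length)) /
    rep(master$edge.length, length(g$trees))
  n <- length(ratios)
  expect_lt(abs(mean(ratios) - 1), 3 * 0.2 / sqrt(n))
  expect_lt(abs(sd(ratios) - 0.2), 0.01)
})

test_that("missingness prunes the expected number of taxa", {
  cfg <- sim_config(
    n_taxa = 20, n_genes = 100, fraction_fast = 0, fraction_slow = 0,
    noise_cv = 0, p_missing = 0.1, fg_clade_size = 5, seed = 3
  )
  master <- simulate_master_tree(20, seed = 3)
  fg <- pick_clade(master, 5, strategy = "nearest")
  g <- simulate_gene_trees(master, cfg, fg)
  kept <- vapply(g$trees, function(t) length(t$tip.label), numeric(1))
  # binomial: mean 18, 3-SE band over 100 genes
  se <- sqrt(20 * 0.1 * 0.9 / 100)
  expect_lt(abs(mean(kept) - 18), 3 * se)
  expect_true(all(kept >= cfg$min_taxa))
})

test_that("clade traits, degenerate BM, and planted offsets behave", {
  master <- simulate_master_tree(12, seed = 4)
  sizes <- table(lengths(node_tip_sets_for_test(master)))
  fg <- pick_clade(master, 4, strategy = "nearest")
  tr <- simulate_traits(master, fg, seed = 4)
  expect_equal(sum(tr$trait_bin), length(fg))
  expect_setequal(tr$species[tr$trait_bin == 1], fg)
  expect_true(all(tr$mass_kg > 0) && all(tr$lifespan_y > 0))

  # sigma = 0: constant continuous trait
  tr0 <- simulate_traits(master, fg, seed = 4, bm_sigma = 0)
  expect_equal(sd(tr0$cont_trait), 0)

  # planted offset shifts exactly the foreground species
  tr2 <- simulate_traits(master, fg, seed = 4, trait_offset = 5)
  base <- simulate_traits(master, fg, seed = 4, trait_offset = 0)
  delta <- tr2$cont_trait - base$cont_trait
  expect_equal(unname(delta[tr2$trait_bin == 1]), rep(5, length(fg)))
  expect_equal(unname(delta[tr2$trait_bin == 0]), rep(0, 12 - length(fg)))

  # strict clade request errors with the available sizes listed
  absent <- setdiff(2:11, as.integer(names(sizes)))
  if (length(absent) > 0) {
    expect_error(
      simulate_traits(master, absent[1], seed = 1),
      "available clade sizes"
    )
  }
})

test_that("brownian increments on disjoint clades are uncorrelated", {
  master <- read_master_tree(
    "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);"
  )
  diffs <- t(vapply(1:400, function(i) {
    tr <- simulate_traits(master, c("A", "B"), seed = 9000 + i)
    v <- setNames(tr$cont_trait, tr$species)
    c(v["A"] - v["B"], v["C"] - v["D"], v["E"] - v["F"])
  }, numeric(3)))
  cors <- cor(diffs)[lower.tri(cor(diffs))]
  expect_true(all(abs(cors) < 3 / sqrt(400)))
})

test_that("gene sets honor composition, truth flags, and the size rule", {
  cfg <- sim_config(
    n_taxa = 16, n_genes = 100, fraction_fast = 0.3, fraction_slow = 0,
    n_sets = 5, n_enriched_sets = 1, enriched_fraction = 1.0,
    enriched_set_size = 20, set_size_range = c(10, 30),
    fg_clade_size = 5, seed = 12
  )
  truth <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:100),
    status = rep(c("fast", "null"), c(30, 70))
  )
  gs <- simulate_gene_sets(truth$gene_id, truth, cfg)
  expect_equal(nrow(gs$sets), 5)
  expect_equal(sum(gs$set_truth$enriched), 1)
  planted <- gs$sets$genes[[which(gs$set_truth$enriched)]]
  # enriched_fraction = 1: all members are fast genes
  expect_true(all(planted %in% truth$gene_id[truth$status == "fast"]))
  expect_length(planted, 20)
  sizes <- lengths(gs$sets$genes)
  expect_true(all(sizes[!gs$set_truth$enriched] >= 10 &
    sizes[!gs$set_truth$enriched] <= 30))

  # unsatisfiable enriched fraction errors out
  cfg_bad <- sim_config(
    n_genes = 100, fraction_fast = 0.05, enriched_fraction = 1,
    enriched_set_size = 30, seed = 1
  )
  truth_bad <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:100),
    status = rep(c("fast", "null"), c(5, 95))
  )
  expect_error(
    simulate_gene_sets(truth_bad$gene_id, truth_bad, cfg_bad),
    "fast genes"
  )

  # null-set overlap with fast genes behaves hypergeometrically
  overlaps <- vapply(1:200, function(i) {
    cfg_i <- sim_config(
      n_taxa = 16, n_genes = 100, fraction_fast = 0.3, fraction_slow = 0,
      n_sets = 1, n_enriched_sets = 0, set_size_range = c(20, 20),
      fg_clade_size = 5, seed = 3000 + i
    )
    g <- simulate_gene_sets(truth$gene_id, truth, cfg_i)
    length(intersect(g$sets$genes[[1]], truth$gene_id[truth$status == "fast"]))
  }, numeric(1))
  mu <- 20 * 0.3
  sigma <- sqrt(20 * 0.3 * 0.7 * (100 - 20) / (100 - 1))
  expect_lt(abs(mean(overlaps) - mu), 3 * sigma / sqrt(200))

  # sets sized 9 are all excluded downstream by the min-size rule
  fas <- setNames(stats::rnorm(100), truth$gene_id)
  cfg9 <- sim_config(
    n_taxa = 16, n_genes = 100, fraction_fast = 0.3, fraction_slow = 0,
    n_sets = 3, n_enriched_sets = 0, set_size_range = c(9, 9),
    fg_clade_size = 5, seed = 5
  )
  g9 <- simulate_gene_sets(truth$gene_id, truth, cfg9)
  for (s in g9$sets$genes) expect_null(mannwhitney_set_test(fas, s))
})

test_that("identical configs give byte-identical bundles on disk", {
  cfg <- sim_config(
    n_taxa = 10, n_genes = 15, fraction_fast = 0.2, fraction_slow = 0.2,
    fg_clade_size = 3, n_sets = 3, enriched_set_size = 3,
    enriched_fraction = 1, set_size_range = c(3, 6), seed = 33
  )
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  suppressMessages({
    write_sim_bundle(simulate_rer_study(cfg), d1)
    write_sim_bundle(simulate_rer_study(cfg), d2)
  })
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f), warn = FALSE),
      readLines(file.path(d2, f), warn = FALSE),
      label = f
    )
  }
})

test_that("truth counts follow the floor convention", {
  sim <- suppressMessages(simulate_rer_study(sim_config(
    n_taxa = 12, n_genes = 47, fraction_fast = 0.15, fraction_slow = 0.3,
    fg_clade_size = 4, n_sets = 2, n_enriched_sets = 0,
    set_size_range = c(5, 10), seed = 20
  )))
  expect_equal(sum(sim$gene_truth$status == "fast"), floor(0.15 * 47))
  expect_equal(sum(sim$gene_truth$status == "slow"), floor(0.30 * 47))
  # truth round-trips losslessly through TSV
  f <- tempfile(fileext = ".tsv")
  write_results(sim$gene_truth, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(back$status, sim$gene_truth$status)
  expect_equal(back$scalar, sim$gene_truth$scalar, tolerance = 1e-12)
})
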