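# Kendall/Pearson per-gene association, BH correction, classification, and
# the Fisher-exact class tests.

test_that("perfect foreground separation gives the maximal tau-b", {
  x <- c(5, 6, 7, 1, 2, 3, 4)
  y <- c(1, 1, 1, 0, 0, 0, 0)
  res <- kendall_association(x, y)
  expect_gt(res$rho, 0)
  expect_equal(res$rho, kendall_tau_oracle(x, y), tolerance = 1e-12)
  # with no ties in x, tau-b maximum for this tie structure
  n <- 7
  np <- n * (n - 1) / 2
  t2 <- 3 * 2 / 2 + 4 * 3 / 2
  expect_equal(res$rho, (3 * 4) / sqrt(np * (np - t2)), tolerance = 1e-12)
})

test_that("n = 6 kendall matches exhaustive concordance and permutation p", {
  withr::with_seed(17, {
    for (rep in 1:8) {
      x <- stats::rnorm(6)
      y <- sample(c(1, 1, 0, 0, 0, 0))
      res <- kendall_association(x, y)
      expect_equal(res$rho, kendall_tau_oracle(x, y), tolerance = 1e-12)
      expect_equal(res$p, kendall_perm_p_oracle(x, y), tolerance = 1e-12)
    }
    # tied residuals as well
    x <- c(1, 1, 2, 3, 3, 4)
    y <- c(0, 1, 0, 1, 0, 1)
    res <- kendall_association(x, y)
    expect_equal(res$rho, kendall_tau_oracle(x, y), tolerance = 1e-12)
    expect_equal(res$p, kendall_perm_p_oracle(x, y), tolerance = 1e-12)
  })
})

test_that("large-n kendall matches cor.test's tie-corrected approximation", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- 40
      x <- stats::rnorm(n)
      y <- rep(0, n)
      y[sample(n, 10)] <- 1
      res <- kendall_association(x, y)
      ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
      expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-10)
      expect_equal(res$p, ct$p.value, tolerance = 1e-8)
    }
  })
})

test_that("kendall is invariant under strictly increasing transforms", {
  withr::with_seed(5, {
    x <- stats::rnorm(20)
    y <- rep(c(0, 1), 10)
    a <- kendall_association(x, y)
    b <- kendall_association(exp(2 * x) + 3, y)
    expect_equal(a$rho, b$rho, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  })
  expect_error(kendall_association(1:5, rep(1, 5)), "constant")
})

test_that("pearson association matches the closed-form oracle", {
  r <- c(x1 = 0.2, x2 = -0.1, x3 = 0.5, x4 = 0.3, x5 = -0.4)
  expect_equal(pearson_association(r, r)$rho, 1, tolerance = 1e-12)
  expect_equal(pearson_association(r, -r)$rho, -1, tolerance = 1e-12)

  t <- c(x1 = 1.2, x2 = 0.4, x3 = 2.2, x4 = 0.9, x5 = 0.1)
  res <- pearson_association(r, t)
  rho_oracle <- sum((r - mean(r)) * (t - mean(t))) /
    sqrt(sum((r - mean(r))^2) * sum((t - mean(t))^2))
  expect_equal(res$rho, rho_oracle, tolerance = 1e-12)
  expect_error(pearson_association(r[1:3], t[1:3]), "fewer than 4")
  expect_error(
    pearson_association(r, setNames(rep(1, 5), names(r))),
    "constant"
  )
})

test_that("BH adjustment follows the step-up formula", {
  # min over the tail of p * m / rank: (0.03, 0.03, 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.037), 0.037)
  # significance order is preserved up to ties
  withr::with_seed(2, {
    p <- stats::runif(50)
    q <- bh_adjust(p)
    expect_equal(q[order(p)], sort(q)) # sorting by p sorts q (up to ties)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p))
  })
})

test_that("gene classification applies the q/sign rule", {
  res <- tibble::tibble(
    rho = c(0.3, -0.3, 0.5, 0),
    q = c(0.04, 0.04, 0.2, 0.01)
  )
  out <- classify_genes(res, alpha = 0.05)
  expect_equal(out$class, c("fast", "slow", "ns", "ns"))
})

test_that("class overrepresentation equals the hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  class_m <- universe[1:10]
  signif <- universe[c(1:5, 11:20)]
  ct <- fisher_overrepresentation(class_m, signif, universe)
  expect_equal(unname(ct$table[1, ]), c(5, 5))
  expect_equal(unname(ct$table[2, ]), c(10, 80))
  expect_equal(ct$p, hyper_tail_oracle(5, 5, 10, 80), tolerance = 1e-12)

  # degenerate: no significant genes at all -> p = 1
  ct2 <- fisher_overrepresentation(class_m, character(), universe)
  expect_equal(ct2$p, 1)

  # all significant genes inside the class: p = 1 / choose(n, k) form
  u <- sprintf("g%d", 1:10)
  ct3 <- fisher_overrepresentation(u[1:3], u[1:3], u)
  expect_equal(ct3$p, 1 / choose(10, 3), tolerance = 1e-12)
  expect_error(fisher_overrepresentation("a", "a", character()), "empty")
})

test_that("sign-bias test matches full-table enumeration", {
  mk_assoc <- function(n_pos_in, n_neg_in, n_pos_out, n_neg_out) {
    n <- n_pos_in + n_neg_in + n_pos_out + n_neg_out
    tibble::tibble(
      gene_id = sprintf("g%03d", seq_len(n)),
      n = 10,
      rho = rep(
        c(1, -1, 1, -1),
        c(n_pos_in, n_neg_in, n_pos_out, n_neg_out)
      ) * 0.5,
      p = 0.001, q = 0.001, class = "fast"
    )
  }
  # [[11,3],[50,50]]
  a <- mk_assoc(11, 3, 50, 50)
  cls <- a$gene_id[1:14]
  st <- sign_bias_test(a, cls, alpha = 0.05)
  expect_equal(st$p, fisher2x2_two_sided_oracle(11, 3, 50, 50), tolerance = 1e-9)
  expect_equal(st$prop_positive_in_class, 11 / 14)

  # identical sign proportions -> p = 1
  b <- mk_assoc(5, 5, 20, 20)
  expect_equal(sign_bias_test(b, b$gene_id[1:10])$p, 1, tolerance = 1e-12)

  # single in-class gene
  c3 <- mk_assoc(1, 0, 6, 9)
  st3 <- sign_bias_test(c3, c3$gene_id[1])
  expect_equal(st3$p, fisher2x2_two_sided_oracle(1, 0, 6, 9), tolerance = 1e-9)

  # zero margin -> warning and p = 1
  d <- mk_assoc(3, 0, 7, 0)
  expect_warning(st4 <- sign_bias_test(d, d$gene_id[1:3]), "margin")
  expect_equal(st4$p, 1)
})

test_that("class uniformity test reduces to 2x2 Fisher and is stable", {
  # identical rows: perfect homogeneity
  expect_equal(
    class_uniformity_test(matrix(c(3, 3, 3, 3), 2))$p, 1,
    tolerance = 1e-12
  )
  # 2x2 input equals the standard two-sided Fisher
  tab <- matrix(c(7, 2, 3, 8), 2, byrow = TRUE)
  expect_equal(
    class_uniformity_test(tab)$p,
    fisher2x2_two_sided_oracle(7, 2, 3, 8),
    tolerance = 1e-9
  )
  # 3x2 with total 12: exact result within 3 Monte Carlo SE of the MC branch
  tab3 <- matrix(c(4, 0, 1, 3, 2, 2), nrow = 3, byrow = TRUE)
  p_exact <- class_uniformity_test(tab3)$p
  p_mc <- class_uniformity_test(tab3, exact_max_total = 5, B = 2e4, seed = 3)$p
  se <- sqrt(p_exact * (1 - p_exact) / 2e4)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1e-4)
  expect_error(class_uniformity_test(matrix(0, 2, 2)), "zero")
})

test_that("associate_binary scans genes, drops untestable ones, applies BH", {
  sim <- small_sim()
  cons <- consensus_from_tree(sim$master)
  bm <- build_branch_matrix(sim$gene_trees, sim$master)
  fit <- compute_rers(bm, consensus = cons)
  assoc <- suppressMessages(associate_binary(fit, sim$design))
  expect_s3_class(assoc, "rer_assoc")
  expect_true(all(assoc$q >= assoc$p))
  expect_equal(assoc$q, bh_adjust(assoc$p))
  expect_true(all(assoc$class %in% c("fast", "slow", "ns")))
  # classification invariant
  expect_true(all(assoc$rho[assoc$class == "fast"] > 0))
  expect_true(all(assoc$rho[assoc$class == "slow"] < 0))
  expect_true(all(assoc$q[assoc$class != "ns"] < 0.05))
})

test_that("planted continuous correlations are recovered with correct sign", {
  sim <- simulate_rer_study(sim_config(
    n_taxa = 24, n_genes = 120, fraction_fast = 0.25, fraction_slow = 0,
    fg_clade_size = 8, trait_offset = 3, n_sets = 1, n_enriched_sets = 0,
    set_size_range = c(10, 20), seed = 13
  ))
  fit <- suppressMessages(compute_rers(
    build_branch_matrix(sim$gene_trees, sim$master),
    consensus = consensus_from_tree(sim$master)
  ))
  trait <- setNames(sim$traits$cont_trait, sim$traits$species)
  assoc <- suppressMessages(
    associate_continuous(fit, sim$master, trait)
  )
  tt <- dplyr::left_join(assoc, sim$gene_truth, by = "gene_id")
  recall <- mean(tt$class[tt$status == "fast"] == "fast")
  expect_gt(recall, 0.5)
  # planted positive correlations never come out significantly negative
  expect_equal(sum(tt$class[tt$status == "fast"] == "slow"), 0)
})
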