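#' Kendall tau-b association between RERs and a binary branch design
#'
#' The binary foreground indicator creates massive ties, so the
#' tie-corrected tau-b is used. The two-sided p-value is exact for small
#' samples — computed by enumerating every placement of the foreground
#' labels among the branches (equivalent to the full permutation
#' distribution) — and otherwise uses the normal approximation with the
#' standard tie-corrected variance of the concordance statistic.
#'
#' @param x Numeric residuals (RERs) on the branches used.
#' @param labels 0/1 foreground indicator, same length as `x`.
#' @param exact_max_n Largest n for which the exact permutation p is
#'   computed (default 10).
#' @return One-row tibble: `rho` (tau-b), `p`, `n`.
#' @export
kendall_association <- function(x, labels, exact_max_n = 10) {
  keep <- !is.na(x) & !is.na(labels)
  x <- x[keep]
  y <- as.integer(labels[keep])
  n <- length(x)
  n1 <- sum(y == 1L)
  n0 <- n - n1
  if (n1 == 0L || n0 == 0L) {
    abort("labels are constant on the branches with residuals")
  }

  S <- kendall_S(x, y)
  npairs <- n * (n - 1) / 2
  tx <- table(x)
  T1 <- sum(tx * (tx - 1) / 2)
  T2 <- n1 * (n1 - 1) / 2 + n0 * (n0 - 1) / 2
  denom <- sqrt((npairs - T1) * (npairs - T2))
  if (denom == 0) abort("residuals are constant; tau-b undefined")
  tau <- S / denom

  if (n <= exact_max_n) {
    # g_i = net concordance contribution of observation i; for any label
    # placement F, S(F) = sum_{i in F} g_i (within-F terms cancel).
    g <- vapply(seq_len(n), function(i) {
      sum(sign(x[i] - x[-i]))
    }, numeric(1))
    placements <- combn(n, n1)
    S_all <- colSums(matrix(g[placements], nrow = n1))
    p <- mean(abs(S_all) >= abs(S) - 1e-12)
  } else {
    tt <- as.numeric(tx)
    uu <- c(n0, n1)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tt * (tt - 1) * (2 * tt + 5))
    vu <- sum(uu * (uu - 1) * (2 * uu + 5))
    v1 <- sum(tt * (tt - 1)) * sum(uu * (uu - 1)) / (2 * n * (n - 1))
    v2 <- sum(tt * (tt - 1) * (tt - 2)) * sum(uu * (uu - 1) * (uu - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(var_s)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  tibble(rho = tau, p = p, n = n)
}

# Concordant-minus-discordant count between x and a 0/1 indicator.
kendall_S <- function(x, y) {
  d <- outer(x[y == 1L], x[y == 0L], "-")
  sum(d > 0) - sum(d < 0)
}

#' Pearson association between species RERs and a continuous trait
#'
#' Standard product-moment correlation with a two-sided t-based p-value
#' over the species carrying both a residual and a trait value.
#'
#' @param rer Numeric residuals named by species (terminal-branch RERs).
#' @param trait Numeric trait values named by species.
#' @param min_n Minimum shared species (default 4).
#' @return One-row tibble: `rho`, `p`, `n`.
#' @export
pearson_association <- function(rer, trait, min_n = 4) {
  common <- intersect(names(rer), names(trait))
  r <- rer[common]
  t <- trait[common]
  keep <- !is.na(r) & !is.na(t)
  r <- r[keep]
  t <- t[keep]
  if (length(r) < min_n) abort(sprintf("fewer than %d shared species", min_n))
  if (sd(t) == 0) abort("trait is constant over the shared species")
  if (sd(r) == 0) abort("residuals are constant over the shared species")
  ct <- cor.test(r, t, method = "pearson", alternative = "two.sided")
  tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(r))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; one family per trait-by-mode analysis.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values, capped at 1.
#' @export
bh_adjust <- function(pvals) p.adjust(pvals, method = "BH")

#' Classify genes as fast, slow, or not significant
#'
#' `fast`: q < alpha and rho > 0 (accelerated on foreground — positive or
#' relaxed negative selection); `slow`: q < alpha and rho < 0 (decelerated —
#' stabilizing selection); otherwise `ns`. A gene with rho exactly 0 is
#' `ns` regardless of q (no direction, no call).
#'
#' @param results Tibble with `rho` and `q` columns.
#' @param alpha Significance level on q (default 0.05).
#' @return `results` with a `class` column.
#' @export
classify_genes <- function(results, alpha = 0.05) {
  mutate(results, class = dplyr::case_when(
    .data$q < alpha & .data$rho > 0 ~ "fast",
    .data$q < alpha & .data$rho < 0 ~ "slow",
    TRUE ~ "ns"
  ))
}

#' Per-gene association scan for a binary foreground design
#'
#' Runs [kendall_association()] for every gene over the branches where it
#' has an RER, applies Benjamini-Hochberg correction across the genes
#' tested (one family per trait analysis), and classifies genes fast/slow.
#' Genes whose labels are constant on their present branches are dropped
#' with a logged reason.
#'
#' @param fit An `rer_fit` from [compute_rers()], or a long RER tibble
#'   (`gene_id`, `branch_id`, `rer`).
#' @param design A `trait_design` from [assign_foreground()].
#' @param alpha Significance level for classification (default 0.05).
#' @return A tibble of class `rer_assoc`: `gene_id`, `n`, `rho`, `p`, `q`,
#'   `class`; dropped genes in attribute `"dropped"`, the design's
#'   trait/mode in attributes.
#' @export
associate_binary <- function(fit, design, alpha = 0.05) {
  rer <- if (inherits(fit, "rer_fit")) fit$rer else fit
  labels <- setNames(design$label, design$branch_id)
  per_gene <- split(rer, rer$gene_id)

  res <- vector("list", length(per_gene))
  dropped_const <- character()
  for (i in seq_along(per_gene)) {
    d <- per_gene[[i]]
    lab <- labels[d$branch_id]
    out <- tryCatch(
      kendall_association(d$rer, lab),
      error = function(e) NULL
    )
    if (is.null(out)) {
      dropped_const <- c(dropped_const, names(per_gene)[i])
    } else {
      res[[i]] <- mutate(out, gene_id = names(per_gene)[i])
    }
  }
  if (length(dropped_const) > 0) {
    inform(sprintf(
      "associate_binary: dropped %d gene(s) with constant labels",
      length(dropped_const)
    ))
  }
  tab <- bind_rows(res)
  if (nrow(tab) == 0) abort("no gene could be tested against the design")
  tab <- tab[, c("gene_id", "n", "rho", "p")]
  tab$q <- bh_adjust(tab$p)
  tab <- classify_genes(tab, alpha = alpha)
  class(tab) <- c("rer_assoc", class(tab))
  attr(tab, "trait_name") <- attr(design, "trait_name")
  attr(tab, "mode") <- attr(design, "mode")
  attr(tab, "alpha") <- alpha
  attr(tab, "dropped") <- bind_rows(
    if (inherits(fit, "rer_fit")) fit$dropped else drop_record(),
    drop_record(dropped_const,
      rep("constant_labels", length(dropped_const)),
      stage = "association"
    )
  )
  tab
}

#' Per-gene association scan for a continuous species trait
#'
#' Terminal-branch RERs are matched to species and correlated (Pearson)
#' with the trait values; continuous traits attach only to terminal
#' branches since the trait is observed on extant species. BH correction
#' and fast/slow classification as in [associate_binary()].
#'
#' @param fit An `rer_fit` from [compute_rers()].
#' @param master Master `phylo` (to identify terminal branches).
#' @param trait Numeric trait values named by species (already
#'   log-normalized if appropriate; see [log_normalize()]).
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum species per gene (default 4).
#' @return A tibble of class `rer_assoc` (as [associate_binary()]).
#' @export
associate_continuous <- function(fit, master, trait, alpha = 0.05, min_n = 4) {
  stopifnot(inherits(fit, "rer_fit"))
  if (sd(trait, na.rm = TRUE) == 0 || all(is.na(trait))) {
    abort("trait is constant; no association is estimable")
  }
  btab <- branch_table(master)
  term <- btab[btab$is_terminal, ]
  sp_of_branch <- setNames(master$tip.label[term$child], term$branch_id)

  rer <- fit$rer[fit$rer$branch_id %in% term$branch_id, ]
  rer$species <- sp_of_branch[rer$branch_id]
  per_gene <- split(rer, rer$gene_id)

  res <- vector("list", length(per_gene))
  dropped <- character()
  for (i in seq_along(per_gene)) {
    d <- per_gene[[i]]
    out <- tryCatch(
      pearson_association(setNames(d$rer, d$species), trait, min_n = min_n),
      error = function(e) NULL
    )
    if (is.null(out)) {
      dropped <- c(dropped, names(per_gene)[i])
    } else {
      res[[i]] <- mutate(out, gene_id = names(per_gene)[i])
    }
  }
  if (length(dropped) > 0) {
    inform(sprintf(
      "associate_continuous: dropped %d gene(s) (too few species or constant values)",
      length(dropped)
    ))
  }
  tab <- bind_rows(res)
  if (nrow(tab) == 0) abort("no gene could be tested against the trait")
  tab <- tab[, c("gene_id", "n", "rho", "p")]
  tab$q <- bh_adjust(tab$p)
  tab <- classify_genes(tab, alpha = alpha)
  class(tab) <- c("rer_assoc", class(tab))
  attr(tab, "mode") <- "continuous"
  attr(tab, "alpha") <- alpha
  attr(tab, "dropped") <- bind_rows(
    fit$dropped,
    drop_record(dropped, rep("continuous_untestable", length(dropped)),
      stage = "association"
    )
  )
  tab
}
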