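#' Foreground acceleration score (FAS)
#'
#' `FAS = sign(rho) * (-log10 p)`: the signed significance of a gene's
#' trait association, combining direction (sign of the correlation) with
#' strength (the raw p-value, not the BH q). p-values are floored at
#' 1e-300 before the log; a p of exactly 1 (or rho of 0) gives FAS 0.
#'
#' @param rho Correlation coefficient(s) in `[-1, 1]`.
#' @param p Raw p-value(s) in `(0, 1]`.
#' @return Numeric FAS score(s), vectorized.
#' @export
compute_fas <- function(rho, p) {
  if (any(p <= 0, na.rm = TRUE)) {
    warn("p-value(s) of 0 floored at 1e-300")
  }
  p <- pmax(p, 1e-300)
  sign(rho) * (-log10(p))
}

#' Mann-Whitney test of a gene set's FAS scores against the background
#'
#' Two-sided Mann-Whitney U comparing member against non-member FAS. Exact
#' p by complete enumeration of member placements when feasible (handles
#' ties correctly, which the classical exact distribution does not);
#' otherwise the normal approximation with tie-corrected variance. Sets
#' with fewer than `min_set_size` scored members are excluded — small sets
#' rarely share enough genes across branches to be testable, and the size
#' floor guards against unstable calls.
#'
#' @param fas Named numeric vector of FAS scores (names = gene ids).
#' @param members Gene ids of the set.
#' @param min_set_size Minimum scored members (default 10).
#' @param exact_max_comb Enumerate the exact null when `choose(n, m)` is at
#'   most this (default 20000).
#' @return One-row tibble `n_genes`, `U`, `p`, or `NULL` when the set is
#'   excluded by the size rule.
#' @export
mannwhitney_set_test <- function(fas, members, min_set_size = 10,
                                 exact_max_comb = 20000) {
  inset <- names(fas) %in% members
  m <- sum(inset)
  if (m < min_set_size) return(NULL)
  if (!any(!inset)) abort("no background genes outside the set")
  xs <- fas[inset]
  ys <- fas[!inset]
  n2 <- length(ys)
  U <- mw_u(xs, ys)

  N <- m + n2
  if (choose(N, m) <= exact_max_comb) {
    all_v <- c(xs, ys)
    r <- rank(all_v)
    # U from ranks: U = sum(ranks of members) - m(m+1)/2
    sets <- combn(N, m)
    U_all <- colSums(matrix(r[sets], nrow = m)) - m * (m + 1) / 2
    mu <- m * n2 / 2
    p <- mean(abs(U_all - mu) >= abs(U - mu) - 1e-9)
  } else {
    r <- rank(c(xs, ys))
    ties <- table(r)
    mu <- m * n2 / 2
    sigma2 <- m * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  tibble(n_genes = m, U = U, p = p)
}

# Mann-Whitney U (number of (member, background) pairs with member larger,
# ties counting one half).
mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Gene-set enrichment over FAS scores
#'
#' Scores every gene by FAS, tests each eligible set against the background
#' by Mann-Whitney, adjusts across eligible sets (BH), and reports the
#' direction as the sign of the mean member correlation: `accelerated`
#' (mean rho > 0) or `decelerated` — the average gene rho is the set's rate
#' of acceleration/deceleration.
#'
#' @param assoc An `rer_assoc` tibble (per-gene `rho`, `p`).
#' @param sets Gene-set tibble from [read_gene_sets()] (columns `set_name`,
#'   `genes`).
#' @param alpha Significance level on q (default 0.05).
#' @param min_set_size Minimum scored members per set (default 10).
#' @param raw_p_filter If `TRUE`, only genes with raw `p < alpha` are
#'   scored (mirrors restricting enrichment to nominally significant
#'   genes); default `FALSE` scores every tested gene.
#' @return A tibble of class `rer_enrich`: `set_name`, `n_genes`, `U`, `p`,
#'   `q`, `mean_rho`, `direction`, `significant`. Excluded sets are listed
#'   in attribute `"excluded"`.
#' @export
enrich_sets <- function(assoc, sets, alpha = 0.05, min_set_size = 10,
                        raw_p_filter = FALSE) {
  d <- assoc
  if (raw_p_filter) d <- filter(d, .data$p < alpha)
  if (nrow(d) == 0) abort("no scored genes available for enrichment")
  fas <- setNames(compute_fas(d$rho, d$p), d$gene_id)
  rho <- setNames(d$rho, d$gene_id)

  rows <- vector("list", nrow(sets))
  excluded <- character()
  for (i in seq_len(nrow(sets))) {
    members <- sets$genes[[i]]
    res <- mannwhitney_set_test(fas, members, min_set_size = min_set_size)
    if (is.null(res)) {
      excluded <- c(excluded, sets$set_name[i])
      next
    }
    mrho <- mean(rho[intersect(names(fas), members)])
    rows[[i]] <- mutate(res, set_name = sets$set_name[i], mean_rho = mrho)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    warn("no gene set met the minimum size; empty enrichment result")
    out <- tibble(
      set_name = character(), n_genes = integer(), U = numeric(),
      p = numeric(), q = numeric(), mean_rho = numeric(),
      direction = character(), significant = logical()
    )
  } else {
    out$q <- bh_adjust(out$p)
    out <- mutate(out,
      direction = ifelse(.data$mean_rho > 0, "accelerated", "decelerated"),
      significant = .data$q < alpha
    )
    out <- out[, c(
      "set_name", "n_genes", "U", "p", "q", "mean_rho",
      "direction", "significant"
    )]
    out <- arrange(out, .data$q, .data$p)
  }
  class(out) <- c("rer_enrich", class(out))
  attr(out, "excluded") <- excluded
  attr(out, "alpha") <- alpha
  attr(out, "min_set_size") <- min_set_size
  out
}

#' Jaccard similarity between two sets
#'
#' @param a,b Vectors treated as sets (at least one non-empty).
#' @return `|a n b| / |a u b|` in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) abort("both sets are empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Cluster significant pathways by Jaccard overlap
#'
#' Builds a graph over the given gene sets with an edge wherever the
#' Jaccard index strictly exceeds `threshold` (default 0.5), and reports
#' its connected components as pathway clusters — chains of mutually
#' overlapping pathways merge into one higher-order process.
#'
#' @param sets Gene-set tibble (columns `set_name`, `genes`), typically the
#'   significant sets only.
#' @param threshold Strict Jaccard threshold in (0, 1); default 0.5.
#' @return A tibble `cluster_id`, `set_name`; the pairwise Jaccard matrix
#'   in attribute `"jaccard"`. Empty input gives an empty clustering.
#' @export
cluster_pathways <- function(sets, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  k <- nrow(sets)
  if (k == 0) {
    return(structure(
      tibble(cluster_id = integer(), set_name = character()),
      jaccard = matrix(numeric(), 0, 0)
    ))
  }
  J <- matrix(1, k, k, dimnames = list(sets$set_name, sets$set_name))
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        J[i, j] <- J[j, i] <- jaccard(sets$genes[[i]], sets$genes[[j]])
      }
    }
  }
  adj <- J > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- tibble(
    cluster_id = as.integer(comp),
    set_name = sets$set_name
  ) |>
    arrange(.data$cluster_id, .data$set_name)
  attr(out, "jaccard") <- J
  out
}
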