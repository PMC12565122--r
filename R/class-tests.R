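# Secondary tests on a designated gene class (e.g. tumor suppressors)
# against the genome-wide scan results. These are post hoc checks, reported
# without FDR correction.

#' Overrepresentation of a gene class among significant genes
#'
#' One-sided (greater) Fisher's exact test on the 2x2 table of class
#' membership against significance — the hypergeometric probability that at
#' least as many class members land in the significant list by chance.
#'
#' @param class_members Gene ids of the class (e.g. oncosuppressors).
#' @param significant Gene ids called significant by the scan.
#' @param universe All gene ids tested.
#' @return A list of class `class_test`: `test`, `table` (2x2), `odds_ratio`,
#'   `p`.
#' @export
fisher_overrepresentation <- function(class_members, significant, universe) {
  if (length(universe) == 0) abort("empty gene universe")
  class_members <- intersect(class_members, universe)
  significant <- intersect(significant, universe)
  a <- length(intersect(class_members, significant))
  b <- length(setdiff(class_members, significant))
  cc <- length(setdiff(significant, class_members))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      class = c("in_class", "out_class"),
      significance = c("significant", "not_significant")
    )
  )
  ft <- fisher.test(tab, alternative = "greater")
  structure(
    list(
      test = "class_overrepresentation",
      table = tab,
      odds_ratio = unname(ft$estimate),
      p = ft$p.value
    ),
    class = "class_test"
  )
}

#' Sign bias of a gene class among significant genes
#'
#' Among significant genes, compares the split of positive versus negative
#' correlations inside the class with the split outside it (two-sided
#' Fisher's exact test on the 2x2 table). A binomial test of the in-class
#' positive fraction against 0.5 is reported alongside, since the 2x2
#' construction needs a comparison group while the headline quantity is the
#' in-class fraction itself.
#'
#' @param assoc An `rer_assoc` tibble.
#' @param class_members Gene ids of the class.
#' @param alpha Significance threshold (default: the scan's alpha).
#' @param use_raw_p Use raw `p < alpha` instead of `q < alpha` to define
#'   significance (default `FALSE`).
#' @return A `class_test` list: `table`, `p` (Fisher), `p_binomial`,
#'   `prop_positive_in_class`.
#' @export
sign_bias_test <- function(assoc, class_members, alpha = NULL,
                           use_raw_p = FALSE) {
  alpha <- alpha %||% attr(assoc, "alpha") %||% 0.05
  sig <- if (use_raw_p) assoc$p < alpha else assoc$q < alpha
  sig <- sig & assoc$rho != 0
  d <- assoc[sig, ]
  in_class <- d$gene_id %in% class_members
  if (sum(in_class) == 0 || sum(!in_class) == 0) {
    abort("need at least one significant gene inside and outside the class")
  }
  tab <- matrix(
    c(
      sum(in_class & d$rho > 0), sum(in_class & d$rho < 0),
      sum(!in_class & d$rho > 0), sum(!in_class & d$rho < 0)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      class = c("in_class", "out_class"),
      sign = c("positive", "negative")
    )
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("a margin of the sign table is zero; Fisher p set to 1")
    p <- 1
  } else {
    p <- fisher.test(tab, alternative = "two.sided")$p.value
  }
  n_pos <- tab[1, 1]
  n_in <- sum(tab[1, ])
  structure(
    list(
      test = "sign_bias",
      table = tab,
      p = p,
      prop_positive_in_class = n_pos / n_in,
      p_binomial = binom.test(n_pos, n_in, p = 0.5)$p.value
    ),
    class = "class_test"
  )
}

#' Homogeneity of correlation sign across gene sub-classes
#'
#' Generalized (Freeman-Halton) Fisher's exact test on an r-by-2 table of
#' gene sub-classes against correlation sign: are accelerated and
#' decelerated genes spread evenly over the sub-classes? Exact when the
#' table total is at most `exact_max_total`; Monte Carlo with `B` samples
#' and a fixed seed otherwise.
#'
#' @param counts Integer matrix with r >= 2 rows and 2 columns.
#' @param exact_max_total Largest total for the exact computation
#'   (default 30).
#' @param B Monte Carlo samples beyond that (default 1e5).
#' @param seed Seed for the Monte Carlo branch (default 1).
#' @return A `class_test` list: `table`, `p`.
#' @export
class_uniformity_test <- function(counts, exact_max_total = 30, B = 1e5,
                                  seed = 1) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) != 2) {
    abort("counts must be an r x 2 table with r >= 2")
  }
  if (sum(counts) == 0) abort("all-zero table")
  p <- if (sum(counts) <= exact_max_total) {
    fisher.test(counts)$p.value
  } else {
    withr::with_seed(
      seed,
      fisher.test(counts, simulate.p.value = TRUE, B = as.integer(B))$p.value
    )
  }
  structure(
    list(test = "class_uniformity", table = counts, p = p),
    class = "class_test"
  )
}

#' @export
print.class_test <- function(x, ...) {
  cat(sprintf("<class_test> %s, p = %.4g\n", x$test, x$p))
  print(x$table)
  invisible(x)
}

#' Tidy a class test into a one-row tibble
#'
#' Table cells are flattened column-wise into `cell_*` columns.
#'
#' @param x A `class_test`.
#' @param ... Unused.
#' @method tidy class_test
#' @export
tidy.class_test <- function(x, ...) {
  cells <- as.vector(x$table)
  out <- tibble(
    test = x$test,
    p = x$p,
    odds_ratio = x$odds_ratio %||% NA_real_,
    prop_positive_in_class = x$prop_positive_in_class %||% NA_real_,
    p_binomial = x$p_binomial %||% NA_real_
  )
  for (i in seq_along(cells)) out[[paste0("cell_", i)]] <- cells[i]
  out
}
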