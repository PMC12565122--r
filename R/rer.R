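#' Compute relative evolutionary rates (RERs)
#'
#' For each gene, branch lengths are square-root transformed and regressed
#' (ordinary least squares with intercept) on the transformed consensus
#' lengths over the branches present for that gene. The residuals are the
#' gene's RERs: positive on branches where the gene evolved faster than the
#' genome-wide expectation, negative where slower. Genes with fewer than
#' `min_branches` present branches, or a constant consensus predictor, are
#' dropped with a logged reason.
#'
#' @param branch_matrix Long tibble from [build_branch_matrix()].
#' @param consensus Optional consensus from [consensus_lengths()]; computed
#'   from `branch_matrix` when `NULL` (a precomputed reference consensus may
#'   be supplied instead).
#' @param min_branches Minimum present branches per gene (default 3).
#' @return An object of class `rer_fit`: a list with `rer` (long tibble
#'   `gene_id`, `branch_id`, `rer`), `coef` (per-gene `intercept`, `slope`,
#'   `n`), `consensus`, and `dropped` (gene, stage, reason).
#' @examples
#' tr <- read_master_tree("((A:1,B:2):1,C:3);")
#' bm <- build_branch_matrix(list(g1 = tr, g2 = tr), tr)
#' fit <- compute_rers(bm)
#' tidy(fit)
#' @export
compute_rers <- function(branch_matrix, consensus = NULL, min_branches = 3) {
  if (is.null(consensus)) consensus <- consensus_lengths(branch_matrix)
  d <- inner_join(branch_matrix, consensus[, c("branch_id", "mean_length")],
    by = "branch_id"
  )
  d <- mutate(d,
    x = transform_lengths(.data$mean_length),
    y = transform_lengths(.data$length)
  )

  stats_tbl <- d |>
    group_by(.data$gene_id) |>
    summarise(n = dplyr::n(), sdx = sd(.data$x), .groups = "drop")
  bad_n <- stats_tbl$gene_id[stats_tbl$n < min_branches]
  bad_const <- setdiff(
    stats_tbl$gene_id[stats_tbl$sdx == 0 | is.na(stats_tbl$sdx)], bad_n
  )
  dropped <- bind_rows(
    attr(branch_matrix, "dropped") %||% drop_record(),
    drop_record(bad_n, rep("too_few_branches", length(bad_n)), "rer"),
    drop_record(bad_const, rep("constant_consensus", length(bad_const)), "rer")
  )
  if (length(bad_n) + length(bad_const) > 0) {
    inform(sprintf(
      "compute_rers: dropped %d gene(s) (too_few_branches: %d, constant_consensus: %d)",
      length(bad_n) + length(bad_const), length(bad_n), length(bad_const)
    ))
  }
  d <- filter(d, !(.data$gene_id %in% c(bad_n, bad_const)))

  fitted <- d |>
    group_by(.data$gene_id) |>
    mutate(
      slope = {
        xc <- .data$x - mean(.data$x)
        sum(xc * (.data$y - mean(.data$y))) / sum(xc^2)
      },
      intercept = mean(.data$y) - .data$slope * mean(.data$x),
      rer = .data$y - .data$intercept - .data$slope * .data$x
    ) |>
    ungroup()

  out <- list(
    rer = fitted[, c("gene_id", "branch_id", "rer")],
    coef = distinct(
      fitted[, c("gene_id", "intercept", "slope")],
      .data$gene_id,
      .keep_all = TRUE
    ) |>
      left_join(stats_tbl[, c("gene_id", "n")], by = "gene_id"),
    consensus = consensus,
    dropped = dropped
  )
  class(out) <- "rer_fit"
  out
}

#' @export
print.rer_fit <- function(x, ...) {
  cat(sprintf(
    "<rer_fit> %d genes x %d branches (%d gene(s) dropped)\n",
    length(unique(x$rer$gene_id)), length(unique(x$rer$branch_id)),
    nrow(x$dropped)
  ))
  invisible(x)
}

#' Tidy per-gene regression diagnostics of an RER fit
#'
#' @param x An `rer_fit`.
#' @param ... Unused.
#' @return Tibble with one row per retained gene: `gene_id`, `intercept`,
#'   `slope`, `n`.
#' @method tidy rer_fit
#' @export
tidy.rer_fit <- function(x, ...) x$coef

#' One-row summary of an RER fit
#'
#' @param x An `rer_fit`.
#' @param ... Unused.
#' @method glance rer_fit
#' @export
glance.rer_fit <- function(x, ...) {
  tibble(
    n_genes = length(unique(x$rer$gene_id)),
    n_branches = length(unique(x$rer$branch_id)),
    n_dropped = nrow(x$dropped),
    median_slope = stats::median(x$coef$slope)
  )
}
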