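#' Fitch maximum-parsimony ancestral states for a binary character
#'
#' Bottom-up pass: each internal node's state set is the intersection of its
#' children's sets when non-empty, else their union (one change counted per
#' union event; for a binary character on a binary tree this equals the
#' minimum number of state changes over all full labelings). Top-down pass:
#' each node resolves to its parent's resolved state when that state lies in
#' its set; an ambiguous root resolves to 0, the background state, so
#' foreground is never inflated by arbitrary tie-breaking.
#'
#' @param tree A rooted `phylo` object.
#' @param terminal_states Named vector (names = tip labels) of 0/1 states;
#'   every tip must be labeled.
#' @return A list of class `fitch_states`: `node_states` tibble (`node`,
#'   `state_set` as `"0"`, `"1"` or `"01"`, `resolved`), and integer
#'   `changes`.
#' @export
fitch_parsimony <- function(tree, terminal_states) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, names(terminal_states))
  if (length(missing) > 0) {
    abort(sprintf(
      "unlabeled terminal(s): %s", paste(missing, collapse = ", ")
    ))
  }
  obs <- as.integer(terminal_states[tree$tip.label])
  if (!all(obs %in% c(0L, 1L))) abort("terminal states must be 0 or 1")

  n_node <- n_tip + tree$Nnode
  # state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  setmask <- integer(n_node)
  setmask[seq_len(n_tip)] <- ifelse(obs == 1L, 2L, 1L)
  po <- ape::reorder.phylo(tree, "postorder")
  changes <- 0L
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]
    ch <- po$edge[k, 2L]
    if (setmask[p] == 0L) {
      setmask[p] <- setmask[ch]
    } else {
      inter <- bitwAnd(setmask[p], setmask[ch])
      if (inter > 0L) {
        setmask[p] <- inter
      } else {
        setmask[p] <- bitwOr(setmask[p], setmask[ch])
        changes <- changes + 1L
      }
    }
  }

  # top-down resolution (preorder = reversed postorder edge list)
  resolved <- integer(n_node)
  root <- n_tip + 1L
  resolved[root] <- if (setmask[root] == 2L) 1L else 0L
  for (k in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[k, 1L]
    ch <- po$edge[k, 2L]
    pmask <- if (resolved[p] == 1L) 2L else 1L
    resolved[ch] <- if (bitwAnd(setmask[ch], pmask) > 0L) {
      resolved[p]
    } else if (setmask[ch] == 3L) {
      0L
    } else if (setmask[ch] == 2L) 1L else 0L
  }

  out <- list(
    node_states = tibble(
      node = seq_len(n_node),
      state_set = c("0", "1", "01")[setmask],
      resolved = resolved
    ),
    changes = changes
  )
  class(out) <- "fitch_states"
  out
}

#' @export
print.fitch_states <- function(x, ...) {
  cat(sprintf(
    "<fitch_states> %d nodes, %d change(s), %d ambiguous node(s)\n",
    nrow(x$node_states), x$changes, sum(x$node_states$state_set == "01")
  ))
  invisible(x)
}
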