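# Internal helpers shared across modules.

# Canonical branch identity: the sorted set of descendant terminal taxa,
# joined with "|". Robust to node rotation and newick ordering.
make_branch_id <- function(tips) {
  vapply(tips, function(t) paste(sort(t), collapse = "|"), character(1))
}

# Descendant tip indices for every node of a phylo object, computed in one
# postorder pass. Returns a list indexed by node number.
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]
    ch <- po$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Seed streams: every stochastic stage draws from root seed + a fixed
# documented offset, so stages can be regenerated independently.
SEED_STREAM <- c(master_tree = 0L, gene_trees = 1L, traits = 2L, gene_sets = 3L)

stream_seed <- function(seed, stream) {
  stopifnot(stream %in% names(SEED_STREAM))
  s <- as.integer(seed) + SEED_STREAM[[stream]]
  if (s >= .Machine$integer.max) s <- s %% 1000003L
  s
}

# Accumulator for per-stage gene drops; every pipeline stage reports the
# genes it removed and why, so the manifest can balance its accounting.
drop_record <- function(gene_id = character(), reason = character(),
                        stage = character()) {
  tibble(gene_id = as.character(gene_id), stage = stage, reason = reason)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
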