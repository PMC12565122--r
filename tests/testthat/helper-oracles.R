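# Independent oracles: brute-force / closed-form re-derivations used to pin
# expected values. These deliberately avoid the package's own code paths.

# OLS by the normal equations (solve X'X b = X'y directly).
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2], resid = as.numeric(y - X %*% beta))
}

# Minimum number of binary-state changes over all internal labelings,
# by exhaustive enumeration.
brute_force_parsimony <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  obs <- as.integer(states[tree$tip.label])
  combos <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    full <- c(obs, combos[r, ])
    ch <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    if (ch < best) best <- ch
  }
  best
}

# Kendall S (concordant minus discordant) by explicit double loop.
kendall_S_oracle <- function(x, y) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    }
  }
  s
}

# tau-b by its definition.
kendall_tau_oracle <- function(x, y) {
  n <- length(x)
  np <- n * (n - 1) / 2
  tx <- table(x)
  ty <- table(y)
  kendall_S_oracle(x, y) /
    sqrt((np - sum(tx * (tx - 1) / 2)) * (np - sum(ty * (ty - 1) / 2)))
}

# All permutations of 1..n (recursive; fine for n <= 7).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

# Exact two-sided permutation p for Kendall S with binary labels, by
# permuting the residual vector over all n! orderings.
kendall_perm_p_oracle <- function(x, y) {
  s_obs <- abs(kendall_S_oracle(x, y))
  perms <- all_perms(length(x))
  hits <- vapply(perms, function(p) {
    abs(kendall_S_oracle(x[p], y)) >= s_obs - 1e-12
  }, logical(1))
  mean(hits)
}

# Mann-Whitney U by pair counting (ties count one half).
mw_u_oracle <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# Exact two-sided p for Mann-Whitney by enumerating all member placements.
mw_exact_p_oracle <- function(x, y) {
  v <- c(x, y)
  m <- length(x)
  mu <- m * length(y) / 2
  u_obs <- mw_u_oracle(x, y)
  sets <- utils::combn(length(v), m)
  u_all <- apply(sets, 2, function(idx) mw_u_oracle(v[idx], v[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Upper-tail hypergeometric p for a 2x2 table [[a, b], [c, d]] by direct
# summation of the density.
hyper_tail_oracle <- function(a, b, c, d) {
  m <- a + b # class size
  n <- c + d
  k <- a + c # significant total
  sum(vapply(a:min(m, k), function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1)))
}

# Two-sided Fisher p for a 2x2 by enumerating all tables with the observed
# margins and summing densities <= the observed one.
fisher2x2_two_sided_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  dens <- function(x) choose(m, x) * choose(n, k - x) / choose(m + n, k)
  d_obs <- dens(a)
  xs <- max(0, k - n):min(m, k)
  sum(vapply(xs, dens, numeric(1))[vapply(xs, dens, numeric(1)) <= d_obs * (1 + 1e-7)])
}

# Branches of a master tree that survive restriction to a taxon subset,
# by direct bipartition set algebra (independent of build_branch_matrix).
restricted_branch_oracle <- function(master, keep) {
  bt <- branch_table(master)
  tips <- strsplit(bt$branch_id, "|", fixed = TRUE)
  restr <- lapply(tips, intersect, keep)
  keys <- vapply(restr, function(s) paste(sort(s), collapse = "|"), character(1))
  ok <- lengths(restr) > 0 & lengths(restr) < length(keep)
  ok & !(keys %in% keys[ok][duplicated(keys[ok])])
}

# Connected components of an undirected graph given as an edge list over
# labeled vertices, by label propagation to a fixed point.
components_oracle <- function(vertices, edges) {
  lab <- setNames(seq_along(vertices), vertices)
  repeat {
    changed <- FALSE
    for (e in edges) {
      m <- min(lab[e[1]], lab[e[2]])
      if (lab[e[1]] != m || lab[e[2]] != m) {
        lab[e[1]] <- lab[e[2]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(lab), lab)
}

# Tip sets per node via ape::prop.part (independent of the package's
# internal postorder accumulation).
node_tip_sets_for_test <- function(tree) {
  n_tip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  c(as.list(seq_len(n_tip)), lapply(pp, as.integer))
}
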