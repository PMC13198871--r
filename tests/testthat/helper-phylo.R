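# Exhaustive minimum-mutation oracle for the parsimony reconstructor: tries
# every assignment of the 5 states to every internal node and returns the
# set of root states occurring in minimum-cost assignments.
exhaustive_root_states <- function(tree, tip_states) {
  states <- c("A", "C", "G", "T", "-")
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(states), n_int),
                                stringsAsFactors = FALSE))
  tipv <- tip_states[tree$tip.label]
  getcol <- function(node) {
    if (node <= n_tip) rep(tipv[node], nrow(grid))
    else grid[, node - n_tip]
  }
  cost <- rep(0L, nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    cost <- cost + (getcol(tree$edge[e, 1]) != getcol(tree$edge[e, 2]))
  }
  sort(unique(grid[cost == min(cost), 1]))  # root is node n_tip + 1
}

decode_fitch_set <- function(mask) {
  states <- c(A = 1L, C = 2L, G = 4L, T = 8L, "-" = 16L)
  sort(names(states)[bitwAnd(mask, states) != 0L])
}

# Brute-force LCA oracle: first common node on the tip-to-root ancestor
# paths.
lca_oracle <- function(tree, tips) {
  anc_path <- function(node) {
    path <- node
    repeat {
      r <- which(tree$edge[, 2] == node)
      if (!length(r)) break
      node <- tree$edge[r, 1]
      path <- c(path, node)
    }
    path
  }
  paths <- lapply(match(tips, tree$tip.label), anc_path)
  common <- Reduce(intersect, paths)
  paths[[1]][min(match(common, paths[[1]]))]
}
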