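# Independent brute-force oracles used to verify the metric and tree
# operations. These deliberately take different computational routes from
# the package implementations.

# Faith's PD, root-inclusive, via an edge-set union over per-tip root
# paths read directly off the edge matrix.
oracle_faith_pd <- function(tree, taxa) {
  tips <- match(taxa, tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L
  edges <- character(0)
  for (tip in tips) {
    node <- tip
    while (node != root) {
      edges <- union(edges, paste(parent[node], node))
      node <- parent[node]
    }
  }
  keys <- paste(tree$edge[, 1], tree$edge[, 2])
  sum(tree$edge.length[keys %in% edges])
}

# Patristic distance by walking both tips to the root and summing the
# unshared parts of the two paths.
oracle_patristic <- function(tree, a, b) {
  walk <- function(tip) {
    parent <- integer(max(tree$edge))
    elen <- numeric(max(tree$edge))
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    elen[tree$edge[, 2]] <- tree$edge.length
    root <- ape::Ntip(tree) + 1L
    nodes <- c(); lens <- c(); node <- tip
    while (node != root) {
      nodes <- c(nodes, node); lens <- c(lens, elen[node]); node <- parent[node]
    }
    list(nodes = c(nodes, root), lens = c(lens, 0))
  }
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  pa <- walk(ia); pb <- walk(ib)
  shared <- intersect(pa$nodes, pb$nodes)
  mrca <- shared[1]
  sum(pa$lens[seq_len(which(pa$nodes == mrca) - 1L)]) +
    sum(pb$lens[seq_len(which(pb$nodes == mrca) - 1L)])
}

# MPD / MNTD by explicit loops over the cophenetic matrix from ape.
oracle_mpd <- function(tree, taxa) {
  D <- ape::cophenetic.phylo(tree)[taxa, taxa]
  tot <- 0; k <- 0
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) if (i < j) {
    tot <- tot + D[i, j]; k <- k + 1
  }
  tot / k
}

oracle_mntd <- function(tree, taxa) {
  D <- ape::cophenetic.phylo(tree)[taxa, taxa]
  mean(vapply(seq_along(taxa), function(i) min(D[i, -i]), numeric(1)))
}

# Random ultrametric test tree with clean labels.
random_test_tree <- function(n, depth = 100) {
  tree <- ape::rcoal(n)
  tree$edge.length <- tree$edge.length * depth / max(ape::node.depth.edgelength(tree))
  tree$tip.label <- paste0("sp", seq_len(n))
  tree
}

random_subset <- function(tree, k) sample(tree$tip.label, k)
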