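## Community phylogenetic diversity metrics, computed directly from the
## edge structure of an ape "phylo" tree. All values are in the tree's
## branch-length units (My for the dated trees used here).

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the given taxa and
#' the root. The default is the root-inclusive convention (the path from
#' the taxa's common ancestor down to the root is counted), matching the
#' standard community-phylogenetics implementations; `include_root =
#' FALSE` gives the crown-based alternative (the spanning subtree of the
#' taxa only, 0 for a single taxon). Monotone non-decreasing under
#' taxon-set inclusion in either convention.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of tip labels, at least one.
#' @param include_root logical; count the stem path to the root.
#' @return Faith's PD in branch-length units.
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE) {
  tree <- validate_phylogeny(tree)
  taxa <- unique(normalize_species(taxa))
  if (length(taxa) < 1L) stop("'taxa' must contain at least one species")
  tips <- match_taxa(tree, taxa)
  paths <- tip_edge_paths(tree, tips)
  on_subtree <- logical(nrow(tree$edge))
  for (p in paths) on_subtree[p] <- TRUE
  pd <- sum(tree$edge.length[on_subtree])
  if (!include_root) {
    ## subtract the shared stem: every edge on all tips' root paths
    shared <- rep(TRUE, nrow(tree$edge))
    for (p in paths) {
      onp <- logical(nrow(tree$edge)); onp[p] <- TRUE
      shared <- shared & onp
    }
    pd <- pd - sum(tree$edge.length[shared])
  }
  pd
}

#' Mean pairwise phylogenetic distance
#'
#' Unweighted mean of patristic distances over all unordered pairs of taxa.
#'
#' @inheritParams faith_pd
#' @param taxa character vector of tip labels, at least two.
#' @return MPD in branch-length units.
#' @export
mpd <- function(tree, taxa) {
  taxa <- unique(normalize_species(taxa))
  if (length(taxa) < 2L)
    stop("MPD requires at least two taxa (the single-fixer 0 convention is applied by the caller)")
  D <- patristic_matrix(tree, taxa)
  mean(D[lower.tri(D)])
}

#' Mean nearest taxon distance
#'
#' Mean over taxa of each taxon's patristic distance to its nearest
#' neighbour within the set. Always `<=` MPD.
#'
#' @inheritParams mpd
#' @return MNTD in branch-length units.
#' @export
mntd <- function(tree, taxa) {
  taxa <- unique(normalize_species(taxa))
  if (length(taxa) < 2L)
    stop("MNTD requires at least two taxa (the single-fixer 0 convention is applied by the caller)")
  D <- patristic_matrix(tree, taxa)
  diag(D) <- Inf
  mean(apply(D, 1L, min))
}

#' All three diversity metrics for a taxon set
#'
#' Convenience wrapper applying the conventions used throughout the
#' pipeline: the empty set has Faith's PD 0 and undefined (NA) MPD/MNTD;
#' a singleton has its root-spanning Faith's PD and, when
#' `single_zero = TRUE`, MPD = MNTD = 0 (otherwise NA).
#'
#' @inheritParams faith_pd
#' @param taxa character vector of tip labels (may be empty).
#' @param single_zero logical; apply the MPD/MNTD = 0 convention for
#'   single-species sets.
#' @return a one-row data frame with `n_taxa`, `faith_pd`, `mpd`, `mntd`.
#' @export
pd_metrics <- function(tree, taxa, single_zero = TRUE) {
  taxa <- unique(normalize_species(taxa))
  n <- length(taxa)
  if (n == 0L)
    return(data.frame(n_taxa = 0L, faith_pd = 0, mpd = NA_real_,
                      mntd = NA_real_))
  pd <- faith_pd(tree, taxa)
  if (n == 1L) {
    fill <- if (single_zero) 0 else NA_real_
    return(data.frame(n_taxa = 1L, faith_pd = pd, mpd = fill, mntd = fill))
  }
  data.frame(n_taxa = n, faith_pd = pd, mpd = mpd(tree, taxa),
             mntd = mntd(tree, taxa))
}
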