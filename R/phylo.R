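## Dated-phylogeny handling: parsing, validation, pruning, grafting,
## patristic distances. Trees are ape "phylo" objects throughout; branch
## lengths are in millions of years (My).

#' Normalize species names
#'
#' Tip labels and trait-table species names are matched with underscores and
#' spaces treated as equivalent and surrounding whitespace ignored. Matching
#' is otherwise case-sensitive.
#'
#' @param x character vector of species names.
#' @return character vector with internal whitespace collapsed to single
#'   underscores.
#' @export
normalize_species <- function(x) {
  x <- trimws(as.character(x))
  gsub("[ \t]+", "_", x)
}

#' Genus of a binomial
#'
#' The genus is the first underscore- or space-delimited token of the name.
#'
#' @param x character vector of (normalized or raw) species names.
#' @return character vector of genus names.
#' @export
genus_of <- function(x) sub("[ _].*$", "", normalize_species(x))

#' Parse a newick string into a validated phylogeny
#'
#' Wraps [ape::read.tree()] and enforces the invariants the downstream
#' metrics rely on: every edge carries a non-negative branch length, tip
#' labels are unique after name normalization, and the tree is rooted.
#' Malformed input is rejected with the character offset of the first
#' unbalanced parenthesis where that can be determined.
#'
#' @param text a single newick string (terminating semicolon required).
#' @return an object of class `phylo` with normalized tip labels.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unbalanced ')' at character offset ", i)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' at end of string")
  if (!grepl(";", text, fixed = TRUE))
    stop("newick parse error: missing terminating ';' at character offset ",
         nchar(text))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree))
    stop("newick parse error: unreadable newick string")
  validate_phylogeny(tree)
}

#' Validate a phylogeny object
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly unchanged except for normalized tip labels.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length))
    stop("branch lengths are missing (no silent default is applied)")
  if (anyNA(tree$edge.length))
    stop("branch lengths contain NA (no silent default is applied)")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tree$tip.label <- normalize_species(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels after normalization: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Write a phylogeny to newick
#'
#' Branch lengths are always written, with 9 significant digits.
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the newick string is returned.
#' @return the newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL) {
  tree <- validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = 9)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Root-to-node depths
#'
#' @param tree a `phylo` object.
#' @return numeric vector over all nodes (tips first, then internal nodes,
#'   in ape numbering) of summed branch lengths from the root.
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

## Sequence of nodes from a tip (or node) back to the root, as node ids.
root_path_nodes <- function(tree, node) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L
  path <- node
  while (node != root) {
    node <- parent[node]
    path <- c(path, node)
  }
  path
}

## Edge indices (rows of tree$edge) on the path from each given tip to the
## root. Returns a list indexed like `tips`.
tip_edge_paths <- function(tree, tips) {
  nnode <- max(tree$edge)
  parent <- integer(nnode)
  edge_of <- integer(nnode)     # edge row whose child is the node
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ape::Ntip(tree) + 1L
  lapply(tips, function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      path <- c(path, edge_of[node])
      node <- parent[node]
    }
    path
  })
}

match_taxa <- function(tree, taxa, what = "tree") {
  taxa <- normalize_species(taxa)
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx))
    stop("taxa not found in ", what, ": ",
         paste(taxa[is.na(idx)], collapse = ", "))
  idx
}

#' Prune a phylogeny to a set of taxa
#'
#' Retains exactly the requested tips; internal nodes left with a single
#' descendant are suppressed with their branch lengths summed, so patristic
#' distances among retained tips are unchanged.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of tip labels to keep (at least one).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, taxa) {
  tree <- validate_phylogeny(tree)
  taxa <- unique(normalize_species(taxa))
  if (length(taxa) < 1L) stop("at least one taxon must be kept")
  match_taxa(tree, taxa)
  if (length(taxa) == ape::Ntip(tree)) return(tree)
  if (length(taxa) == 1L) {
    ## keep.tip() cannot return a single-tip tree; build it directly with the
    ## tip's full root-to-tip depth so Faith's PD of the singleton is exact.
    d <- node_depths(tree)[match_taxa(tree, taxa)]
    t1 <- ape::read.tree(text = paste0("(", taxa, ":", format(d, digits = 17), ");"))
    return(validate_phylogeny(t1))
  }
  validate_phylogeny(ape::keep.tip(tree, taxa))
}

#' Patristic distance matrix for a set of taxa
#'
#' Distances are sums of branch lengths along the tree path between tips,
#' computed from root-to-tip depths and most recent common ancestors.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of tip labels (non-empty).
#' @return a symmetric numeric matrix with zero diagonal, dimnames = taxa.
#' @export
patristic_matrix <- function(tree, taxa) {
  tree <- validate_phylogeny(tree)
  taxa <- normalize_species(taxa)
  if (length(taxa) < 1L) stop("'taxa' must be non-empty")
  tips <- match_taxa(tree, taxa)
  depths <- node_depths(tree)
  paths <- lapply(tips, function(t) root_path_nodes(tree, t))
  k <- length(tips)
  D <- matrix(0, k, k, dimnames = list(taxa, taxa))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      on_i <- logical(max(tree$edge))
      on_i[paths[[i]]] <- TRUE
      for (j in seq.int(i + 1L, k)) {
        ## MRCA = first node of j's root path that also lies on i's path
        pj <- paths[[j]]
        mrca <- pj[which(on_i[pj])[1]]
        D[i, j] <- D[j, i] <- depths[tips[i]] + depths[tips[j]] - 2 * depths[mrca]
      }
    }
  }
  D
}

#' Test ultrametricity
#'
#' @param tree a `phylo` object.
#' @param tol absolute tolerance on the root-to-tip depth range.
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol
}

#' Read a species trait table
#'
#' @param file CSV with columns `species,genus,family,is_fixer`
#'   (`is_fixer` coded 0/1).
#' @return data frame with normalized species names, `is_fixer` logical.
#' @export
read_traits_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_traits(df)
}

#' Validate a trait table
#'
#' Checks required columns, non-empty genus and family, 0/1 fixer coding and
#' genus-constancy of the fixer trait.
#'
#' @param df data frame with columns `species,genus,family,is_fixer`.
#' @return the validated data frame (`species` normalized, `is_fixer`
#'   logical).
#' @export
validate_traits <- function(df) {
  need <- c("species", "genus", "family", "is_fixer")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trait table missing columns: ",
                         paste(miss, collapse = ", "))
  df$species <- normalize_species(df$species)
  if (anyDuplicated(df$species))
    stop("duplicate species in trait table: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  if (any(!nzchar(df$genus)) || any(!nzchar(df$family)))
    stop("genus and family must be non-empty for every species")
  if (!all(df$is_fixer %in% c(0, 1, TRUE, FALSE)))
    stop("is_fixer must be coded 0/1")
  df$is_fixer <- as.logical(df$is_fixer)
  bad <- tapply(df$is_fixer, df$genus, function(z) length(unique(z)) > 1L)
  if (any(bad))
    stop("fixer status varies within genus: ",
         paste(names(bad)[bad], collapse = ", "))
  df
}

## Pendant length so that a tip attached at `node` reaches `target_depth`.
graft_pendant <- function(depths, node, target_depth) {
  len <- target_depth - depths[node]
  if (len < -1e-9)
    stop("graft target depth ", format(target_depth),
         " is above the attachment node (depth ", format(depths[node]), ")")
  max(len, 0)
}

#' Graft missing species onto a phylogeny
#'
#' Species absent from the tree are attached at the genus level when the
#' genus has tips in the tree, otherwise at the family level (families taken
#' from `records`). With two or more group members the new tip joins the
#' group's most recent common ancestor as a polytomy; with exactly one
#' member the member's pendant branch is split at its midpoint and the new
#' tip attached there as a cherry. Pendant lengths are chosen so the new
#' tip's root-to-tip depth equals the mean depth of its group's original
#' tips; on an ultrametric input the output is therefore ultrametric.
#' Placements are computed against the original tips only, so the order of
#' grafting cannot change where any species is placed.
#'
#' @param tree a `phylo` object.
#' @param records trait data frame (`species,genus,family,is_fixer`)
#'   covering at least the species to add and, for family-level placement,
#'   the families of existing tips.
#' @return a `phylo` object containing every species in `records`.
#' @export
graft_missing <- function(tree, records) {
  tree <- validate_phylogeny(tree)
  records <- validate_traits(records)
  missing <- records$species[!records$species %in% tree$tip.label]
  if (!length(missing)) return(tree)

  orig_tips <- tree$tip.label
  ## genus of existing tips: trait table where available, else the first
  ## token of the binomial
  orig_genus <- records$genus[match(orig_tips, records$species)]
  orig_genus[is.na(orig_genus)] <- genus_of(orig_tips[is.na(orig_genus)])
  fam_lookup <- records$family[match(orig_tips, records$species)]
  depths0 <- node_depths(tree)

  ## resolve every placement against the original tree first
  placements <- vector("list", length(missing))
  unplaceable <- character(0)
  for (i in seq_along(missing)) {
    sp <- missing[i]
    rec <- records[records$species == sp, ]
    members <- orig_tips[orig_genus == rec$genus]
    level <- "genus"
    if (!length(members)) {
      members <- orig_tips[!is.na(fam_lookup) & fam_lookup == rec$family]
      level <- "family"
    }
    if (!length(members)) {
      unplaceable <- c(unplaceable, sp)
      next
    }
    placements[[i]] <- list(species = sp, members = members, level = level,
                            target = mean(depths0[match(members, orig_tips)]))
  }
  if (length(unplaceable))
    stop("no congeneric or confamilial tips to graft onto for: ",
         paste(unplaceable, collapse = ", "))

  one_tip <- function(label, len) {
    ape::read.tree(text = sprintf("(%s:%.17g);", label, len))
  }
  for (pl in placements) {
    if (is.null(pl)) next
    depths <- node_depths(tree)
    memb_idx <- match(pl$members, tree$tip.label)
    if (length(memb_idx) >= 2L) {
      ## crown polytomy at the group MRCA
      node <- ape::getMRCA(tree, memb_idx)
      len <- graft_pendant(depths, node, pl$target)
      tree <- ape::bind.tree(tree, one_tip(pl$species, len),
                             where = node, position = 0)
    } else {
      ## cherry splitting the lone member's stem at its midpoint
      tip <- memb_idx
      pend <- tree$edge.length[tree$edge[, 2] == tip]
      pos <- pend / 2
      new_node_depth <- depths[tip] - pos
      len <- max(pl$target - new_node_depth, 0)
      tree <- ape::bind.tree(tree, one_tip(pl$species, len),
                             where = tip, position = pos)
    }
  }
  validate_phylogeny(tree)
}

#' Prepare the analysis phylogeny for an observed species pool
#'
#' Mirrors the standard resurvey workflow: species already in the reference
#' tree are kept, species missing from it are grafted at the genus or family
#' level, and the tree is pruned to exactly the observed pool.
#'
#' @param tree reference `phylo` object.
#' @param traits trait table covering the observed species.
#' @param species character vector of observed species names.
#' @return a `phylo` object whose tip set equals `species`.
#' @export
prepare_phylogeny <- function(tree, traits, species) {
  species <- unique(normalize_species(species))
  traits <- validate_traits(traits)
  unknown <- setdiff(species, traits$species)
  if (length(unknown))
    stop("species missing from trait table: ", paste(unknown, collapse = ", "))
  tree <- graft_missing(tree, traits[traits$species %in% species, , drop = FALSE])
  prune_to_taxa(tree, species)
}
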