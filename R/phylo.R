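#' Read a rooted phylogeny from a Newick file or string
#'
#' Thin wrapper over [ape::read.tree()] that validates what the downstream
#' statistics require: unique tip labels and non-negative branch lengths on
#' every edge.
#'
#' @param path path to a Newick file (ignored when `text` is given).
#' @param text optional Newick string.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("no such file: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w))
  )
  if (is.null(tree)) stop("malformed Newick: could not parse input")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Write a phylogeny as Newick
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# Node heights above the root (root = 0) for every node, via edge traversal.
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Tree depth (maximum root-to-tip path length)
#' @param tree an [ape::phylo] tree.
#' @return The depth in branch-length units.
#' @export
tree_depth <- function(tree) max(node_depths(tree)[seq_along(tree$tip.label)])

#' Test whether a tree is ultrametric
#'
#' Uses a relative tolerance on root-to-tip path lengths: the spread of tip
#' depths must be below `tol` times the maximum depth.
#'
#' @param tree an [ape::phylo] tree.
#' @param tol relative tolerance (default 1e-6).
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(d)
}

#' Prune a phylogeny to a taxon set
#'
#' Retains the minimal subtree spanning the requested tips; internal nodes
#' left with a single child are suppressed with their branch lengths summed.
#' Taxa absent from the tree are reported via a warning and an attribute.
#'
#' @param tree an [ape::phylo] tree.
#' @param taxa character vector of tip labels to keep.
#' @return The pruned tree, with attribute `missing_taxa` listing requested
#'   taxa not found in the tree.
#' @export
prune_to_taxa <- function(tree, taxa) {
  taxa <- as.character(taxa)
  keep <- intersect(tree$tip.label, taxa)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(keep) == 0L) stop("no requested taxa are present in the tree")
  if (length(missing)) {
    warning(length(missing), " requested taxa absent from the tree")
  }
  if (length(keep) == length(tree$tip.label)) {
    out <- tree
  } else if (length(keep) == 1L) {
    # root-to-tip path collapses to a single terminal branch
    depth <- node_depths(tree)[match(keep, tree$tip.label)]
    out <- ape::read.tree(text = sprintf("(%s:%.12g);", keep, depth))
  } else {
    out <- ape::keep.tip(tree, keep)
  }
  attr(out, "missing_taxa") <- missing
  out
}

#' Slice an ultrametric tree into the lineages alive at time T
#'
#' Cuts the tree at `T` time units before the present. A branch spanning
#' times `[t_child, t_parent)` before present is alive at the slice iff
#' `t_child <= T < t_parent` (half-open toward the root), so node-height ties
#' resolve deterministically. Each live branch defines one lineage whose
#' members are the tips descended from it; the member sets partition the tip
#' set. `T = 0` returns one lineage per tip.
#'
#' @param tree a rooted ultrametric [ape::phylo] tree.
#' @param T slice time before present; must satisfy `0 <= T <` tree depth.
#' @param tol relative ultrametricity tolerance.
#' @return An object of class `lineage_slice`: list with `T`, `lineage_ids`,
#'   `members` (named list mapping lineage id to tip labels) and `n_lineages`.
#' @export
time_slice <- function(tree, T, tol = 1e-6) {
  if (!is_ultrametric_tree(tree, tol)) {
    stop("time_slice requires an ultrametric tree")
  }
  depth <- tree_depth(tree)
  if (T < 0 || T >= depth) stop("T must satisfy 0 <= T < tree depth")
  ntip <- length(tree$tip.label)
  heights <- node_depths(tree)          # above root
  times <- depth - heights              # before present
  times[seq_len(ntip)][abs(times[seq_len(ntip)]) <= tol * depth] <- 0

  desc <- descendant_tips(tree)
  alive <- which(times[tree$edge[, 2L]] <= T & T < times[tree$edge[, 1L]])
  members <- lapply(alive, function(e) {
    child <- tree$edge[e, 2L]
    tree$tip.label[desc[[child]]]
  })
  ids <- vapply(seq_along(alive), function(i) {
    child <- tree$edge[alive[i], 2L]
    if (child <= ntip) tree$tip.label[child] else sprintf("lineage_%03d", i)
  }, character(1L))
  names(members) <- ids
  all_members <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_members) ||
      !setequal(all_members, tree$tip.label)) {
    stop("internal error: slice member sets do not partition the tips")
  }
  structure(
    list(T = T, lineage_ids = ids, members = members,
         n_lineages = length(ids)),
    class = "lineage_slice"
  )
}

#' @export
print.lineage_slice <- function(x, ...) {
  cat(sprintf("lineage_slice at T = %g: %d lineages\n", x$T, x$n_lineages))
  invisible(x)
}

# Tip indices descended from each node (tips included, mapped to themselves).
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # postorder: children are filled before their parent
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1L]
    child <- po$edge[e, 2L]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  desc
}

#' Collapse species presences to lineage presences
#'
#' Given a slice of the phylogeny, a lineage is present in a site iff any of
#' its descendant species is present there; each lineage's range is the union
#' of its members' ranges.
#'
#' @param pa a [presence_absence] whose taxa include every slice member.
#' @param slice a `lineage_slice` from [time_slice()].
#' @return A [presence_absence] at lineage level (taxon axis = lineage ids),
#'   carrying the same sites and coordinates.
#' @export
lineage_presence <- function(pa, slice) {
  stopifnot(inherits(pa, "presence_absence"), inherits(slice, "lineage_slice"))
  tips <- unlist(slice$members, use.names = FALSE)
  missing <- setdiff(tips, pa$taxon_ids)
  if (length(missing)) {
    stop("slice members missing from presence matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  lm <- vapply(slice$members, function(members) {
    as.integer(rowSums(pa$m[, members, drop = FALSE]) > 0L)
  }, integer(nrow(pa$m)))
  presence_absence(lm, site_ids = pa$site_ids,
                   taxon_ids = slice$lineage_ids, coords = pa$coords)
}

# Logical vector over edges: does the edge lie on the rooted spanning
# subtree of `taxa` (i.e. does any member tip descend from its child node)?
spanning_edges <- function(tree, taxa, desc = descendant_tips(tree)) {
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown taxa: ",
         paste(utils::head(taxa[is.na(idx)], 5L), collapse = ", "))
  }
  in_set <- logical(length(tree$tip.label))
  in_set[idx] <- TRUE
  vapply(seq_len(nrow(tree$edge)), function(e) {
    any(in_set[desc[[tree$edge[e, 2L]]]])
  }, logical(1L))
}

#' Faith's phylogenetic diversity (rooted convention)
#'
#' Sum of the branch lengths of the minimal subtree connecting the taxa and
#' the root. The root-inclusive convention is used throughout the package so
#' that PD, standardized PD and UniFrac share one spanning-subtree
#' definition.
#'
#' @param tree an [ape::phylo] tree.
#' @param taxa nonempty character vector of tip labels.
#' @return PD in branch-length units (Myr for a dated tree).
#' @export
faiths_pd <- function(tree, taxa) {
  if (length(taxa) == 0L) stop("taxon set is empty")
  sum(tree$edge.length[spanning_edges(tree, taxa)])
}

#' Richness-standardized phylogenetic diversity
#'
#' Standardizes observed PD against a null of `n_null` uniform draws (without
#' replacement) of the same number of tips: `z = (PD_obs - mean) / sd` of the
#' null PDs. Negative values indicate phylogenetic clustering. When the null
#' is degenerate (zero variance, e.g. all tips drawn), `z` is defined as 0
#' and flagged.
#'
#' @param tree an [ape::phylo] tree.
#' @param taxa nonempty subset of tip labels.
#' @param n_null number of null draws (default 10000).
#' @param seed RNG seed for the null draws.
#' @return A list with `z`, `pd_obs`, `null_mean`, `null_sd`, `n_taxa`,
#'   `degenerate_null`.
#' @export
standardized_pd <- function(tree, taxa, n_null = 10000L, seed = 1L) {
  ntip <- length(tree$tip.label)
  s <- length(taxa)
  if (s < 1L || s > ntip) stop("taxon set size out of range")
  if (n_null < 2L) stop("n_null must be at least 2")
  desc <- descendant_tips(tree)
  pd_obs <- sum(tree$edge.length[spanning_edges(tree, taxa, desc)])
  # edge x tip incidence: edge covered by a draw iff any sampled tip below it
  nedge <- nrow(tree$edge)
  inc <- matrix(FALSE, nedge, ntip)
  for (e in seq_len(nedge)) inc[e, desc[[tree$edge[e, 2L]]]] <- TRUE
  draws <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      v <- logical(ntip)
      v[sample.int(ntip, s)] <- TRUE
      v
    }, logical(ntip))
  })
  covered <- (inc %*% draws) > 0
  pd_null <- as.numeric(crossprod(tree$edge.length, covered))
  mu <- mean(pd_null)
  sdev <- stats::sd(pd_null)
  degenerate <- sdev < 1e-12
  list(
    z = if (degenerate) 0 else (pd_obs - mu) / sdev,
    pd_obs = pd_obs, null_mean = mu, null_sd = sdev,
    n_taxa = s, degenerate_null = degenerate
  )
}

#' Unweighted UniFrac distance between two taxon sets
#'
#' Fraction of the branch length unique to one set's rooted spanning subtree:
#' the summed length of branches on exactly one of the two spanning subtrees,
#' divided by the summed length of branches on either. Uses the same
#' root-inclusive spanning convention as [faiths_pd()]. Equals 1 iff the two
#' spanning branch sets are disjoint (phylogenetically non-overlapping
#' groups) and 0 for identical sets.
#'
#' @param tree an [ape::phylo] tree.
#' @param set_a,set_b nonempty character vectors of tip labels.
#' @return A number in \[0, 1\].
#' @export
unifrac <- function(tree, set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L) stop("empty taxon set")
  desc <- descendant_tips(tree)
  on_a <- spanning_edges(tree, set_a, desc)
  on_b <- spanning_edges(tree, set_b, desc)
  len <- tree$edge.length
  sum(len[xor(on_a, on_b)]) / sum(len[on_a | on_b])
}

#' Weighted Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(w_a, w_b)) / (sum(w_a) + sum(w_b))` for two nonnegative
#' weight vectors over the same taxa. Equals 0 for identical vectors and 1
#' when the supports are disjoint.
#'
#' @param w_a,w_b nonnegative numeric vectors of equal length, each with at
#'   least one positive entry.
#' @return A number in \[0, 1\].
#' @export
bray_curtis_weighted <- function(w_a, w_b) {
  if (length(w_a) != length(w_b)) stop("weight vectors differ in length")
  if (any(w_a < 0) || any(w_b < 0)) stop("weights must be nonnegative")
  if (sum(w_a) == 0 || sum(w_b) == 0) stop("all-zero weight vector")
  1 - 2 * sum(pmin(w_a, w_b)) / (sum(w_a) + sum(w_b))
}
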