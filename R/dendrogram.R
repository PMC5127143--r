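# Communities (connected components) at a threshold, recursive
# sub-community analysis, and the sigma-height merge dendrogram of the
# threshold family, with Newick export.

#' Communities and isolates of a threshold network
#'
#' Connected components of the network: components with at least two members
#' are communities, singleton components are isolated nodes.
#'
#' @param net A \code{"threshold_network"}.
#' @return Object of class \code{"community_partition"}: list with
#'   \code{sigma}, \code{communities} (list of label vectors, each of size
#'   >= 2), \code{isolates} (label vector).
#' @export
components_at <- function(net) {
  comp <- igraph::components(as_igraph(net))
  sets <- split(net$labels, comp$membership)
  sets <- unname(sets[order(vapply(sets, function(s) min(match(s, net$labels)),
                                   integer(1)))])
  sizes <- lengths(sets)
  structure(list(sigma = net$sigma,
                 communities = sets[sizes >= 2],
                 isolates = unlist(sets[sizes == 1], use.names = FALSE) %||% character(0)),
            class = "community_partition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition of a similarity matrix at one threshold
#'
#' Convenience wrapper: [build_network()] then [components_at()].
#'
#' @inheritParams build_network
#' @export
partition_at <- function(S, sigma) components_at(build_network(S, sigma))

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition at sigma = %g: %d communities (sizes %s), %d isolate(s)\n",
              x$sigma, length(x$communities),
              paste(lengths(x$communities), collapse = ", "),
              length(x$isolates)))
  invisible(x)
}

# All blocks (communities and isolates) of a partition as a list of sets.
partition_blocks <- function(p) {
  c(p$communities, as.list(p$isolates))
}

new_dendro_node <- function(members, split_sigma = NA_real_, children = list()) {
  structure(list(members = members, split_sigma = split_sigma,
                 children = children),
            class = "dendro_node")
}

components_of_submatrix <- function(values, valid, sigma) {
  adj <- (values >= sigma) & valid
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# Recursive construction: find the first grid sigma (strictly after the
# parent's split) at which the induced subgraph on `members` disconnects,
# and branch there. Nestedness of the family guarantees children can only
# split at larger sigma.
grow_node <- function(values, valid, members, points, from_idx) {
  if (length(members) == 1) return(new_dendro_node(members))
  v <- values[members, members, drop = FALSE]
  ok <- valid[members, members, drop = FALSE]
  for (k in seq(from_idx, length(points))) {
    memb <- components_of_submatrix(v, ok, points[k])
    if (max(memb) > 1) {
      parts <- split(members, memb)
      parts <- unname(parts[order(vapply(parts, function(s) min(match(s, members)),
                                         integer(1)))])
      children <- lapply(parts, function(p)
        grow_node(values, valid, p, points, k + 1))
      return(new_dendro_node(members, points[k], children))
    }
  }
  # still one component at the top of the grid (e.g. identical sequences):
  # the node never splits within the grid; children are direct leaves
  if (length(members) > 1)
    return(new_dendro_node(members, NA_real_,
                           lapply(members, new_dendro_node)))
  new_dendro_node(members)
}

#' Build the sigma-height dendrogram of the threshold family
#'
#' Sweeps sigma upward over the grid; whenever a connected component splits
#' into two or more parts, an internal node is created at that sigma with the
#' parts as children (simultaneous splits give a single multifurcation). The
#' result is the full merge tree of the threshold network family: cutting it
#' at any grid sigma reproduces the connected components at that threshold.
#' A component still connected at the top of the grid (e.g. identical
#' sequences) becomes an unsplit node (\code{split_sigma = NA}) whose
#' children are its member leaves.
#'
#' @param S A [similarity_matrix()].
#' @param grid A [sigma_grid()]; should cover 0..100.
#' @return Root \code{"dendro_node"}: list with \code{members},
#'   \code{split_sigma} and \code{children}.
#' @export
build_dendrogram <- function(S, grid = sigma_grid()) {
  grid <- as_sigma_grid(grid)
  grow_node(S$values, S$valid, S$labels, grid$points, 1L)
}

node_height <- function(node) {
  if (!length(node$children)) return(100)
  if (is.na(node$split_sigma)) 100 else node$split_sigma
}

#' Cut a dendrogram at a threshold
#'
#' Returns the partition the dendrogram implies at height sigma: a node whose
#' split sigma is at or below the cut contributes its children's blocks,
#' otherwise its full member set stays together. For any grid sigma this
#' equals the connected components of [build_network()] at that sigma.
#'
#' @param root A \code{"dendro_node"}.
#' @param sigma Cut height in percent.
#' @return List of label vectors (the blocks).
#' @export
cut_dendrogram <- function(root, sigma) {
  if (!length(root$children) ||
      is.na(root$split_sigma) || sigma < root$split_sigma)
    return(list(root$members))
  unlist(lapply(root$children, cut_dendrogram, sigma = sigma),
         recursive = FALSE)
}

#' @export
print.dendro_node <- function(x, ...) {
  n_leaves <- length(x$members)
  cat(sprintf("dendro_node: %d leaves, split at sigma = %s\n", n_leaves,
              if (length(x$children)) format(x$split_sigma) else "(leaf)"))
  invisible(x)
}

quote_newick_label <- function(label) {
  if (grepl("[\\s()\\[\\]:;,']", label, perl = TRUE))
    paste0("'", gsub("'", "''", label), "'")
  else label
}

newick_string <- function(node, parent_height, height_mode) {
  h <- node_height(node)
  len <- switch(height_mode,
                sigma = max(h - parent_height, 0),
                none = NULL)
  suffix <- if (is.null(len)) "" else paste0(":", format(len, digits = 10))
  if (!length(node$children))
    return(paste0(quote_newick_label(node$members), suffix))
  inner <- vapply(node$children, newick_string, character(1),
                  parent_height = h, height_mode = height_mode)
  paste0("(", paste(inner, collapse = ","), ")", suffix)
}

#' Serialise a dendrogram to Newick
#'
#' Internal nodes sit at height equal to their split sigma and leaves at
#' height 100, so a branch length is the child's height minus the parent's
#' (the root carries length 0). The tree is therefore ultrametric: every
#' root-to-leaf path sums to 100 minus the root's split sigma. Labels
#' containing whitespace or Newick metacharacters are single-quoted.
#'
#' @param root A \code{"dendro_node"}.
#' @param height_mode \code{"sigma"} (branch lengths from split sigmas,
#'   default) or \code{"none"} (topology only).
#' @return A Newick string terminated by \code{";"}.
#' @export
to_newick <- function(root, height_mode = c("sigma", "none")) {
  height_mode <- match.arg(height_mode)
  if (!length(root$children)) {
    suffix <- if (height_mode == "sigma") ":0" else ""
    return(paste0(quote_newick_label(root$members), suffix, ";"))
  }
  base <- if (is.na(root$split_sigma)) 100 else root$split_sigma
  paste0(newick_string(root, parent_height = base, height_mode = height_mode),
         ";")
}

#' Delta-distance analysis of a sub-community
#'
#' Restricts the similarity matrix to \code{members}, recomputes the
#' delta-distance curve and its critical thresholds on the induced submatrix,
#' and reports the community partition at each critical threshold. This is
#' the recursion step of the pipeline: a community found at one level is
#' treated as an independent network and re-scanned.
#'
#' @param S A [similarity_matrix()].
#' @param members Labels of the sub-community (at least 2).
#' @param grid A [sigma_grid()].
#' @param min_prominence_frac Passed to [detect_critical_thresholds()].
#' @return Object of class \code{"sub_analysis"}: list with \code{members},
#'   \code{curve}, \code{thresholds} and \code{partitions} (one
#'   \code{"community_partition"} per critical threshold).
#' @export
analyze_subcommunity <- function(S, members, grid = sigma_grid(),
                                 min_prominence_frac = 0.1) {
  if (length(members) < 2)
    stop_sigmanet("sub-community needs at least 2 members",
                  "sigmanet_error_members")
  Ssub <- sub_similarity(S, members)
  curve <- delta_curve(Ssub, grid)
  thresholds <- detect_critical_thresholds(curve, min_prominence_frac)
  partitions <- lapply(thresholds$sigma_cst, function(s) partition_at(Ssub, s))
  structure(list(members = members, curve = curve, thresholds = thresholds,
                 partitions = partitions),
            class = "sub_analysis")
}

#' @export
print.sub_analysis <- function(x, ...) {
  cat(sprintf("sub_analysis: %d members, %d critical threshold(s)\n",
              length(x$members), nrow(x$thresholds)))
  if (nrow(x$thresholds))
    cat(sprintf("  sigma_cst: %s\n",
                paste(x$thresholds$sigma_cst, collapse = ", ")))
  invisible(x)
}
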