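# One-parameter family of threshold networks M(sigma) built from a
# similarity matrix: an edge joins i and j iff the pair is valid and
# s_ij >= sigma.

#' Similarity-threshold grid
#'
#' Regular grid of thresholds sigma (percent) over which the network family
#' is generated. The grid step is the Delta-sigma of the delta-distance scan.
#'
#' @param start,stop Grid limits in percent, \code{0 <= start < stop <= 101}.
#' @param step Grid step (percentage points), > 0. Default 1, matching the
#'   integer-percent resolution at which critical thresholds are reported.
#' @return An object of class \code{"sigma_grid"} with fields \code{points}
#'   and \code{step}.
#' @export
sigma_grid <- function(start = 0, stop = 100, step = 1) {
  if (!(start >= 0 && start < stop && stop <= 101 && step > 0))
    stop_sigmanet("need 0 <= start < stop <= 101 and step > 0",
                  "sigmanet_error_grid")
  structure(list(points = seq(start, stop, by = step), step = step),
            class = "sigma_grid")
}

as_sigma_grid <- function(grid) {
  if (inherits(grid, "sigma_grid")) return(grid)
  if (is.numeric(grid) && length(grid) == 3)
    return(sigma_grid(grid[1], grid[2], grid[3]))
  stop_sigmanet("grid must be a sigma_grid or numeric c(start, stop, step)",
                "sigmanet_error_grid")
}

#' Build the threshold network at one sigma
#'
#' Edge rule: \code{adjacency[i, j] = 1} iff the pair is valid, \code{i != j}
#' and \code{s_ij >= sigma}. The boundary \code{s_ij == sigma} keeps the edge.
#'
#' @param S A [similarity_matrix()].
#' @param sigma Threshold in percent, >= 0.
#' @return An object of class \code{"threshold_network"}: list with
#'   \code{sigma}, \code{labels} and a binary symmetric \code{adjacency}
#'   matrix with zero diagonal.
#' @export
build_network <- function(S, sigma) {
  if (!inherits(S, "similarity_matrix"))
    stop_sigmanet("S must be a similarity_matrix", "sigmanet_error_input")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop_sigmanet("sigma must be a single value >= 0", "sigmanet_error_sigma")
  adj <- (S$values >= sigma) & S$valid
  diag(adj) <- FALSE
  storage.mode(adj) <- "integer"
  structure(list(sigma = sigma, labels = S$labels, adjacency = adj),
            class = "threshold_network")
}

#' Build the network family over a sigma grid
#'
#' @param S A [similarity_matrix()].
#' @param grid A [sigma_grid()] (or \code{c(start, stop, step)}).
#' @return List of [build_network()] results in ascending sigma order.
#' @export
network_family <- function(S, grid = sigma_grid()) {
  grid <- as_sigma_grid(grid)
  lapply(grid$points, function(s) build_network(S, s))
}

#' @export
print.threshold_network <- function(x, ...) {
  n_edges <- sum(x$adjacency) / 2
  cat(sprintf("threshold_network: sigma = %g, %d nodes, %d edges\n",
              x$sigma, length(x$labels), n_edges))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Export a network's edge list as two-column TSV
#'
#' One row per undirected edge (each edge once), for external visualisation.
#'
#' @param net A \code{"threshold_network"}.
#' @param path Output path.
#' @export
write_edgelist_tsv <- function(net, path) {
  idx <- which(net$adjacency == 1 & upper.tri(net$adjacency), arr.ind = TRUE)
  df <- data.frame(source = net$labels[idx[, 1]],
                   target = net$labels[idx[, 2]])
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
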