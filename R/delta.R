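# Inter-network delta-distance: geodesic neighborhood matrices, the
# delta(sigma, sigma + step) curve over a threshold grid, and peak
# detection yielding critical thresholds sigma_cst.

#' Geodesic neighborhood matrix of a network
#'
#' All-pairs unweighted shortest-path distances, with disconnected pairs
#' assigned the finite cap \code{n} (the node count) so that component
#' break-ups register as large, bounded distance changes.
#'
#' @param net A \code{"threshold_network"}.
#' @param cap Value for disconnected pairs; default \code{n}.
#' @return Symmetric integer-valued matrix with zero diagonal; entries in
#'   \code{\{0, 1, ..., n - 1\} U \{cap\}}.
#' @export
neighborhood_matrix <- function(net, cap = length(net$labels)) {
  d <- igraph::distances(as_igraph(net))
  d[is.infinite(d)] <- cap
  dimnames(d) <- list(net$labels, net$labels)
  d
}

#' delta-distance between two networks on the same node set
#'
#' Mean absolute entrywise difference of the two geodesic neighborhood
#' matrices over ordered off-diagonal pairs:
#' \deqn{\delta = \frac{1}{n(n-1)} \sum_{i \ne j} |D^A_{ij} - D^B_{ij}|}
#' With the finite cap for disconnected pairs this is a metric on networks
#' over a fixed node set, and it is zero iff the adjacency matrices coincide.
#'
#' @param netA,netB \code{"threshold_network"} objects with identical labels.
#' @param cap Cap for disconnected pairs (default \code{n}).
#' @return Non-negative scalar.
#' @export
delta_distance <- function(netA, netB, cap = length(netA$labels)) {
  if (!identical(netA$labels, netB$labels))
    stop_sigmanet("networks are defined on different node sets",
                  "sigmanet_error_mismatched_nodes")
  n <- length(netA$labels)
  if (n < 2) return(0)
  dA <- neighborhood_matrix(netA, cap = cap)
  dB <- neighborhood_matrix(netB, cap = cap)
  sum(abs(dA - dB)) / (n * (n - 1))
}

#' delta-distance curve over a sigma grid
#'
#' For each pair of adjacent grid thresholds, the delta-distance between the
#' two corresponding networks. Each value is indexed by the \emph{upper}
#' threshold of its pair: the curve point at sigma is
#' \code{delta(sigma - step, sigma)}, so a peak at sigma marks the first
#' threshold at which the changed (typically split) structure is in force.
#' The curve has one point fewer than the grid.
#'
#' @param S A [similarity_matrix()].
#' @param grid A [sigma_grid()].
#' @param cap Cap for disconnected pairs (default \code{n}).
#' @return Object of class \code{"delta_curve"}: data.frame with columns
#'   \code{sigma} and \code{delta}, attributes \code{step} and \code{n}.
#' @export
delta_curve <- function(S, grid = sigma_grid(), cap = length(S$labels)) {
  grid <- as_sigma_grid(grid)
  nets <- network_family(S, grid)
  n <- length(S$labels)
  dist_mats <- lapply(nets, neighborhood_matrix, cap = cap)
  m <- length(nets)
  deltas <- vapply(seq_len(m - 1), function(k) {
    if (n < 2) return(0)
    sum(abs(dist_mats[[k]] - dist_mats[[k + 1]])) / (n * (n - 1))
  }, numeric(1))
  out <- data.frame(sigma = grid$points[-1], delta = deltas)
  structure(out, class = c("delta_curve", "data.frame"),
            step = grid$step, n = n)
}

#' Detect critical thresholds from a delta curve
#'
#' Local maxima of the delta curve whose height is at least
#' \code{min_prominence_frac} times the curve maximum; the global maximum is
#' always reported. Each peak is then carried to the end of its significant
#' non-increasing run: consecutive structural changes (e.g. two communities
#' separating in adjacent grid steps) merge into one broad peak, and the
#' reported sigma_cst is the first threshold at which the post-change
#' structure is fully in force. The peak height is the maximum delta of the
#' peak.
#'
#' @param curve A \code{"delta_curve"}.
#' @param min_prominence_frac Fraction of the global maximum a local peak
#'   must reach to be reported (default 0.1).
#' @return data.frame with columns \code{sigma_cst}, \code{peak_height} and
#'   \code{rank} (1 = highest peak), sorted by sigma; zero rows when the
#'   curve is identically zero.
#' @export
detect_critical_thresholds <- function(curve, min_prominence_frac = 0.1) {
  if (!nrow(curve) || all(curve$delta == 0))
    return(data.frame(sigma_cst = numeric(0), peak_height = numeric(0),
                      rank = integer(0)))
  d <- curve$delta
  # runs of equal values; a run is a peak iff higher than both neighbours
  r <- rle(d)
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  peak_run <- r$values > 0 & r$values > left & r$values > right
  run_first <- cumsum(c(1, r$lengths[-k]))
  idx <- run_first[peak_run]
  idx <- union(idx, run_first[which.max(r$values)])
  idx <- sort(idx[d[idx] >= min_prominence_frac * max(d)])
  # carry each peak through its significant non-increasing tail, so that
  # changes landing in adjacent grid steps report the settled threshold
  thr <- min_prominence_frac * max(d)
  m <- length(d)
  ext <- vapply(as.integer(idx), function(i) {
    j <- i
    while (j < m && d[j + 1] >= thr && d[j + 1] <= d[j]) j <- j + 1L
    j
  }, integer(1))
  out <- data.frame(sigma_cst = curve$sigma[ext], peak_height = d[idx])
  out$rank <- rank(-out$peak_height, ties.method = "first")
  out[order(out$sigma_cst), , drop = FALSE]
}

#' Write a delta curve as two-column TSV
#'
#' @param curve A \code{"delta_curve"}.
#' @param path Output path.
#' @export
write_delta_tsv <- function(curve, path) {
  utils::write.table(as.data.frame(curve)[, c("sigma", "delta")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a delta curve
#'
#' Simple base-graphics line plot of delta against sigma, with detected
#' critical thresholds marked.
#'
#' @param x A \code{"delta_curve"}.
#' @param min_prominence_frac Passed to [detect_critical_thresholds()].
#' @param ... Further arguments to [plot()].
#' @export
plot.delta_curve <- function(x, min_prominence_frac = 0.1, ...) {
  plot(x$sigma, x$delta, type = "l", xlab = expression(sigma ~ "(%)"),
       ylab = expression(delta), ...)
  cst <- detect_critical_thresholds(x, min_prominence_frac)
  if (nrow(cst)) {
    graphics::abline(v = cst$sigma_cst, lty = 3, col = "grey40")
    graphics::points(cst$sigma_cst, cst$peak_height, pch = 19)
  }
  invisible(x)
}
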