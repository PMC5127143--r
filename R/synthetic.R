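# Synthetic inputs with planted group structure: direct planted-block
# similarity matrices with additive noise, and simulated protein families
# with known group membership.

#' Planted-block similarity design
#'
#' Describes a block-structured similarity matrix: high similarity
#' \code{s_within} inside each group, lower \code{s_between} across groups,
#' plus symmetric Gaussian noise. This is the idealised structure a family of
#' homologous sequences with clear sub-families produces.
#'
#' @param group_sizes Integer vector of group sizes (each >= 1).
#' @param s_within Within-group similarity level (percent).
#' @param s_between Between-group similarity: a single percent value, or a
#'   K x K symmetric matrix of per-pair-of-groups levels (diagonal ignored).
#'   Every between level must be below \code{s_within}.
#' @param noise_sd Standard deviation of the additive noise (percentage
#'   points), >= 0.
#' @param seed Integer seed; the generated matrix is a pure function of the
#'   design.
#' @return Object of class \code{"planted_design"}.
#' @export
planted_design <- function(group_sizes, s_within = 90, s_between = 20,
                           noise_sd = 0, seed = 1) {
  stopifnot(length(group_sizes) >= 1, all(group_sizes >= 1),
            noise_sd >= 0, s_within >= 0, s_within <= 100)
  K <- length(group_sizes)
  if (is.matrix(s_between)) {
    stopifnot(nrow(s_between) == K, ncol(s_between) == K,
              isTRUE(all.equal(s_between, t(s_between))))
  } else {
    stopifnot(length(s_between) == 1)
    s_between <- matrix(s_between, K, K)
  }
  off <- s_between[upper.tri(s_between)]
  if (K > 1 && any(off >= s_within))
    stop_sigmanet("s_between must be below s_within", "sigmanet_error_design")
  structure(list(group_sizes = as.integer(group_sizes), s_within = s_within,
                 s_between = s_between, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "planted_design")
}

#' Generate a planted-block similarity matrix
#'
#' Off-diagonal entries are the design's block level plus one symmetric
#' Gaussian noise draw per unordered pair; the noised matrix is then
#' truncated to \code{[0, 100]} (after symmetrisation, so the matrix
#' invariants always hold) and the diagonal set to 100. All pairs are valid.
#' A warning of class \code{"sigmanet_warning_band_overlap"} is raised when
#' the +/- 3 sd noise bands around the within and the highest between level
#' overlap, since planted-partition recovery is then not guaranteed.
#'
#' @param design A [planted_design()].
#' @return A [similarity_matrix()] with labels \code{"G<k>_<i>"}. The planted
#'   membership is attached as attribute \code{"groups"}.
#' @export
planted_block_similarity <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  K <- length(design$group_sizes)
  n <- sum(design$group_sizes)
  grp <- rep(seq_len(K), design$group_sizes)
  labels <- unlist(lapply(seq_len(K), function(k)
    paste0("G", k, "_", seq_len(design$group_sizes[k]))))
  base <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      base[i, j] <- if (grp[i] == grp[j]) design$s_within
                    else design$s_between[grp[i], grp[j]]
  if (K > 1) {
    gap_top <- max(design$s_between[upper.tri(design$s_between)])
    if (gap_top + 3 * design$noise_sd >= design$s_within - 3 * design$noise_sd)
      warning(warningCondition(
        "noise bands around s_within and s_between overlap; planted recovery not guaranteed",
        class = "sigmanet_warning_band_overlap"))
  }
  vals <- with_seed(design$seed, {
    eps <- matrix(0, n, n)
    ut <- upper.tri(eps)
    eps[ut] <- stats::rnorm(sum(ut), 0, design$noise_sd)
    eps <- eps + t(eps)
    base + eps
  })
  vals <- pmin(pmax(vals, 0), 100)
  diag(vals) <- 100
  dimnames(vals) <- list(labels, labels)
  S <- similarity_matrix(vals)
  attr(S, "groups") <- stats::setNames(grp, labels)
  S
}

#' Simulated protein-family design
#'
#' A star-of-stars model: one random root sequence, one ancestor per group at
#' expected divergence \code{d_between} substitutions per site from the root,
#' and leaves at expected divergence \code{d_within} from their group
#' ancestor. Substitution counts are Poisson; each substitution replaces a
#' uniformly chosen site by one of the 19 other residues.
#'
#' @param n_groups Number of groups (>= 1).
#' @param seqs_per_group Sequences per group (>= 1).
#' @param seq_length Sequence length in residues (>= 50).
#' @param d_between,d_within Expected substitutions per site on the
#'   root-to-ancestor and ancestor-to-leaf branches;
#'   \code{0 <= d_within < d_between <= 3}.
#' @param seed Integer root seed.
#' @return Object of class \code{"family_design"}.
#' @export
family_design <- function(n_groups = 3, seqs_per_group = 4, seq_length = 250,
                          d_between = 1.5, d_within = 0.02, seed = 1) {
  stopifnot(n_groups >= 1, seqs_per_group >= 1, seq_length >= 50,
            d_within >= 0, d_within < d_between, d_between <= 3)
  structure(list(n_groups = as.integer(n_groups),
                 seqs_per_group = as.integer(seqs_per_group),
                 seq_length = as.integer(seq_length),
                 d_between = d_between, d_within = d_within,
                 seed = as.integer(seed)),
            class = "family_design")
}

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

mutate_sequence <- function(res, n_hits) {
  if (n_hits == 0) return(res)
  pos <- sample.int(length(res), n_hits, replace = TRUE)
  for (p in pos) res[p] <- sample(setdiff(AA20, res[p]), 1)
  res
}

#' Simulate a protein family with planted groups
#'
#' @param design A [family_design()].
#' @return An \code{AAStringSet} named \code{"G<k>_<i> group <k>"}; the
#'   planted membership is attached as attribute \code{"groups"}.
#' @export
simulate_protein_family <- function(design) {
  stopifnot(inherits(design, "family_design"))
  L <- design$seq_length
  seqs <- with_seed(design$seed, {
    root <- sample(AA20, L, replace = TRUE)
    out <- character(0)
    for (k in seq_len(design$n_groups)) {
      anc <- mutate_sequence(root, stats::rpois(1, design$d_between * L))
      for (i in seq_len(design$seqs_per_group)) {
        leaf <- mutate_sequence(anc, stats::rpois(1, design$d_within * L))
        out[[sprintf("G%d_%d group %d", k, i, k)]] <- paste(leaf, collapse = "")
      }
    }
    out
  })
  set <- as_sequence_set(seqs)
  grp <- rep(seq_len(design$n_groups), each = design$seqs_per_group)
  attr(set, "groups") <- stats::setNames(grp, sequence_ids(set))
  set
}

#' Serialise a generator design to JSON
#'
#' @param design A [planted_design()] or [family_design()].
#' @param path Output path.
#' @export
write_design_json <- function(design, path) {
  x <- unclass(design)
  x$design_class <- class(design)[1]
  if (is.matrix(x$s_between)) x$s_between <- as.data.frame(x$s_between)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
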