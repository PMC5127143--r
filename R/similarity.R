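# Pairwise percent-similarity scoring of protein sequences and the
# symmetric similarity matrix S consumed by the network construction.

AA_ALPHABET_20X <- "ACDEFGHIKLMNPQRSTVWYX"

stop_sigmanet <- function(message, class, call. = FALSE) {
  stop(errorCondition(message, class = c(class, "sigmanet_error", "error")))
}

#' Scoring parameters for pairwise local alignment
#'
#' Bundles the substitution matrix, affine gap penalties and Karlin-Altschul
#' statistical parameters used by [pairwise_scores()]. Defaults correspond to
#' the classic protein local-alignment setup: BLOSUM62 with gap open 11 and
#' gap extend 1, and the matching gapped Karlin-Altschul parameters
#' (lambda = 0.267, K = 0.041, H = 0.14).
#'
#' @param method How a local alignment is turned into a percent similarity in
#'   \code{[0, 100]}: \code{"bitscore"} (the default; alignment bit score
#'   normalised by the smaller self-alignment bit score, a whole-sequence
#'   relatedness measure that stays near zero for unrelated pairs),
#'   \code{"positives"} (fraction of aligned columns with a positive
#'   substitution score, the "similarity" column of common local-alignment
#'   reports; short chance alignments of unrelated sequences score high under
#'   it), or \code{"identity"} (fraction of identical aligned columns).
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   \pkg{Biostrings} (e.g. \code{"BLOSUM62"}).
#' @param gap_open,gap_extend Affine gap penalties (positive costs). A gap of
#'   length k costs \code{gap_open + k * gap_extend}.
#' @param lambda,K,H Karlin-Altschul parameters for the chosen matrix and gap
#'   penalties, used by the internal E-value approximation.
#' @return An object of class \code{"scoring_params"}.
#' @export
scoring_params <- function(method = c("bitscore", "positives", "identity"),
                           substitution_matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041, H = 0.14) {
  method <- match.arg(method)
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0, H > 0)
  structure(list(method = method,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, H = H),
            class = "scoring_params")
}

get_subst_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Coerce sequences to a validated amino-acid sequence set
#'
#' Accepts a named character vector or a [Biostrings::AAStringSet]. Names are
#' parsed as \code{"id taxon name"}: the first whitespace-delimited token is
#' the unique identifier, the remainder (if any) a display label. Residues
#' must come from the 20-letter amino-acid alphabet plus \code{X}.
#'
#' @param x Named character vector of residues, or an \code{AAStringSet}.
#' @return An \code{AAStringSet} with attributes \code{ids} and \code{labels}.
#' @export
as_sequence_set <- function(x) {
  if (inherits(x, "AAStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x)) {
    seqs <- x
  } else {
    stop_sigmanet("sequences must be a named character vector or AAStringSet",
                  "sigmanet_error_input")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_sigmanet("every sequence needs a name ('id' or 'id taxon name')",
                  "sigmanet_error_labels")
  if (any(!nzchar(seqs)))
    stop_sigmanet("empty sequence(s) present", "sigmanet_error_empty_sequence")
  bad <- grepl(sprintf("[^%s]", AA_ALPHABET_20X), toupper(seqs))
  if (any(bad))
    stop_sigmanet(sprintf("non-amino-acid characters in sequence(s): %s",
                          paste(names(seqs)[bad], collapse = ", ")),
                  "sigmanet_error_bad_alphabet")
  ids <- sub("\\s.*$", "", names(seqs))
  labels <- trimws(sub("^\\S+\\s*", "", names(seqs)))
  if (anyDuplicated(ids))
    stop_sigmanet("sequence ids must be unique", "sigmanet_error_labels")
  out <- Biostrings::AAStringSet(toupper(seqs))
  names(out) <- names(seqs)
  attr(out, "ids") <- ids
  attr(out, "labels") <- labels
  out
}

sequence_ids <- function(seqs) {
  ids <- attr(seqs, "ids")
  if (is.null(ids)) ids <- sub("\\s.*$", "", names(seqs))
  ids
}

# Karlin-Altschul E-value for a raw local alignment score, with the standard
# edge-effect length adjustment. An approximation to what a full search
# engine reports, adequate for the coarse validity cutoff (E <= 1) used here.
karlin_altschul_evalue <- function(raw_score, m, n, params) {
  l <- log(params$K * m * n) / params$H
  m_eff <- max(m - l, 1)
  n_eff <- max(n - l, 1)
  params$K * m_eff * n_eff * exp(-params$lambda * raw_score)
}

align_pair <- function(a, b, subst, params) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  len <- length(ap)
  aligned <- ap != "-" & as_ != "-"
  n_ident <- sum(aligned & ap == as_)
  n_pos <- sum(subst[cbind(
    match(ap[aligned], rownames(subst)),
    match(as_[aligned], colnames(subst)))] > 0)
  list(raw = Biostrings::score(pa), len = len,
       n_ident = n_ident, n_pos = n_pos)
}

self_raw_score <- function(s, subst) {
  r <- strsplit(s, "")[[1]]
  sum(subst[cbind(match(r, rownames(subst)), match(r, colnames(subst)))])
}

bit_score <- function(raw, params) {
  (params$lambda * raw - log(params$K)) / log(2)
}

percent_from_alignment <- function(al, self_a, self_b, params) {
  p <- switch(params$method,
    positives = 100 * al$n_pos / al$len,
    identity  = 100 * al$n_ident / al$len,
    bitscore  = 100 * bit_score(al$raw, params) /
                bit_score(min(self_a, self_b), params))
  min(max(p, 0), 100)
}

#' Directed pairwise similarity scores with E-values
#'
#' Performs Smith-Waterman local alignment for every pair of sequences and
#' reports a percent similarity score plus an E-value per ordered pair.
#' Self comparisons score 100 with E-value 0. With an exact local aligner and
#' a symmetric substitution matrix the two directions of a pair are identical,
#' so each unordered pair is aligned once and mirrored; the directed container
#' is kept so that externally produced (possibly asymmetric) scores can flow
#' through the same [symmetrize()] step.
#'
#' @param seqs Sequences accepted by [as_sequence_set()]; at least 2.
#' @param scoring A [scoring_params()] object.
#' @return An object of class \code{"raw_scores"}: list with \code{score} and
#'   \code{evalue} (n x n matrices over ordered pairs) and \code{labels}.
#' @export
pairwise_scores <- function(seqs, scoring = scoring_params()) {
  seqs <- as_sequence_set(seqs)
  n <- length(seqs)
  if (n < 2)
    stop_sigmanet("need at least 2 sequences", "sigmanet_error_input")
  ids <- sequence_ids(seqs)
  chars <- as.character(seqs)
  subst <- get_subst_matrix(scoring$substitution_matrix)
  selfs <- vapply(chars, self_raw_score, numeric(1), subst = subst)
  score <- matrix(100, n, n, dimnames = list(ids, ids))
  evalue <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # canonical argument order: with several co-optimal local alignments
      # the reported alignment (and hence percent positives/identity) can
      # depend on which sequence is the pattern, so order by content to make
      # S invariant under permutation of the input
      swap <- chars[[i]] > chars[[j]]
      al <- if (swap) align_pair(chars[[j]], chars[[i]], subst, scoring)
            else align_pair(chars[[i]], chars[[j]], subst, scoring)
      p <- percent_from_alignment(al, selfs[[i]], selfs[[j]], scoring)
      e <- karlin_altschul_evalue(al$raw, nchar(chars[[i]]),
                                  nchar(chars[[j]]), scoring)
      score[i, j] <- score[j, i] <- p
      evalue[i, j] <- evalue[j, i] <- e
    }
  }
  raw_scores(score, evalue)
}

#' Construct a directed raw-score container
#'
#' @param score n x n matrix of directed percent similarities in \code{[0, 100]}.
#' @param evalue n x n matrix of non-negative E-values.
#' @return An object of class \code{"raw_scores"}.
#' @export
raw_scores <- function(score, evalue) {
  if (!is.matrix(score) || nrow(score) != ncol(score))
    stop_sigmanet("raw score matrix must be square", "sigmanet_error_nonsquare")
  if (!identical(dim(score), dim(evalue)))
    stop_sigmanet("score and evalue dimensions differ", "sigmanet_error_nonsquare")
  if (any(score < 0 | score > 100))
    stop_sigmanet("scores must lie in [0, 100]", "sigmanet_error_input")
  if (any(evalue < 0))
    stop_sigmanet("E-values must be non-negative", "sigmanet_error_input")
  labels <- rownames(score)
  if (is.null(labels))
    labels <- paste0("seq", seq_len(nrow(score)))
  dimnames(score) <- dimnames(evalue) <- list(labels, labels)
  structure(list(score = score, evalue = evalue, labels = labels),
            class = "raw_scores")
}

#' Symmetrize directed scores into a similarity matrix
#'
#' The symmetric similarity is the mean of the two directed scores,
#' \code{s_ij = (score_ij + score_ji) / 2}. A pair is valid when the smaller
#' of its two E-values is at or below \code{evalue_max} (default 1.0); invalid
#' pairs are recorded as similarity 0 so that they never produce an edge at
#' any positive threshold.
#'
#' @param raw A \code{"raw_scores"} object.
#' @param evalue_max Validity cutoff on the pair's best E-value.
#' @return A [similarity_matrix()].
#' @export
symmetrize <- function(raw, evalue_max = 1.0) {
  if (!inherits(raw, "raw_scores"))
    raw <- do.call(raw_scores, raw)
  values <- (raw$score + t(raw$score)) / 2
  valid <- pmin(raw$evalue, t(raw$evalue)) <= evalue_max
  diag(values) <- 100
  diag(valid) <- TRUE
  similarity_matrix(values, valid)
}

#' Symmetric percent-similarity matrix
#'
#' The central data structure of the pipeline: a symmetric matrix of percent
#' similarities \code{0 <= s_ij <= 100} with a parallel logical validity mask.
#' The diagonal is 100 and valid; invalid entries are forced to 0, the
#' representation under which they can never contribute an edge.
#'
#' @param values Square numeric matrix with row/column labels; symmetric
#'   within \code{tol}.
#' @param valid Optional logical matrix of the same shape (default: all valid).
#' @param tol Symmetry tolerance.
#' @return An object of class \code{"similarity_matrix"} with fields
#'   \code{values}, \code{valid}, \code{labels}.
#' @export
similarity_matrix <- function(values, valid = NULL, tol = 1e-9) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop_sigmanet("similarity matrix must be square", "sigmanet_error_nonsquare")
  labels <- rownames(values)
  if (is.null(labels) || is.null(colnames(values)))
    stop_sigmanet("similarity matrix needs row and column labels",
                  "sigmanet_error_labels")
  if (!identical(labels, colnames(values)))
    stop_sigmanet("row and column labels differ", "sigmanet_error_labels")
  if (anyDuplicated(labels))
    stop_sigmanet("labels must be unique", "sigmanet_error_labels")
  if (is.null(valid)) valid <- !is.na(values)
  storage.mode(valid) <- "logical"
  na_vals <- is.na(values)
  if (any(na_vals & valid))
    stop_sigmanet("NA similarity on a valid pair", "sigmanet_error_input")
  values[na_vals] <- 0
  if (max(abs(values - t(values))) > tol)
    stop_sigmanet("similarity values asymmetric beyond tolerance",
                  "sigmanet_error_asymmetric")
  if (!identical(valid, t(valid)))
    stop_sigmanet("validity mask is asymmetric", "sigmanet_error_asymmetric")
  values <- (values + t(values)) / 2
  if (any(abs(diag(values) - 100) > tol) || any(!diag(valid)))
    stop_sigmanet("diagonal must be 100 and valid", "sigmanet_error_input")
  if (any(values < -tol | values > 100 + tol))
    stop_sigmanet("similarities must lie in [0, 100]", "sigmanet_error_input")
  values <- pmin(pmax(values, 0), 100)
  diag(values) <- 100
  values[!valid] <- 0
  structure(list(values = values, valid = valid, labels = labels),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- length(x$labels)
  n_invalid <- sum(!x$valid[upper.tri(x$valid)])
  cat(sprintf("similarity_matrix: %d sequences, %d invalid pair(s)\n",
              n, n_invalid))
  off <- x$values[upper.tri(x$values)][x$valid[upper.tri(x$valid)]]
  if (length(off))
    cat(sprintf("  valid off-diagonal s_ij: range [%.1f, %.1f]\n",
                min(off), max(off)))
  invisible(x)
}

#' Restrict a similarity matrix to a subset of sequences
#'
#' @param S A \code{"similarity_matrix"}.
#' @param members Character vector of labels to keep (order preserved).
#' @return The induced \code{"similarity_matrix"}.
#' @export
sub_similarity <- function(S, members) {
  missing <- setdiff(members, S$labels)
  if (length(missing))
    stop_sigmanet(sprintf("unknown labels: %s", paste(missing, collapse = ", ")),
                  "sigmanet_error_labels")
  similarity_matrix(S$values[members, members, drop = FALSE],
                    S$valid[members, members, drop = FALSE])
}

#' Convenience: similarity matrix straight from sequences
#'
#' Runs [pairwise_scores()] then [symmetrize()].
#'
#' @inheritParams pairwise_scores
#' @inheritParams symmetrize
#' @export
similarity_from_sequences <- function(seqs, scoring = scoring_params(),
                                      evalue_max = 1.0) {
  symmetrize(pairwise_scores(seqs, scoring), evalue_max = evalue_max)
}

#' Read / write a similarity matrix as TSV
#'
#' Tab-separated matrix with sequence labels in the first row and first
#' column. Invalid pairs are written with the sentinel \code{NA} and read back
#' as invalid (similarity 0). The round trip is lossless up to floating-point
#' printing precision.
#'
#' @param path File path.
#' @rdname similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  if (!file.exists(path))
    stop_sigmanet(sprintf("no such file: %s", path), "sigmanet_error_io")
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      any(!nzchar(rownames(m))) || any(!nzchar(colnames(m))))
    stop_sigmanet("similarity TSV must carry labels in first row and column",
                  "sigmanet_error_labels")
  if (!identical(rownames(m), colnames(m)))
    stop_sigmanet("row and column labels differ", "sigmanet_error_labels")
  vals <- m
  vals[is.na(vals)] <- 0
  if (max(abs(vals - t(vals))) > 1e-9 || !identical(is.na(m), t(is.na(m))))
    stop_sigmanet("matrix in TSV is asymmetric beyond tolerance 1e-9",
                  "sigmanet_error_asymmetric")
  similarity_matrix(m, valid = !is.na(m))
}

#' @param S A \code{"similarity_matrix"}.
#' @rdname similarity_tsv
#' @export
write_similarity_tsv <- function(S, path) {
  out <- S$values
  out[!S$valid] <- NA
  diag(out) <- 100
  df <- data.frame(label = S$labels, out, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' Description lines are parsed as \code{"id taxon name"}; the id must be
#' unique per record.
#'
#' @param path FASTA file path.
#' @return An \code{AAStringSet} validated by [as_sequence_set()].
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path))
    stop_sigmanet(sprintf("no such file: %s", path), "sigmanet_error_io")
  as_sequence_set(Biostrings::readAAStringSet(path))
}

#' Write sequences to FASTA
#'
#' @param seqs Sequences accepted by [as_sequence_set()].
#' @param path Output path.
#' @export
write_protein_fasta <- function(seqs, path) {
  seqs <- as_sequence_set(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
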