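# End-to-end orchestration: similarity -> threshold-family scan ->
# recursive community analysis -> dendrogram, with standard-format
# artifacts (TSV, JSON, Newick) written to an output directory.

#' Pipeline configuration
#'
#' @param input Path to the input file.
#' @param format \code{"fasta"} (protein sequences; similarity is computed)
#'   or \code{"tsv"} (precomputed similarity matrix; the similarity stage is
#'   bypassed).
#' @param out_dir Output directory (created if missing).
#' @param grid A [sigma_grid()].
#' @param scoring A [scoring_params()] (FASTA input only).
#' @param evalue_max Pair-validity cutoff on the E-value (default 1.0).
#' @param min_prominence_frac Peak-prominence fraction for
#'   [detect_critical_thresholds()].
#' @param min_recurse_size Smallest community that is re-scanned (default 3;
#'   a 2-member community splits trivially at its own pairwise similarity).
#' @param seed Optional integer seed (analysis is deterministic; the seed
#'   exists for configs that drive synthetic generation).
#' @return Object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(input, format = c("fasta", "tsv"),
                            out_dir = ".",
                            grid = sigma_grid(),
                            scoring = scoring_params(),
                            evalue_max = 1.0,
                            min_prominence_frac = 0.1,
                            min_recurse_size = 3,
                            seed = NULL) {
  format <- match.arg(format)
  if (evalue_max <= 0)
    stop_sigmanet("evalue_max must be > 0", "sigmanet_error_config")
  structure(list(input = input, format = format, out_dir = out_dir,
                 grid = as_sigma_grid(grid), scoring = scoring,
                 evalue_max = evalue_max,
                 min_prominence_frac = min_prominence_frac,
                 min_recurse_size = min_recurse_size, seed = seed),
            class = "pipeline_config")
}

safe_level_name <- function(level) {
  gsub("[^A-Za-z0-9_.-]+", "_", level)
}

#' Run the full threshold-network pipeline
#'
#' Reads the input (FASTA sequences or a similarity TSV), computes or loads
#' the similarity matrix, scans the delta-distance curve, extracts the
#' community partition at the dominant critical threshold, and recurses into
#' every community of at least \code{min_recurse_size} members until no
#' critical threshold passes the prominence cutoff. Also builds the global
#' sigma-height dendrogram. Artifacts written to \code{out_dir}:
#' \code{similarity.tsv}, one \code{delta_<level>.tsv} per analysed level,
#' \code{report.json} (critical thresholds, communities and isolates per
#' level) and \code{dendrogram.nwk}. Every split event is logged via
#' [message()] with its level, sigma and community sizes.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the similarity matrix, per-level analyses,
#'   dendrogram, Newick string and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$input))
    stop_sigmanet(sprintf("input not readable: %s", config$input),
                  "sigmanet_error_io")
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  S <- switch(config$format,
    fasta = similarity_from_sequences(read_protein_fasta(config$input),
                                      scoring = config$scoring,
                                      evalue_max = config$evalue_max),
    tsv = read_similarity_tsv(config$input))
  off_valid <- S$valid; diag(off_valid) <- FALSE
  if (length(S$labels) > 1 && !any(off_valid))
    stop_sigmanet("no valid sequence pair after the E-value filter",
                  "sigmanet_error_no_valid_pairs")

  paths <- list(similarity = file.path(config$out_dir, "similarity.tsv"))
  write_similarity_tsv(S, paths$similarity)

  levels <- list()
  recurse <- function(members, level) {
    ana <- analyze_subcommunity(S, members, config$grid,
                                config$min_prominence_frac)
    lev_file <- file.path(config$out_dir,
                          sprintf("delta_%s.tsv", safe_level_name(level)))
    write_delta_tsv(ana$curve, lev_file)
    entry <- list(level = level, members = members,
                  sigma_cst = ana$thresholds$sigma_cst,
                  delta_tsv = basename(lev_file))
    if (!nrow(ana$thresholds)) {
      entry$communities <- list()
      entry$isolates <- character(0)
      levels[[length(levels) + 1]] <<- entry
      return(invisible(NULL))
    }
    dom <- which.max(ana$thresholds$peak_height)
    part <- ana$partitions[[dom]]
    entry$dominant_sigma_cst <- ana$thresholds$sigma_cst[dom]
    entry$communities <- part$communities
    entry$isolates <- part$isolates
    levels[[length(levels) + 1]] <<- entry
    message(sprintf(
      "[%s] split at sigma_cst = %g: %d communities (sizes %s), %d isolate(s)",
      level, part$sigma, length(part$communities),
      paste(lengths(part$communities), collapse = ","),
      length(part$isolates)))
    blocks <- part$communities
    if (length(blocks) == 1 && length(blocks[[1]]) == length(members))
      return(invisible(NULL))  # peak without a split: do not recurse in place
    for (b in seq_along(blocks)) {
      child <- blocks[[b]]
      if (length(child) >= config$min_recurse_size)
        recurse(child, paste0(level, "/C", b))
    }
    invisible(NULL)
  }
  if (length(S$labels) >= 2) recurse(S$labels, "root")

  dendro <- build_dendrogram(S, config$grid)
  newick <- to_newick(dendro)
  paths$newick <- file.path(config$out_dir, "dendrogram.nwk")
  writeLines(newick, paths$newick)

  report <- list(
    n_sequences = length(S$labels),
    grid = list(start = config$grid$points[1],
                stop = config$grid$points[length(config$grid$points)],
                step = config$grid$step),
    min_prominence_frac = config$min_prominence_frac,
    evalue_max = config$evalue_max,
    levels = lapply(levels, function(e) {
      list(level = e$level,
           n_members = length(e$members),
           members = e$members,
           sigma_cst = e$sigma_cst,
           dominant_sigma_cst = e$dominant_sigma_cst,
           communities = e$communities,
           isolates = e$isolates)
    }),
    newick = newick)
  paths$report <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  invisible(list(similarity = S, levels = levels, dendrogram = dendro,
                 newick = newick, paths = paths))
}

parse_ncbi_fasta_records <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- grep("^>", lines)
  lapply(seq_along(starts), function(k) {
    from <- starts[k] + 1
    to <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    header <- sub("^>", "", lines[starts[k]])
    list(id = sub("\\s.*$", "", header),
         description = header,
         sequence = paste(lines[from:to], collapse = ""))
  })
}

default_ncbi_fetcher <- function(accession) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=protein&rettype=fasta&retmode=text&id=", accession)
  txt <- tryCatch(paste(readLines(url, warn = FALSE), collapse = "\n"),
                  error = function(e) stop_sigmanet(
                    sprintf("fetch failed for %s: %s", accession,
                            conditionMessage(e)),
                    "sigmanet_error_fetch"))
  recs <- parse_ncbi_fasta_records(txt)
  if (!length(recs))
    stop_sigmanet(sprintf("no record returned for %s", accession),
                  "sigmanet_error_fetch")
  recs[[1]]
}

#' Fetch study sequences by accession (network required)
#'
#' Retrieves protein records for a list of accessions and assembles a FASTA
#' sequence set, excluding records whose description flags them as
#' \code{PREDICTED} (model/predicted RefSeq entries). Retrieval is pluggable
#' so the function is testable without network access: \code{fetcher} takes
#' one accession and returns \code{list(id, description, sequence)}.
#'
#' @param accessions Character vector of accessions, or a path to a text
#'   file with one accession per line.
#' @param fetcher Retrieval function; defaults to NCBI efetch over HTTPS.
#' @param path Optional FASTA output path.
#' @return An \code{AAStringSet} (possibly empty, with a warning).
#' @export
fetch_study_sequences <- function(accessions, fetcher = default_ncbi_fetcher,
                                  path = NULL) {
  if (length(accessions) == 1 && file.exists(accessions))
    accessions <- readLines(accessions, warn = FALSE)
  accessions <- trimws(accessions)
  accessions <- accessions[nzchar(accessions)]
  if (!length(accessions)) {
    warning("empty accession list; returning empty sequence set")
    out <- Biostrings::AAStringSet()
    if (!is.null(path)) Biostrings::writeXStringSet(out, path)
    return(out)
  }
  recs <- lapply(accessions, fetcher)
  predicted <- vapply(recs, function(r)
    grepl("\\bPREDICTED\\b", r$description), logical(1))
  for (r in recs[predicted])
    message(sprintf("excluding PREDICTED record %s", r$id))
  recs <- recs[!predicted]
  seqs <- stats::setNames(vapply(recs, `[[`, character(1), "sequence"),
                          vapply(recs, `[[`, character(1), "description"))
  out <- if (length(seqs)) as_sequence_set(seqs) else Biostrings::AAStringSet()
  if (!is.null(path)) Biostrings::writeXStringSet(out, path)
  out
}
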