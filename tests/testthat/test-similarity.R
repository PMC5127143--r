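test_that("self and identical sequences score 100 with zero/negligible E-value", {
  s <- paste(rep(c("A", "C", "D", "E", "F"), 30), collapse = "")
  rs <- pairwise_scores(c(a = s, b = s))
  expect_equal(diag(rs$score), c(a = 100, b = 100))
  expect_equal(diag(rs$evalue), c(a = 0, b = 0))
  expect_equal(rs$score[1, 2], 100)
  expect_equal(rs$score[2, 1], 100)
  expect_lt(rs$evalue[1, 2], 1e-6)
})

test_that("a single substitution in 250 residues keeps the score at 99 or above", {
  set.seed(11)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  base <- sample(aa, 250, replace = TRUE)
  mutated <- base
  mutated[100] <- setdiff(aa, base[100])[1]
  seqs <- c(w = paste(base, collapse = ""), m = paste(mutated, collapse = ""))
  for (method in c("bitscore", "positives", "identity")) {
    rs <- pairwise_scores(seqs, scoring_params(method = method))
    expect_gte(rs$score[1, 2], 99)
  }
})

test_that("unrelated random sequences fall in the empirical baseline bands", {
  # bands frozen from the empirical distribution over 1000 random length-250
  # pairs (BLOSUM62 11/1): normalised bit score has median ~3.2 (range
  # ~2.6-5), percent positives of the best local alignment has median ~47
  # (IQR 41-56, heavy right tail), and the E-value has median ~0.18.
  set.seed(2024)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  bit <- pos <- evals <- numeric(30)
  for (k in seq_len(30)) {
    pair <- c(a = paste(sample(aa, 250, TRUE), collapse = ""),
              b = paste(sample(aa, 250, TRUE), collapse = ""))
    rs_bit <- pairwise_scores(pair)  # default: normalised bit score
    rs_pos <- pairwise_scores(pair, scoring_params(method = "positives"))
    bit[k] <- rs_bit$score[1, 2]
    pos[k] <- rs_pos$score[1, 2]
    evals[k] <- rs_bit$evalue[1, 2]
  }
  expect_gt(median(bit), 2)
  expect_lt(median(bit), 5)
  expect_lt(max(bit), 10)     # unrelated pairs never look related
  expect_gt(median(pos), 38)
  expect_lt(median(pos), 62)  # best-HSP positives sit near 50% for noise
  expect_gt(median(evals), 0.02)
  expect_lt(median(evals), 0.9)
})

test_that("symmetrize averages directions and applies the min E-value rule", {
  score <- matrix(c(100, 80, 10,
                    90, 100, 12,
                    10, 12, 100), 3, 3, byrow = TRUE,
                  dimnames = list(letters[1:3], letters[1:3]))
  evalue <- matrix(c(0, 0.5, 2,
                     2, 0, 3,
                     2, 3, 0), 3, 3, byrow = TRUE,
                   dimnames = list(letters[1:3], letters[1:3]))
  S <- symmetrize(raw_scores(score, evalue))
  expect_equal(S$values["a", "b"], 85)
  expect_equal(S$values["b", "a"], 85)
  # a-b valid through min(0.5, 2) <= 1; a-c invalid (both E > 1) -> 0
  expect_true(S$valid["a", "b"])
  expect_false(S$valid["a", "c"])
  expect_equal(S$values["a", "c"], 0)
  expect_false(S$valid["b", "c"])
  # already symmetric scores pass through unchanged on valid pairs
  score2 <- (score + t(score)) / 2
  S2 <- symmetrize(raw_scores(score2, matrix(0, 3, 3)))
  expect_equal(S2$values["a", "b"], 85)
  expect_equal(S2$values["a", "c"], 10)
  # idempotence: re-symmetrizing the symmetric matrix changes nothing
  S3 <- symmetrize(raw_scores(S2$values, matrix(0, 3, 3)))
  expect_equal(S3$values, S2$values)
})

test_that("input validation produces named error conditions", {
  expect_error(pairwise_scores(c(a = "ACDE")), class = "sigmanet_error_input")
  expect_error(pairwise_scores(c(a = "ACDE", b = "")),
               class = "sigmanet_error_empty_sequence")
  expect_error(pairwise_scores(c(a = "ACDE", b = "AC1E")),
               class = "sigmanet_error_bad_alphabet")
  expect_error(pairwise_scores(c(a = "ACDE", a = "ACDF")),
               class = "sigmanet_error_labels")
  expect_error(raw_scores(matrix(50, 2, 3), matrix(0, 2, 3)),
               class = "sigmanet_error_nonsquare")
  expect_error(similarity_matrix(matrix(c(100, 10, 20, 100), 2, 2,
                                        dimnames = list(c("a", "b"), c("a", "b")))),
               class = "sigmanet_error_asymmetric")
})

test_that("similarity is invariant under permutation of the input order", {
  set.seed(21)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  seqs <- vapply(1:4, function(i) paste(sample(aa, 80, TRUE), collapse = ""),
                 character(1))
  names(seqs) <- paste0("s", 1:4)
  S1 <- similarity_from_sequences(seqs)
  perm <- c(3, 1, 4, 2)
  S2 <- similarity_from_sequences(seqs[perm])
  expect_equal(S2$values, S1$values[perm, perm])
  expect_equal(S2$valid, S1$valid[perm, perm])
  expect_equal(S1$values, t(S1$values))
  expect_equal(diag(S1$values), setNames(rep(100, 4), names(seqs)))
})

test_that("similarity TSV round trip is lossless, including the validity mask", {
  S <- rand_sim(8, seed = 5)
  S$valid[2, 5] <- S$valid[5, 2] <- FALSE
  S <- similarity_matrix(S$values * ifelse(S$valid, 1, 0), S$valid)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_tsv(S, path)
  S2 <- read_similarity_tsv(path)
  expect_equal(S2$values, S$values)
  expect_equal(S2$valid, S$valid)
  expect_equal(S2$labels, S$labels)
})

test_that("similarity TSV stores plain decimal values and rejects bad files", {
  v <- matrix(c(100, 42.5, 42.5, 100), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_tsv(similarity_matrix(v), path)
  expect_true(any(grepl("42.5", readLines(path), fixed = TRUE)))
  expect_equal(read_similarity_tsv(path)$values["a", "b"], 42.5)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\ta\tb", "a\t100\t40", "b\t41\t100"), bad)
  expect_error(read_similarity_tsv(bad), class = "sigmanet_error_asymmetric")
  expect_error(read_similarity_tsv("does-not-exist.tsv"),
               class = "sigmanet_error_io")
})

test_that("FASTA reader parses 'id taxon name' headers and round trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">NP_1 Homo sapiens", "ACDEFGHIKLMNPQRSTVWY",
               ">NP_2 Danio rerio", "ACDEFGHIKLMNPQRSTVWY"), path)
  seqs <- read_protein_fasta(path)
  expect_equal(attr(seqs, "ids"), c("NP_1", "NP_2"))
  expect_equal(attr(seqs, "labels"), c("Homo sapiens", "Danio rerio"))
  out <- withr::local_tempfile(fileext = ".fasta")
  write_protein_fasta(seqs, out)
  seqs2 <- read_protein_fasta(out)
  expect_equal(as.character(seqs2), as.character(seqs))
})
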