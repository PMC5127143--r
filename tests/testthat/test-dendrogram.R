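two_leaf_sim <- function(s = 60) {
  v <- matrix(c(100, s, s, 100), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  similarity_matrix(v)
}

test_that("components split into communities (>= 2 members) and isolates", {
  S <- rand_sim(5, seed = 2)
  complete <- components_at(build_network(S, 0))
  expect_length(complete$communities, 1)
  expect_length(complete$isolates, 0)
  expect_setequal(complete$communities[[1]], S$labels)

  empty <- components_at(build_network(S, 101))
  expect_length(empty$communities, 0)
  expect_setequal(empty$isolates, S$labels)
})

test_that("partition at a sigma inside the planted gap equals the blocks", {
  S <- planted_block_similarity(planted_design(c(4, 3), s_within = 90,
                                               s_between = 20, noise_sd = 0))
  p <- partition_at(S, 55)
  expect_equal(canon_partition(p$communities),
               canon_partition(list(paste0("G1_", 1:4), paste0("G2_", 1:3))))
  memb <- uf_components(build_network(S, 55)$adjacency)
  expect_equal(canon_partition(p$communities),
               canon_partition(membership_blocks(memb, S$labels)))
})

test_that("a single sequence gives a bare leaf", {
  v <- matrix(100, 1, 1, dimnames = list("A", "A"))
  root <- build_dendrogram(similarity_matrix(v))
  expect_length(root$children, 0)
  expect_equal(root$members, "A")
  expect_equal(to_newick(root), "A:0;")
})

test_that("two sequences split at the first sigma that removes their edge", {
  root <- build_dendrogram(two_leaf_sim(60))
  expect_equal(root$split_sigma, 61)
  expect_equal(to_newick(root), "(A:39,B:39):0;")
})

test_that("the planted three-group tree has the planted topology and heights", {
  between <- matrix(c(0, 70, 30,
                      70, 0, 30,
                      30, 30, 0), 3, 3)
  S <- planted_block_similarity(planted_design(c(3, 3, 3), s_within = 95,
                                               s_between = between,
                                               noise_sd = 0))
  root <- build_dendrogram(S)
  # first split separates G3 just above 30
  expect_equal(root$split_sigma, 31)
  expect_length(root$children, 2)
  sizes <- vapply(root$children, function(ch) length(ch$members), integer(1))
  g12 <- root$children[[which(sizes == 6)]]
  g3 <- root$children[[which(sizes == 3)]]
  expect_setequal(g3$members, paste0("G3_", 1:3))
  # G1/G2 part ways in the (70, 95) interval, here at 71
  expect_equal(g12$split_sigma, 71)
  expect_true(all(vapply(g12$children, function(ch)
    length(ch$members) == 3, logical(1))))
})

test_that("cutting the dendrogram reproduces components at every grid sigma", {
  for (seed in c(4, 9)) {
    S <- rand_sim(12, seed)
    root <- build_dendrogram(S)
    for (sigma in seq(0, 100, by = 7)) {
      cut_blocks <- cut_dendrogram(root, sigma)
      p <- components_at(build_network(S, sigma))
      expect_equal(canon_partition(cut_blocks),
                   canon_partition(blocks_of(p)),
                   info = sprintf("seed %d sigma %d", seed, sigma))
    }
  }
})

test_that("the dendrogram agrees with the single-linkage oracle", {
  for (seed in 11:14) {
    S <- rand_sim(10, seed)
    root <- build_dendrogram(S)
    for (sigma in seq(1, 100, by = 9)) {
      expect_equal(canon_partition(cut_dendrogram(root, sigma)),
                   canon_partition(single_linkage_partition(S, sigma)),
                   info = sprintf("seed %d sigma %d", seed, sigma))
    }
  }
})

test_that("newick export is ultrametric and survives an ape round trip", {
  skip_if_not_installed("ape")
  for (seed in c(7, 15)) {
    S <- rand_sim(9, seed)
    root <- build_dendrogram(S)
    tr <- ape::read.tree(text = to_newick(root))
    expect_setequal(tr$tip.label, S$labels)
    depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    expect_equal(max(depths) - min(depths), 0, tolerance = 1e-8)
    expect_equal(max(depths), 100 - root$split_sigma, tolerance = 1e-8)
    # serialize -> parse -> serialize is stable
    rt <- ape::read.tree(text = ape::write.tree(tr))
    expect_equal(ape::write.tree(rt), ape::write.tree(tr))
  }
})

test_that("labels with spaces are quoted in newick output", {
  v <- matrix(c(100, 60, 60, 100), 2, 2,
              dimnames = list(c("Homo sapiens", "Danio rerio"),
                              c("Homo sapiens", "Danio rerio")))
  nwk <- to_newick(build_dendrogram(similarity_matrix(v)))
  expect_match(nwk, "'Homo sapiens'", fixed = TRUE)
  skip_if_not_installed("ape")
  # ape's parser keeps the quote characters; strip them before comparing
  tr <- ape::read.tree(text = nwk)
  expect_setequal(gsub("'", "", tr$tip.label),
                  c("Homo sapiens", "Danio rerio"))
})

test_that("identical sequences stay together through the top of the grid", {
  v <- matrix(c(100, 100, 40,
                100, 100, 40,
                40, 40, 100), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  root <- build_dendrogram(similarity_matrix(v))
  twin <- root$children[[which(vapply(root$children, function(ch)
    length(ch$members), integer(1)) == 2)]]
  expect_true(is.na(twin$split_sigma))
  # A and B are never separated at any grid sigma
  for (sigma in seq(0, 100, 10)) {
    blocks <- cut_dendrogram(root, sigma)
    holds <- any(vapply(blocks, function(b) all(c("A", "B") %in% b), logical(1)))
    expect_true(holds)
  }
})

test_that("sub-community analysis restricts cleanly and finds the inner peak", {
  S <- planted_block_similarity(planted_design(c(4, 4), s_within = 85,
                                               s_between = 25, noise_sd = 0))
  # restriction to the full node set is the identity
  full <- analyze_subcommunity(S, S$labels)
  expect_equal(full$curve$delta, delta_curve(S)$delta)
  # one planted block alone has a single change point at its within level
  sub <- analyze_subcommunity(S, paste0("G1_", 1:4))
  expect_equal(sub$curve$sigma[sub$curve$delta > 0], 86)
  expect_equal(sub$thresholds$sigma_cst, 86)
  expect_error(analyze_subcommunity(S, "G1_1"),
               class = "sigmanet_error_members")
})

test_that("induced subgraph edges equal global edges among members", {
  S <- rand_sim(10, seed = 31)
  members <- S$labels[c(2, 4, 5, 9)]
  Ssub <- sub_similarity(S, members)
  for (sigma in c(10, 45, 80)) {
    sub_adj <- build_network(Ssub, sigma)$adjacency
    glob_adj <- build_network(S, sigma)$adjacency[members, members]
    expect_equal(sub_adj, glob_adj)
  }
})
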