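test_that("node degree obeys the handshake lemma", {
  atlas <- tiny_atlas(8)
  E <- n_edges(8)
  expect_equal(node_degree(rep(FALSE, E), atlas), rep(0L, 8))
  one <- rep(FALSE, E)
  one[1] <- TRUE  # edge (1, 2) in canonical order
  expect_equal(node_degree(one, atlas), c(1L, 1L, rep(0L, 6)))
  expect_equal(node_degree(rep(TRUE, E), atlas), rep(7L, 8))
  for (s in 1:20) {
    mask <- random_mask(8, p = 0.4, seed = s)
    expect_equal(sum(node_degree(mask, atlas)), 2L * sum(mask))
  }
})

test_that("hemisphere partition enumerates endpoint labels", {
  # 2 L-nodes then 2 R-nodes, complete graph: LL, LR, LR, LR, LR, RR
  atlas4 <- tiny_atlas(4, hemisphere = c("L", "L", "R", "R"))
  full <- rep(TRUE, 6)
  expect_equal(hemisphere_partition(full, atlas4),
               c(ipsi_R = 1L, ipsi_L = 1L, inter = 4L))
  allL <- tiny_atlas(6, hemisphere = rep("L", 6))
  hp <- hemisphere_partition(rep(TRUE, n_edges(6)), allL)
  expect_equal(unname(hp["inter"]), 0L)
  # brute-force per-edge classification on random masks
  atlas <- tiny_atlas(10)
  ep <- edge_pairs(10)
  for (s in 1:10) {
    mask <- random_mask(10, p = 0.3, seed = 100 + s)
    want <- c(ipsi_R = 0L, ipsi_L = 0L, inter = 0L)
    for (e in which(mask)) {
      h <- paste0(sort(c(atlas$hemisphere[ep$i[e]], atlas$hemisphere[ep$j[e]])),
                  collapse = "")
      key <- switch(h, RR = "ipsi_R", LL = "ipsi_L", "inter")
      want[key] <- want[key] + 1L
    }
    expect_equal(hemisphere_partition(mask, atlas), want)
  }
})

test_that("range partition classifies by centroid distance and tests the split", {
  # two tight clusters 100 mm apart: within-cluster edges short, between long
  K <- 30
  pos <- ifelse(seq_len(K) <= 15, 0, 100)
  atlas <- as_atlas(data.frame(
    node_id = seq_len(K), hemisphere = rep_len(c("L", "R"), K),
    network = rep_len(CANONICAL_NETWORKS, K), region = "prefrontal",
    x = pos, y = 0, z = 0))
  ep <- edge_pairs(K)
  long_edges <- which(xor(ep$i <= 15, ep$j <= 15))
  short_edges <- which(!xor(ep$i <= 15, ep$j <= 15))
  # the observed split of the positive network in the study: 120 long of 266
  mask <- rep(FALSE, n_edges(K))
  mask[long_edges[1:120]] <- TRUE
  mask[short_edges[1:146]] <- TRUE
  rp <- range_partition(mask, atlas, threshold_mm = 60,
                        expected = c(0.5, 0.5))
  expect_equal(rp$counts, c(long = 120L, short = 146L))
  expect_equal(rp$chi2, (120 - 133)^2 / 133 + (146 - 133)^2 / 133,
               tolerance = 1e-10)
  expect_equal(rp$p, pchisq(rp$chi2, df = 1, lower.tail = FALSE))
  # coincident centroids: nothing is long-range
  flat <- as_atlas(data.frame(
    node_id = 1:10, hemisphere = rep_len(c("L", "R"), 10),
    network = CANONICAL_NETWORKS, region = "x", x = 0, y = 0, z = 0))
  rp0 <- range_partition(rep(TRUE, 45), flat, threshold_mm = 60,
                         expected = c(0.5, 0.5))
  expect_equal(unname(rp0$counts["long"]), 0L)
  expect_error(range_partition(mask, atlas, expected = c(0.6, 0.6)),
               "sum to 1")
  # balanced observed split against a balanced null: chi2 = 0, p = 1
  mask2 <- rep(FALSE, n_edges(K))
  mask2[long_edges[1:10]] <- TRUE
  mask2[short_edges[1:10]] <- TRUE
  rp2 <- range_partition(mask2, atlas, expected = c(0.5, 0.5))
  expect_equal(rp2$chi2, 0)
  expect_equal(rp2$p, 1)
})

test_that("network matrix counts edges within and between canonical networks", {
  # nodes 1..10 carry each canonical network once
  atlas <- as_atlas(data.frame(
    node_id = 1:10, hemisphere = rep_len(c("L", "R"), 10),
    network = CANONICAL_NETWORKS, region = "x",
    x = 1:10, y = 0, z = 0))
  ep <- edge_pairs(10)
  mot <- which(CANONICAL_NETWORKS == "Mot")
  sal <- which(CANONICAL_NETWORKS == "SAL")
  mask <- rep(FALSE, 45)
  mask[which(ep$i == mot & ep$j == sal)] <- TRUE
  M <- network_matrix(mask, atlas)
  expect_equal(M["Mot", "SAL"], 1)
  expect_equal(M["SAL", "Mot"], 1)
  expect_equal(sum(M[upper.tri(M, diag = TRUE)]), 1)
  # a within-network edge lands on the diagonal
  atlas2 <- tiny_atlas(12)  # networks repeat after 10 nodes
  ep2 <- edge_pairs(12)
  within_mf <- which(ep2$i == 1 & ep2$j == 11)  # both MF
  mask2 <- rep(FALSE, n_edges(12))
  mask2[within_mf] <- TRUE
  M2 <- network_matrix(mask2, atlas2)
  expect_equal(M2["MF", "MF"], 1)
  expect_equal(sum(M2[upper.tri(M2, diag = TRUE)]), 1)
})

test_that("network matrix is invariant under node relabeling", {
  K <- 12
  atlas <- tiny_atlas(K)
  mask <- random_mask(K, p = 0.3, seed = 6)
  M <- network_matrix(mask, atlas)
  # permute node order, carrying labels and mask along
  perm <- withr::with_seed(2, sample.int(K))
  atlas_p <- as.data.frame(atlas)[perm, ]
  atlas_p$node_id <- seq_len(K)
  atlas_p <- as_atlas(atlas_p)
  ep <- edge_pairs(K)
  inv <- order(perm)  # old node -> new node
  idx <- matrix(0L, K, K)
  idx[cbind(ep$i, ep$j)] <- seq_len(n_edges(K))
  mask_p <- logical(n_edges(K))
  ni <- inv[ep$i[mask]]
  nj <- inv[ep$j[mask]]
  mask_p[idx[cbind(pmin(ni, nj), pmax(ni, nj))]] <- TRUE
  expect_equal(network_matrix(mask_p, atlas_p), M)
})

test_that("all four partitions conserve the total edge count", {
  atlas <- generate_atlas(24, seed = 3)
  for (s in 1:25) {
    mask <- random_mask(24, p = runif(1, 0.05, 0.6), seed = 200 + s)
    total <- sum(mask)
    expect_equal(sum(node_degree(mask, atlas)), 2L * total)
    expect_equal(sum(hemisphere_partition(mask, atlas)), total)
    rp <- range_partition(mask, atlas, expected = c(0.5, 0.5))
    expect_equal(sum(rp$counts), total)
    NM <- network_matrix(mask, atlas)
    expect_equal(sum(NM[upper.tri(NM, diag = TRUE)]), total)
    RM <- region_matrix(mask, atlas)
    expect_equal(sum(RM[upper.tri(RM, diag = TRUE)]), total)
  }
})

test_that("edge-list export round-trips the mask", {
  atlas <- generate_atlas(15, seed = 8)
  mask <- random_mask(15, p = 0.25, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_edge_list(mask, atlas, path)
  expect_equal(nrow(out), sum(mask))
  expect_identical(read_edge_list_mask(path, atlas), mask)
  # empty mask: header-only file
  path2 <- withr::local_tempfile(fileext = ".tsv")
  export_edge_list(rep(FALSE, n_edges(15)), atlas, path2)
  expect_length(readLines(path2), 1L)
  expect_identical(read_edge_list_mask(path2, atlas),
                   rep(FALSE, n_edges(15)))
})

test_that("summary bundles the partitions consistently", {
  atlas <- generate_atlas(20, seed = 5)
  mask <- random_mask(20, p = 0.2, seed = 4)
  s <- summarize_network(mask, atlas)
  expect_equal(s$total_edges, sum(mask))
  expect_equal(sum(s$degree), 2 * s$total_edges)
  expect_equal(sum(s$hemisphere_counts), s$total_edges)
  expect_equal(sum(s$range$counts), s$total_edges)
})
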