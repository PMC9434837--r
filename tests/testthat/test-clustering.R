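blob_matrix <- function(n_per, centers, sd = 1, seed = 1, d = 5) {
  set.seed(seed)
  m <- do.call(rbind, lapply(seq_along(centers), function(i)
    matrix(rnorm(n_per * d, centers[[i]], sd), n_per, d)))
  rownames(m) <- sprintf("c%04d", seq_len(nrow(m)))
  colnames(m) <- sprintf("f%d", seq_len(d))
  m
}

test_that("kNN graph basics: tiny graphs, duplicates, separated blobs", {
  m <- blob_matrix(3, list(0), seed = 2)[1:3, ]
  expect_warning(g <- build_neighbor_graph(m, k = 20), "reducing k")
  expect_equal(igraph::ecount(g), 3)          # complete on 3 vertices

  # duplicated cells are mutual nearest neighbours
  dup <- blob_matrix(20, list(0), seed = 3)
  dup[2, ] <- dup[1, ]
  nn <- adtgate:::cpp_knn(unname(dup), 5L)
  expect_identical(nn[1, 1], 2L)
  expect_identical(nn[2, 1], 1L)

  # two blobs 10 SDs apart: no inter-blob edges
  m2 <- blob_matrix(100, list(0, 10), sd = 1, seed = 4)
  g2 <- build_neighbor_graph(m2, k = 10)
  ends <- igraph::ends(g2, igraph::E(g2))
  blob <- rep(1:2, each = 100)[match(ends, rownames(m2))]
  dim(blob) <- dim(ends)
  expect_identical(sum(blob[, 1] != blob[, 2]), 0L)
  expect_equal(attr(g2, "n_components"), 2)
})

test_that("Louvain recovers blobs across the resolution range, deterministically", {
  # k is sized to the blobs (40 of 80): a kNN graph much sparser than its
  # communities fragments at high resolution, like any SNN-Louvain tool
  m <- blob_matrix(80, list(0, 10), sd = 1, seed = 5)
  g <- build_neighbor_graph(m, k = 40)
  blob <- rep(1:2, each = 80)
  for (res in c(0.3, 0.8, 1.3)) {
    cl <- modularity_cluster(g, resolution = res, seed = 9)
    expect_equal(length(unique(cl)), 2L)
    expect_gte(adjusted_rand(cl, blob), 0.99)
  }
  single <- blob_matrix(200, list(0), sd = 1, seed = 6)
  g1 <- build_neighbor_graph(single, k = 50)
  expect_identical(length(unique(modularity_cluster(g1, 0.3, seed = 9))), 1L)
  expect_identical(modularity_cluster(g, 1.0, seed = 4),
                   modularity_cluster(g, 1.0, seed = 4))
})

test_that("cluster count is non-decreasing in resolution on a fixed graph", {
  m <- blob_matrix(80, list(0, 4, 8, 30), sd = 1, seed = 7)
  g <- build_neighbor_graph(m, k = 30)
  counts <- vapply(c(0.3, 0.5, 0.8, 1.0, 1.3), function(r)
    length(unique(modularity_cluster(g, r, seed = 1))), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("RNA features are refused by the graph builder", {
  m <- blob_matrix(50, list(0), seed = 8)
  attr(m, "modality") <- "RNA"
  expect_error(build_neighbor_graph(m), "antibody")
})

test_that("three planted subtypes in one major type: ARI >= 0.9", {
  # CLR-like profiles: 8 markers, subtypes positive on disjoint pairs
  set.seed(11)
  n <- 200
  centers <- list(c(4, 4, 0, 0, 0, 0, 0, 0),
                  c(0, 0, 4, 4, 0, 0, 0, 0),
                  c(0, 0, 0, 0, 4, 4, 0, 0))
  m <- do.call(rbind, lapply(centers, function(ce)
    matrix(rnorm(n * 8, rep(ce, each = n), 0.6), n, 8)))
  rownames(m) <- sprintf("c%04d", seq_len(3 * n))
  colnames(m) <- sprintf("m%d", 1:8)
  truth <- rep(1:3, each = n)
  asg <- cluster_major_types(m, rep("CD4T", 3 * n),
                             resolutions = c(CD4T = 1.0), k = 60, seed = 3)
  expect_gte(adjusted_rand(asg$cluster, truth), 0.9)
})

test_that("split_cluster partitions, rejects empty sides, and reverses", {
  set.seed(13)
  n <- 100
  m <- cbind(CD163 = c(rep(3, 50), rep(0, 50)), CD11c = rnorm(n, 2, 0.1))
  rownames(m) <- sprintf("c%04d", 1:n)
  asg <- data.frame(cell_id = rownames(m), major_type = "CM",
                    cluster = "CM_1", resolution = 0.5,
                    stringsAsFactors = FALSE)
  out <- split_cluster(asg, m, split_rule("CM_1", "CD163"))
  expect_identical(sort(unique(out$cluster)), c("CM_1a", "CM_1b"))
  expect_identical(sum(out$cluster == "CM_1a"), 50L)
  expect_identical(unique(out$original_cluster), "CM_1")

  # all-hi split is rejected unchanged
  expect_warning(same <- split_cluster(asg, m, split_rule("CM_1", "CD11c")),
                 "rejected")
  expect_identical(same$cluster, asg$cluster)

  # reversing provenance reconstructs the original assignment
  back <- unsplit_cluster(out, "CM_1")
  expect_identical(back$cluster, asg$cluster)
  expect_error(split_cluster(asg, m, split_rule("nope", "CD163")), "nope")
})

test_that("embed_2d is shape-preserving and reproducible", {
  m <- blob_matrix(60, list(0, 5), seed = 15)
  xy <- embed_2d(m)
  expect_identical(dim(xy), c(120L, 2L))
  expect_identical(rownames(xy), rownames(m))
  expect_identical(xy, embed_2d(m))
})
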