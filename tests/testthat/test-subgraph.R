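test_that("isolated anchor pairs pad up to K", {
  net <- toy_network()
  net$Y[] <- 0; net$Y["d1", "t1"] <- 1
  net <- dti_network(net$Y, net$S_D, net$S_T)
  sub <- extract_subgraph(net, 1, 1, K = 10)
  expect_equal(nrow(sub$vertices), 2)
  expect_equal(sub$padded_count, 8)
  expect_equal(sub$vertices$id, c("d1", "t1"))
  expect_true(sub$anchor_edge_present)
  expect_equal(sum(sub$dti_adj), 0)  # the anchor edge itself is removed
  expect_error(extract_subgraph(net, 1, 1, K = 1), "at least 2")
})

test_that("first hop fills K on the 3x3 toy and unreachable vertices stay out", {
  sub <- extract_subgraph(toy_network(), 1, 1, K = 4)
  expect_setequal(sub$vertices$id, c("d1", "t1", "d2", "t2"))
  expect_equal(sub$vertices$id[1:2], c("d1", "t1"))
  expect_equal(sub$padded_count, 0)
  # induced interaction edges minus the anchor edge
  expect_setequal(paste(subgraph_edges(sub)$drug_id,
                        subgraph_edges(sub)$target_id),
                  c("d2 t1", "d1 t2"))
})

test_that("oversized first hop is truncated by the labeling ranks", {
  # hand refinement of the 4-vertex subgraph: anchors colour 1;
  # d2 and t2 tie on geometric mean distance sqrt(6) and on refined colour
  # (one interaction edge to an anchor each), so the drug-before-target rule
  # keeps d2 and discards t2
  sub <- extract_subgraph(toy_network(), 1, 1, K = 3)
  expect_setequal(sub$vertices$id, c("d1", "t1", "d2"))
  expect_equal(sub$padded_count, 0)
})

test_that("anchors survive truncation even when far from everything", {
  net <- random_network(10, 12, density = 0.4, seed = 2)
  for (K in c(3, 5, 8)) {
    sub <- extract_subgraph(net, 1, 1, K)
    expect_lte(nrow(sub$vertices), K)
    expect_equal(sub$vertices$index[1:2], c(1L, 1L))
    expect_equal(sub$vertices$role[1:2], c("drug", "target"))
    expect_equal(nrow(sub$vertices) + sub$padded_count, K)
  }
})

test_that("pre-truncation vertex sets grow monotonically in K", {
  net <- random_network(15, 15, density = 0.12, seed = 5)
  keyset <- function(sub) paste(sub$vertices$role, sub$vertices$index)
  checked <- 0
  for (pair in list(c(2, 3), c(5, 9), c(7, 1), c(1, 1), c(12, 4))) {
    # restrict to pairs whose first hop fits the smallest K, so no
    # truncation interferes and the grown sets are the pre-truncation sets
    fh <- 2 + sum(net$Y[pair[1], -pair[2]]) + sum(net$Y[-pair[1], pair[2]])
    if (fh > 6) next
    prev <- NULL
    for (K in c(6, 10, 14)) {
      sub <- extract_subgraph(net, pair[1], pair[2], K)
      ks <- keyset(sub)
      if (!is.null(prev)) {
        expect_true(all(prev %in% ks))
        checked <- checked + 1
      }
      prev <- ks
    }
  }
  expect_gte(checked, 4)
})

test_that("every non-anchor vertex is DTI-connected to an anchor", {
  net <- random_network(12, 12, density = 0.15, seed = 6)
  for (seed_pair in list(c(1, 1), c(3, 7), c(10, 2))) {
    sub <- extract_subgraph(net, seed_pair[1], seed_pair[2], K = 8)
    nv <- nrow(sub$vertices)
    if (nv > 2) {
      d1 <- oracle_distances_from(sub$dti_adj, 1)
      d2 <- oracle_distances_from(sub$dti_adj, 2)
      expect_true(all(is.finite(pmin(d1, d2)[3:nv])))
    }
  }
})

test_that("extraction is deterministic", {
  net <- random_network(14, 14, density = 0.15, seed = 8)
  a <- extract_subgraph(net, 2, 5, K = 10)
  b <- extract_subgraph(net, 2, 5, K = 10)
  expect_identical(a, b)
})

test_that("pool admission follows similarity to the anchors", {
  # second hop: t1's other drugs d2, d3 compete; S_D[d1, d3] > S_D[d1, d2]
  d <- c("d1", "d2", "d3"); t <- c("t1", "t2")
  Y <- matrix(0, 3, 2, dimnames = list(d, t))
  Y["d1", "t1"] <- 1; Y["d2", "t1"] <- 1; Y["d3", "t1"] <- 1
  S_D <- sym_mat(3, c(0.2, 0.8, 0.5), d)  # (d1,d2)=0.2, (d1,d3)=0.8
  net <- dti_network(Y, S_D, diag(2))
  sub <- extract_subgraph(net, 1, 2, K = 3)  # anchors d1, t2 (negative pair)
  # first hop adds t1 (from d1); pool {d2, d3} ranked by S_D to d1 -> d3 wins
  expect_setequal(sub$vertices$id, c("d1", "t2", "t1"))
  sub4 <- extract_subgraph(net, 1, 2, K = 4)
  expect_setequal(sub4$vertices$id, c("d1", "t2", "t1", "d3"))
})
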