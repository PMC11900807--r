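two_families <- function(n_each = 35, n_bits = 256) {
  rbind(block_fps(n_each, 1:60, n_bits, prefix = "a"),
        block_fps(n_each, 129:188, n_bits, prefix = "b", seed = 100))
}

test_that("two well-separated fingerprint families form exactly 2 clusters", {
  fps <- two_families()
  asg <- embed_and_cluster(fps, min_cluster_size = 30, seed = 42)
  expect_equal(max(asg$labels), 2L)
  expect_equal(sum(asg$labels == NOISE), 0L)
  # each family lands wholly in one cluster
  fam_a <- asg$labels[grep("^a", names(asg$labels))]
  fam_b <- asg$labels[grep("^b", names(asg$labels))]
  expect_length(unique(fam_a), 1)
  expect_length(unique(fam_b), 1)
  expect_false(fam_a[[1]] == fam_b[[1]])
})

test_that("fewer molecules than the cluster-size floor are all noise", {
  fps <- block_fps(10, 1:60)
  asg <- embed_and_cluster(fps, min_cluster_size = 30)
  expect_true(all(asg$labels == NOISE))
})

test_that("clustering is deterministic and input-order invariant", {
  fps <- two_families()
  a <- embed_and_cluster(fps, min_cluster_size = 30, seed = 42)
  b <- embed_and_cluster(fps, min_cluster_size = 30, seed = 42)
  expect_identical(a$labels, b$labels)
  withr::with_seed(1, perm <- sample(nrow(fps)))
  c <- embed_and_cluster(fps[perm, ], min_cluster_size = 30, seed = 42)
  nm <- sort(names(a$labels))
  expect_identical(a$labels[nm], c$labels[nm])
  expect_error(embed_and_cluster(fps[1, , drop = FALSE]), "at least 2")
})

test_that("consistency report matches a brute-force pairwise computation", {
  fps <- two_families(n_each = 8)
  labels <- stats::setNames(rep(c(1L, 2L), each = 8), rownames(fps))
  asg <- structure(list(embedding = NULL, labels = labels,
                        parameters = list()), class = "cluster_assignment")
  cc <- cluster_consistency(asg, fps)
  for (cl in c("1", "2")) {
    members <- names(labels)[labels == as.integer(cl)]
    pairs <- utils::combn(members, 2)
    oracle <- mean(vapply(seq_len(ncol(pairs)), function(j)
      tanimoto(fps[pairs[1, j], ], fps[pairs[2, j], ]), 0))
    expect_equal(cc$intra[[cl]], oracle)
  }
  expect_equal(cc$inter["1", "2"],
               tanimoto(fps[cc$medoids[["1"]], ], fps[cc$medoids[["2"]], ]))
  expect_true(cc$pass)  # disjoint blocks: intra > inter = 0 necessarily
})

test_that("identical members give intra 1 and disjoint clusters inter 0", {
  fps <- matrix(0L, 6, 64, dimnames = list(paste0("m", 1:6), NULL))
  fps[1:3, 1:10] <- 1L
  fps[4:6, 33:42] <- 1L
  labels <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), rownames(fps))
  asg <- structure(list(labels = labels, parameters = list()),
                   class = "cluster_assignment")
  cc <- cluster_consistency(asg, fps)
  expect_equal(unname(cc$intra), c(1, 1))
  expect_equal(cc$inter["1", "2"], 0)
  expect_true(cc$pass)
})

test_that("consistency passes across seeds on the two-family construction", {
  for (seed in c(1, 7, 42, 99)) {
    fps <- two_families()
    asg <- embed_and_cluster(fps, min_cluster_size = 30, seed = seed)
    expect_true(cluster_consistency(asg, fps)$pass)
  }
})

slate_fixture <- function() {
  fps <- rbind(block_fps(12, 1:40, prefix = "a"),
               block_fps(12, 101:140, prefix = "b", seed = 5),
               block_fps(12, 201:240, prefix = "c", seed = 6))
  labels <- stats::setNames(rep(c(1L, 2L, 3L), each = 12), rownames(fps))
  asg <- structure(list(labels = labels, parameters = list()),
                   class = "cluster_assignment")
  scores <- score_table("R1",
    stats::setNames(-(36:1) / 10, rownames(fps)))  # a01 best ... c12 worst
  list(asg = asg, scores = scores, ids = rownames(fps))
}

test_that("unflagged clusters contribute one best-scoring candidate each", {
  fx <- slate_fixture()
  slate <- select_candidates(fx$ids, fx$asg, fx$scores)
  expect_equal(nrow(slate), 3)
  expect_equal(slate$molecule, c("a01", "b01", "c01"))
  expect_true(all(!slate$flagged))
})

test_that("flagged clusters contribute up to 5 available candidates", {
  fx <- slate_fixture()
  avail <- setdiff(fx$ids, c("a01", "a03", "a04", "a05", "a06"))  # 7 of 12 left
  slate <- select_candidates(fx$ids, fx$asg, fx$scores,
                             known_ligands = "a02", available = avail)
  fl <- slate[slate$flagged, ]
  expect_equal(nrow(fl), 5)
  expect_equal(fl$molecule, c("a02", "a07", "a08", "a09", "a10"))
  expect_true(all(fl$molecule %in% avail))
  # unflagged cluster with unavailable best falls back to second best
  avail2 <- setdiff(fx$ids, "b01")
  slate2 <- select_candidates(fx$ids, fx$asg, fx$scores, available = avail2)
  expect_true("b02" %in% slate2$molecule)
  expect_false("b01" %in% slate2$molecule)
})

test_that("noise molecules never enter the slate and size bounds hold", {
  fx <- slate_fixture()
  fx$asg$labels[c("c10", "c11", "c12")] <- NOISE
  slate <- select_candidates(fx$ids, fx$asg, fx$scores,
                             known_ligands = c("a02", "b02"))
  expect_false(any(c("c10", "c11", "c12") %in% slate$molecule))
  expect_lte(nrow(slate), 2 * 5 + 1)
  # clusters reported densest first
  expect_equal(slate$cluster_size, sort(slate$cluster_size, decreasing = TRUE))
  expect_error(select_candidates(character(), fx$asg, fx$scores), "empty")
})
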