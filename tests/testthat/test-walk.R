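test_that("walk parameters are validated", {
  expect_error(walk_params(removal_visits = 0), "removal_visits")
  expect_error(walk_params(n_walks = 0), "n_walks")
  expect_error(walk_params(gap_factor = 0), "gap_factor")
  expect_error(walk_params(break_frac = 1), "break_frac")
})

test_that("zero cross-similarity forces block exhaustion before crossing", {
  # two disconnected perfect pair blocks: the walk must finish one block
  # before any teleport can reach the other
  sim <- block_matrix(c(2, 2), within = 1, cross = 0)
  labels <- block_labels(c(2, 2))
  for (seed in 1:20) {
    w <- run_regulated_walk(dcgnet:::as_similarity(sim), walk_params(), seed = seed)
    first_two <- labels[w$removal_order[1:2]]
    expect_equal(first_two[1], first_two[2])
    expect_length(w$segments, 2)
    expect_setequal(vapply(w$segments, function(s) unique(labels[s]), integer(1)),
                    1:2)
  }
})

test_that("a single all-similar block yields one segment", {
  sim <- block_matrix(3, within = 1)
  for (seed in 1:20) {
    w <- run_regulated_walk(dcgnet:::as_similarity(sim), walk_params(), seed = seed)
    expect_length(w$segments, 1)
    expect_setequal(w$segments[[1]], 1:3)
  }
})

test_that("every node is removed exactly once and steps increase", {
  set.seed(1)
  m <- block_matrix(c(4, 3, 5), within = 0.8, cross = 0.05)
  w <- run_regulated_walk(dcgnet:::as_similarity(m), walk_params(), seed = 3)
  expect_setequal(w$removal_order, 1:12)
  expect_true(all(diff(w$removal_steps) > 0))
  expect_setequal(unlist(w$segments), 1:12)
})

test_that("planted three-block similarity is recovered by most walks", {
  sizes <- c(5, 5, 5)
  sim <- block_matrix(sizes, within = 0.9, cross = 0.01)
  labels <- block_labels(sizes)
  # assigning each node its segment's majority block should recover the
  # planted labels for most nodes of most walks (a single walk is noisy by
  # design; the ensemble average is tested separately)
  accuracy <- vapply(1:200, function(seed) {
    w <- run_regulated_walk(dcgnet:::as_similarity(sim), walk_params(),
                            seed = seed)
    assigned <- rep(NA_integer_, sum(sizes))
    for (seg in w$segments) {
      tab <- table(labels[seg])
      assigned[seg] <- as.integer(names(tab)[which.max(tab)])
    }
    mean(assigned == labels)
  }, numeric(1))
  expect_gte(mean(accuracy), 0.75)
  expect_gte(mean(accuracy >= 0.6), 0.9)
})

test_that("segment boundaries follow the gap, teleport and break rules", {
  # large central gap
  segs <- segment_removals(1:6, c(1, 2, 3, 40, 41, 42))
  expect_equal(segs, list(1:3, 4:6))
  # no spread, no boundary
  expect_length(segment_removals(1:5, c(2, 4, 6, 8, 10)), 1)
  # teleports cut even without a step gap
  segs <- segment_removals(1:4, 1:4, teleported = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(segs, list(1:2, 3:4))
  # similarity break: the middle link is far below its row-relative floor
  segs <- segment_removals(1:3, 1:3,
                           link_sims = c(1e-9, 0.5),
                           link_floors = c(1e-4, 1e-4))
  expect_equal(segs, list(1L, 2:3))
  # single node
  expect_equal(segment_removals(7L, 5L), list(7L))
})

test_that("sharing matrices are exact indicators for perfect blocks", {
  sim <- dcgnet:::as_similarity(block_matrix(c(2, 2), within = 1, cross = 0))
  p <- sharing_matrix(sim, walk_params(n_walks = 25, seed = 4))
  expect_equal(unname(p$values),
               unname(block_matrix(c(2, 2), within = 1, cross = 0)))

  # a single walk gives 0/1 indicators
  p1 <- sharing_matrix(sim, walk_params(n_walks = 1, seed = 9))
  expect_true(all(p1$values %in% c(0, 1)))
})

test_that("planted blocks dominate the sharing matrix", {
  sizes <- c(5, 5, 5)
  sim <- dcgnet:::as_similarity(block_matrix(sizes, within = 0.9, cross = 0.01))
  p <- sharing_matrix(sim, walk_params(n_walks = 100, seed = 11))
  labels <- block_labels(sizes)
  same <- outer(labels, labels, "==")
  off <- upper.tri(p$values)
  within_mean <- mean(p$values[same & off])
  cross_mean <- mean(p$values[!same & off])
  expect_gte(within_mean - cross_mean, 0.5)
})

test_that("sharing matrices are reproducible bit-for-bit under a seed", {
  sim <- dcgnet:::as_similarity(block_matrix(c(4, 4), within = 0.8, cross = 0.1))
  a <- sharing_matrix(sim, walk_params(seed = 42))
  b <- sharing_matrix(sim, walk_params(seed = 42))
  expect_identical(a$values, b$values)
  c <- sharing_matrix(sim, walk_params(seed = 43))
  expect_false(identical(a$values, c$values))
})

test_that("sharing probabilities are exchangeable under node relabeling", {
  sizes <- c(4, 4, 4)
  sim <- block_matrix(sizes, within = 0.9, cross = 0.02)
  perm <- c(5, 9, 1, 12, 3, 7, 2, 11, 6, 10, 4, 8)
  sim_p <- sim[perm, perm]
  dimnames(sim_p) <- dimnames(sim)
  p1 <- sharing_matrix(dcgnet:::as_similarity(sim), walk_params(seed = 2))$values
  p2 <- sharing_matrix(dcgnet:::as_similarity(sim_p), walk_params(seed = 2))$values
  # permuting inputs permutes the expected sharing; compare up to Monte-Carlo
  # tolerance on the block means
  labels <- block_labels(sizes)
  same <- outer(labels, labels, "==") & upper.tri(sim)
  same_p <- outer(labels[perm], labels[perm], "==") & upper.tri(sim)
  expect_lt(abs(mean(p1[same]) - mean(p2[same_p])), 0.1)
  expect_lt(abs(mean(p1[!same & upper.tri(sim)]) -
                  mean(p2[!same_p & upper.tri(sim)])), 0.1)
})

test_that("an all-zero similarity row is handled by teleports, not errors", {
  m <- block_matrix(c(2, 2), within = 1, cross = 0)
  m[3, ] <- m[, 3] <- 0
  diag(m) <- 1
  w <- run_regulated_walk(dcgnet:::as_similarity(m), walk_params(), seed = 5)
  expect_setequal(w$removal_order, 1:4)
})
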