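test_that("Rand index matches hand-computed cases", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(rand_index(c(1, 1, 1), c(1, 2, 3)), 0.0)
  # {a,b}{c,d} vs {a,b,c}{d}: pairs ab, cd agree-same/disagree, ... -> 3/6
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0.5)
})

test_that("named partitions are aligned by element name", {
  a <- c(x = 1, y = 1, z = 2)
  b <- c(z = 9, x = 4, y = 4)   # same partition, scrambled order and labels
  expect_equal(rand_index(a, b), 1.0)
  expect_error(rand_index(a, c(q = 1, r = 2, s = 3)), "different element sets")
})

test_that("Rand index agrees with the brute-force oracle exhaustively", {
  # all partition pairs on up to 5 elements (the 6-element sweep runs in
  # the acceptance suite)
  for (n in 2:5) {
    parts <- all_partitions(n)
    grid <- expand.grid(a = seq_along(parts), b = seq_along(parts))
    got <- mapply(function(i, j) rand_index(parts[[i]], parts[[j]]),
                  grid$a, grid$b)
    want <- mapply(function(i, j) rand_oracle(parts[[i]], parts[[j]]),
                   grid$a, grid$b)
    expect_identical(got, want)
  }
})

test_that("retention features cover the identity and merged extremes", {
  atlas <- make_atlas(c(P = 2L, Q = 2L))
  # membership identical to regions
  lev <- list(membership = stats::setNames(c(1L, 1L, 2L, 2L), 1:4))
  f <- retention_features(lev, atlas)
  expect_named(f, c("intra_P", "intra_Q", "inter_P_Q"))
  expect_equal(unname(f), c(1, 1, 0))
  # one global cluster retains everything
  lev1 <- list(membership = stats::setNames(rep(1L, 4), 1:4))
  expect_equal(unname(retention_features(lev1, atlas)), c(1, 1, 1))
})

test_that("retention features match hand enumeration on a 4-ROI toy", {
  atlas <- make_atlas(c(P = 2L, Q = 2L))
  # clusters {1,2,3},{4}: intra P = 1, intra Q = 0, inter = 2/4
  lev <- list(membership = stats::setNames(c(1L, 1L, 1L, 2L), 1:4))
  f <- retention_features(lev, atlas)
  expect_equal(unname(f), c(1, 0, 0.5))
})

test_that("retention features ignore cluster label permutations", {
  atlas <- make_atlas(c(P = 4L, Q = 2L))
  mem <- stats::setNames(c(1L, 1L, 2L, 2L, 3L, 3L), 1:6)
  relab <- stats::setNames(c(7L, 7L, 5L, 5L, 9L, 9L), 1:6)
  expect_equal(retention_features(list(membership = mem), atlas),
               retention_features(list(membership = relab), atlas))
})

test_that("the default atlas produces the canonical 55 feature labels", {
  atlas <- make_atlas()
  mem <- stats::setNames(rep(1L, nrow(atlas)), atlas$roi_id)
  f <- retention_features(list(membership = mem), atlas)
  expect_length(f, 55)
  expect_identical(sum(startsWith(names(f), "intra_")), 10L)
  expect_identical(sum(startsWith(names(f), "inter_")), 45L)
  # intra features come first, in atlas region order
  expect_identical(names(f)[1:2], c("intra_Subcortical", "intra_Parietal"))
})

test_that("feature screening keeps direction and cutoff semantics", {
  set.seed(31)
  asd <- matrix(rnorm(29 * 3, mean = c(0, 0, 1)), 29, 3, byrow = TRUE,
                dimnames = list(NULL, c("f1", "f2", "f3")))
  td <- matrix(rnorm(29 * 3, mean = 0), 29, 3,
               dimnames = list(NULL, c("f1", "f2", "f3")))
  res <- screen_features(asd, td, p_cut = 0.05)
  expect_true("f3" %in% res$feature)
  expect_identical(res$direction[res$feature == "f3"], "ASD")

  # identical groups select nothing
  expect_identical(nrow(screen_features(td, td, p_cut = 0.105)), 0L)

  # forced sign: ASD all near 1, TD all near 0
  asd1 <- matrix(1 + rnorm(10, sd = 0.01), 5, 2)
  td1 <- matrix(rnorm(10, sd = 0.01), 5, 2)
  res1 <- screen_features(asd1, td1)
  expect_identical(nrow(res1), 2L)
  expect_true(all(res1$t > 0))
})

test_that("screening t-values match the Welch formula to 1e-10", {
  set.seed(5)
  asd <- matrix(rnorm(40), 10, 4)
  td <- matrix(rnorm(48, mean = 0.3), 12, 4)
  res <- screen_features(asd, td, all = TRUE)
  for (j in 1:4) {
    manual <- (mean(asd[, j]) - mean(td[, j])) /
      sqrt(var(asd[, j]) / 10 + var(td[, j]) / 12)
    expect_equal(res$t[j], manual, tolerance = 1e-10)
  }
})

test_that("zero-variance features are dropped with a warning", {
  asd <- cbind(const = rep(1, 5), ok = rnorm(5))
  td <- cbind(const = rep(1, 5), ok = rnorm(5))
  expect_warning(res <- screen_features(asd, td, all = TRUE), "zero-variance")
  expect_identical(res$feature, "ok")
})

test_that("a planted regional shift is detected by the screen", {
  # dedicated design: a strong between-region correlation increase in ASD
  # merges the two regions' geometry, which the retention features pick up
  shift <- data.frame(region_a = "A", region_b = "B", group = "ASD",
                      delta = 0.3)
  design <- cohort_design(n_per_group = 8L, trials = "green",
                          region_counts = c(A = 4L, B = 4L, C = 2L),
                          regional_shifts = shift)
  hits <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    cohort <- simulate_cohort(design, seed = 100 + r)
    feats <- cohort_coarse_features(cohort, k_target = 3L,
                                    t_grid = default_t_grid(n = 10),
                                    params = walk_params(seed = r))
    cols <- grep("^(intra|inter)_", names(feats), value = TRUE)
    asd <- as.matrix(feats[feats$group == "ASD", cols])
    td <- as.matrix(feats[feats$group == "TD", cols])
    res <- suppressWarnings(screen_features(asd, td, p_cut = 0.105))
    if ("inter_A_B" %in% res$feature &&
        res$direction[res$feature == "inter_A_B"] == "ASD") {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_rep, 0.95)
})
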