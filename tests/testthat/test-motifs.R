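test_that("motif identifiers are canonical under member ordering", {
  expect_identical(motif_id(c(88, 87)), "87,88")
  expect_identical(motif_id(c(3, 1, 2)), "1,2,3")
  expect_identical(motif_members("87,88"), c(87L, 88L))
  expect_error(motif_id(c("a", "b")), "integer")
})

test_that("configurations are extracted from pair-block sharing", {
  p <- block_matrix(c(2, 2), within = 1, cross = 0)
  cfg <- motif_configuration(dcgnet:::as_sharing(p), prune_height = 0.85)
  expect_identical(cfg$motifs, c("1,2", "3,4"))

  # all off-diagonal sharing zero: all singletons, empty configuration
  p0 <- diag(4); dimnames(p0) <- list(1:4, 1:4)
  cfg0 <- motif_configuration(dcgnet:::as_sharing(p0), prune_height = 0.85)
  expect_length(cfg0$motifs, 0)

  expect_error(motif_configuration(dcgnet:::as_sharing(p), prune_height = 0),
               "prune_height")
})

test_that("configurations are invariant to input ROI ordering", {
  p <- block_matrix(c(2, 3), within = 0.95, cross = 0.02)
  perm <- c(4, 1, 5, 2, 3)
  pp <- p[perm, perm]
  dimnames(pp) <- list(rownames(p)[perm], colnames(p)[perm])
  c1 <- motif_configuration(dcgnet:::as_sharing(p), 0.85)
  c2 <- motif_configuration(dcgnet:::as_sharing(pp), 0.85)
  expect_identical(c1$motifs, c2$motifs)
})

test_that("motif domains count exact-set prevalence", {
  c1 <- make_config(list(c(87, 88), c(1, 2)), subject_id = "a")
  c2 <- make_config(list(c(88, 87)), subject_id = "b")
  dom <- motif_domain(list(c1, c2))
  expect_identical(unname(dom$prevalence["87,88"]), 2L)
  expect_identical(unname(dom$prevalence["1,2"]), 1L)
  expect_identical(dom$n_subjects, 2L)

  # disjoint configurations: every prevalence is one
  d1 <- make_config(list(c(1, 2)), subject_id = "a")
  d2 <- make_config(list(c(3, 4)), subject_id = "b")
  expect_true(all(motif_domain(list(d1, d2))$prevalence == 1L))

  # mixed groups are rejected
  c3 <- make_config(list(c(5, 6)), subject_id = "c", group = "TD")
  expect_error(motif_domain(list(c1, c3)), "mix")
})

test_that("prevalence is conserved between configurations and domains", {
  set.seed(8)
  configs <- lapply(1:10, function(i) {
    carried <- which(runif(12) < 0.6)
    make_config(lapply(carried, function(k) c(2 * k - 1, 2 * k)),
                subject_id = paste0("s", i))
  })
  dom <- motif_domain(configs)
  expect_identical(sum(dom$prevalence),
                   sum(lengths(lapply(configs, `[[`, "motifs"))))
})

test_that("domain restriction thresholds prevalence and is monotone", {
  dom <- make_domain(c(`1,2` = 14L, `3,4` = 15L, `5,6` = 2L))
  expect_identical(names(restrict_domain(dom, 15)$prevalence), "3,4")
  expect_identical(restrict_domain(dom, 1)$prevalence, dom$prevalence)
  expect_length(restrict_domain(dom, 99)$prevalence, 0)
  expect_error(restrict_domain(dom, 0), "tau")

  for (tau1 in 1:5) {
    for (tau2 in tau1:5) {
      r1 <- restrict_domain(dom, tau1)$prevalence
      r2 <- restrict_domain(dom, tau2)$prevalence
      expect_true(all(names(r2) %in% names(r1)))
    }
  }
})

test_that("odds scores follow the prevalence ratio and its symmetries", {
  da <- make_domain(c(`87,88` = 10L), group = "ASD")
  dt <- make_domain(c(`87,88` = 21L), group = "TD")
  cfg <- make_config(list(c(87, 88)))
  # equal-size domains: the score is the plain log prevalence ratio,
  # negative = TD-favoring
  expect_equal(odds_score(cfg, da, dt), log(10 / 21))
  expect_lt(odds_score(cfg, da, dt), 0)

  # no motifs in either restricted domain
  empty <- make_domain(stats::setNames(integer(0), character(0)))
  expect_identical(odds_score(cfg, empty, empty), 0)

  # log-symmetric cancellation: ratios 2 and 1/2
  da2 <- make_domain(c(`1,2` = 20L, `3,4` = 10L))
  dt2 <- make_domain(c(`1,2` = 10L, `3,4` = 20L), group = "TD")
  cfg2 <- make_config(list(c(1, 2), c(3, 4)))
  expect_equal(odds_score(cfg2, da2, dt2), 0)

  # antisymmetry under swapping the domains
  set.seed(3)
  da3 <- make_domain(c(`1,2` = 7L, `3,4` = 18L, `5,6` = 25L))
  dt3 <- make_domain(c(`1,2` = 12L, `3,4` = 18L, `5,6` = 4L), group = "TD")
  cfg3 <- make_config(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(odds_score(cfg3, da3, dt3), -odds_score(cfg3, dt3, da3))
})

test_that("missing counts track restricted-domain membership", {
  da <- make_domain(c(`1,2` = 20L))
  dt <- make_domain(c(`1,2` = 20L, `3,4` = 16L), group = "TD")
  cfg <- make_config(list(c(1, 2), c(3, 4)))
  expect_identical(missing_counts(cfg, da, dt),
                   c(miss_asd = 1L, miss_td = 0L))
  empty_cfg <- make_config(list())
  expect_identical(missing_counts(empty_cfg, da, dt),
                   c(miss_asd = 0L, miss_td = 0L))
})

test_that("the tau = 15 worked example restricts as described", {
  # a motif with prevalence 14 (ASD) and 16 (TD) drops out of the restricted
  # ASD domain only, so a carrier contributes one ASD-missing count
  da <- restrict_domain(make_domain(c(`5,6` = 14L)), 15)
  dt <- restrict_domain(make_domain(c(`5,6` = 16L), group = "TD"), 15)
  cfg <- make_config(list(c(5, 6)))
  expect_identical(missing_counts(cfg, da, dt),
                   c(miss_asd = 1L, miss_td = 0L))
})

test_that("motif tables mirror the two-domain summary layout", {
  da <- make_domain(c(`87,88` = 10L, `1,2` = 26L))
  dt <- make_domain(c(`87,88` = 21L, `1,2` = 22L, `9,10` = 3L), group = "TD")
  tab <- motif_table(da, dt)
  expect_named(tab, c("motif", "prevalence_asd", "prevalence_td",
                      "abs_difference"))
  expect_identical(tab$abs_difference[tab$motif == "87,88"], 11L)
  expect_identical(tab$prevalence_asd[tab$motif == "9,10"], 0L)
  expect_identical(tab$motif[1], "87,88")   # sorted by decreasing difference
})
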