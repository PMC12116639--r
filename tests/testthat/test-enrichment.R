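# The odds-ratio, KS and gene-set statistics against enumeration and
# brute-force oracles, plus the direction-consistency rule.

test_that("the odds ratio follows the (td/tn)/(nd/nn) formula", {
  universe <- paste0("g", 1:1100)
  targets <- universe[1:100]        # td = 30, tn = 70
  regulated <- c(universe[1:30], universe[101:200])  # nd = 100
  fo <- fisher_or(targets, regulated, universe)
  expect_equal(c(fo$td, fo$tn, fo$nd, fo$nn), c(30, 70, 100, 900))
  expect_equal(fo$odds_ratio, (30 / 70) / (100 / 900))
  expect_equal(fo$odds_ratio, 27 / 7)
  # proportional targets give OR = 1
  u2 <- paste0("h", 1:100)
  fo2 <- fisher_or(u2[1:20], c(u2[1:10], u2[21:60]), u2)  # td/tn = nd/nn = 1/1
  expect_equal(fo2$odds_ratio, 1)
  # degenerate margins hit the +inf sentinel
  fo3 <- fisher_or(u2[1:50], u2[1:50], u2)
  expect_equal(fo3$odds_ratio, Inf)
})

test_that("one-sided Fisher p equals the hypergeometric enumeration oracle", {
  set.seed(17)
  for (i in 1:60) {
    n_tot <- sample(10:40, 1)
    universe <- paste0("g", seq_len(n_tot))
    targets <- sample(universe, sample(1:(n_tot - 1), 1))
    regulated <- sample(universe, sample(1:(n_tot - 1), 1))
    fo <- fisher_or(targets, regulated, universe)
    expect_equal(fo$p, oracle_hyper_p(fo$td, fo$tn, fo$nd, fo$nn),
                 tolerance = 1e-12)
    # independent cross-check against the standard exact test
    ft <- fisher.test(matrix(c(fo$td, fo$nd, fo$tn, fo$nn), 2),
                      alternative = "greater")
    expect_equal(fo$p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("the contingency reacts to universe edits only through tn/nn", {
  universe <- paste0("g", 1:200)
  targets <- universe[1:40]
  regulated <- universe[c(1:10, 51:70)]
  fo <- fisher_or(targets, regulated, universe)
  # removing a gene outside both sets changes only tn/nn
  fo2 <- fisher_or(targets, regulated, setdiff(universe, "g200"))
  expect_equal(c(fo2$td, fo2$nd), c(fo$td, fo$nd))
  expect_equal(fo2$nn, fo$nn - 1)
  # relabeling genes leaves everything unchanged
  relab <- setNames(paste0("x", 1:200), universe)
  fo3 <- fisher_or(relab[targets], relab[regulated], relab[universe])
  expect_equal(fo3[c("td", "tn", "nd", "nn", "p")],
               fo[c("td", "tn", "nd", "nn", "p")])
})

test_that("KS distance matches forced cases and the double-loop oracle", {
  fc <- c(a = -1, b = -2, c = 1, d = 2)
  ks <- ks_seed_enrichment(fc, c("a", "b"))
  expect_equal(ks$D, 1)              # disjoint supports
  expect_equal(ks$direction, -1)
  fc2 <- c(a = 1, b = 2, c = 1, d = 2)
  expect_equal(ks_seed_enrichment(fc2, c("a", "b"))$D, 0)  # identical multisets
  fc3 <- c(a = 0, b = 2, c = 1)
  expect_equal(ks_seed_enrichment(fc3, c("a", "b"))$D, 0.5)
  set.seed(18)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    v <- setNames(round(rnorm(n), 2), paste0("g", seq_len(n)))
    tg <- sample(names(v), sample(2:(n - 2), 1))
    ks <- ks_seed_enrichment(v, tg)
    expect_identical(ks$D, oracle_ks_D(v[tg], v[setdiff(names(v), tg)]))
    # asymptotic p agrees with the standard two-sample test
    suppressWarnings(
      ref <- ks.test(unname(v[tg]), unname(v[setdiff(names(v), tg)]),
                     exact = FALSE))
    expect_equal(ks$p, ref$p.value, tolerance = 5e-4)
  }
  expect_error(ks_seed_enrichment(fc, names(fc)), "partition is empty")
})

test_that("direction consistency requires opposite signs and rejects zero shift", {
  up_targets_down <- list(direction = -1)
  expect_true(direction_consistent(1, up_targets_down))
  # the down-isomiR-with-down-targets pattern is excluded
  expect_false(direction_consistent(-1, up_targets_down))
  expect_false(direction_consistent(1, list(direction = 0)))
  expect_true(direction_consistent(-2, list(direction = 1)))
})

test_that("gene-set enrichment singles out a planted set and zeroes disjoint ones", {
  set.seed(19)
  universe <- paste0("g", 1:500)
  down <- universe[1:50]
  sets <- list(HIT = down,
               MISS = universe[451:500],
               RAND1 = sample(universe, 50),
               RAND2 = sample(universe, 50))
  gs <- geneset_enrichment(down, sets, universe)
  expect_equal(gs$set[1], "HIT")
  expect_lt(gs$p[gs$set == "HIT"], min(gs$p[gs$set != "HIT"]))
  expect_equal(gs$odds_ratio[gs$set == "MISS"], 0)
  expect_true(gs$enriched[gs$set == "HIT"])
  # p equals the enumeration oracle on a small universe
  u <- paste0("u", 1:30)
  gs2 <- geneset_enrichment(u[1:6], list(s = u[4:12]), u)
  td <- 3; tn <- 6; nd <- 3; nn <- 18
  expect_equal(gs2$p, oracle_hyper_p(td, tn, nd, nn), tolerance = 1e-12)
})

test_that("null KS enrichment stays at the nominal rate across seeds", {
  hits <- 0; tests <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    lfc <- setNames(rnorm(800), paste0("g", 1:800))
    ps <- vapply(1:12, function(i)
      ks_seed_enrichment(lfc, sample(names(lfc), 60))$p, numeric(1))
    hits <- hits + sum(ps < 0.05)
    tests <- tests + length(ps)
  }
  rate <- hits / tests
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / tests))
})

test_that("planted repression is detected with OR > 1 and a consistent direction", {
  ok <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    universe <- paste0("g", 1:2000)
    lfc <- setNames(rnorm(2000, 0, 0.5), universe)
    targets <- sample(universe, 100)
    lfc[targets] <- lfc[targets] - 1
    ks <- ks_seed_enrichment(lfc, targets)
    down <- names(lfc)[lfc < -0.7]
    fo <- fisher_or(targets, down, universe)
    if (ks$p < 0.05 && fo$odds_ratio > 1 && direction_consistent(1, ks))
      ok <- ok + 1
  }
  expect_gte(ok, 9)
})
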