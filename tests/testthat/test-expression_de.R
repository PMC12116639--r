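# Normalization, BH, the NB-Wald test and the selection filters, against
# direct-recomputation oracles and analytically forced cases.

test_that("size factors match the median-of-ratios definition", {
  # counts (k, 2k) in every feature force factors (1/sqrt(2), sqrt(2))
  m <- cbind(s1 = c(10, 100, 7), s2 = c(20, 200, 14))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)))
  # identical samples give unit factors
  m2 <- cbind(a = c(5, 8, 2), b = c(5, 8, 2), c = c(5, 8, 2))
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
  # random matrix vs feature-by-feature recomputation
  set.seed(3)
  r <- matrix(rpois(250, 40) + 1, 50, 5,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:5)))
  r[sample(250, 20)] <- 0
  sf <- size_factors(r)
  ok <- apply(r, 1, function(x) all(x > 0))
  geo <- apply(r[ok, ], 1, function(x) prod(x)^(1 / length(x)))
  brute <- vapply(1:5, function(j) median(r[ok, j] / geo), numeric(1))
  expect_equal(unname(sf), brute)
  # independent cross-check against the reference median-of-ratios code
  # (even-length medians interpolate on the log scale there, hence the
  # loose tolerance)
  ref_sf <- DESeq2::estimateSizeFactorsForMatrix(r)
  expect_equal(unname(sf), unname(ref_sf), tolerance = 1e-3)
  expect_error(size_factors(diag(3)), "undefined")
})

test_that("scaling one sample's counts scales its relative size factor accordingly", {
  set.seed(4)
  m <- matrix(rpois(200, 50) + 1, 40, 5)
  sf <- size_factors(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  sf2 <- size_factors(m2)
  # the factor relative to any other sample scales by c; the raw factor
  # absorbs c^((n-1)/n) because the per-feature geometric means move too
  expect_equal((sf2[3] / sf2[1]) / (sf[3] / sf[1]), 4, tolerance = 1e-12)
  expect_equal(sf2[3] / sf[3], 4^(4 / 5), tolerance = 1e-12)
})

test_that("RPM columns sum to one million", {
  expect_equal(unname(to_rpm(cbind(a = c(50, 50)))[, 1]), c(5e5, 5e5))
  expect_equal(unname(to_rpm(cbind(a = 7))[1, 1]), 1e6)
  set.seed(5)
  r <- matrix(rpois(300, 30), 60, 5)
  r[1, ] <- r[1, ] + 1
  expect_equal(unname(colSums(to_rpm(r))), rep(1e6, 5), tolerance = 1e-6)
  expect_error(to_rpm(cbind(a = c(0, 0))), "zero column")
})

test_that("FPKM matches its defining formula", {
  m <- matrix(1e6, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(unname(to_fpkm(m, c(g1 = 1000))[1, 1]), 1e6)
  set.seed(6)
  nc <- matrix(runif(50, 10, 500), 10, 5,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  len <- setNames(sample(500:3000, 10), paste0("g", 1:10))
  fp <- to_fpkm(nc, len)
  brute <- nc
  for (j in 1:5) for (i in 1:10)
    brute[i, j] <- nc[i, j] / (len[i] / 1e3) / (sum(nc[, j]) / 1e6)
  expect_equal(fp, brute)
  # doubling one gene's length halves its FPKM under the fixed denominator
  len2 <- len; len2["g3"] <- len["g3"] * 2
  expect_equal(to_fpkm(nc, len2)["g3", ], fp["g3", ] / 2)
  expect_error(to_fpkm(nc, len[-3]), "missing gene length")
})

test_that("BH q-values equal the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(7)
  for (i in 1:30) {
    p <- runif(sample(1:8, 1))^2
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  # min-over-suffix formulation, exhaustive over all orderings at n = 4
  base <- c(0.008, 0.04, 0.21, 0.6)
  perms <- rbind(c(1,2,3,4), c(4,3,2,1), c(2,4,1,3), c(3,1,4,2))
  for (k in seq_len(nrow(perms))) {
    p <- base[perms[k, ]]
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  expect_error(bh_fdr(c(0.1, NA)), "NaN|NA")
})

test_that("the NB-Wald test is calibrated under the null and label-symmetric", {
  set.seed(8)
  n <- 1000
  mu <- rlnorm(n, log(300), 1)
  cnt <- sapply(1:15, function(j) rnbinom(n, mu = mu, size = 10))
  rownames(cnt) <- paste0("f", 1:n)
  grp <- rep(c("a", "b"), c(7, 8))
  de <- nb_wald_de(cnt, grp)
  expect_gt(mean(de$p < 0.05), 0.02)
  expect_lt(mean(de$p < 0.05), 0.09)
  expect_true(all(de$q >= de$p - 1e-12))
  # swapping the reference group negates every log2 FC, p unchanged
  de2 <- nb_wald_de(cnt, factor(grp, levels = c("b", "a")))
  expect_equal(de2$log2FC, -de$log2FC, tolerance = 1e-12)
  expect_equal(de2$p, de$p, tolerance = 1e-12)
  # sample-permuted identical groups at low dispersion: median |log2FC| small
  cnt2 <- sapply(1:15, function(j) rnbinom(n, mu = mu, size = 100))
  rownames(cnt2) <- paste0("f", 1:n)
  expect_lt(median(abs(nb_wald_de(cnt2, grp)$log2FC)), 0.1)
  expect_error(nb_wald_de(cnt[, 1:3], c("a", "a", "b")), ">= 2 samples")
})

test_that("planted effects are recovered with small bias at moderate depth", {
  set.seed(9)
  n <- 1200
  mu <- rlnorm(n, log(400), 0.8)
  lfc <- rep(0, n); aff <- 1:80
  mu[aff] <- pmax(mu[aff], 200)
  lfc[aff] <- sample(c(-1.5, 1.5), 80, TRUE)
  cnt <- sapply(1:15, function(j)
    rnbinom(n, mu = if (j > 7) mu * 2^lfc else mu, size = 10))
  rownames(cnt) <- paste0("f", 1:n)
  de <- nb_wald_de(cnt, rep(c("a", "b"), c(7, 8)))
  expect_gte(mean(de$q[aff] < 0.05 & abs(de$log2FC[aff]) > 1), 0.8)
  expect_lt(mean(abs(de$log2FC[aff] - lfc[aff])), 0.25)
})

test_that("abundance selection applies the RPM floor then the cumulative rule", {
  mean_rpm <- c(a = 5e5, b = 3e5, c = 1.5e5, d = 3e4, e = 1.5e4, f = 5e3)
  rpm <- cbind(mean_rpm, mean_rpm)  # two identical samples
  sel <- select_abundant(rpm, filter_thresholds(cum_fraction = 0.95))
  expect_equal(sel, c("a", "b", "c"))   # 0.5 + 0.3 + 0.15 = 0.95
  sel_all <- select_abundant(rpm, filter_thresholds(cum_fraction = 1.0))
  expect_equal(sel_all, c("a", "b", "c", "d", "e", "f"))
  # brute-force prefix search on a random vector
  set.seed(10)
  v <- sort(runif(40, 0, 1e5), decreasing = TRUE)
  names(v) <- sprintf("i%02d", 1:40)
  rpm2 <- cbind(v, v)
  th <- filter_thresholds(min_mean_rpm = 100, cum_fraction = 0.9)
  sel2 <- select_abundant(rpm2, th)
  kept <- v[v > 100]
  shares <- cumsum(kept) / sum(v)
  expect_equal(sel2, names(kept)[seq_len(which(shares >= 0.9)[1])])
  expect_error(select_abundant(rpm[0, , drop = FALSE]), "empty")
})

test_that("top-expressed selection sorts by mean FPKM with label tie-break", {
  fp <- cbind(s1 = c(g1 = 5, g2 = 9, g3 = 2))
  expect_equal(select_top_expressed(fp, 1), "g2")
  expect_equal(sort(select_top_expressed(fp, 3)), c("g1", "g2", "g3"))
  set.seed(11)
  fp2 <- matrix(runif(100), 20, 5,
                dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:5)))
  got <- select_top_expressed(fp2, 7)
  expect_equal(got,
               names(sort(rowMeans(fp2), decreasing = TRUE))[1:7])
  expect_error(select_top_expressed(fp2, 50), "exceeds")
})

test_that("DE classification honors the fold rule for genes but not isomiRs by default", {
  de <- data.frame(feature = c("x", "y", "z"),
                   log2FC = c(0.5, 1.5, -1.5),
                   q = c(0.01, 0.01, 0.2))
  th <- filter_thresholds()
  g <- classify_de(de, th, apply_fold = TRUE)
  expect_equal(g$direction, c("ns", "up", "ns"))
  i <- classify_de(de, th, apply_fold = th$fold_applies_to_isomirs)
  expect_equal(i$direction, c("up", "up", "ns"))
})
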