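test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 40, 80, 5, 100,
                10, 20, 40, 80, 5, 100), ncol = 2,
              dimnames = list(sprintf("b%d", 1:6), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))
  m2 <- cbind(m[, 1, drop = FALSE], s2 = 2 * m[, 1])
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  # invariant to bin order
  set.seed(1)
  m3 <- matrix(rpois(60, 50) + 1, ncol = 3)
  rownames(m3) <- sprintf("b%d", 1:20); colnames(m3) <- sprintf("s%d", 1:3)
  expect_equal(estimate_size_factors(m3),
               estimate_size_factors(m3[sample(20), ]))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  m <- matrix(rnbinom(80, mu = 100 * rep(c(1, 2, 0.5, 1), each = 20),
                      size = 5) + 1, ncol = 4)
  rownames(m) <- sprintf("b%d", 1:20)
  colnames(m) <- sprintf("s%d", 1:4)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  got <- estimate_size_factors(m)
  # identical up to the geometric-mean rescaling
  expect_equal(unname(got / ref), rep(unname(got[1] / ref[1]), 4),
               tolerance = 1e-8)
})

test_that("bin inputs complement the feature totals", {
  m <- matrix(c(3, 7, 5, 2, 8, 1), ncol = 2,
              dimnames = list(c("a:1", "a:2", "b:1"), c("s1", "s2")))
  feature <- c("a:1" = "a", "a:2" = "a", "b:1" = "b")
  inp <- build_bin_inputs(m, feature, conditions = c(1, 2))
  expect_equal(unname(inp$o["a:1", ]), c(7, 8))
  expect_equal(unname(inp$o["a:2", ]), c(3, 2))
  expect_false(inp$testable[["b:1"]])
  expect_true(all(inp$y + inp$o ==
                    rbind(m[1, ] + m[2, ], m[1, ] + m[2, ], m[3, ])))
})

test_that("dispersion estimation recovers Poisson and overdispersed data", {
  set.seed(61)
  cond <- rep(1:2, each = 25); sf <- rep(1, 50)
  y <- rpois(50, 400); o <- rpois(50, 1500)
  expect_lt(estimate_dispersion(y, o, cond, sf), 0.01)
  hits <- replicate(30, {
    y <- rnbinom(50, mu = 400, size = 5); o <- rnbinom(50, mu = 1500, size = 5)
    est <- estimate_dispersion(y, o, cond, sf)
    est > 0.1 && est < 0.4
  })
  expect_gte(mean(hits), 0.9)
})

test_that("dispersion and p-values are invariant to joint count/offset scaling", {
  set.seed(62)
  cond <- rep(1:2, each = 3); sf <- c(0.8, 1, 1.2, 0.9, 1.1, 1)
  y <- rnbinom(6, mu = 300 * sf, size = 20)
  o <- rnbinom(6, mu = 900 * sf, size = 20)
  d1 <- estimate_dispersion(y, o, cond, sf)
  # rescaling the size factors alone shifts only the offsets: exact
  expect_equal(d1, estimate_dispersion(y, o, cond, 5 * sf),
               tolerance = 1e-6)
  p1 <- test_bin(y, o, cond, sf, 0.05)$p_value
  expect_equal(p1, test_bin(y, o, cond, 5 * sf, 0.05)$p_value,
               tolerance = 1e-9)
  # doubling counts and size factors together changes only the
  # discreteness of the data: near-invariance
  d2 <- estimate_dispersion(2 * y, 2 * o, cond, 2 * sf)
  expect_equal(d1, d2, tolerance = 0.1)
  p2 <- test_bin(3 * y, 3 * o, cond, 3 * sf, 0.05)$p_value
  expect_equal(p1, p2, tolerance = 0.05)
})

test_that("the dispersion trend recovers a planted b0 + b1/mu law", {
  set.seed(63)
  mu <- exp(runif(500, log(10), log(5000)))
  disp <- (0.02 + 5 / mu) * exp(rnorm(500, 0, 0.3))
  tr <- fit_dispersion_trend(disp, mu)
  expect_lt(abs(tr["b0"] - 0.02) / 0.02, 0.3)
  expect_lt(abs(tr["b1"] - 5) / 5, 0.3)
  # constant dispersions give a flat trend at that constant
  tr2 <- fit_dispersion_trend(rep(0.07, 50), mu[1:50])
  expect_equal(unname(tr2["b0"]), 0.07, tolerance = 0.01)
  expect_equal(unname(tr2["b1"]), 0, tolerance = 1)
  # the trend tends to b0 for large mu
  expect_equal(unname(dtubench:::eval_trend(tr, 1e12)), unname(tr["b0"]),
               tolerance = 1e-6)
  # too few bins: constant fallback at the median
  expect_message(tr3 <- fit_dispersion_trend(rep(0.2, 5), rep(100, 5)),
                 "constant")
  expect_equal(unname(tr3["b0"]), 0.2)
})

test_that("shrinkage pulls estimates toward the trend but keeps outliers", {
  set.seed(64)
  cond <- rep(1:2, each = 3); sf <- rep(1, 6)
  y <- rnbinom(6, mu = 500, size = 10); o <- rnbinom(6, mu = 1500, size = 10)
  raw <- estimate_dispersion(y, o, cond, sf)
  # prior centered on the estimate: stays put
  same <- shrink_dispersion(y, o, cond, sf, raw, raw, 0.5)
  expect_equal(log(same), log(raw), tolerance = 0.05)
  # very wide prior: also stays put
  wide <- shrink_dispersion(y, o, cond, sf, raw, raw * 4, 50)
  expect_equal(log(wide), log(raw), tolerance = 0.05)
  # moderate prior strictly between estimate and trend
  trend <- raw * 3
  mid <- shrink_dispersion(y, o, cond, sf, raw, trend, 0.4)
  expect_gt(mid, raw); expect_lt(mid, trend)
  # far above the trend: outlier rule keeps the raw value
  out <- shrink_dispersion(y, o, cond, sf, raw, raw / 20, 0.25)
  expect_identical(out, raw)
})

test_that("the LRT is null at no signal and matches a 2x2 oracle at high counts", {
  cond <- rep(1:2, each = 3); sf <- rep(1, 6)
  flat <- test_bin(rep(100, 6), rep(300, 6), cond, sf, 0.05)
  expect_lt(flat$lrt_stat, 1e-6)
  expect_gt(flat$p_value, 0.999)
  # strong switch: (y,o) = (1000,1000) vs (2000,500)
  y <- c(1000, 1000, 1000, 2000, 2000, 2000)
  o <- c(1000, 1000, 1000, 500, 500, 500)
  strong <- test_bin(y, o, cond, sf, 0.01)
  expect_lt(strong$p_value, 1e-6)
  # chi-square test on the pooled 2x2 table as an independent anchor:
  # -log10 p within a factor of two (Poisson-limit comparison, phi -> 0)
  tiny <- test_bin(y, o, cond, sf, 1e-8)
  oracle <- chisq.test(rbind(c(3000, 3000), c(6000, 1500)),
                       correct = FALSE)
  r <- -log10(tiny$p_value) / -log10(oracle$p.value)
  expect_gt(r, 0.5); expect_lt(r, 2)
})

test_that("bin p-values are uniform under a known-dispersion null", {
  set.seed(65)
  cond <- rep(1:2, each = 3); sf <- rep(1, 6)
  pv <- replicate(400, {
    mu_y <- runif(1, 50, 500)
    y <- rnbinom(6, mu = mu_y, size = 1 / 0.05)
    o <- rnbinom(6, mu = 4 * mu_y, size = 1 / 0.05)
    test_bin(y, o, cond, sf, 0.05)$p_value
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("independent filtering thresholds the mean normalized count", {
  m <- matrix(c(0, 0, 0, 10, 6, 2, 4, 8, 12, 100, 90, 110, 3, 3, 3,
                7, 7, 7), ncol = 3, byrow = TRUE,
              dimnames = list(sprintf("b%d", 1:6), c("s1", "s2", "s3")))
  sf <- rep(1, 3)
  keep <- independent_filter(m, sf, 5)
  expect_equal(unname(keep), unname(rowMeans(m) >= 5))
  expect_false(keep[["b1"]])
  expect_true(all(independent_filter(m, sf, 0)))
})

test_that("gene-level aggregation follows the Sidak family bound", {
  br <- data.frame(bin_id = sprintf("b%d", 1:11),
                   feature_id = c("gA", rep("gB", 10)),
                   p_value = c(0.05, 0.01, runif(9, 0.3, 0.9)),
                   tested = TRUE)
  gr <- per_gene_qvalues(br)
  expect_equal(gr$gene_p[gr$feature_id == "gA"], 0.05)
  expect_equal(gr$gene_p[gr$feature_id == "gB"], 1 - 0.99^10,
               tolerance = 1e-12)
  # all equal gene p-values: q equals p under BH
  br2 <- data.frame(bin_id = c("x", "y"), feature_id = c("g1", "g2"),
                    p_value = c(0.2, 0.2), tested = TRUE)
  gr2 <- per_gene_qvalues(br2)
  expect_equal(gr2$q_value, c(0.2, 0.2))
  # monotone in theta and n
  p_small <- 1 - (1 - 0.01)^3
  p_big <- 1 - (1 - 0.02)^5
  expect_lt(p_small, p_big)
})

test_that("dtu_test is invariant to sample permutation with matched labels", {
  set.seed(66)
  sim <- sim_bin_counts(30, mu = 800, phi = 0.05, switch_first = FALSE)
  fit1 <- dtu_test(sim$counts, sim$conditions, sim$feature)
  perm <- c(4, 1, 5, 2, 6, 3)
  fit2 <- dtu_test(sim$counts[, perm], sim$conditions[perm], sim$feature)
  expect_equal(fit1$gene_results$q_value, fit2$gene_results$q_value,
               tolerance = 1e-6)
})

test_that("dtu_test controls the null and detects strong switches", {
  set.seed(67)
  null <- sim_bin_counts(100, mu = 700, phi = 0.04)
  fit <- dtu_test(null$counts, null$conditions, null$feature)
  expect_lte(mean(fit$gene_results$q_value < 0.05), 0.1)
  strong <- sim_bin_counts(40, mu = 2000, phi = 0.01,
                           switch_first = TRUE)
  fit2 <- dtu_test(strong$counts, strong$conditions, strong$feature)
  expect_gte(mean(fit2$gene_results$q_value < 0.01), 0.8)
})

test_that("single-bin features and all-filtered features get no q-value", {
  m <- matrix(rep(c(50, 2), each = 6), ncol = 6, byrow = TRUE,
              dimnames = list(c("gA:1", "gB:1"),
                              sprintf("s%d", 1:6)))
  feature <- c("gA:1" = "gA", "gB:1" = "gB")
  expect_warning(fit <- dtu_test(m, rep(1:2, each = 3), feature),
                 "no testable bins")
  expect_equal(nrow(fit$gene_results), 0L)
})

test_that("fixed dispersions bypass estimation for calibration studies", {
  set.seed(68)
  sim <- sim_bin_counts(10, mu = 500, phi = 0.05)
  disp <- setNames(rep(0.05, nrow(sim$counts)), rownames(sim$counts))
  fit <- dtu_test(sim$counts, sim$conditions, sim$feature,
                  dispersions = disp)
  expect_true(all(fit$bin_results$dispersion[fit$bin_results$tested] ==
                    0.05))
})
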