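test_that("the worked example and symmetry cases are exact", {
  ut <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_equal(ut@uStatistic, 0)
  expect_equal(ut@pTwoSided, 1 / 3)
  expect_equal(ut@method, "exact")
  same <- mannWhitneyU(5, 5)
  expect_equal(same@uStatistic, 1 * 1 / 2)
  expect_equal(same@pTwoSided, 1)
  expect_error(mannWhitneyU(numeric(), 1), "non-empty")
})

test_that("exact p equals the enumeration oracle for all tie-free n1 = n2 <= 4", {
  for (n in 1:4) {
    picks <- combn(2 * n, n)
    for (j in seq_len(ncol(picks))) {
      a <- picks[, j]
      b <- setdiff(seq_len(2 * n), a)
      ut <- mannWhitneyU(a, b)
      expect_equal(ut@method, "exact")
      expect_equal(ut@pTwoSided, oracleUTwoSided(a, b), tolerance = 1e-12)
    }
  }
})

test_that("exact branch agrees with wilcox.test on random tie-free samples", {
  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(1000, n1 + n2)
    a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
    ut <- mannWhitneyU(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ut@uStatistic, unname(ref$statistic))
    expect_equal(ut@pTwoSided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("U_a + U_b = n1 n2 holds on 1000 random tied samples", {
  set.seed(12)
  for (rep in 1:1000) {
    n1 <- sample(1:12, 1); n2 <- sample(1:12, 1)
    a <- sample(0:5, n1, TRUE); b <- sample(0:5, n2, TRUE)
    ua <- mannWhitneyU(a, b)@uStatistic
    ub <- mannWhitneyU(b, a)@uStatistic
    expect_equal(ua + ub, n1 * n2)
    expect_true(ua >= 0 && ua <= n1 * n2)
  }
})

test_that("normal approximation tracks the exact p for n1 = n2 = 6", {
  set.seed(77)
  for (rep in 1:30) {
    v <- sample(10000, 12)
    a <- v[1:6]; b <- v[7:12]
    pExact <- oracleUTwoSided(a, b)
    # force the approximation branch by adding a distant tie-free pair? No:
    # call the internal approximation via a 13-value sample is a different
    # problem; instead compare the implementation's two branches directly.
    ut <- mannWhitneyU(a, b)
    mu <- 18; sigma2 <- 6 * 6 / 12 * 13
    z <- max(0, (abs(ut@uStatistic - mu) - 0.5) / sqrt(sigma2))
    pApprox <- min(1, 2 * pnorm(-z))
    expect_lt(abs(pExact - pApprox), 0.02)
  }
})

test_that("tie-corrected approximation agrees with wilcox.test", {
  set.seed(55)
  for (rep in 1:20) {
    a <- sample(0:8, 15, TRUE); b <- sample(0:8, 18, TRUE)
    ut <- mannWhitneyU(a, b)
    expect_equal(ut@method, "normal_approx_tie_corrected")
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(ut@pTwoSided, ref$p.value, tolerance = 1e-9)
  }
})

test_that("group comparison applies the chosen unit of analysis", {
  gA <- data.frame(volume_id = rep(c("a1", "a2"), each = 8),
                   length_um = c(1:8, 3:10),
                   avg_cross_section_um2 = 1)
  gB <- data.frame(volume_id = rep(c("b1", "b2"), each = 8),
                   length_um = c(11:18, 13:20),
                   avg_cross_section_um2 = 1)
  seg <- compareGroups(gA, gB, "length_um", unit = "segment")
  expect_equal(seg$n, c(16L, 16L))
  expect_true(seg$significant)
  expect_equal(seg$method, "normal_approx_tie_corrected")
  vm <- compareGroups(gA, gB, "length_um", unit = "volume_mean")
  expect_equal(vm$n, c(2L, 2L))
  expect_equal(vm$method, "exact")
  one <- gA[gA$volume_id == "a1", ]
  expect_error(compareGroups(one, gB, "length_um", unit = "volume_mean"),
               "at least 2 volumes")
})

test_that("8 vs 8 distinct values use the approximation branch", {
  set.seed(2)
  a <- sample(1000, 8); b <- sample(2000:3000, 8)
  ut <- mannWhitneyU(a, b)
  expect_equal(ut@method, "normal_approx_tie_corrected")
})

test_that("comparison reports serialize to CSV and JSON", {
  gA <- data.frame(volume_id = "a", length_um = c(1, 2, 5),
                   avg_cross_section_um2 = c(2, 2, 3))
  gB <- data.frame(volume_id = "b", length_um = c(7, 8, 12),
                   avg_cross_section_um2 = c(4, 5, 6))
  cmp <- compareGroups(gA, gB, "length_um")
  base <- tempfile()
  writeComparison(cmp, base)
  csv <- read.csv(paste0(base, ".csv"))
  expect_equal(csv$u_statistic, cmp$u_statistic)
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(js$p_two_sided[1], cmp$p_two_sided)
})
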