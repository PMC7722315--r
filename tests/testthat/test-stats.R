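test_that("2x2 chi-square matches the corrected and classical formulas", {
  t0 <- matrix(c(10, 10, 10, 10), 2)
  r0 <- chi_square_2x2(t0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  t1 <- matrix(c(30, 10, 70, 90), 2)
  expect_equal(chi_square_2x2(t1)$statistic, 11.28125)
  expect_equal(chi_square_2x2(t1, yates = FALSE)$statistic, 12.5)
  # row swap leaves the statistic unchanged
  expect_equal(chi_square_2x2(t1[2:1, ])$statistic,
               chi_square_2x2(t1)$statistic)
  expect_true(is.na(chi_square_2x2(matrix(c(5, 0, 0, 0), 2))$p))
  set.seed(31)
  for (i in 1:100) {
    tb <- matrix(sample(1:30, 4, replace = TRUE), 2)
    expect_equal(chi_square_2x2(tb)$statistic, oracle_chi2(tb))
    un <- chi_square_2x2(tb, yates = FALSE)$statistic
    expect_equal(un, oracle_chi2(tb, yates = FALSE))
    # classical closed form N(ad-bc)^2 / product of margins
    expect_equal(un, sum(tb) * (tb[1, 1] * tb[2, 2] -
                                  tb[1, 2] * tb[2, 1])^2 /
                   prod(rowSums(tb), colSums(tb)))
  }
})

test_that("one-tailed Fisher equals hypergeometric enumeration", {
  expect_equal(fisher_one_tailed(matrix(c(2, 0, 0, 2), 2)), 1 / 6)
  expect_equal(fisher_one_tailed(matrix(c(0, 2, 2, 0), 2)), 1)
  expect_equal(fisher_one_tailed(matrix(c(5, 0, 0, 0), 2)), 1)
  set.seed(32)
  for (i in 1:150) {
    tb <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tb) == 0 || sum(tb) > 40) next
    expect_equal(fisher_one_tailed(tb),
                 oracle_fisher_greater(tb[1, 1], tb[1, 2],
                                       tb[2, 1], tb[2, 2]))
  }
})

test_that("rank-sum test matches exact enumeration for small samples", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6), 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2)), 1)
  set.seed(33)
  for (i in 1:40) {
    nx <- sample(2:4, 1)
    ny <- sample(2:4, 1)
    x <- round(rnorm(nx), 4)  # continuous draws: no ties
    y <- round(rnorm(ny), 4)
    expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcox_two_sided(x, y))
  }
})

test_that("exact and approximate rank-sum p agree for moderate n", {
  set.seed(34)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- rnorm(15)
    exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE)$p.value)
    expect_lt(abs(wilcoxon_rank_sum(x, y) - exact), 0.011)
    expect_lt(abs(exact - approx), 0.011)
  }
})

test_that("Welch t-test is symmetric and agrees with a permutation p", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  x <- c(1.2, 3.4, 0.8, 2.2, 1.7)
  y <- c(2.5, 4.1, 3.3, 2.9)
  flip <- welch_t_test(-x, -y)
  expect_equal(flip$t, -welch_t_test(x, y)$t)
  expect_equal(flip$p, welch_t_test(x, y)$p)
  expect_warning(welch_t_test(c(1, 1), c(1, 1)), "zero variance")
  set.seed(35)
  x <- rnorm(10)
  y <- rnorm(10, mean = 1)
  pw <- welch_t_test(x, y)$p
  pooled <- c(x, y)
  tobs <- abs(welch_t_test(x, y)$t)
  perm <- replicate(4000, {
    idx <- sample(20, 10)
    abs(welch_t_test(pooled[idx], pooled[-idx])$t)
  })
  expect_lt(abs(pw - mean(perm >= tobs)), 0.05)
})

test_that("BH adjustment equals the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(36)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
    # identical rejection counts at several levels
    for (q in c(0.05, 0.1, 0.3)) {
      expect_equal(sum(bh_adjust(p) <= q), sum(oracle_bh(p) <= q))
    }
  }
})

test_that("empirical p uses the add-one estimator", {
  expect_equal(empirical_p(10, rep(1, 100)), 1 / 101)
  expect_equal(empirical_p(5, rep(5, 100)), 1)
  expect_equal(empirical_p(0, c(-1, 1)), 2 / 3)
})

test_that("GO enrichment tests qualifying terms with fold and Fisher p", {
  go <- data.frame(
    rbp = c("A", "B", "C", "A", "X"),
    term = c("t1", "t1", "t1", "t2", "t3"),
    domain = "BP")
  all_rbps <- c(LETTERS[1:10])
  out <- go_enrichment(c("A", "B"), all_rbps, go)
  expect_false("t2" %in% out$term)  # single-RBP terms excluded
  expect_false("t3" %in% out$term)  # annotation outside background dropped
  row <- out[out$term == "t1", ]
  expect_equal(row$fold, (2 / 2) / (3 / 10))
  expect_equal(row$p, oracle_fisher_greater(2, 0, 1, 7))
  # subset 2/10 vs background 2/100 is a 10-fold enrichment
  pool <- sprintf("R%03d", 1:100)
  go2 <- data.frame(rbp = pool[1:2], term = "t")
  out2 <- go_enrichment(pool[1:10], pool, go2)
  expect_equal(out2$fold, 10)
  # subset == background gives fold 1 everywhere
  out3 <- go_enrichment(pool, pool, go2)
  expect_equal(out3$fold, 1)
  expect_error(go_enrichment(c("ZZZ"), all_rbps, go), "contained")
})

test_that("co-localization counts shared-compartment pairs", {
  circ <- data.frame(circ_id = c("c1", "c1", "c2", "c3"),
                     compartment = c("cytoplasm", "nucleus", "cytoplasm",
                                     "cytoplasm"))
  rbp <- data.frame(rbp = c("r1", "r2", "r2"),
                    compartment = c("nucleus", "nucleus", "cytoplasm"))
  inter <- data.frame(circ_id = c("c1", "c2", "c3", "c9"),
                      rbp = c("r1", "r2", "r1", "r1"))
  out <- colocalization_fraction(inter, circ, rbp)
  expect_equal(out$n_resolved, 3)
  expect_equal(out$n_colocalized, 2)   # c1-r1 share nucleus; c2-r2 cytoplasm
  expect_equal(out$percent, 100 * 2 / 3)
  expect_equal(out$n_unresolved, 1)    # c9 missing from the table
})
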