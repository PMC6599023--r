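test_that("published worked examples are reproduced at printed precision", {
  # patient vs control allele-count enrichment
  expect_equal(signif(fisher_two_sided(table2x2(14, 648, 148, 24610)), 2),
               9.2e-5)
  # solved-cases vs controls: OR, CI, p
  t_solved <- table2x2(6, 716, 148, 24610)
  expect_equal(round(cmle_odds_ratio(t_solved), 1), 1.4)
  expect_equal(round(fisher_two_sided(t_solved), 2), 0.46)
  ci <- exact_ci(t_solved)
  expect_equal(round(ci[["low"]], 2), 0.50)
  expect_equal(ci[["high"]], 3.12, tolerance = 0.01)
  # enrichment arithmetic and multiple-testing threshold
  expect_equal(round(fold_enrichment(14 / 662, 148 / 24758), 1), 3.5)
  expect_equal(signif(bonferroni_threshold(0.05, 178), 3), 2.81e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
})

test_that("small-table p-values match hand enumeration", {
  # symmetric table: identical rows
  expect_equal(fisher_two_sided(table2x2(1, 9, 1, 9)), 1.0)
  # 2 alt alleles among margins (10, 10): p = 2 * 45/190
  expect_equal(fisher_two_sided(table2x2(2, 8, 0, 10)), 2 * 45 / 190)
  # degenerate: one table consistent with margins
  expect_equal(fisher_two_sided(table2x2(0, 5, 0, 7)), 1.0)
  expect_equal(fisher_two_sided(table2x2(5, 0, 7, 0)), 1.0)
})

test_that("invalid tables are rejected", {
  expect_error(table2x2(-1, 2, 3, 4), "non-negative")
  expect_error(table2x2(0, 0, 3, 4), "at least one allele")
  expect_error(table2x2(1.5, 2, 3, 4), "integers")
  expect_error(exact_ci(table2x2(1, 2, 3, 4), level = 1.2), "probability")
})

test_that("two-sided p equals the enumeration oracle exhaustively (n <= 30)", {
  worst <- 0
  for (n1 in 1:29) for (n2 in 1:(30 - n1)) for (S in 0:(n1 + n2)) {
    k <- max(0, S - n2):min(n1, S)
    for (a in k) {
      p_impl <- fisher_two_sided(table2x2(a, n1 - a, S - a, n2 - (S - a)))
      worst <- max(worst, abs(p_impl - oracle_fisher_p(a, n1 - a, S - a,
                                                       n2 - (S - a))))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("p-values agree with stats::fisher.test on random tables", {
  for (x in random_tables(150, 300, seed = 42)) {
    ft <- stats::fisher.test(matrix(x, 2, byrow = TRUE))
    expect_equal(fisher_two_sided(table2x2(x[1], x[2], x[3], x[4])),
                 ft$p.value, tolerance = 1e-9)
  }
})

test_that("p is invariant under simultaneous row and column swap", {
  for (x in random_tables(60, 150, seed = 5)) {
    expect_equal(fisher_two_sided(table2x2(x[1], x[2], x[3], x[4])),
                 fisher_two_sided(table2x2(x[4], x[3], x[2], x[1])))
  }
})

test_that("upper tail P(A >= a) weakly decreases as a grows at fixed b,c,d", {
  for (bcd in list(c(8, 3, 10), c(2, 5, 5), c(20, 1, 30))) {
    tails <- vapply(0:10, function(a) {
      t <- table2x2(a, bcd[1], bcd[2], bcd[3])
      sup <- quasimendel:::support2x2(t)
      w <- exp(sup$logp0 - max(sup$logp0)); w <- w / sum(w)
      sum(w[sup$k >= a])
    }, numeric(1))
    expect_true(all(diff(tails) <= 1e-12))
  }
})

test_that("CMLE odds ratio matches likelihood-maximization oracle and fisher.test", {
  for (x in random_tables(200, 200, seed = 9)) {
    or <- cmle_odds_ratio(table2x2(x[1], x[2], x[3], x[4]))
    gold <- oracle_cmle(x[1], x[2], x[3], x[4])
    if (is.finite(or) && or > 0) {
      expect_equal(or, gold, tolerance = 1e-4)
    } else {
      expect_identical(or, gold)
    }
  }
  # boundary of support
  expect_identical(cmle_odds_ratio(table2x2(0, 10, 5, 5)), 0)
  expect_identical(cmle_odds_ratio(table2x2(10, 0, 5, 5)), Inf)
  # degenerate: no alt alleles anywhere
  expect_true(is.na(cmle_odds_ratio(table2x2(0, 10, 0, 5))))
})

test_that("exact CI inverts the tail tests and brackets the CMLE", {
  # frozen: bisection inversion of the enumerated tails for (2,8,0,10)
  expect_equal(exact_ci(table2x2(2, 8, 0, 10)),
               c(low = oracle_ci(2, 8, 0, 10)[1], high = Inf),
               tolerance = 1e-3)
  expect_equal(exact_ci(table2x2(0, 10, 5, 5))[["low"]], 0)
  for (x in random_tables(100, 200, seed = 21)) {
    t <- table2x2(x[1], x[2], x[3], x[4])
    or <- cmle_odds_ratio(t)
    ci <- exact_ci(t)
    if (is.finite(or) && or > 0) {
      expect_lte(ci[["low"]], or)
      expect_gte(ci[["high"]], or)
    }
    # the returned bounds solve the tail equations
    if (anyNA(ci)) next
    if (ci[["low"]] > 0) {
      expect_equal(oracle_nch_tail(x[1], x[2], x[3], x[4], ci[["low"]], "ge"),
                   0.025, tolerance = 1e-5)
    }
    if (is.finite(ci[["high"]])) {
      expect_equal(oracle_nch_tail(x[1], x[2], x[3], x[4], ci[["high"]], "le"),
                   0.025, tolerance = 1e-5)
    }
  }
})

test_that("HWE exact test matches enumeration and handles edge cases", {
  expect_equal(hwe_exact(7, 0, 0), 1.0)
  expect_equal(hwe_exact(0, 0, 9), 1.0)
  # frozen from the enumeration oracle: 12 individuals, 4 alt alleles
  expect_equal(hwe_exact(9, 2, 1), 0.2546584, tolerance = 1e-7)
  expect_equal(hwe_exact(9, 2, 1), oracle_hwe(9, 2, 1))
  # counts at exact HWE proportions sit at the mode
  expect_gte(hwe_exact(25, 50, 25), 0.99)
  set.seed(13)
  for (i in 1:60) {
    n <- sample(5:80, 1)
    g <- table(factor(rbinom(n, 2, runif(1, 0.1, 0.9)), levels = 0:2))
    expect_equal(hwe_exact(g[1], g[2], g[3]), oracle_hwe(g[1], g[2], g[3]),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact(0, 0, 0), "summing")
})

test_that("HWE p-values are super-uniform under the null", {
  set.seed(31)
  m <- 2000
  p <- vapply(seq_len(m), function(i) {
    g <- table(factor(rbinom(80, 2, runif(1, 0.1, 0.5)), levels = 0:2))
    hwe_exact(g[1], g[2], g[3])
  }, numeric(1))
  for (alpha in c(0.01, 0.05)) {
    expect_lte(mean(p <= alpha), alpha + 2 * sqrt(alpha * (1 - alpha) / m))
  }
})

test_that("heterozygote-excess tail flags het-heavy sites", {
  # 50/50 het column: enormous excess relative to HWE
  expect_lt(hwe_excess_het(0, 50, 0), 1e-10)
  # no excess: upper tail includes the bulk of the distribution
  expect_gt(hwe_excess_het(25, 50, 25), 0.5)
  # one-sided tail is the sum of enumerated masses at or above the count
  expect_equal(hwe_excess_het(9, 2, 1),
               oracle_nch_het_tail <- {
                 h <- c(0, 2, 4)
                 pr <- vapply(h, function(hh) {
                   haa <- (4 - hh) / 2
                   exp(lfactorial(12) - lfactorial(12 - hh - haa) -
                         lfactorial(hh) - lfactorial(haa) + hh * log(2) +
                         lfactorial(4) + lfactorial(20) - lfactorial(24))
                 }, numeric(1))
                 sum(pr[h >= 2]) / sum(pr)
               })
})

test_that("fold enrichment and its degenerate inputs behave", {
  expect_equal(fold_enrichment(0.3, 0.3), 1.0)
  expect_equal(fold_enrichment(0, 0.2), 0.0)
  expect_error(fold_enrichment(0.1, 0), "> 0")
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})
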