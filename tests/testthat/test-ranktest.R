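test_that("circular ranks map joint order to equally spaced scores", {
  rp <- circular_ranks(c(0.1, 0.3), c(0.2, 0.4))
  expect_equal(rp$scores_1, c(pi / 2, 3 * pi / 2))
  expect_equal(rp$scores_2, c(pi, 2 * pi))
  expect_equal(rp$n, 4L)

  # combined scores are exactly the lattice {2*pi*r/n}
  set.seed(5)
  for (i in 1:10) {
    n1 <- sample(2:20, 1)
    n2 <- sample(2:20, 1)
    rp <- circular_ranks(runif(n1, 0, 2 * pi), runif(n2, 0, 2 * pi))
    all_scores <- sort(c(rp$scores_1, rp$scores_2))
    expect_equal(all_scores, 2 * pi * seq_len(n1 + n2) / (n1 + n2))
  }
})

test_that("ranking preserves each population's circular order", {
  # two overlapping von Mises clouds, as in a prestim/poststim contrast
  pop1 <- rvonmises(15, theta = 0, kappa = 4, seed = 21)
  pop2 <- rvonmises(15, theta = pi / 4, kappa = 4, seed = 22)
  rp <- circular_ranks(pop1, pop2)
  # within each population, sorting original angles sorts the scores the
  # same way (rank transformation is monotone from 0 around the circle)
  expect_equal(order(as.numeric(pop1)), order(rp$scores_1))
  expect_equal(order(as.numeric(pop2)), order(rp$scores_2))
  # and across populations: any pop1 angle below a pop2 angle keeps its
  # score below that pop2 angle's score
  cmp_angles <- outer(as.numeric(pop1), as.numeric(pop2), `<`)
  cmp_scores <- outer(rp$scores_1, rp$scores_2, `<`)
  expect_identical(cmp_angles, cmp_scores)
})

test_that("tied angles are split reproducibly without distorting spacing", {
  pop1 <- c(0.5, 0.5, 1.0)
  pop2 <- c(0.5, 2.0)
  rp1 <- circular_ranks(pop1, pop2, tie_seed = 3)
  rp2 <- circular_ranks(pop1, pop2, tie_seed = 3)
  expect_identical(rp1, rp2)
  expect_equal(
    sort(c(rp1$scores_1, rp1$scores_2)),
    2 * pi * (1:5) / 5
  )
})

test_that("the two population resultants give the same statistic", {
  set.seed(8)
  for (i in 1:20) {
    rp <- circular_ranks(
      runif(sample(2:15, 1), 0, 2 * pi),
      runif(sample(2:15, 1), 0, 2 * pi)
    )
    s1 <- ust_statistic(rp, k = 1)
    s2 <- ust_statistic(rp, k = 2)
    expect_equal(s1$R_squared, s2$R_squared, tolerance = 1e-10)
    expect_equal(s1$R_star, s2$R_star, tolerance = 1e-10)
  }
})

test_that("alternating ranks cancel and hand-computed cases agree", {
  # strictly alternating ranks: population scores are evenly spaced vectors
  m <- 6
  pop1 <- (2 * pi * (2 * (1:m) - 1) / (2 * m)) - 1e-4
  pop2 <- 2 * pi * (2 * (1:m)) / (2 * m) - 2e-4
  rp <- circular_ranks(pop1, pop2)
  expect_lt(ust_statistic(rp)$R_squared, 1e-10)

  # n1 = n2 = 3, fixed rank assignment {1, 4, 5} for population 1
  rp <- circular_ranks(c(0.05, 0.8, 1.0), c(0.2, 0.4, 1.5))
  expect_equal(rank(c(0.05, 0.8, 1.0, 0.2, 0.4, 1.5))[1:3], c(1, 4, 5))
  expect_equal(
    ust_statistic(rp)$R_star,
    oracle_rstar_from_ranks(c(1, 4, 5), 3, 3),
    tolerance = 1e-12
  )

  # the "root" reading of the normalization, for comparison only
  expect_equal(
    ust_statistic(rp, normalization = "root")$R_star,
    2 * 5 * sqrt(ust_statistic(rp)$R_squared) / 9,
    tolerance = 1e-12
  )
})

test_that("the two-sample test separates well-separated populations", {
  pop1 <- rvonmises(25, theta = 0, kappa = 50, seed = 31)
  pop2 <- rvonmises(25, theta = pi, kappa = 50, seed = 32)
  res <- ustpl_test(pop1, pop2,
    mode = "permutation",
    n_permutations = 1e4, seed = 33
  )
  expect_lt(res$p_value, 0.001)
  expect_equal(res$mode, "permutation")
  res_asym <- ustpl_test(pop1, pop2, mode = "auto")
  expect_equal(res_asym$mode, "asymptotic")
  expect_lt(res_asym$p_value, 1e-6)
})

test_that("auto mode upgrades small samples to exact enumeration", {
  pop1 <- rvonmises(5, 0, 2, seed = 41)
  pop2 <- rvonmises(5, 1, 2, seed = 42)
  res <- ustpl_test(pop1, pop2, mode = "auto", seed = 43)
  expect_equal(res$mode, "exact")
  expect_equal(res$n_permutations, choose(10, 5))
  expect_equal(res$p_value, oracle_exact_ustpl_p(
    as.numeric(pop1),
    as.numeric(pop2)
  ))
})

test_that("Monte-Carlo permutation agrees with exact enumeration", {
  set.seed(55)
  for (i in 1:5) {
    pop1 <- runif(5, 0, 2 * pi)
    pop2 <- runif(5, 0, 2 * pi)
    p_exact <- oracle_exact_ustpl_p(pop1, pop2)
    res <- ustpl_test(pop1, pop2,
      mode = "permutation",
      n_permutations = 2000, seed = i, exact_cap = 1
    )
    se <- sqrt(p_exact * (1 - p_exact) / 2000)
    expect_lt(abs(res$p_value - p_exact), 2 * se + 2 / 2000)
  }
})

test_that("asymptotic p ranks instances like the exact p", {
  set.seed(77)
  p_exact <- p_asym <- numeric(0)
  for (m in c(4, 5, 6)) {
    for (i in 1:17) {
      pop1 <- runif(m, 0, 2 * pi)
      pop2 <- runif(m, 0, 2 * pi)
      p_exact <- c(p_exact, oracle_exact_ustpl_p(pop1, pop2))
      p_asym <- c(
        p_asym,
        ustpl_test(pop1, pop2, mode = "asymptotic")$p_value
      )
    }
  }
  expect_gt(cor(p_exact, p_asym, method = "spearman"), 0.95)
})

test_that("test statistic and p-values are rotation invariant", {
  pop1 <- rvonmises(12, 0.3, 3, seed = 61)
  pop2 <- rvonmises(14, 1.1, 1, seed = 62)
  base <- ustpl_test(pop1, pop2, mode = "asymptotic")
  for (shift in c(0.5, pi / 3, 2, 5.5)) {
    rot <- ustpl_test(as.numeric(pop1) + shift, as.numeric(pop2) + shift,
      mode = "asymptotic"
    )
    expect_equal(rot$statistic, base$statistic, tolerance = 1e-10)
    expect_equal(rot$p_value, base$p_value, tolerance = 1e-10)
  }
})

test_that("the test is symmetric in its two populations", {
  pop1 <- rvonmises(10, 0, 2, seed = 71)
  pop2 <- rvonmises(20, 2, 5, seed = 72)
  a <- ustpl_test(pop1, pop2, mode = "asymptotic")
  b <- ustpl_test(pop2, pop1, mode = "asymptotic")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("null R* has mean 2 and near-uniform asymptotic p-values", {
  set.seed(123)
  n_rep <- 4000
  rstar <- replicate(n_rep, {
    ust_statistic(circular_ranks(
      runif(25, 0, 2 * pi),
      runif(25, 0, 2 * pi)
    ))$R_star
  })
  se <- sd(rstar) / sqrt(n_rep)
  expect_lt(abs(mean(rstar) - 2), 3 * se)
  p <- pchisq(rstar, 2, lower.tail = FALSE)
  # approximately uniform on (0, 1]: coarse histogram within MC error
  bins <- table(cut(p, seq(0, 1, 0.2)))
  expect_true(all(abs(bins / n_rep - 0.2) < 3 * sqrt(0.2 * 0.8 / n_rep) + 0.02))
})

test_that("power against a concentrated alternative grows with kappa", {
  n_rep <- 400
  rates <- vapply(c(1, 4, 20, 50), function(kappa) {
    rej <- vapply(seq_len(n_rep), function(i) {
      pop1 <- rvonmises(30, 0, kappa, seed = 1000 * kappa + i)
      pop2 <- rvonmises(30, 0, 0, seed = 2000 * kappa + i)
      ustpl_test(pop1, pop2, mode = "asymptotic")$p_value < 0.05
    }, logical(1))
    mean(rej)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[4], 0.95)
})

test_that("generic permutation p-value handles ties and errors cleanly", {
  pop1 <- rvonmises(10, 0, 3, seed = 81)
  pop2 <- rvonmises(10, 0, 3, seed = 82)
  # constant statistic: every permutation ties the observed value
  res <- permutation_pvalue(function(a, b) 1, pop1, pop2,
    n_permutations = 100, seed = 1
  )
  expect_equal(res$p, 1)
  # identical samples, |PLV difference|: observed 0, all permutations >= 0
  res <- permutation_pvalue(
    function(a, b) abs(plv(a) - plv(b)),
    pop1, pop1,
    n_permutations = 100, seed = 2
  )
  expect_equal(res$p, 1)
  # errors in the statistic are reported with the permutation index
  # (first call computes the observed value, later calls are permutations)
  flaky <- local({
    calls <- 0L
    function(a, b) {
      calls <<- calls + 1L
      if (calls > 1L) stop("boom")
      1
    }
  })
  expect_error(
    permutation_pvalue(flaky, pop1, pop2, n_permutations = 5, seed = 3),
    "permutation 1.*boom"
  )
})

test_that("result container enforces the p-value range", {
  expect_error(
    test_result("USTPL", 1, p_value = 0, n1 = 5, n2 = 5),
    "\\(0, 1\\]"
  )
  expect_error(
    test_result("USTPL", 1, p_value = 1.2, n1 = 5, n2 = 5),
    "\\(0, 1\\]"
  )
  r <- test_result("PLV", 0.5, p_value = 0.2, n1 = 5, n2 = 5)
  expect_s3_class(r, "test_result")
})
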