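# Independent oracles used to freeze expected values. Deliberately written
# from the defining formulas, not by calling the package's own code paths.

# Trapezoid-rule quadrature of a function over [0, 2*pi).
oracle_quadrature <- function(f, n_grid = 1e5) {
  x <- seq(0, 2 * pi, length.out = n_grid + 1)
  y <- f(x)
  sum((y[-1] + y[-length(y)]) / 2) * (2 * pi / n_grid)
}

# Von Mises density straight from its definition (unstabilized).
oracle_vm_density <- function(x, theta, kappa) {
  exp(kappa * cos(x - theta)) / (2 * pi * besselI(kappa, 0))
}

# Mean resultant length of a von Mises distribution by quadrature
# (no Bessel-ratio shortcut).
oracle_vm_resultant <- function(kappa, n_grid = 1e5) {
  oracle_quadrature(function(x) cos(x) * oracle_vm_density(x, 0, kappa), n_grid)
}

# Probability mass of von Mises(0, kappa) within +/- delta of the mean.
oracle_vm_mass_within <- function(kappa, delta, n_grid = 1e5) {
  x <- seq(-delta, delta, length.out = n_grid + 1)
  y <- oracle_vm_density(x, 0, kappa)
  sum((y[-1] + y[-length(y)]) / 2) * (2 * delta / n_grid)
}

# Mann-Whitney AUC by brute-force pairwise comparison, ties counted 1/2.
oracle_auc_pairwise <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Direct evaluation of the normalized uniform-scores statistic from a rank
# assignment: ranks_1 are population 1's joint ranks among n = n1 + n2.
oracle_rstar_from_ranks <- function(ranks_1, n1, n2) {
  n <- n1 + n2
  beta <- 2 * pi * ranks_1 / n
  r2 <- sum(cos(beta))^2 + sum(sin(beta))^2
  2 * (n - 1) * r2 / (n1 * n2)
}

# Exact permutation p-value of the uniform-scores test by full enumeration
# over all choose(n, n1) rank assignments. Assumes no ties among angles.
oracle_exact_ustpl_p <- function(pop1, pop2) {
  n1 <- length(pop1)
  n2 <- length(pop2)
  n <- n1 + n2
  pooled <- c(pop1, pop2) %% (2 * pi)
  stopifnot(anyDuplicated(pooled) == 0L)
  ranks_1 <- rank(pooled)[seq_len(n1)]
  obs <- oracle_rstar_from_ranks(ranks_1, n1, n2)
  all_r <- utils::combn(n, n1)
  null_vals <- apply(all_r, 2, oracle_rstar_from_ranks, n1 = n1, n2 = n2)
  mean(null_vals >= obs - 1e-12)
}

# Invert the von Mises mean-resultant relation rho = A(kappa) numerically,
# using the quadrature resultant (not besselI) as the forward map.
oracle_kappa_from_resultant <- function(rho) {
  stats::uniroot(function(k) oracle_vm_resultant(k, n_grid = 2e4) - rho,
    c(1e-3, 500),
    tol = 1e-7
  )$root
}

# Wrap helper for tests comparing angles on the circle.
wrap_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
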