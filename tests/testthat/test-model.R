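test_that("copy-state adjustment rescales counts and masks zero states", {
  C <- matrix(c(100L, 50L, 80L, 60L), 2, 2)
  S <- matrix(1, 2, 2)
  expect_equal(adjusted_counts(C, S), C + 0)
  S[1, 1] <- 0.5
  expect_equal(adjusted_counts(C, S)[1, 1], 200)
  S[2, 2] <- 0
  expect_true(is.na(adjusted_counts(C, S)[2, 2]))
})

test_that("size factors are 1 under symmetry and follow depth ratios", {
  C <- matrix(rep(c(100, 200, 300, 400), 3), ncol = 3)
  expect_equal(unname(size_factors(C)), rep(1, 3))

  # subject 2 = 2 x subject 1: g_j = c_1j * sqrt(2), f = (1/sqrt2, sqrt2)
  c1 <- c(50, 120, 300, 1000)
  C2 <- cbind(c1, 2 * c1)
  expect_equal(unname(size_factors(C2)), c(1 / sqrt(2), sqrt(2)))

  # median over targets is order-free
  perm <- c(3, 1, 4, 2)
  expect_equal(size_factors(C2[perm, ]), size_factors(C2))
})

test_that("size factors honor the subset threshold and name failing subjects", {
  # all counts below the subset threshold for subject "B"
  C <- cbind(A = c(100, 200, 300), B = c(4, 5, 6))
  expect_error(size_factors(C), "subject B")
  # zero in one subject zeroes the geometric mean, excluding that target
  C3 <- cbind(A = c(100, 200, 50), B = c(100, 0, 50), C = c(100, 200, 50))
  f <- size_factors(C3, min_count = 10)
  expect_true(all(is.finite(f) & f > 0))
})

test_that("method-of-moments dispersion matches hand arithmetic", {
  f <- c(1, 1, 1)
  # {90,100,110}: mean 100, sample var 100 -> phi = 0 (floored difference)
  r <- mom_dispersion(cbind(90, 100, 110) + matrix(0, 1, 3), f)
  expect_equal(r$mu, 100)
  expect_equal(r$phi, 0)
  # {50,100,150}: mean 100, sample var 2500 -> phi = (2500-100)/1e4 = 0.24
  r <- mom_dispersion(matrix(c(50, 100, 150), 1, 3), f)
  expect_equal(r$phi, 0.24)
  # all equal: variance 0 -> phi 0
  r <- mom_dispersion(matrix(100, 1, 3), f)
  expect_equal(r$phi, 0)
})

test_that("dispersion shrinkage is a clamped convex combination", {
  phi <- c(0.05, 0.1, 0.4, 0.01, 0.2)
  J <- length(phi)
  s <- shrink_dispersion(phi)
  expect_true(s$delta >= 0 && s$delta <= 1)
  # default target: the mean, where delta degenerates to (J-2)/(J-1)
  expect_equal(s$xi, mean(phi))
  expect_equal(s$delta, (J - 2) / (J - 1))
  expect_true(all(s$phi_shrunk >= pmin(phi, s$xi) - 1e-12))
  expect_true(all(s$phi_shrunk <= pmax(phi, s$xi) + 1e-12))
  # alternative target: closed form mean + population sd / sqrt(3),
  # matching an independent grid minimization of the criterion
  s2 <- shrink_dispersion(phi, target = "min-derivative")
  expect_equal(s2$xi, mean(phi) + sqrt(mean((phi - mean(phi))^2) / 3))
  expect_gt(s2$xi, mean(phi))
  expect_lt(s2$delta, s$delta)
  expect_equal(poolcnv:::xi_grid(phi), s2$xi, tolerance = 1e-3)
  # identical raw values: full-weight no-op
  s0 <- shrink_dispersion(rep(0.2, 10))
  expect_equal(s0$delta, 1)
  expect_equal(s0$phi_shrunk, rep(0.2, 10))
  expect_error(shrink_dispersion(c(0.1, 0.2)), "3 targets")
})

test_that("shrunken dispersions beat raw ones under a common true phi", {
  # Monte-Carlo shrinkage dominance: NB data with shared true dispersion
  set.seed(101)
  phi_true <- 0.08
  wins <- replicate(100, {
    C <- matrix(rnbinom(50 * 4, size = 1 / phi_true, mu = 100), 50, 4)
    mom <- mom_dispersion(C, rep(1, 4))
    s <- shrink_dispersion(mom$phi)
    mean(abs(s$phi_shrunk - phi_true)) <= mean(abs(mom$phi - phi_true))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("the NB likelihood has the stated parameterization and limits", {
  # phi = 0 is exactly Poisson
  expect_identical(nb_loglik(5, 5, 0), dpois(5, 5, log = TRUE))
  expect_equal(nb_loglik(0:20, 3.3, 0), dpois(0:20, 3.3, log = TRUE))
  # the pmf normalizes
  expect_equal(sum(exp(nb_loglik(0:5000, 50, 0.3))), 1, tolerance = 1e-9)
  # variance = m + phi m^2
  set.seed(8)
  x <- rnbinom(1e6, size = 1 / 0.1, mu = 100)
  expect_equal(var(x), 100 + 0.1 * 100^2, tolerance = 0.02)
  # continuity of the phi -> 0 limit
  expect_equal(nb_loglik(7, 5, 1e-12), dpois(7, 5, log = TRUE),
               tolerance = 1e-8)
})

test_that("state updates equal a brute-force likelihood loop", {
  set.seed(21)
  n <- 300
  f <- runif(n, 0.5, 2)
  mu <- runif(n, 5, 500)
  phi <- runif(n, 0, 0.3)
  cc <- rpois(n, mu * f * sample(c(0.5, 1, 1.5, 2), n, replace = TRUE))
  oracle <- mapply(brute_force_state, cc, f, mu, phi)
  got <- vapply(seq_len(n), function(k) {
    update_states(matrix(cc[k], 1, 1), f[k], mu[k], phi[k])$states[1, 1]
  }, numeric(1))
  expect_identical(got, oracle)
})

test_that("forced examples pick the expected copy state", {
  # halved count under tight dispersion: heterozygous deletion
  expect_equal(update_states(matrix(100L, 1, 1), 1, 200, 0.001)$states[1, 1],
               0.5)
  # diploid-consistent count stays diploid
  expect_equal(update_states(matrix(200L, 1, 1), 1, 200, 0.001)$states[1, 1],
               1)
  # zero-mean target is not callable
  expect_true(is.na(update_states(matrix(5L, 1, 1), 1, 0, 0.1)$states[1, 1]))
})

test_that("diploid p-values behave like doubled exact NB tails", {
  # extreme count under a tight model
  expect_lt(diploid_pvalue(0, 1, 1000, 0.001), 1e-10)
  # central value caps at 1
  expect_equal(diploid_pvalue(100, 1, 100, 0.01), 1)
  # monotone non-increasing as the count moves away from the center
  p_up <- diploid_pvalue(100:160, 1, 100, 0.01)
  expect_true(all(diff(p_up) <= 1e-12))
  p_dn <- diploid_pvalue(100:40, 1, 100, 0.01)
  expect_true(all(diff(p_dn) <= 1e-12))
  expect_true(all(p_up >= 0 & p_up <= 1))
})

test_that("BH adjustment matches the step-up rule and a hand example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  p <- c(0.001, 0.2, 0.9, 0.04, 0.5)
  expect_true(all(bh_adjust(p) >= p))
  # permutation equivariance
  perm <- c(3, 5, 1, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
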