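# closed-form layer: medians, intensity constants, spectra, windows

test_that("median first-success time matches the closed form", {
  expect_equal(median_first_success_time(default_params()),
               460.517, tolerance = 1e-5)
  # lambda0 = 0.01 variant, evaluated independently:
  # log(1e-4 / (1e-6 * 0.04)) / 0.01 = log(2500)/0.01 = 782.4046
  p <- two_type_params(b0 = 0.99)
  expect_equal(median_first_success_time(p), log(2500) / 0.01,
               tolerance = 1e-12)
  expect_equal(median_first_success_time(p), 782.405, tolerance = 1e-6)
  # u1 chosen so the log argument is exactly 1 gives median 0
  p0 <- two_type_params(u1 = 0.02^2 / 0.04)
  expect_equal(median_first_success_time(p0), 0)
  # beyond that the asymptotic regime breaks down
  expect_error(median_first_success_time(two_type_params(u1 = 0.5)),
               "asymptotic")
})

test_that("limiting-intensity constant is lambda0 * gamma(alpha) / lambda1^alpha", {
  expect_equal(limit_intensity_constant(default_params()),
               0.02 * sqrt(pi) / sqrt(0.04), tolerance = 1e-12)
  expect_equal(limit_intensity_constant(default_params()), 0.1772,
               tolerance = 3e-4)
  # alpha = 1/4 variant: 0.01 * gamma(0.25) * 0.04^(-0.25)
  p <- two_type_params(b0 = 0.99)
  expect_equal(limit_intensity_constant(p),
               0.01 * gamma(0.25) / 0.04^0.25, tolerance = 1e-12)
  expect_equal(limit_intensity_constant(p), 0.08107, tolerance = 1e-4)
  # alpha >= 1 cannot even be constructed
  expect_error(two_type_params(b1 = 0.98), "alpha")
})

test_that("driver-mutation spectrum has the stated constant and shape", {
  # at f = 1/2 the spectrum equals its leading constant, 2/pi at alpha = 1/2
  expect_equal(sfs_1a(0.5, 0.5), 2 / pi, tolerance = 1e-12)
  expect_equal(sfs_1a(0.5, 0.5), 0.6366, tolerance = 1e-4)
  for (a in c(0.3, 0.5, 0.7)) {
    expect_equal(sfs_1a(0.5, a), sin(pi * a) / (pi * a), tolerance = 1e-12)
    f <- seq(0.05, 0.95, by = 0.05)
    expect_true(all(diff(sfs_1a(f, a)) < 0))     # strictly decreasing
  }
  expect_equal(sfs_1a(0.2, 0.5), 2 / pi * 2, tolerance = 1e-12)
  expect_lt(sfs_1a(0.999, 0.5), 0.03)            # vanishes as f -> 1
  expect_error(sfs_1a(0, 0.5), "f must")
  expect_error(sfs_1a(0.5, 1), "alpha")
})

test_that("neutral spectra follow the 1/f laws", {
  expect_equal(neutral_sfs(0.5, rate = 0.02, growth = 0.04,
                           mode = "continuous"), 1)
  # unit-frequency anchor: exactly rate/growth
  expect_equal(neutral_sfs(1, rate = 0.02, growth = 0.04,
                           mode = "continuous"), 0.5)
  # conservation: f * M(f) is the at-birth mutation rate, for any f
  f <- exp(seq(log(0.01), 0, length.out = 25))
  expect_equal(f * neutral_sfs(f, rate = 0.3, mode = "at_birth"),
               rep(0.3, 25))
  # at-birth count does not involve the growth rate
  expect_identical(neutral_sfs(0.2, 0.1, growth = 1, mode = "at_birth"),
                   neutral_sfs(0.2, 0.1, growth = 9, mode = "at_birth"))
  expect_error(neutral_sfs(0, 0.1, mode = "at_birth"), "f must")
})

test_that("subclone coexistence window depends only on the growth-rate gap", {
  p <- two_type_params(b1 = 0.965)                # lambda1 - lambda0 = 0.015
  expect_equal(subclone_ratio_window(p), log(16) / 0.015, tolerance = 1e-12)
  expect_equal(subclone_ratio_window(p), 184, tolerance = 1 / 184)
  expect_equal(subclone_ratio_window(default_params()), log(16) / 0.02,
               tolerance = 1e-12)
  # invariant under a common shift of both growth rates
  p2 <- two_type_params(b0 = 0.93, b1 = 0.91)     # 0.07 and 0.09
  expect_equal(subclone_ratio_window(p2), subclone_ratio_window(default_params()))
  expect_equal(subclone_ratio_window(p, ratio_lo = 2, ratio_hi = 2), 0)
  # independent of the mutation rates
  expect_equal(subclone_ratio_window(two_type_params(b1 = 0.965, u1 = 1e-3,
                                                     nu = 1)),
               subclone_ratio_window(p))
})

test_that("later-family dominance probability matches the exponential-ratio law", {
  expect_equal(second_family_dominance_prob(100, 0.04), 1 / (exp(4) + 1),
               tolerance = 1e-12)
  expect_equal(second_family_dominance_prob(100, 0.04), 0.018,
               tolerance = 0.001 / 0.018)
  expect_equal(second_family_dominance_prob(0, 0.04), 0.5)
  # Monte-Carlo oracle on the ratio of i.i.d. exponentials
  set.seed(404)
  n <- 1e5
  w0 <- rexp(n); w1 <- rexp(n)
  emp <- mean(w1 * exp(-0.04 * 100) > w0)
  thr <- second_family_dominance_prob(100, 0.04)
  se <- sqrt(thr * (1 - thr) / n)
  expect_lt(abs(emp - thr), 3 * se)
  expect_error(second_family_dominance_prob(-1, 0.04), "nonnegative")
})

test_that("random-fitness family tail integral is correct", {
  p <- default_params()
  fd <- fitness_distribution(0.04, 0.005)
  # empty tail at large x
  expect_lt(random_fitness_family_tail(60, p, fd, t_end = 1000), 1e-6)
  # nonincreasing in x
  v <- random_fitness_family_tail(c(0, 5, 10, 20, 40), p, fd, t_end = 1000)
  expect_true(all(diff(v) <= 0))
  # d -> 0 degenerates to the constant-fitness count
  # u1*lambda1*int_0^{t-x/lambda1} v0 e^{lambda0 s} ds
  fd0 <- fitness_distribution(0.04, 0)
  for (x in c(0, 10, 30)) {
    t_cut <- 1000 - x / 0.04
    closed <- 1e-6 * 0.04 * 50 * expm1(0.02 * t_cut) / 0.02
    expect_equal(random_fitness_family_tail(x, p, fd0, 1000), closed,
                 tolerance = 1e-6)
  }
  # small-d limit approaches the degenerate count away from the kink
  fd_small <- fitness_distribution(0.04, 1e-5)
  expect_equal(random_fitness_family_tail(10, p, fd_small, 1000),
               random_fitness_family_tail(10, p, fd0, 1000),
               tolerance = 1e-4)
  expect_error(random_fitness_family_tail(0, p, fd, t_end = -1), "t_end")
})

test_that("random-fitness family tail agrees with candidate-thinning Monte Carlo", {
  # independent oracle: candidate founders as an inhomogeneous Poisson
  # process at rate u1*Z0(s), normal growth rates, success-thinning with
  # probability min(max(l,0),a1)/a1 -- scaled up u1 to keep it cheap
  p <- two_type_params(u1 = 1e-3)
  fd <- fitness_distribution(m = 0.1, d = 0.03)
  t_end <- 300; v0 <- 50
  set.seed(505)
  n_rep <- 2000
  xs <- c(0, 10, 25)
  counts <- matrix(0, n_rep, length(xs))
  mean_cand <- p$u1 * v0 * expm1(p$lambda0 * t_end) / p$lambda0
  for (r in seq_len(n_rep)) {
    n <- rpois(1, mean_cand)
    s <- log1p(runif(n) * expm1(p$lambda0 * t_end)) / p$lambda0
    l <- rnorm(n, fd$m, fd$d)
    keep <- runif(n) < pmin(pmax(l, 0), p$a1) / p$a1
    proxy <- l[keep] * (t_end - s[keep])
    counts[r, ] <- vapply(xs, function(x) sum(proxy > x), numeric(1))
  }
  for (j in seq_along(xs)) {
    th <- random_fitness_family_tail(xs[j], p, fd, t_end, v0 = v0)
    se <- sd(counts[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(counts[, j]) - th), 3 * se + 1e-9)
  }
})

test_that("subclone-frequency cdf is a valid cdf and matches its Monte-Carlo oracle", {
  bp <- moderate_bozic(M = 1e9)
  # vanishing and saturating limits
  expect_lt(bozic_subclonal_cdf(1e-9, bp), 1e-4)
  expect_equal(bozic_subclonal_cdf(1 - 1e-9, bp),
               1 - exp(-bp$u * bp$c * bp$M / bp$b1), tolerance = 1e-4)
  # monotone nondecreasing, bounded
  y <- seq(0.05, 0.95, by = 0.05)
  v <- bozic_subclonal_cdf(y, bp)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 0 & v <= 1))
  expect_gte(bozic_subclonal_cdf(0.8, bp), bozic_subclonal_cdf(0.2, bp))
  # Monte-Carlo oracle: X0 ~ Exp(uc/b1) truncated at M, W1 ~ Exp(cr/b1),
  # f_sub <= y iff W1 <= y (1-y)^(-c) X0^c M^(1-c)
  set.seed(606)
  n <- 2e5
  x0 <- rexp(n, rate = bp$u * bp$c / bp$b1)
  w1 <- rexp(n, rate = bp$c * bp$r / bp$b1)
  for (yy in c(0.1, 0.3, 0.6, 0.9)) {
    mc <- mean(x0 <= bp$M &
                 w1 <= yy * (1 - yy)^(-bp$c) * x0^bp$c * bp$M^(1 - bp$c))
    se <- sqrt(mc * (1 - mc) / n)
    expect_lt(abs(bozic_subclonal_cdf(yy, bp) - mc), 3 * se)
  }
  # fixed Riemann-sum mode agrees with adaptive quadrature away from y -> 1
  expect_equal(bozic_subclonal_cdf(0.3, bp, method = "riemann"),
               bozic_subclonal_cdf(0.3, bp), tolerance = 2e-3)
  expect_error(bozic_subclonal_cdf(1.2, bp), "y must")
})

test_that("detectable-driver probability behaves like a probability", {
  bp <- moderate_bozic(M = 1e8)
  expect_equal(detectable_driver_probability(bp, 0.3, 0.3), 0)
  pr <- detectable_driver_probability(bp)
  expect_true(pr >= 0 && pr <= 1)
  expect_equal(pr, bozic_subclonal_cdf(0.8, bp) - bozic_subclonal_cdf(0.2, bp),
               tolerance = 1e-12)
})

test_that("parameter containers validate their invariants", {
  expect_error(two_type_params(a0 = -1), "nonnegative")
  expect_error(two_type_params(b0 = 1.0), "lambda0")
  expect_error(two_type_params(b1 = 0.99), "lambda1")
  p <- two_type_params()
  expect_equal(p$alpha, 0.5)
  expect_equal(p$lambda0, 0.02)
  expect_error(bozic_params(b = 0.14, d = 0.14, b1 = 0.2, d1 = 0.1,
                            u = 1e-5, M = 1e9), "r = b - d")
  expect_error(bozic_params(b = 0.14, d = 0.13, b1 = 0.14, d1 = 0.131,
                            u = 1e-5, M = 1e9), "c = r1/r")
  bp <- moderate_bozic()
  expect_equal(bp$c, 1.3)
  expect_equal(bp$g, 0.3, tolerance = 1e-12)
  tp <- as_two_type_params(bp)
  expect_equal(tp$lambda0, bp$r)
  expect_equal(tp$lambda1, bp$r1)
  expect_error(fitness_distribution(d = -0.1), "d >= 0")
  fd <- fitness_distribution(0.04, 0)
  expect_equal(fd$Phi(0.039), 0)
  expect_equal(fd$Phi(0.04), 1)
})
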