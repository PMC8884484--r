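test_that("mindset schedule follows 1 - exp(-t/tau) with the tau = 0 convention", {
  expect_identical(beta_schedule(0, 60), 0)
  expect_equal(beta_schedule(60, 60), 1 - exp(-1))
  # tau_beta = 0 means mindsets are formed from the start: beta is 1 at all t
  expect_identical(beta_schedule(c(0, 1, 17, 5000), 0), rep(1, 4))
  # non-decreasing in t, approaching 1
  b <- beta_schedule(0:5000, 120)
  expect_true(all(diff(b) >= 0))
  expect_true(all(b >= 0 & b <= 1))
  expect_lt(abs(b[5001] - 1), 1e-15)
  # non-decreasing in 1/tau: faster mindset change means larger beta at fixed t
  taus <- c(240, 120, 60, 10, 0)
  expect_true(all(diff(vapply(taus, function(tb) beta_schedule(50, tb),
                              numeric(1))) >= 0))
  expect_error(beta_schedule(-1, 60), "invalid")
  expect_error(beta_schedule(10, -3), "invalid")
})

test_that("staying probability is bounded, peaks at n = beta*K, and saturates to 1 - delta", {
  # at n = K with beta = 1 the bonus e * 1 * e^-1 is exactly 1
  expect_equal(staying_probability(5000, 5000, beta = 1, delta = 0.2), 1)
  # empty city at beta = 0: exp(0) = 1
  expect_equal(staying_probability(0, 5000, beta = 0, delta = 0.2), 1)
  # overcrowded city: bonus vanishes, probability -> 1 - delta
  expect_equal(staying_probability(100 * 5000, 5000, beta = 1, delta = 0.2),
               0.8, tolerance = 1e-12)
  # bounds hold across a grid of populations and betas
  for (beta in c(0, 0.25, 0.5, 0.75, 1)) {
    v <- staying_probability(seq(0, 5e4, length.out = 200), 5000, beta, 0.2)
    expect_true(all(v >= 0.8 - 1e-12 & v <= 1 + 1e-12))
    # the maximum over n sits at n = beta * K
    expect_equal(staying_probability(beta * 5000, 5000, beta, 0.2), 1,
                 tolerance = 1e-12)
  }
  expect_error(staying_probability(10, -1, 1, 0.2), "invalid")
  expect_error(staying_probability(10, 5000, 2, 0.2), "invalid")
})

test_that("attraction weight combines homophily, distance decay, and crowding pressure", {
  m <- city_map(rbind(c(0, 0), c(1, 0)), K = 5000)
  p <- chase_params(gamma = 50, alpha = 1)
  # destination 2 holds 100 origin-1 people and nobody else
  n <- matrix(0, 2, 2)
  n[2, 1] <- 100
  expect_equal(attraction_weight(2, 1, 1, n, m, p, beta = 1),
               5000 * exp(-0.02))
  # gamma = 1 collapses the numerator to the total destination population
  p1 <- chase_params(gamma = 1)
  expect_equal(attraction_weight(2, 1, 1, n, m, p1, beta = 1),
               100 * exp(-0.02))
  # empty destination contributes nothing when agglomeration matters
  expect_equal(attraction_weight(1, 2, 1, n, m, p, beta = 1), 0)
  # ... but at beta = 0 the population factor is identically 1
  expect_equal(attraction_weight(1, 2, 1, n, m, p, beta = 0), exp(0))
  expect_error(attraction_weight(1, 1, 1, n, m, p, beta = 1), "differ")
  # strictly increasing in own-origin presence when gamma, beta > 0
  n2 <- n
  n2[2, 1] <- 150
  expect_gt(attraction_weight(2, 1, 1, n2, m, p, beta = 1),
            attraction_weight(2, 1, 1, n, m, p, beta = 1))
  # zero distance is a degenerate map
  broken <- m
  broken$dist[1, 2] <- broken$dist[2, 1] <- 0
  expect_error(attraction_weight(2, 1, 1, n, broken, p, beta = 1),
               "degenerate")
})

test_that("kernel columns are stochastic with bounded diagonals on randomized states", {
  p <- chase_params(gamma = 50, tau_beta = 120)
  for (seed in 1:8) {
    L <- sample(2:6, 1)
    m <- tiny_map(L = L, seed = seed)
    s <- random_state(L, seed + 100)
    for (t in c(0, 3, 500)) {
      for (k in seq_len(L)) {
        ker <- transition_kernel(s, t, k, m, p)
        expect_lt(max(abs(colSums(ker$w) - 1)), 1e-12)
        expect_true(all(ker$w >= 0 & ker$w <= 1 + 1e-12))
        expect_true(all(diag(ker$w) >= 1 - p$delta - 1e-12))
      }
    }
  }
})

test_that("kernel matches a naive per-entry reference implementation", {
  p <- chase_params(gamma = 7, tau_beta = 60, delta = 0.3, alpha = 1.5)
  for (seed in 1:5) {
    m <- tiny_map(L = 4, seed = seed)
    s <- random_state(4, seed)
    t <- 25
    beta <- beta_schedule(t, p$tau_beta)
    for (k in 1:4) {
      ker <- transition_kernel(s, t, k, m, p)
      ref <- reference_kernel(s$n, beta, k, m, p$delta, p$gamma, p$alpha)
      expect_equal(ker$w, ref, tolerance = 1e-12)
    }
  }
})

test_that("identical, equidistant cities are chosen with equal probability", {
  # cities 1 and 2 have identical composition and sit at the same
  # distance from city 3: movers out of 3 cannot tell them apart
  m <- city_map(rbind(c(-0.5, 0), c(0.5, 0), c(0, 0.8)), K = 5000)
  n <- rbind(c(400, 300, 300),
             c(400, 300, 300),
             c(100, 100, 800))
  p <- chase_params(gamma = 50, tau_beta = 0)
  for (k in 1:3) {
    w <- transition_kernel(n, 0, k, m, p)$w
    expect_equal(w[1, 3], w[2, 3])
  }
  # and the direct exchange between the twins is symmetric too
  w1 <- transition_kernel(n, 0, 1, m, p)$w
  expect_equal(w1[2, 1], w1[1, 2])
})

test_that("a lone populated city keeps everyone when beta > 0", {
  m <- tiny_map(L = 3, seed = 1)
  n <- matrix(0, 3, 3)
  n[2, 2] <- 3000
  p <- chase_params(tau_beta = 0)  # beta = 1 throughout
  ker <- transition_kernel(n, 0, 2, m, p)
  # all destinations are empty so 0^beta = 0: stay probability forced to 1
  expect_equal(ker$w[, 2], c(0, 1, 0))
  expect_lt(max(abs(colSums(ker$w) - 1)), 1e-12)
})

test_that("the beta -> 0 kernel agrees with the distance-only limiting form", {
  # evaluate the full kernel at beta = 1e-8 and compare against the
  # beta = 0 form computed independently, entrywise
  p <- chase_params(gamma = 50, tau_beta = 1)
  t_small <- -1 * log(1 - 1e-8)  # beta_schedule(t_small, 1) == 1e-8
  for (seed in 1:5) {
    m <- tiny_map(L = 4, seed = seed)
    s <- random_state(4, seed + 7)
    for (k in 1:4) {
      ker <- transition_kernel(s, t_small, k, m, p)
      ref0 <- reference_kernel(s$n, 0, k, m, p$delta, p$gamma, p$alpha)
      expect_lt(max(abs(ker$w - ref0)), 1e-6)
    }
  }
})

test_that("the kernel is invariant under uniform rescaling of the map", {
  p <- chase_params(gamma = 50, tau_beta = 120, alpha = 1)
  for (cc in c(1e-3, 0.1, 7, 1e4)) {
    m1 <- tiny_map(L = 4, seed = 3)
    m2 <- city_map(m1$coords * cc, m1$K)
    s <- random_state(4, 11)
    for (k in 1:4) {
      w1 <- transition_kernel(s, 10, k, m1, p)$w
      w2 <- transition_kernel(s, 10, k, m2, p)$w
      expect_lt(max(abs(w1 - w2)), 1e-12)
    }
  }
})

test_that("stronger social ties shift movers toward same-origin destinations", {
  # 3 cities: city 1 holds the origin-1 movers; city 2 is richer in
  # origin-1 people than city 3 but both have the same total population
  m <- city_map(rbind(c(0, 0), c(0.4, 0.3), c(0.4, -0.3)), K = 5000)
  n <- rbind(c(1000, 0, 0),
             c(800, 200, 0),
             c(200, 0, 800))
  p <- chase_params(tau_beta = 0)  # beta = 1
  probs <- vapply(c(1, 2, 5, 10, 50, 200), function(g) {
    pg <- chase_params(gamma = g, tau_beta = 0)
    w <- transition_kernel(n, 0, 1, m, p = pg)$w
    w[2, 1] / (w[2, 1] + w[3, 1])
  }, numeric(1))
  expect_true(all(diff(probs) >= -1e-12))
  expect_gt(probs[length(probs)], probs[1])
})
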