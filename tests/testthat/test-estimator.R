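test_that("the likelihood matches a direct log-Gamma evaluation", {
  set.seed(71)
  for (i in 1:25) {
    params <- random_params()
    X <- params$X
    p <- 1 - (1 - 1 / X)^params$y
    z <- pmin(round(params$r_cap * X * p * runif(length(p), 0.8, 1.2)),
              floor(X * params$r_cap))
    z <- pmax(z, 1)
    k <- z / params$r_cap
    direct <- sum(lgamma(X + 1) - lgamma(k + 1) - lgamma(X - k + 1) +
                    k * log(p) + (X - k) * log(1 - p))
    expect_equal(formation_loglik(params, z), direct, tolerance = 1e-10)
  }
})

test_that("the likelihood support excludes impossible observations", {
  params <- formation_params(X = 100, r_cap = 0.5, y = c(50, 50))
  expect_identical(formation_loglik(params, c(60, 10)), -Inf) # 60/0.5 > 100
  expect_error(formation_loglik(formation_params(X = 100, r_cap = 0,
                                                 y = c(50, 50)),
                                c(10, 10)), "positive")
})

test_that("the likelihood peaks where observations hit their expectation", {
  params <- formation_params(X = 1000, r_cap = 0.6, y = c(300, 500))
  p <- 1 - (1 - 1 / 1000)^params$y
  z_star <- params$r_cap * 1000 * p
  ll0 <- formation_loglik(params, z_star)
  # perturbing y away from the generating value can only lower it
  for (d in c(-20, 20)) {
    alt <- formation_params(X = 1000, r_cap = 0.6, y = c(300 + d, 500 - d))
    expect_lt(formation_loglik(alt, z_star), ll0)
  }
})

test_that("parameters are recovered from simulated observations", {
  truth <- formation_params(X = 7000, r_cap = 0.55, y = rep(750, 4))
  tr <- formation_rates(truth)
  sim <- simulate_formation(truth, reps = 1, seed = 72)
  est <- estimate_formation(sim$z, total_cells = 3000, n_gem = sim$n_gem,
                            seed = 1)
  er <- formation_rates(est)
  expect_lt(abs(er$p_singlet - tr$p_singlet) / tr$p_singlet, 0.10)
  expect_lt(abs(er$p_msm - tr$p_msm) / tr$p_msm, 0.10)
  expect_lt(abs(er$p_ssm - tr$p_ssm) / tr$p_ssm, 0.10)
  expect_equal(er$p_singlet + er$p_msm + er$p_ssm, 1, tolerance = 1e-12)
})

test_that("the collision-free limit pins r_cap * X * p to z", {
  # one sample: z_1 and the GEM total coincide, so X itself is not
  # identifiable and must be pinned; as the pinned X grows, collisions
  # vanish and the implied SSM rate tends to zero while the estimate
  # keeps matching the observation r_cap * X * p = z
  z <- 450
  ssm <- vapply(c(2e3, 2e4, 2e5, 2e6), function(X0) {
    est <- estimate_formation(c(HTO1 = z), total_cells = 1000,
                              n_gem = 450, fix_X = X0, seed = 1)
    p <- 1 - (1 - 1 / est$X)^est$y
    expect_equal(unname(est$r_cap * est$X * p), z, tolerance = 0.02)
    formation_rates(est)$p_ssm
  }, numeric(1L))
  expect_true(all(diff(ssm) < 0))
  expect_lt(ssm[length(ssm)], 1e-3)
})

test_that("estimates are reproducible across optimizer seeds", {
  truth <- formation_params(X = 5000, r_cap = 0.7, y = c(400, 800, 300))
  sim <- simulate_formation(truth, reps = 1, seed = 73)
  e1 <- estimate_formation(sim$z, total_cells = 1500, n_gem = sim$n_gem,
                           seed = 1)
  e2 <- estimate_formation(sim$z, total_cells = 1500, n_gem = sim$n_gem,
                           seed = 2026)
  expect_equal(e1$X, e2$X, tolerance = 1e-4)
  expect_equal(e1$r_cap, e2$r_cap, tolerance = 1e-4)
  expect_equal(e1$y, e2$y, tolerance = 1e-4)
})

test_that("no small coordinate perturbation improves the likelihood", {
  truth <- formation_params(X = 5000, r_cap = 0.7, y = c(400, 800, 300))
  sim <- simulate_formation(truth, reps = 1, seed = 74)
  est <- estimate_formation(sim$z, total_cells = 1500, n_gem = sim$n_gem,
                            seed = 1)
  ll <- formation_loglik(est, sim$z)
  # perturbations along the constraint surface (the anchor ties r_cap to
  # X, and the y simplex to Y), at +-0.1 %
  for (eps in c(-0.001, 0.001)) {
    Xp <- est$X * (1 + eps)
    rp <- attr(est, "n_gem") / (Xp * (1 - (1 - 1 / Xp)^est$Y))
    alt <- formation_params(X = Xp, r_cap = min(rp, 1), y = est$y)
    expect_lte(formation_loglik(alt, sim$z), ll + 1e-6)
    for (j in seq_along(est$y)) {
      y2 <- est$y
      bump <- y2[j] * eps
      y2[j] <- y2[j] + bump
      y2[-j] <- y2[-j] * (1 - bump / sum(y2[-j]))
      alt2 <- formation_params(X = est$X, r_cap = est$r_cap,
                               y = y2 / sum(y2) * est$Y)
      expect_lte(formation_loglik(alt2, sim$z), ll + 1e-6)
    }
  }
})

test_that("model-expected Venn counts cover the classifier-observed ones", {
  truth <- formation_params(X = 4000, r_cap = 0.6, y = rep(500, 4))
  sim <- simulate_formation(truth, reps = 1, seed = 75)
  est <- estimate_formation(sim$z, total_cells = 2000, n_gem = sim$n_gem,
                            seed = 1)
  expected <- expected_msm_venn(est)
  for (nm in names(expected)) {
    lambda <- expected[[nm]]
    got <- if (nm %in% names(sim$venn)) sim$venn[[nm]] else 0
    # 99% binomial/Poisson interval around the model expectation
    expect_lt(abs(got - lambda), 2.576 * sqrt(lambda + 1) + 1)
  }
})

test_that("the X profile is reported and fix_X honours the pin", {
  truth <- formation_params(X = 5000, r_cap = 0.7, y = c(700, 800))
  sim <- simulate_formation(truth, reps = 1, seed = 76)
  est <- estimate_formation(sim$z, total_cells = 1500, n_gem = sim$n_gem,
                            seed = 1, profile = TRUE)
  prof <- attr(est, "profile")
  expect_s3_class(prof, "data.frame")
  expect_true(all(c("X", "r_cap", "loglik") %in% names(prof)))
  expect_true(any(is.finite(prof$loglik)))

  pinned <- estimate_formation(sim$z, total_cells = 1500,
                               n_gem = sim$n_gem, fix_X = 5000, seed = 1)
  expect_equal(pinned$X, 5000)
  expect_equal(formation_rates(pinned)$p_singlet,
               formation_rates(truth)$p_singlet, tolerance = 0.02)
})

test_that("estimator input validation", {
  expect_error(estimate_formation(c(0, 0), total_cells = 100, n_gem = 10),
               "z_l >= 1")
  expect_error(estimate_formation(c(10, 10), total_cells = 0, n_gem = 20),
               "positive")
  expect_error(estimate_formation(c(10, 10), total_cells = 100),
               "n_gem")
})
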