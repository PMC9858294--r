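test_that("mixing matrices are column-stochastic by construction", {
  r <- regions6()
  zero <- flux_matrix(matrix(0, 6, 6, dimnames = list(r$region_id, r$region_id)),
                      "total")
  mix0 <- mixing_matrices(zero, r)
  expect_equal(mix0$phi, diag(6), ignore_attr = TRUE)
  expect_equal(mix0$phi_hat, diag(6), ignore_attr = TRUE)

  set.seed(9)
  for (i in 1:10) {
    fx <- random_flux(r, frac = runif(1, 0.01, 0.3))
    mix <- mixing_matrices(fx, r)
    expect_equal(colSums(mix$phi), rep(1, 6), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(colSums(mix$phi_hat), rep(1, 6), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(diag(mix$phi)), unname(1 - mix$outflow_fraction))
  }

  # more travellers than residents is rejected
  r_small <- dplyr::mutate(r, population = 10)
  expect_error(mixing_matrices(random_flux(r, frac = 0.05), r_small), "outflow")
})

test_that("temperature-dependent transmission obeys its form and cap", {
  expect_equal(beta_of_temperature(5, 0.1, -1), exp(-1.5), tolerance = 1e-12)
  expect_equal(beta_of_temperature(0, 0.1, 10, dt = 1), (1 - 1e-9))
  expect_equal(beta_of_temperature(1e6, 0.1, 0), 0, tolerance = 1e-30)
  grid <- seq(-10, 35, by = 0.5)
  b <- beta_of_temperature(grid, 0.08, 0.3)
  expect_true(all(diff(b) <= 0))
  expect_error(beta_of_temperature(5, -0.1, 0), "a_beta")
})

test_that("a single Euler step matches the hand-computed update", {
  r1 <- tibble::tibble(region_id = c("A", "B"), name = c("A", "B"),
                       population = c(1000, 1000), gdp = c(1, 1),
                       lat = c(40, 45), lon = c(9, 11))
  zero <- flux_matrix(matrix(0, 2, 2, dimnames = list(r1$region_id, r1$region_id)),
                      "total")
  mix <- mixing_matrices(zero, r1)
  st <- list(S = c(999, 1000), I = c(1, 0), R = c(0, 0))
  out <- sir_step(st, mix, beta = c(0.5, 0.5), gamma = 0.1, regions = r1)
  expect_equal(out$S[1], 998.5005, tolerance = 1e-12)
  expect_equal(out$I[1], 1.3995, tolerance = 1e-12)
  expect_equal(out$R[1], 0.1, tolerance = 1e-12)
  expect_equal(out$S[2], 1000)

  # null dynamics leave the state untouched
  same <- sir_step(st, mix, beta = c(0, 0), gamma = 0, regions = r1)
  expect_identical(same[c("S", "I", "R")], st)
})

test_that("trajectories conserve the total population", {
  r <- regions6()
  set.seed(17)
  for (trial in 1:10) {
    fx <- random_flux(r, frac = runif(1, 0.02, 0.2))
    mix <- mixing_matrices(fx, r)
    # epidemiologically sensible growth regime (no Euler overshoot)
    gamma <- runif(1, 0.3, 0.6)
    beta <- pmax(gamma + runif(6, -0.3, 0.2), 0)
    st <- list(S = r$population, I = rep(0, 6), R = rep(0, 6))
    i0 <- sample(6, 1)
    st$S[i0] <- st$S[i0] - 1
    st$I[i0] <- 1
    total0 <- sum(unlist(st))
    for (s in 1:30) st <- sir_step(st, mix, beta, gamma, r)
    expect_lt(abs(sum(unlist(st[c("S", "I", "R")])) - total0) / total0, 1e-9)
  }
})

test_that("closed-form and decoupled limits of the monthly epidemic hold", {
  r <- regions6()
  fx <- random_flux(r, frac = 0.05)
  # beta = 0: only the patient zero recovers, geometrically
  p_beta0 <- full_model_params(a_h = 0.1, b_h = -12, rho0 = rep(1, 6),
                               kappa_e = 0, d0_e = 100, mu = 0,
                               a_beta = 1e-9, b_beta = -1e9, gamma = 0.1)
  r30 <- run_monthly_epidemic(rep(10, 6), 2, fx, p_beta0, r)
  expect_equal(sum(r30), 1 - (1 - 0.1)^30, tolerance = 1e-12)

  # zero flux: nothing reaches the other regions
  zero <- flux_matrix(matrix(0, 6, 6, dimnames = list(r$region_id, r$region_id)),
                      "total")
  p <- full_model_params(a_h = 0.1, b_h = -12, rho0 = rep(1, 6),
                         kappa_e = 0, d0_e = 100, mu = 0,
                         a_beta = 0.08, b_beta = 0.2, gamma = 0.25)
  r30z <- run_monthly_epidemic(rep(2, 6), 3, zero, p, r)
  expect_identical(unname(r30z[-3] == 0), rep(TRUE, 5))
  expect_gt(r30z[3], 0)
})

test_that("a single-region network reproduces the scalar Euler SIR", {
  r1 <- toy_regions(pop = c(5000, 1), gdp = c(1, 1))[1, ] |>
    dplyr::bind_rows(tibble::tibble(region_id = "Z", name = "Z", population = 1,
                                    gdp = 1e-12, lat = 0, lon = 0))
  # effectively single region: zero flux, the second region inert
  zero <- flux_matrix(matrix(0, 2, 2, dimnames = list(r1$region_id, r1$region_id)),
                      "total")
  p <- full_model_params(a_h = 0.1, b_h = -12, rho0 = rep(1, 2),
                         kappa_e = 0, d0_e = 100, mu = 0,
                         a_beta = 0.05, b_beta = -0.3, gamma = 0.15)
  temps <- c(4, 4)
  r30 <- run_monthly_epidemic(temps, 1, zero, p, r1)

  # independent scalar oracle
  beta <- exp(-0.05 * 4 - 0.3)
  S <- 4999; I <- 1; R <- 0; pop <- 5000
  for (t in 1:30) {
    dI <- beta * S * I / pop
    S <- S - dI; R <- R + 0.15 * I; I <- I + dI - 0.15 * I
  }
  expect_equal(unname(r30[1]), R, tolerance = 1e-12)
})

test_that("a two-region coupled epidemic matches an independent loop implementation", {
  r2 <- toy_regions(pop = c(10000, 10000), gdp = c(5, 5),
                    lat = c(40, 41), lon = c(9, 10))[1:2, ]
  f <- matrix(c(0, 800, 800, 0), 2, 2, dimnames = list(r2$region_id, r2$region_id))
  fx <- flux_matrix(f, "total")
  p <- full_model_params(a_h = 0.1, b_h = -12, rho0 = rep(1, 2),
                         kappa_e = 0, d0_e = 100, mu = 0,
                         a_beta = 0.06, b_beta = 0.1, gamma = 0.2)
  temps <- c(3, 3)
  r30 <- run_monthly_epidemic(temps, 1, fx, p, r2)

  # straightforward re-implementation with explicit loops
  pop <- r2$population
  phi <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) if (i != j) phi[i, j] <- f[i, j] / pop[j]
  for (j in 1:2) phi[j, j] <- 1 - sum(f[, j]) / pop[j]
  phihat <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) phihat[i, j] <- phi[j, i] / sum(phi[j, ])
  beta <- exp(-0.06 * temps + 0.1)
  S <- pop; I <- c(0, 0); R <- c(0, 0); S[1] <- S[1] - 1; I[1] <- 1
  for (t in 1:30) {
    dpool <- numeric(2)
    for (l in 1:2) {
      sp <- phi[l, 1] * S[1] + phi[l, 2] * S[2]
      ip <- phi[l, 1] * I[1] + phi[l, 2] * I[2]
      dpool[l] <- beta[l] / pop[l] * sp * ip
    }
    dI <- c(phihat[1, 1] * dpool[1] + phihat[1, 2] * dpool[2],
            phihat[2, 1] * dpool[1] + phihat[2, 2] * dpool[2])
    S <- S - dI; R <- R + 0.2 * I; I <- I + dI - 0.2 * I
  }
  expect_equal(unname(r30), R, tolerance = 1e-10)
  expect_equal(unname(r30[1] / r30[2]), R[1] / R[2], tolerance = 1e-10)
})

test_that("total recoveries never decrease when transmission increases", {
  r <- regions6()
  fx <- random_flux(r, frac = 0.05)
  totals <- vapply(seq(-1.5, 0.5, by = 0.25), function(bb) {
    p <- full_model_params(a_h = 0.1, b_h = -12, rho0 = rep(1, 6),
                           kappa_e = 0, d0_e = 100, mu = 0,
                           a_beta = 0.08, b_beta = bb, gamma = 0.25)
    sum(suppressWarnings(run_monthly_epidemic(rep(5, 6), 1, fx, p, r)))
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
  # recoveries bounded by the total population
  expect_true(all(totals >= 0 & totals <= sum(r$population)))
})

test_that("patient-zero distribution is GDP-proportional", {
  r4 <- toy_regions(pop = rep(1000, 4), gdp = rep(3, 4),
                    lat = 40:43, lon = 9:12)
  expect_equal(unname(patient_zero_distribution(r4)), rep(0.25, 4))
  r3 <- toy_regions(gdp = c(2, 1, 1))
  expect_equal(unname(patient_zero_distribution(r3)), c(0.5, 0.25, 0.25))
  r <- generate_regions(15, seed = 3)
  expect_equal(sum(patient_zero_distribution(r)), 1, tolerance = 1e-15)
})

test_that("expected deaths add their three components", {
  r <- regions6()
  fx <- random_flux(r, frac = 0.05)
  temps <- rep(8, 6)
  rho0 <- seq(100, 600, by = 100)
  # component isolation: baseline only
  p_base <- full_model_params(a_h = 0.1, b_h = -500, rho0 = rho0, kappa_e = 0,
                              d0_e = 100, mu = 0, a_beta = 0.1, b_beta = -1,
                              gamma = 0.2)
  expect_equal(unname(expected_deaths(temps, 1, fx, p_base, r)), rho0)
  # warm arm only
  p_warm <- full_model_params(a_h = 0.1, b_h = -10, rho0 = rep(0, 6), kappa_e = 0,
                              d0_e = 100, mu = 0, a_beta = 0.1, b_beta = -1,
                              gamma = 0.2)
  expect_equal(unname(expected_deaths(temps, 1, fx, p_warm, r)),
               r$population * exp(0.1 * 8 - 10), tolerance = 1e-12)
  # full model is the sum of the three parts
  p_full <- full_model_params(a_h = 0.1, b_h = -10, rho0 = rho0, kappa_e = 0,
                              d0_e = 100, mu = 0.3, a_beta = 0.08, b_beta = 0.2,
                              gamma = 0.25)
  r30 <- run_monthly_epidemic(temps, 1, fx, p_full, r)
  expect_equal(unname(expected_deaths(temps, 1, fx, p_full, r)),
               unname(r$population * exp(0.1 * 8 - 10) + rho0 + 0.3 * r30),
               tolerance = 1e-12)
})

test_that("the C++ epidemic engine matches the R implementation", {
  tr <- truth6()
  p <- tr$true_model
  ep <- episodic_flux(tr$regions, tr$distances, p$kappa_e, p$d0_e)
  ft <- total_flux(tr$commuter_flux, ep)
  for (m in c(1, 7, 30)) {
    temps <- as.numeric(tr$temperatures[, m])
    i0 <- ((m - 1) %% 6) + 1
    rR <- suppressWarnings(run_monthly_epidemic(temps, i0, ft, p, tr$regions))
    rC <- mortnet:::cpp_sir_r30(tr$regions$population, unclass(ft),
                                matrix(temps), as.integer(i0),
                                p$a_beta, p$b_beta, p$gamma)
    expect_equal(unname(rR), as.numeric(rC), tolerance = 1e-12)
  }
})
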