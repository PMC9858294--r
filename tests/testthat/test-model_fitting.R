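test_that("mean Poisson log-likelihood matches hand-computed values", {
  expect_equal(poisson_loglik(0, 1), -1)
  # lambda = n: (2 log 2 - 2 + 3 log 3 - 3) / 2
  expect_equal(poisson_loglik(c(2, 3), c(2, 3)),
               (2 * log(2) - 2 + 3 * log(3) - 3) / 2, tolerance = 1e-12)
  # stationarity at lambda = n
  base <- poisson_loglik(c(2, 3), c(2, 3))
  expect_lt(poisson_loglik(c(2, 3), c(2, 3) * 1.01), base)
  expect_lt(poisson_loglik(c(2, 3), c(2, 3) * 0.99), base)
  expect_error(poisson_loglik(c(2, 3), c(-1, 3)), "zero-probability")
})

test_that("outflow-fraction prior is flat inside and quadratic outside", {
  r <- toy_regions(pop = c(1000, 1000), gdp = c(1, 1),
                   lat = c(40, 42), lon = c(9, 11))
  # fractions: A-out = 250/1000 = 0.25, B-out = 100/1000 = 0.10
  f <- matrix(c(0, 250, 100, 0), 2, 2, dimnames = list(r$region_id, r$region_id))
  expect_equal(flux_fraction_prior(flux_matrix(f, "total"), r, stiffness = 1e6),
               -1e6 * 0.05^2)
  f_in <- matrix(c(0, 100, 100, 0), 2, 2, dimnames = list(r$region_id, r$region_id))
  expect_identical(flux_fraction_prior(flux_matrix(f_in, "total"), r), 0)
  # flat region: small perturbations inside the range do not change the prior
  f_in2 <- f_in * 1.5
  expect_identical(flux_fraction_prior(flux_matrix(f_in2, "total"), r), 0)
})

test_that("episodic decay-length prior follows its quadratic form", {
  expect_identical(d0e_log_prior(0), 0)
  expect_equal(d0e_log_prior(1000), -0.974, tolerance = 1e-12)
  d <- seq(0, 2000, by = 100)
  expect_true(all(diff(d0e_log_prior(d)) < 0))
})

test_that("correlation regularizer matches a direct formula evaluation", {
  set.seed(44)
  n <- 20
  model <- matrix(rnorm(n * 15), n, 15)
  data_counts <- matrix(rpois(n * 15, 50), n, 15)
  dc <- cor(t(data_counts))
  ups <- 8.76e2
  pen <- correlation_regularizer(model, dc, ups)
  # independent direct evaluation
  mc <- cor(t(model))
  expected <- -ups / 190 * sum((mc[upper.tri(mc)] - dc[upper.tri(dc)])^2)
  expect_equal(pen, expected, tolerance = 1e-12)

  # perfect match gives zero penalty
  expect_equal(correlation_regularizer(data_counts, dc, ups), 0, tolerance = 1e-12)

  # two regions, model corr 1 vs data corr 0, weight 1
  m2 <- rbind(1:10, 1:10 * 2)
  d2 <- diag(2)
  expect_equal(correlation_regularizer(m2, d2, 1), -1, tolerance = 1e-12)

  # zero-variance series are skipped with a warning
  m0 <- model
  m0[1, ] <- 7
  expect_warning(p0 <- correlation_regularizer(m0, dc, ups), "zero-variance")
  mc0 <- cor(t(m0[-1, ]))
  expected0 <- -ups / 190 * sum((mc0[upper.tri(mc0)] - dc[-1, -1][upper.tri(mc0)])^2)
  expect_equal(p0, expected0, tolerance = 1e-12)
})

test_that("learning-rate schedule decays with the documented power law", {
  cfg <- fit_config()
  expect_equal(learning_rate(0, cfg), 1e-3, tolerance = 1e-15)
  expect_equal(learning_rate(1e4, cfg), 1e-3 * 2^(-0.75), tolerance = 1e-15)
  expect_equal(learning_rate(2e4, cfg) / learning_rate(0, cfg), 3^(-0.75),
               tolerance = 1e-12)
  steps <- seq(0, 1e5, by = 1e3)
  expect_true(all(diff(learning_rate(steps, cfg)) < 0))
})

test_that("calendar split holds out one exemplar of each month", {
  months <- month_seq(108)
  split <- make_split(months, seed = 11)
  expect_length(split$train_months, 96)
  expect_length(split$test_months, 12)
  expect_setequal(union(split$train_months, split$test_months), months)
  cal <- as.integer(substr(split$test_months, 6, 7))
  expect_setequal(cal, 1:12)
  # exactly 3 years contribute two test months, spaced 6 calendar months apart
  yrs <- substr(split$test_months, 1, 4)
  twice <- names(which(table(yrs) == 2))
  expect_length(twice, 3)
  for (y in twice) {
    cal_y <- sort(as.integer(substr(split$test_months[yrs == y], 6, 7)))
    expect_equal(diff(cal_y), 6)
  }
  expect_identical(make_split(months, seed = 11), split)
  expect_false(identical(make_split(months, seed = 12), split))
  expect_error(make_split(months[1:100], seed = 1), "9 full years")
  u <- make_split(months[1:40], seed = 2, method = "uniform")
  expect_length(intersect(u$train_months, u$test_months), 0)
})

test_that("the C++ objective agrees with the R-level components", {
  tr <- truth6()
  p <- tr$true_model
  n <- 6
  theta <- mortnet:::theta_pack(p)
  b_idx <- c(1, 15, 30, 55, 80, 100, 7, 61)
  i0 <- c(1L, 3L, 2L, 6L, 4L, 5L, 2L, 1L)
  res <- mortnet:::cpp_batch_objective(
    theta, tr$regions$population, tr$regions$gdp,
    unclass(tr$distances), unclass(tr$commuter_flux),
    unclass(tr$temperatures)[, b_idx], unclass(tr$deaths)[, b_idx], i0,
    TRUE, 8.76e2, 0, 0.2, 1e6, 9.74e-7
  )
  # Poisson part via the R pipeline
  lam <- expected_deaths_panel(p, tr$temperatures[, b_idx], tr$commuter_flux,
                               tr$regions, tr$distances,
                               i0_seq = tr$regions$region_id[i0])
  expect_equal(res$loglik,
               poisson_loglik(unclass(tr$deaths)[, b_idx], unclass(lam)),
               tolerance = 1e-10)
  # priors via the R functions
  ep <- episodic_flux(tr$regions, tr$distances, p$kappa_e, p$d0_e)
  ft <- total_flux(tr$commuter_flux, ep)
  expect_equal(res$prior_flux, flux_fraction_prior(ft, tr$regions), tolerance = 1e-10)
  expect_equal(res$prior_d0e, d0e_log_prior(p$d0_e), tolerance = 1e-12)
  # correlation regularizer via the R function
  dc <- cor(t(unclass(tr$deaths)[, b_idx]))
  expect_equal(res$corr_pen,
               correlation_regularizer(unclass(lam), dc, 8.76e2),
               tolerance = 1e-10)
  expect_equal(res$value,
               res$loglik + res$prior_flux + res$prior_d0e + res$corr_pen)
})

test_that("finite-difference gradients match a dense numerical check", {
  tr <- truth6()
  theta <- mortnet:::theta_pack(tr$true_model)
  b_idx <- c(2, 40, 90, 101)
  i0 <- c(2L, 1L, 4L, 6L)
  args <- list(tr$regions$population, tr$regions$gdp, unclass(tr$distances),
               unclass(tr$commuter_flux), unclass(tr$temperatures)[, b_idx],
               unclass(tr$deaths)[, b_idx], i0, TRUE, 8.76e2, 0, 0.2, 1e6, 9.74e-7)
  g <- do.call(mortnet:::cpp_objective_grad, c(list(theta), args))
  f <- function(th) do.call(mortnet:::cpp_batch_objective, c(list(th), args))$value
  for (k in c(1, 2, 5, 9, 10, 11, 12, 13, 14)) {
    h <- 1e-5 * max(1, abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    expect_equal(g$grad[k], (f(tp) - f(tm)) / (2 * h),
                 tolerance = 1e-6, label = sprintf("grad component %d", k))
  }
})

test_that("full-model fitting is deterministic and reduces to the plain likelihood", {
  tr <- truth6()
  split <- make_split(colnames(tr$deaths), seed = 2)
  cfg <- fit_config(n_steps = 60, phase_switch_step = 30, nbatch_phase1 = 5,
                    nbatch_phase2 = 10, seed = 4, log_every = 20,
                    test_eval_every = 30)
  f1 <- fit_full_model(tr$deaths, tr$temperatures, tr$commuter_flux, tr$regions,
                       tr$distances, split, cfg)
  f2 <- fit_full_model(tr$deaths, tr$temperatures, tr$commuter_flux, tr$regions,
                       tr$distances, split, cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$training_log, f2$training_log)

  # with upsilon = 0 and priors in their flat region, the objective is the
  # batch Poisson log-likelihood alone
  theta <- mortnet:::theta_pack(tr$true_model)
  b_idx <- seq_len(20)
  i0 <- rep(1L, 20)
  res <- mortnet:::cpp_batch_objective(
    theta, tr$regions$population, tr$regions$gdp, unclass(tr$distances),
    unclass(tr$commuter_flux), unclass(tr$temperatures)[, b_idx],
    unclass(tr$deaths)[, b_idx], i0, FALSE, 0, 0, 0.2, 1e6, 0
  )
  expect_equal(res$value, res$loglik)
})

test_that("the trainer recovers a mu = 0 warm-plus-baseline model", {
  r <- generate_regions(5, seed = 23)
  temps <- generate_temperatures(r, 108, seed = 5)
  true_p <- full_model_params(
    a_h = 0.12, b_h = -11.3, rho0 = 5e-4 * r$population,
    kappa_e = 1e-9, d0_e = 200, mu = 0,
    a_beta = 0.08, b_beta = 0.35, gamma = 0.3
  )
  truth <- list(regions = r, temperatures = temps,
                commuter_flux = generate_commuters(r, seed = 6),
                true_model = true_p)
  deaths <- suppressWarnings(generate_mortality_panel(truth, seed = 7))
  split <- make_split(colnames(deaths), seed = 3)
  cfg <- fit_config(n_steps = 5000, phase_switch_step = 4000, seed = 9,
                    log_every = 500, test_eval_every = 2500)
  fit <- fit_full_model(deaths, temps, truth$commuter_flux, r, split = split,
                        cfg = cfg)
  lam_true <- attr(deaths, "lambda")
  lam_fit <- unclass(fit$fitted_lambda)
  rel_rms <- sqrt(mean((lam_fit / lam_true - 1)^2))
  expect_lt(rel_rms, 0.05)
  # training improved on the deterministic warm start
  theta0 <- mortnet:::init_theta(deaths, temps, truth$commuter_flux, r,
                                 distance_matrix(r),
                                 match(split$train_months, colnames(deaths)))
  lam0 <- unclass(expected_deaths_panel(mortnet:::theta_unpack(theta0, 5), temps,
                                        truth$commuter_flux, r))
  rel_rms0 <- sqrt(mean((lam0 / lam_true - 1)^2))
  expect_lt(rel_rms, rel_rms0)
})
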