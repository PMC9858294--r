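#' Configuration of the stochastic maximum-likelihood fit
#'
#' Defaults follow the training machinery of the full model: Adam
#' (`beta1 = 0.9`, `beta2 = 0.99`) with learning rate
#' `lr(step) = lr0 * (1 + step / lr_decay_scale)^(-lr_exponent)`, a first
#' phase of `phase_switch_step` steps with small batches (`nbatch = 10`),
#' then larger batches (`nbatch = 100`) plus the correlation regularizer
#' with weight `upsilon_corr = 8.76e2`; a soft flat prior keeping each
#' region's daily outflow fraction inside `[0, 0.2]`, and a quadratic
#' log-prior `-9.74e-7 * d0_e^2` on the episodic decay length.
#'
#' @param n_steps total optimisation steps (default 1e6; scale down for
#'   desk-size problems).
#' @param nbatch_phase1,nbatch_phase2 batch sizes before/after the switch.
#' @param phase_switch_step step at which the batch grows and the
#'   correlation regularizer switches on.
#' @param upsilon_corr correlation-regularizer weight.
#' @param flux_fraction_range allowed daily outflow fraction range.
#' @param flux_prior_stiffness quadratic penalty weight outside the range.
#' @param d0e_prior_coeff coefficient (per km^2) of the d0_e log-prior.
#' @param lr0,lr_decay_scale,lr_exponent learning-rate schedule.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @param seed integer seed driving batching and patient-zero draws.
#' @param test_eval_every evaluate the held-out log-likelihood every this
#'   many steps.
#' @param test_i0_draws Monte-Carlo patient-zero draws per test month.
#' @param log_every record the training objective every this many steps.
#' @param fd_h relative finite-difference step for the gradient.
#' @return a `fit_config` list.
#' @export
fit_config <- function(n_steps = 1e6, nbatch_phase1 = 10, nbatch_phase2 = 100,
                       phase_switch_step = 1e4, upsilon_corr = 8.76e2,
                       flux_fraction_range = c(0, 0.2),
                       flux_prior_stiffness = 1e6,
                       d0e_prior_coeff = 9.74e-7,
                       lr0 = 1e-3, lr_decay_scale = 1e4, lr_exponent = 0.75,
                       adam_beta1 = 0.9, adam_beta2 = 0.99, adam_eps = 1e-8,
                       seed = 1, test_eval_every = 1000, test_i0_draws = 5,
                       log_every = 100, fd_h = 1e-5) {
  cfg <- as.list(environment())
  if (cfg$n_steps <= 0 || cfg$nbatch_phase1 <= 0 || cfg$nbatch_phase2 <= 0 ||
      cfg$phase_switch_step <= 0) {
    abort("all step/batch counts must be positive")
  }
  if (cfg$upsilon_corr < 0) abort("upsilon_corr must be >= 0")
  structure(cfg, class = "fit_config")
}

#' Learning-rate schedule
#'
#' `lr(step) = lr0 * (1 + step / lr_decay_scale)^(-lr_exponent)`, monotone
#' decreasing from `lr0`.
#'
#' @param step optimisation step (>= 0).
#' @param cfg a [fit_config()].
#' @return learning rate.
#' @export
learning_rate <- function(step, cfg = fit_config()) {
  if (any(step < 0)) abort("step must be >= 0")
  cfg$lr0 * (1 + step / cfg$lr_decay_scale)^(-cfg$lr_exponent)
}

#' Mean Poisson log-likelihood of a panel slice
#'
#' `(1 / N) * sum(n * log(lambda) - lambda)` over all cells; the constant
#' `log(n!)` terms are dropped.
#'
#' @param counts observed counts (vector or matrix).
#' @param lambdas matching Poisson means.
#' @return mean log-likelihood (scalar).
#' @export
poisson_loglik <- function(counts, lambdas) {
  if (length(counts) != length(lambdas)) abort("counts and lambdas lengths differ")
  if (any(lambdas <= 0 & counts > 0)) {
    abort("lambda <= 0 with observed counts > 0: zero-probability data")
  }
  term <- ifelse(counts > 0, counts * log(lambdas), 0) - lambdas
  mean(term)
}

#' Soft flat prior on the daily outflow fraction
#'
#' Zero while every region's outflow fraction `sum_k f_ki / pop_i` stays in
#' `range`; quadratic (`-stiffness * excess^2`, summed over regions)
#' outside it.
#'
#' @param flux total [flux_matrix()].
#' @param regions region tibble.
#' @param range allowed `[lo, hi]` fraction interval.
#' @param stiffness quadratic penalty weight (> 0).
#' @return log-prior (<= 0).
#' @export
flux_fraction_prior <- function(flux, regions, range = c(0, 0.2),
                                stiffness = 1e6) {
  if (stiffness <= 0) abort("stiffness must be > 0")
  regions <- validate_region_table(regions)
  f <- unclass(flux)[regions$region_id, regions$region_id, drop = FALSE]
  frac <- colSums(f) / regions$population
  excess <- pmax(frac - range[2], 0) + pmax(range[1] - frac, 0)
  -stiffness * sum(excess^2)
}

#' Quadratic log-prior on the episodic decay length
#'
#' `log p(d0_e) = -coeff * d0_e^2` (up to a constant), penalising very long
#' episodic decay lengths.
#'
#' @param d0_e decay length, km (>= 0).
#' @param coeff per-km^2 coefficient (default 9.74e-7).
#' @return log-prior (up to a constant).
#' @export
d0e_log_prior <- function(d0_e, coeff = 9.74e-7) {
  if (any(d0_e < 0)) abort("d0_e must be >= 0")
  -coeff * d0_e^2
}

#' Correlation-network regularizer
#'
#' `-(upsilon / n_pairs) * sum_{i>j} (corr_model_ij - corr_data_ij)^2` with
#' `n_pairs = n(n-1)/2` (190 for 20 regions). Pairs whose model series has
#' zero variance in the batch are skipped with a warning.
#'
#' @param model_series region x month matrix of model expectations.
#' @param data_corr a `correlation_matrix` of the observed counts over the
#'   matching months.
#' @param upsilon regularizer weight.
#' @return penalty (<= 0).
#' @export
correlation_regularizer <- function(model_series, data_corr, upsilon) {
  n <- nrow(model_series)
  if (n < 2) abort("need at least 2 regions")
  if (ncol(model_series) < 3) abort("need at least 3 months in the batch")
  n_pairs <- n * (n - 1) / 2
  sds <- apply(model_series, 1, sd)
  dc <- unclass(data_corr)
  pen <- 0
  skipped <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sds[i] == 0 || sds[j] == 0 || !is.finite(dc[i, j])) {
        skipped <- skipped + 1
        next
      }
      cm <- cor(model_series[i, ], model_series[j, ])
      pen <- pen - (cm - dc[i, j])^2
    }
  }
  if (skipped > 0) {
    warn(sprintf("%d zero-variance pair(s) skipped in the correlation regularizer",
                 skipped))
  }
  upsilon / n_pairs * pen
}

#' Calendar-balanced train/test month split
#'
#' For a 9-year (108-month) panel, holds out 12 test months containing one
#' exemplar of each calendar month January-December; since only 9 years are
#' available, exactly 3 randomly selected years contribute two test months
#' spaced 6 calendar months apart (e.g. April and October), and the other
#' 6 years one each. The remaining 96 months form the training set.
#'
#' @param months character vector of `"YYYY-MM"` labels.
#' @param seed integer seed.
#' @param method `"calendar"` (the protocol above) or `"uniform"` (plain
#'   random 12-month holdout for generic month lists).
#' @return list with `train_months` and `test_months` (sorted).
#' @export
make_split <- function(months, seed = 1, method = c("calendar", "uniform")) {
  method <- match.arg(method)
  months <- sort(months)
  if (method == "uniform") {
    return(with_seed(seed, {
      test <- sort(sample(months, min(12, length(months) %/% 4)))
      list(train_months = setdiff(months, test), test_months = test)
    }))
  }
  years <- substr(months, 1, 4)
  cal <- as.integer(substr(months, 6, 7))
  tab <- table(years)
  if (length(months) != 108 || length(tab) != 9 || any(tab != 12)) {
    abort("calendar split needs 108 months forming 9 full years; use method = 'uniform' otherwise")
  }
  yrs <- names(tab)
  with_seed(seed, {
    pair_bases <- sample(1:6, 3)              # calendar months hosting (m, m+6) pairs
    pair_years <- sample(yrs, 3)              # the 3 years contributing two months
    single_cals <- setdiff(1:12, c(pair_bases, pair_bases + 6))
    single_years <- sample(setdiff(yrs, pair_years))  # random year per leftover month
    test <- c(
      sprintf("%s-%02d", rep(pair_years, each = 2),
              as.vector(rbind(pair_bases, pair_bases + 6))),
      sprintf("%s-%02d", single_years, single_cals)
    )
    test <- sort(test)
    list(train_months = setdiff(months, test), test_months = test)
  })
}

theta_pack <- function(p) {
  c(log(p$a_h), p$b_h, log(p$rho0), log(p$kappa_e), log(p$d0_e),
    log(p$mu / (1 - p$mu)), log(p$a_beta), p$b_beta, log(p$gamma))
}

theta_unpack <- function(theta, n) {
  full_model_params(
    a_h = exp(theta[1]), b_h = theta[2],
    rho0 = exp(theta[3:(n + 2)]),
    kappa_e = exp(theta[n + 3]), d0_e = exp(theta[n + 4]),
    mu = stats::plogis(theta[n + 5]),
    a_beta = exp(theta[n + 6]), b_beta = theta[n + 7],
    gamma = exp(theta[n + 8])
  )
}

# deterministic warm-start for the full-model fit
init_theta <- function(deaths, temps, commuters, regions, dist, train_idx) {
  n <- nrow(regions)
  d_tr <- unclass(deaths)[, train_idx, drop = FALSE]
  t_tr <- unclass(temps)[, train_idx, drop = FALSE]
  rho0 <- pmax(rowMeans(d_tr) * 0.8, 1)
  # warm-arm pre-fit on the hottest tercile of cells
  hot <- t_tr >= quantile(t_tr, 2 / 3)
  y <- log(pmax(d_tr[hot] - rho0[row(d_tr)[hot]], 0.1) / regions$population[row(d_tr)[hot]])
  pre <- lm(y ~ t_tr[hot])
  a_h <- max(coef(pre)[[2]], 0.01)
  b_h <- coef(pre)[[1]]
  d0_e <- tryCatch(2 * fit_gravity(commuters, dist, regions)$d0, error = function(e) 300)
  if (!is.finite(d0_e) || d0_e <= 0) d0_e <- 300
  e1 <- episodic_flux(regions, dist, 1, d0_e)
  kappa_e <- 0.01 / max(colSums(unclass(e1)) / regions$population)
  theta_pack(list(a_h = a_h, b_h = b_h, rho0 = rho0, kappa_e = kappa_e,
                  d0_e = d0_e, mu = 0.05, a_beta = 0.1, b_beta = -1,
                  gamma = 0.2))
}

#' Fit the full flux-temperature model by stochastic maximum likelihood
#'
#' Trains the `8 + n` model parameters with Adam on the batched Poisson
#' log-likelihood plus the outflow-fraction and `d0_e` priors, adding the
#' correlation regularizer after the phase switch. Each step samples
#' `nbatch` training months with replacement and one GDP-distributed
#' patient zero per sampled month; positivity constraints are enforced by
#' optimising log- (and, for `mu`, logit-) transformed parameters.
#' Deterministic given `cfg$seed`.
#'
#' @param deaths `"deaths"` [monthly_panel()].
#' @param temps matching `"temperature"` panel.
#' @param commuters commuter [flux_matrix()].
#' @param regions region tibble.
#' @param dist distance matrix (km); computed from `regions` when `NULL`.
#' @param split a [make_split()] result; a seeded calendar split when `NULL`.
#' @param cfg a [fit_config()].
#' @return a `mortnet_fit`: `params` ([full_model_params()]), `theta`,
#'   `training_log` tibble (`step, lr, train_obj, loglik, test_ll`),
#'   `fitted_lambda` (expectation-over-patient-zero `"expected"` panel),
#'   `split`, `cfg`, `clamped` (total Euler clamps seen).
#' @export
fit_full_model <- function(deaths, temps, commuters, regions, dist = NULL,
                           split = NULL, cfg = fit_config()) {
  regions <- validate_region_table(regions)
  stopifnot_same_shape(deaths, temps)
  n <- nrow(regions)
  if (is.null(dist)) dist <- distance_matrix(regions)
  months <- colnames(deaths)
  if (is.null(split)) split <- make_split(months, seed = cfg$seed)
  train_idx <- match(split$train_months, months)
  test_idx <- match(split$test_months, months)
  if (anyNA(train_idx) || anyNA(test_idx)) abort("split months missing from the panel")

  pop <- regions$population
  gdp <- regions$gdp
  d_m <- unclass(dist)[regions$region_id, regions$region_id]
  c_m <- unclass(commuters)[regions$region_id, regions$region_id]
  t_m <- unclass(temps)
  n_m <- unclass(deaths)
  p0 <- patient_zero_distribution(regions)

  theta <- init_theta(deaths, temps, commuters, regions, dist, train_idx)
  adam_m <- numeric(length(theta))
  adam_v <- numeric(length(theta))
  log_rows <- list()
  total_clamped <- 0

  grad_call <- function(theta, b_idx, i0, phase2, upsilon) {
    cpp_objective_grad(
      theta, pop, gdp, d_m, c_m,
      t_m[, b_idx, drop = FALSE], n_m[, b_idx, drop = FALSE], i0,
      phase2, upsilon,
      cfg$flux_fraction_range[1], cfg$flux_fraction_range[2],
      cfg$flux_prior_stiffness, cfg$d0e_prior_coeff,
      1.0, 30L, cfg$fd_h
    )
  }
  test_ll_fun <- function(theta) {
    i0 <- sample(seq_len(n), length(test_idx) * cfg$test_i0_draws,
                 replace = TRUE, prob = p0)
    idx <- rep(test_idx, times = cfg$test_i0_draws)
    res <- cpp_batch_objective(
      theta, pop, gdp, d_m, c_m,
      t_m[, idx, drop = FALSE], n_m[, idx, drop = FALSE], i0,
      FALSE, 0,
      cfg$flux_fraction_range[1], cfg$flux_fraction_range[2],
      cfg$flux_prior_stiffness, cfg$d0e_prior_coeff, 1.0, 30L
    )
    res$loglik
  }

  with_seed(cfg$seed, {
    last_test_ll <- NA_real_
    for (step in seq_len(cfg$n_steps)) {
      phase2 <- step > cfg$phase_switch_step
      nbatch <- if (phase2) cfg$nbatch_phase2 else cfg$nbatch_phase1
      b_idx <- sample(train_idx, nbatch, replace = TRUE)
      i0 <- sample(seq_len(n), nbatch, replace = TRUE, prob = p0)
      res <- grad_call(theta, b_idx, i0, phase2, cfg$upsilon_corr)
      total_clamped <- total_clamped + res$clamped
      g <- res$grad
      adam_m <- cfg$adam_beta1 * adam_m + (1 - cfg$adam_beta1) * g
      adam_v <- cfg$adam_beta2 * adam_v + (1 - cfg$adam_beta2) * g^2
      m_hat <- adam_m / (1 - cfg$adam_beta1^step)
      v_hat <- adam_v / (1 - cfg$adam_beta2^step)
      theta <- theta + learning_rate(step, cfg) * m_hat / (sqrt(v_hat) + cfg$adam_eps)
      if (step %% cfg$test_eval_every == 0) last_test_ll <- test_ll_fun(theta)
      if (step %% cfg$log_every == 0 || step == cfg$n_steps) {
        log_rows[[length(log_rows) + 1]] <- tibble(
          step = step, lr = learning_rate(step, cfg),
          train_obj = res$value, loglik = res$loglik,
          test_ll = last_test_ll
        )
      }
    }
  })

  params <- theta_unpack(theta, n)
  fitted_lambda <- expected_deaths_panel(params, temps, commuters, regions, dist)
  structure(
    list(params = params, theta = theta,
         training_log = dplyr::bind_rows(log_rows),
         fitted_lambda = fitted_lambda, split = split, cfg = cfg,
         regions = regions, clamped = total_clamped),
    class = "mortnet_fit"
  )
}

#' Model-expected deaths panel, marginal over the patient zero
#'
#' Evaluates `lambda_im` for every month, averaging the infective component
#' over the GDP-distributed patient-zero location (exact weighted sum over
#' all regions, not Monte Carlo).
#'
#' @param params [full_model_params()].
#' @param temps temperature panel.
#' @param commuters commuter [flux_matrix()].
#' @param regions region tibble.
#' @param dist distance matrix; computed when `NULL`.
#' @param i0_seq optional per-month patient-zero ids/indices; when given,
#'   the conditional (not marginal) expectation is returned.
#' @return an `"expected"` [monthly_panel()].
#' @export
expected_deaths_panel <- function(params, temps, commuters, regions,
                                  dist = NULL, i0_seq = NULL) {
  regions <- validate_region_table(regions)
  if (is.null(dist)) dist <- distance_matrix(regions)
  n <- nrow(regions)
  n_months <- ncol(temps)
  episodic <- episodic_flux(regions, dist, params$kappa_e, params$d0_e)
  f_tot <- unclass(total_flux(commuters, episodic))
  t_m <- unclass(temps)
  if (is.null(i0_seq)) {
    idx <- rep(seq_len(n_months), each = n)
    i0 <- rep(seq_len(n), times = n_months)
  } else {
    if (is.character(i0_seq)) i0_seq <- match(i0_seq, regions$region_id)
    idx <- seq_len(n_months)
    i0 <- i0_seq
  }
  r30 <- cpp_sir_r30(regions$population, f_tot, t_m[, idx, drop = FALSE],
                     i0, params$a_beta, params$b_beta, params$gamma)
  warm <- regions$population * exp(params$a_h * t_m + params$b_h) + params$rho0
  if (is.null(i0_seq)) {
    p0 <- patient_zero_distribution(regions)
    inf_part <- vapply(seq_len(n_months), function(m) {
      cols <- ((m - 1) * n + 1):(m * n)
      as.vector(r30[, cols, drop = FALSE] %*% p0)
    }, numeric(n))
  } else {
    inf_part <- r30
  }
  lam <- warm + params$mu * inf_part
  dimnames(lam) <- dimnames(t_m)
  monthly_panel(lam, "expected")
}

#' @export
print.mortnet_fit <- function(x, ...) {
  gl <- glance(x)
  cat(sprintf("<mortnet_fit> %d regions, %d + %d train/test months\n",
              length(x$params$rho0), length(x$split$train_months),
              length(x$split$test_months)))
  cat(sprintf("  final objective %.4f, test LL %s after %d steps\n",
              gl$train_obj, format(gl$test_ll, digits = 5), gl$n_steps))
  print(x$params)
  invisible(x)
}

#' @export
tidy.mortnet_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("a_h", "b_h", paste0("rho0[", x$regions$region_id, "]"),
             "kappa_e", "d0_e", "mu", "a_beta", "b_beta", "gamma"),
    estimate = c(p$a_h, p$b_h, p$rho0, p$kappa_e, p$d0_e, p$mu,
                 p$a_beta, p$b_beta, p$gamma)
  )
}

#' @export
glance.mortnet_fit <- function(x, ...) {
  tl <- x$training_log
  tibble(
    n_steps = max(tl$step), train_obj = tl$train_obj[nrow(tl)],
    test_ll = tl$test_ll[nrow(tl)],
    n_params = 8 + length(x$params$rho0),
    clamped_steps = x$clamped
  )
}

#' @export
#' @rdname fit_full_model
#' @param object a `mortnet_fit`.
#' @param ... unused.
autoplot.mortnet_fit <- function(object, ...) {
  tl <- object$training_log
  ggplot2::ggplot(tl, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$train_obj, colour = "train objective")) +
    ggplot2::geom_line(
      data = tl[!is.na(tl$test_ll), ],
      ggplot2::aes(y = .data$test_ll, colour = "test log-likelihood")
    ) +
    ggplot2::labs(x = "Adam step", y = "mean log-likelihood (nats)",
                  colour = NULL, title = "Training trajectory")
}
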