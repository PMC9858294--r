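#' Daytime mixing matrices for the metapopulation SIR
#'
#' From the total-flux matrix `f` (entry `[i, j]` = persons/day moving from
#' region j to region i) build:
#' \itemize{
#'   \item `phi`: the column-stochastic daytime presence matrix,
#'     `phi[i, j] = f[i, j] / pop_j` off the diagonal and
#'     `1 - sum_k f[k, j] / pop_j` on it (the fraction of j's residents that
#'     stay home);
#'   \item `phi_hat`: the evening redistribution matrix,
#'     `phi_hat[i, j] = phi[j, i] / sum_k phi[j, k]`, i.e. newly infected
#'     people generated while pooled in region j are sent back in proportion
#'     to the fraction each origin contributed. Both matrices have columns
#'     summing to one, which is what makes the dynamics conserve people.
#' }
#'
#' @param flux a [flux_matrix()] (persons/day).
#' @param regions region tibble (populations).
#' @return list with matrices `phi` and `phi_hat` and the per-region
#'   `outflow_fraction`.
#' @export
mixing_matrices <- function(flux, regions) {
  regions <- validate_region_table(regions)
  pop <- setNames(regions$population, regions$region_id)
  f <- unclass(flux)[regions$region_id, regions$region_id, drop = FALSE]
  n <- nrow(f)
  outflow <- colSums(f) / pop
  if (any(outflow >= 1)) {
    bad <- names(which(outflow >= 1))
    abort(sprintf("daily outflow exceeds the resident population for region(s): %s",
                  paste(bad, collapse = ", ")))
  }
  phi <- sweep(f, 2, pop, "/")
  diag(phi) <- 1 - outflow
  row_tot <- rowSums(phi)
  phi_hat <- t(phi / row_tot)
  list(phi = phi, phi_hat = phi_hat, outflow_fraction = outflow)
}

#' Temperature-modulated transmission rate
#'
#' `beta(T) = exp(-a_beta * T + b_beta)`, capped just below `1/dt`: a full
#' population infected within one Euler step is the hard ceiling of the
#' discretisation, beyond which the scheme goes unphysical.
#'
#' @param temp temperature(s), degrees C.
#' @param a_beta cooling sensitivity (1/degC, > 0): transmission decreases
#'   with temperature.
#' @param b_beta log-rate intercept.
#' @param dt Euler step in days (default 1).
#' @return transmission rate(s), 1/day.
#' @export
beta_of_temperature <- function(temp, a_beta, b_beta, dt = 1) {
  if (a_beta <= 0) abort("a_beta must be > 0")
  pmin(exp(-a_beta * temp + b_beta), (1 - 1e-9) / dt)
}

#' One Euler step of the network SIR
#'
#' Incidence is computed in the daytime pools (`dI_l = beta_l / pop_l *
#' (phi S)_l * (phi I)_l`) and redistributed to home regions through
#' `phi_hat`; recovery removes `gamma * I`. States that would go negative
#' are clamped at zero and counted in the `clamped` attribute (a warning is
#' raised), never silently.
#'
#' @param state list with numeric vectors `S`, `I`, `R`.
#' @param mix output of [mixing_matrices()].
#' @param beta per-region (pool) transmission rates, 1/day.
#' @param gamma recovery rate, 1/day.
#' @param regions region tibble.
#' @param dt Euler step, days.
#' @return updated state list (with `clamped` count attribute when any
#'   clamp fired).
#' @export
sir_step <- function(state, mix, beta, gamma, regions, dt = 1) {
  pop <- regions$population
  s_pool <- as.vector(mix$phi %*% state$S)
  i_pool <- as.vector(mix$phi %*% state$I)
  d_i_pool <- beta / pop * s_pool * i_pool
  d_i <- as.vector(mix$phi_hat %*% d_i_pool)
  if (any(!is.finite(d_i))) abort("non-finite incidence in SIR step")
  s_new <- state$S - dt * d_i
  i_new <- state$I + dt * (d_i - gamma * state$I)
  r_new <- state$R + dt * gamma * state$I
  clamped <- sum(s_new < 0) + sum(i_new < 0)
  if (clamped > 0) {
    warn(sprintf("SIR Euler step overshot zero in %d compartment(s); clamped", clamped))
    s_new <- pmax(s_new, 0)
    i_new <- pmax(i_new, 0)
  }
  out <- list(S = s_new, I = i_new, R = r_new)
  if (clamped > 0) attr(out, "clamped") <- clamped
  out
}

#' Run one month's epidemic from a single patient zero
#'
#' The epidemic restarts every month: the whole population is susceptible
#' except one infected individual in region `i0`, and the SIR runs for a
#' fixed 30-day month (Euler, `dt = 1`) with region-wise transmission rates
#' from [beta_of_temperature()] evaluated at that month's temperatures.
#'
#' @param month_temps per-region temperatures for the month (named or in
#'   region-table order).
#' @param i0 patient-zero region index (or region id).
#' @param flux total [flux_matrix()].
#' @param params [full_model_params()] list.
#' @param regions region tibble.
#' @param dt,t_end Euler step and month length in days.
#' @return named per-region vector of recovered individuals at `t_end`.
#' @export
run_monthly_epidemic <- function(month_temps, i0, flux, params, regions,
                                 dt = 1, t_end = 30) {
  regions <- validate_region_table(regions)
  n <- nrow(regions)
  if (is.character(i0)) i0 <- match(i0, regions$region_id)
  if (is.na(i0) || i0 < 1 || i0 > n) abort("invalid patient-zero region")
  mix <- mixing_matrices(flux, regions)
  beta <- beta_of_temperature(month_temps, params$a_beta, params$b_beta, dt)
  state <- list(S = regions$population, I = rep(0, n), R = rep(0, n))
  state$S[i0] <- state$S[i0] - 1
  state$I[i0] <- 1
  n_steps <- round(t_end / dt)
  for (s in seq_len(n_steps)) {
    state <- sir_step(state, mix, beta, params$gamma, regions, dt)
  }
  setNames(state$R, regions$region_id)
}

#' Patient-zero seeding distribution
#'
#' Each month's epidemic is seeded in a random region with probability
#' proportional to regional GDP (a proxy for the external traveller flux
#' into the region).
#'
#' @param regions region tibble.
#' @return named probability vector summing to 1.
#' @export
patient_zero_distribution <- function(regions) {
  regions <- validate_region_table(regions)
  setNames(regions$gdp / sum(regions$gdp), regions$region_id)
}

#' Expected monthly deaths under the flux-temperature model
#'
#' `lambda_i = pop_i * exp(a_h * T_i + b_h) + rho0_i + mu * R_i(30)`:
#' a warm-season arm shared across regions, a region-specific baseline, and
#' a fraction `mu` of the month's recovered individuals.
#'
#' @inheritParams run_monthly_epidemic
#' @return named per-region vector of Poisson means.
#' @export
expected_deaths <- function(month_temps, i0, flux, params, regions,
                            dt = 1, t_end = 30) {
  regions <- validate_region_table(regions)
  r30 <- run_monthly_epidemic(month_temps, i0, flux, params, regions, dt, t_end)
  lam <- regions$population * exp(params$a_h * month_temps + params$b_h) +
    params$rho0 + params$mu * r30
  if (any(lam <= 0)) {
    abort("expected deaths must be positive: all model components vanish for some region")
  }
  setNames(lam, regions$region_id)
}

#' Parameters of the full flux-temperature mortality model
#'
#' The model has `8 + n` free parameters for `n` regions: the shared
#' warm-season arm (`a_h`, `b_h`), per-region baselines `rho0`, the episodic
#' gravity flux (`kappa_e`, `d0_e`), the infection-fatality fraction `mu`,
#' the temperature-transmission law (`a_beta`, `b_beta`) and the recovery
#' rate `gamma`.
#'
#' @param a_h warm-arm slope (1/degC, > 0).
#' @param b_h warm-arm log-rate intercept (per person per month).
#' @param rho0 per-region baseline deaths/month (length n, > 0).
#' @param kappa_e episodic-flux scale (>= 0).
#' @param d0_e episodic-flux distance decay, km (> 0).
#' @param mu deaths per recovered individual, in `[0, 1]`.
#' @param a_beta transmission cooling sensitivity (1/degC, > 0).
#' @param b_beta transmission log-rate intercept.
#' @param gamma recovery rate, 1/day (>= 0).
#' @return validated parameter list of class `full_model_params`.
#' @export
full_model_params <- function(a_h, b_h, rho0, kappa_e, d0_e, mu,
                              a_beta, b_beta, gamma) {
  if (a_h <= 0) abort("a_h must be > 0")
  if (a_beta <= 0) abort("a_beta must be > 0")
  if (gamma < 0) abort("gamma must be >= 0")
  if (mu < 0 || mu > 1) abort("mu must lie in [0, 1]")
  if (kappa_e < 0) abort("kappa_e must be >= 0")
  if (d0_e <= 0) abort("d0_e must be > 0")
  if (any(rho0 < 0)) abort("rho0 must be non-negative")
  structure(
    list(a_h = a_h, b_h = b_h, rho0 = rho0, kappa_e = kappa_e, d0_e = d0_e,
         mu = mu, a_beta = a_beta, b_beta = b_beta, gamma = gamma),
    class = "full_model_params"
  )
}

#' @export
print.full_model_params <- function(x, ...) {
  cat(sprintf(
    "<full_model_params> n = %d regions (%d free parameters)\n",
    length(x$rho0), 8 + length(x$rho0)
  ))
  cat(sprintf("  warm arm: a_h = %.4g, b_h = %.4g\n", x$a_h, x$b_h))
  cat(sprintf("  episodic flux: kappa_e = %.4g, d0_e = %.4g km\n", x$kappa_e, x$d0_e))
  cat(sprintf("  infection: mu = %.4g, a_beta = %.4g, b_beta = %.4g, gamma = %.4g\n",
              x$mu, x$a_beta, x$b_beta, x$gamma))
  cat(sprintf("  rho0: %s ...\n", paste(signif(utils::head(x$rho0, 4), 4), collapse = ", ")))
  invisible(x)
}
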