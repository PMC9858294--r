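# Run expr with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic region table
#'
#' Regions are laid out over a roughly 1000 km latitudinal extent with
#' log-uniform populations in `[1e5, 1e7]` and GDPs proportional to
#' population times a log-normal productivity factor (sd 0.3 on the log
#' scale, per-capita scale 0.025 GDP units/person).
#'
#' @param n number of regions (>= 2).
#' @param seed integer seed; the same seed reproduces the same table.
#' @return a validated region tibble.
#' @export
generate_regions <- function(n, seed = 1) {
  if (n < 2) abort("need n >= 2 regions")
  with_seed(seed, {
    tibble(
      region_id = sprintf("R%02d", seq_len(n)),
      name = sprintf("Region %02d", seq_len(n)),
      population = round(10^runif(n, 5, 7)),
      lat = runif(n, 38, 47),
      lon = runif(n, 8, 16)
    ) |>
      dplyr::mutate(gdp = .data$population * 0.025 * rlnorm(n, 0, 0.3)) |>
      dplyr::select("region_id", "name", "population", "gdp", "lat", "lon") |>
      validate_region_table()
  })
}

#' Generate synthetic monthly regional temperatures
#'
#' Seasonal sinusoids with a latitude-linear baseline (18 degC at 38 N
#' falling to 10 degC at 47 N), per-region amplitudes uniform in 8-12 degC,
#' a July peak, and iid N(0, noise_sd) monthly noise.
#'
#' @param regions region tibble.
#' @param n_months number of months (>= 12); labels start at `start_month`.
#' @param seed integer seed.
#' @param noise_sd monthly noise sd, degC (default 1).
#' @param start_month first month label (default `"2011-01"`).
#' @return a `"temperature"` [monthly_panel()].
#' @export
generate_temperatures <- function(regions, n_months = 108, seed = 1,
                                  noise_sd = 1, start_month = "2011-01") {
  regions <- validate_region_table(regions)
  if (n_months < 12) abort("need n_months >= 12")
  n <- nrow(regions)
  months <- month_labels(start_month, n_months)
  cal <- as.integer(substr(months, 6, 7))
  with_seed(seed, {
    base <- 18 - (regions$lat - 38) * (8 / 9)
    amp <- runif(n, 8, 12)
    vals <- outer(base, rep(1, n_months)) +
      outer(amp, cos(2 * pi * (cal - 7) / 12)) +
      matrix(rnorm(n * n_months, 0, noise_sd), n, n_months)
    dimnames(vals) <- list(regions$region_id, months)
    monthly_panel(vals, "temperature")
  })
}

month_labels <- function(start, n) {
  y0 <- as.integer(substr(start, 1, 4))
  m0 <- as.integer(substr(start, 6, 7))
  idx <- (m0 - 1) + seq_len(n) - 1
  sprintf("%04d-%02d", y0 + idx %/% 12, idx %% 12 + 1)
}

#' Generate a synthetic commuter matrix
#'
#' Mean flows follow the combined gravity law
#' `kappa * pop_j * GDP_i * exp(-d_ij / d0)` with multiplicative log-normal
#' scatter; a fraction of the longest-distance pairs is zeroed out exactly,
#' mimicking the empty cells of real origin-destination tables.
#'
#' @param regions region tibble.
#' @param kappa gravity scale (default 4e-7; absorbs the pop x GDP units).
#' @param d0 decay length, km (default 150).
#' @param sigma log-normal scatter sd (default 0.3).
#' @param zero_fraction fraction of off-diagonal pairs zeroed, drawn from
#'   the longest-distance half of the candidates (default 0.1).
#' @param seed integer seed.
#' @param dist optional precomputed distance matrix.
#' @return a `"commuter"` [flux_matrix()].
#' @export
generate_commuters <- function(regions, kappa = 4e-7, d0 = 150, sigma = 0.3,
                               zero_fraction = 0.1, seed = 1, dist = NULL) {
  regions <- validate_region_table(regions)
  if (kappa <= 0 || d0 <= 0 || sigma < 0) abort("kappa, d0 must be > 0 and sigma >= 0")
  if (zero_fraction < 0 || zero_fraction >= 1) abort("zero_fraction must lie in [0, 1)")
  d <- if (is.null(dist)) distance_matrix(regions) else unclass(dist)
  n <- nrow(regions)
  with_seed(seed, {
    mean_flux <- kappa * outer(regions$gdp, regions$population) * exp(-d / d0)
    noise <- matrix(rlnorm(n * n, 0, sigma), n, n)
    c_mat <- mean_flux * noise
    diag(c_mat) <- 0
    n_off <- n * (n - 1)
    n_zero <- round(zero_fraction * n_off)
    if (n_zero > 0) {
      off <- which(off_diagonal_mask(c_mat))
      ord <- off[order(d[off], decreasing = TRUE)]
      pool <- ord[seq_len(min(length(ord), max(n_zero, 2 * n_zero)))]
      zeros <- sample(pool, n_zero)
      c_mat[zeros] <- 0
    }
    dimnames(c_mat) <- list(regions$region_id, regions$region_id)
    flux_matrix(c_mat, "commuter")
  })
}

#' Default ground-truth parameters for the synthetic forward model
#'
#' Chosen so that the infective (winter) and warm-season (summer) mortality
#' components have comparable magnitude, with a region-specific baseline of
#' 5e-4 deaths per person per month. Winter epidemics run large (attack
#' fractions of tens of percent, as in strong influenza seasons) with a
#' small per-infection fatality `mu`; summers are epidemic-free because
#' transmission falls below recovery at warm temperatures.
#'
#' @param regions region tibble.
#' @return a [full_model_params()].
#' @export
default_truth_params <- function(regions) {
  regions <- validate_region_table(regions)
  full_model_params(
    a_h = 0.12, b_h = -11.3,
    rho0 = 5e-4 * regions$population,
    kappa_e = 2e-7, d0_e = 400,
    mu = 0.002,
    a_beta = 0.08, b_beta = 0.35, gamma = 0.3
  )
}

#' Generate a synthetic mortality panel from the forward model
#'
#' For each month a patient-zero region is drawn from the GDP-proportional
#' distribution, the monthly-restarting network SIR is run on the total
#' flux, and counts are sampled Poisson around
#' `lambda_i = pop_i exp(a_h T + b_h) + rho0_i + mu R_i(30)`.
#'
#' @param truth a `synthetic_truth` list (see [synthetic_truth()]), or any
#'   list with `regions`, `temperatures`, `commuter_flux`, `true_model`.
#' @param seed integer seed.
#' @return a `"deaths"` [monthly_panel()] with attributes `i0_seq` (drawn
#'   patient-zero ids) and `lambda` (the true Poisson means).
#' @export
generate_mortality_panel <- function(truth, seed = 1) {
  regions <- validate_region_table(truth$regions)
  temps <- truth$temperatures
  params <- truth$true_model
  dist <- truth$distances %||% distance_matrix(regions)
  episodic <- episodic_flux(regions, dist, params$kappa_e, params$d0_e)
  f_total <- total_flux(truth$commuter_flux, episodic)
  p0 <- patient_zero_distribution(regions)
  n <- nrow(regions)
  months <- colnames(temps)
  with_seed(seed, {
    i0_seq <- sample(seq_len(n), length(months), replace = TRUE, prob = p0)
    lambda <- matrix(NA_real_, n, length(months),
                     dimnames = list(regions$region_id, months))
    for (m in seq_along(months)) {
      lambda[, m] <- expected_deaths(as.numeric(temps[, m]), i0_seq[m],
                                     f_total, params, regions)
    }
    if (any(lambda <= 0)) abort("invalid truth parameters: non-positive Poisson mean")
    counts <- matrix(rpois(length(lambda), lambda), n, length(months),
                     dimnames = dimnames(lambda))
    panel <- monthly_panel(counts, "deaths")
    attr(panel, "i0_seq") <- regions$region_id[i0_seq]
    attr(panel, "lambda") <- lambda
    panel
  })
}

#' Generate a complete synthetic study with known ground truth
#'
#' One call builds the full fixture set every downstream stage needs:
#' regions, distances, temperatures, commuter flux, the true model
#' parameters, and the Poisson mortality panel. A single global seed streams
#' to per-component seeds by fixed offsets, so components are independently
#' reproducible.
#'
#' @param n_regions number of regions (default 20).
#' @param n_months number of months (default 108, i.e. 9 full years).
#' @param seed global integer seed.
#' @param true_model optional [full_model_params()] overriding
#'   [default_truth_params()].
#' @param kappa,d0,sigma,zero_fraction commuter-generator settings, see
#'   [generate_commuters()].
#' @return a `synthetic_truth` list: `regions`, `distances`, `temperatures`,
#'   `commuter_flux`, `true_model`, `true_biphasic` (NULL until fitted),
#'   `deaths`, `i0_seq`, `lambda`, `seed`.
#' @export
synthetic_truth <- function(n_regions = 20, n_months = 108, seed = 1,
                            true_model = NULL, kappa = 4e-7, d0 = 150,
                            sigma = 0.3, zero_fraction = 0.1) {
  regions <- generate_regions(n_regions, seed = seed + 1L)
  dist <- distance_matrix(regions)
  temps <- generate_temperatures(regions, n_months, seed = seed + 2L)
  commuters <- generate_commuters(regions, kappa, d0, sigma, zero_fraction,
                                  seed = seed + 3L, dist = dist)
  params <- true_model %||% default_truth_params(regions)
  truth <- list(regions = regions, distances = dist, temperatures = temps,
                commuter_flux = commuters, true_model = params, seed = seed)
  deaths <- generate_mortality_panel(truth, seed = seed + 4L)
  truth$deaths <- deaths
  truth$i0_seq <- attr(deaths, "i0_seq")
  truth$lambda <- attr(deaths, "lambda")
  class(truth) <- "synthetic_truth"
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d regions x %d months (seed %d)\n",
              nrow(x$regions), ncol(x$temperatures), x$seed))
  invisible(x)
}

#' Fabricate daily station readings consistent with a temperature panel
#'
#' Test helper for the station reader/aggregator: writes `k` stations per
#' region scattered around each capital whose daily readings fluctuate
#' around the region's monthly values.
#'
#' @param regions region tibble.
#' @param temps `"temperature"` panel to emulate.
#' @param k stations per region.
#' @param seed integer seed.
#' @param daily_sd day-to-day sd around the monthly mean, degC.
#' @return tibble in [read_station_readings()] layout (columns
#'   `STATION,LATITUDE,LONGITUDE,DATE,TAVG,TMAX,TMIN`).
#' @export
generate_station_readings <- function(regions, temps, k = 3, seed = 1,
                                      daily_sd = 2) {
  regions <- validate_region_table(regions)
  months <- colnames(temps)
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(regions)), function(r) {
      purrr::map_dfr(seq_len(k), function(s) {
        sid <- sprintf("ST_%s_%d", regions$region_id[r], s)
        slat <- regions$lat[r] + runif(1, -0.2, 0.2)
        slon <- regions$lon[r] + runif(1, -0.2, 0.2)
        purrr::map_dfr(seq_along(months), function(m) {
          first <- as.Date(paste0(months[m], "-01"))
          days <- seq(first, first + 27, by = "day")
          t_day <- temps[r, m] + rnorm(length(days), 0, daily_sd)
          tibble(STATION = sid, LATITUDE = slat, LONGITUDE = slon,
                 DATE = format(days, "%Y-%m-%d"),
                 TAVG = round(t_day, 2),
                 TMAX = round(t_day + 4, 2), TMIN = round(t_day - 4, 2))
        })
      })
    })
    rows
  })
}
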