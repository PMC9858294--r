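# Shared small fixtures, built in code. Cached in the helper environment so
# that multiple test files reuse the same objects.

fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

regions6 <- function() get_fixture("regions6", function() generate_regions(6, seed = 42))

truth6 <- function() {
  get_fixture("truth6", function() {
    suppressWarnings(synthetic_truth(n_regions = 6, n_months = 108, seed = 7))
  })
}

# a small hand-made region table for exact-value tests
toy_regions <- function(pop = c(1000, 2000, 1500), gdp = c(30, 80, 45),
                        lat = NULL, lon = NULL) {
  n <- length(pop)
  lat <- lat %||% seq(40, 44, length.out = n)
  lon <- lon %||% seq(9, 13, length.out = n)
  tibble::tibble(
    region_id = LETTERS[seq_len(n)], name = paste("Region", LETTERS[seq_len(n)]),
    population = pop, gdp = gdp, lat = lat, lon = lon
  )
}

# random valid flux matrix with modest outflow AND inflow fractions, as in
# real commuter tables (no region sends or receives more than `frac` of a
# resident population per day)
random_flux <- function(regions, frac = 0.05) {
  n <- nrow(regions)
  pop <- regions$population
  m <- matrix(runif(n * n), n, n)
  diag(m) <- 0
  m <- sweep(m, 2, colSums(m), "/") * frac * pop[col(m)]
  inflow_excess <- pmax(rowSums(m) / (frac * pop), 1)
  m <- m / inflow_excess[row(m)]
  dimnames(m) <- list(regions$region_id, regions$region_id)
  flux_matrix(m, "total")
}

month_seq <- function(n, start = "2011-01") {
  y0 <- as.integer(substr(start, 1, 4))
  m0 <- as.integer(substr(start, 6, 7))
  idx <- (m0 - 1) + seq_len(n) - 1
  sprintf("%04d-%02d", y0 + idx %/% 12, idx %% 12 + 1)
}

panel_of <- function(values, kind = "deaths", ids = NULL, months = NULL) {
  ids <- ids %||% sprintf("R%02d", seq_len(nrow(values)))
  months <- months %||% month_seq(ncol(values))
  dimnames(values) <- list(ids, months)
  monthly_panel(values, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
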