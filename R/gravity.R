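#' Distance-only exponential decay fit of commuter flux
#'
#' Fits `c(d) = kappa * exp(-d / d0) + b0` by minimising the squared
#' log-residual `sum (log c_ij - log c(d_ij))^2` over the strictly positive
#' entries (zero flows are excluded: a log-normal scatter model cannot see
#' them). `b0` is constrained non-negative.
#'
#' @param flux commuter [flux_matrix()].
#' @param dist distance matrix (km) from [distance_matrix()].
#' @return a `gravity_fit` list: `kappa`, `d0`, `b0`, `n_pairs`, `sse`.
#' @export
fit_distance_decay <- function(flux, dist) {
  ok <- off_diagonal_mask(flux) & unclass(flux) > 0
  if (sum(ok) < 10) abort("need at least 10 strictly positive off-diagonal flux entries")
  y <- log(unclass(flux)[ok])
  d <- unclass(dist)[ok]

  # moment start: straight log-linear regression ignoring b0
  init_fit <- lm(y ~ d)
  d0_init <- max(-1 / coef(init_fit)[[2]], 10)
  kappa_init <- exp(coef(init_fit)[[1]])
  b0_init <- max(min(exp(y)) / 2, 1e-6)

  obj <- function(th) {
    pred <- exp(th[1]) * exp(-d / exp(th[2])) + exp(th[3])
    sum((y - log(pred))^2)
  }
  best <- NULL
  for (lb0 in c(log(b0_init), log(b0_init) - 6)) {
    res <- optim(c(log(kappa_init), log(d0_init), lb0), obj,
                 method = "L-BFGS-B",
                 lower = c(log(kappa_init) - 15, log(1), log(b0_init) - 25),
                 upper = c(log(kappa_init) + 15, log(1e5), log(max(exp(y)))),
                 control = list(maxit = 1000, factr = 1e4))
    if (is.null(best) || res$value < best$value) best <- res
  }
  structure(
    list(kappa = exp(best$par[1]), d0 = exp(best$par[2]), b0 = exp(best$par[3]),
         n_pairs = sum(ok), sse = best$value, model = "distance"),
    class = "gravity_fit"
  )
}

#' GDP-attractiveness fit of total inflow
#'
#' Fits `c_i = kappa * GDP_i` (inflow to region i, summed over origins) by
#' minimising the squared log-residual; the minimiser is the geometric-mean
#' ratio `log kappa = mean(log c_i - log GDP_i)`.
#'
#' @param flux commuter [flux_matrix()].
#' @param regions region tibble.
#' @return a `gravity_fit` list with `kappa` and the inflows used.
#' @export
fit_gdp_linear <- function(flux, regions) {
  regions <- validate_region_table(regions)
  f <- unclass(flux)[regions$region_id, regions$region_id, drop = FALSE]
  inflow <- rowSums(f)
  if (any(inflow <= 0)) {
    abort(sprintf("zero total inflow for region(s): %s",
                  paste(regions$region_id[inflow <= 0], collapse = ", ")))
  }
  kappa <- exp(mean(log(inflow) - log(regions$gdp)))
  structure(
    list(kappa = kappa, n_pairs = length(inflow),
         sse = sum((log(inflow) - log(kappa * regions$gdp))^2),
         model = "gdp"),
    class = "gravity_fit"
  )
}

#' Combined gravity fit of commuter flux
#'
#' Fits `c_ij = kappa * pop_j * GDP_i * exp(-d_ij / d0)` over the strictly
#' positive entries by minimising the squared log-residual. In log space the
#' model is linear in `(log kappa, 1/d0)`, so the exact minimiser is an
#' ordinary least-squares regression of
#' `log c_ij - log(pop_j * GDP_i)` on `d_ij`.
#'
#' @param flux commuter [flux_matrix()].
#' @param dist distance matrix (km).
#' @param regions region tibble.
#' @return a `gravity_fit` list: `kappa`, `d0`, `n_pairs`, `sse`.
#' @export
fit_gravity <- function(flux, dist, regions) {
  regions <- validate_region_table(regions)
  ids <- regions$region_id
  f <- unclass(flux)[ids, ids, drop = FALSE]
  d <- unclass(dist)[ids, ids, drop = FALSE]
  mask <- off_diagonal_mask(flux) & f > 0
  if (sum(mask) < 10) abort("need at least 10 strictly positive off-diagonal flux entries")
  mass <- outer(regions$gdp, regions$population)  # [i, j] = GDP_i * pop_j
  y <- log(f[mask]) - log(mass[mask])
  x <- d[mask]
  fit <- lm(y ~ x)
  slope <- coef(fit)[[2]]
  if (slope >= 0) {
    # no measurable decay: flat model, d0 -> infinity
    d0 <- Inf
    kappa <- exp(mean(y))
  } else {
    d0 <- -1 / slope
    kappa <- exp(coef(fit)[[1]])
  }
  pred <- log(kappa) - x / d0
  structure(
    list(kappa = kappa, d0 = d0, n_pairs = sum(mask), sse = sum((y - pred)^2),
         model = "gravity"),
    class = "gravity_fit"
  )
}

#' @export
print.gravity_fit <- function(x, ...) {
  cat(sprintf("<gravity_fit[%s]> ", x$model))
  if (x$model == "distance") {
    cat(sprintf("kappa = %.4g, d0 = %.4g km, b0 = %.4g", x$kappa, x$d0, x$b0))
  } else if (x$model == "gdp") {
    cat(sprintf("kappa = %.4g per GDP unit", x$kappa))
  } else {
    cat(sprintf("kappa = %.4g, d0 = %.4g km", x$kappa, x$d0))
  }
  cat(sprintf("  (%d pairs, SSE = %.4g)\n", x$n_pairs, x$sse))
  invisible(x)
}

#' @export
tidy.gravity_fit <- function(x, ...) {
  terms <- switch(x$model,
    distance = c("kappa", "d0", "b0"),
    gdp = "kappa",
    gravity = c("kappa", "d0")
  )
  tibble(term = terms, estimate = unlist(x[terms], use.names = FALSE))
}

#' @export
glance.gravity_fit <- function(x, ...) {
  tibble(model = x$model, n_pairs = x$n_pairs, sse = x$sse)
}

#' Episodic (non-commuter) traveller flux
#'
#' Longer-range irregular travel, with the same gravity form as the
#' commuter flux but its own scale and (larger) decay length:
#' `e_ij = kappa_e * pop_j * GDP_i * exp(-d_ij / d0_e)`. `d0_e = Inf` gives
#' the distance-free limit.
#'
#' @param regions region tibble.
#' @param dist distance matrix (km).
#' @param kappa_e episodic scale (>= 0).
#' @param d0_e episodic decay length, km (> 0, may be `Inf`).
#' @return an `"episodic"` [flux_matrix()].
#' @export
episodic_flux <- function(regions, dist, kappa_e, d0_e) {
  regions <- validate_region_table(regions)
  if (kappa_e < 0) abort("kappa_e must be >= 0")
  if (d0_e <= 0) abort("d0_e must be > 0")
  ids <- regions$region_id
  d <- unclass(dist)[ids, ids, drop = FALSE]
  e <- kappa_e * outer(regions$gdp, regions$population) * exp(-d / d0_e)
  diag(e) <- 0
  dimnames(e) <- list(ids, ids)
  flux_matrix(e, "episodic")
}

#' Total traveller flux
#'
#' Element-wise sum of the commuter and episodic components,
#' `f_ij = c_ij + e_ij`.
#'
#' @param commuter,episodic conforming [flux_matrix()] objects.
#' @return a `"total"` [flux_matrix()].
#' @export
total_flux <- function(commuter, episodic) {
  if (!identical(dim(commuter), dim(episodic)) ||
      !identical(rownames(commuter), rownames(episodic))) {
    abort("commuter and episodic flux matrices do not conform")
  }
  flux_matrix(unclass(commuter) + unclass(episodic), "total")
}

off_diagonal_mask <- function(m) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  diag(out) <- FALSE
  out
}
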