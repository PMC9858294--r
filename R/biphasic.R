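#' Biphasic (U-shaped) temperature-mortality curve
#'
#' Expected monthly deaths as a function of temperature,
#' `lambda(T) = exp(-a_c * T + b_c) + exp(a_h * T + b_h)`: a cold arm that
#' decays with temperature and a hot arm that grows with it, with a unique
#' minimum in between. Monthly counts are modelled as Poisson around this
#' mean.
#'
#' @param temp temperature(s), degrees C.
#' @param params list or tibble row with `a_c`, `b_c`, `a_h`, `b_h`
#'   (`a_c > 0`, `a_h > 0`).
#' @return expected deaths (same length as `temp`), strictly positive and
#'   convex in `temp`.
#' @export
biphasic_lambda <- function(temp, params) {
  check_biphasic(params)
  exp(-params$a_c * temp + params$b_c) + exp(params$a_h * temp + params$b_h)
}

#' Temperature of minimum mortality
#'
#' The unique minimiser of [biphasic_lambda()]:
#' `T_min = (b_c - b_h + log(a_c / a_h)) / (a_c + a_h)`, obtained by setting
#' the derivative of the curve to zero.
#'
#' @inheritParams biphasic_lambda
#' @return degrees C.
#' @export
biphasic_tmin <- function(params) {
  check_biphasic(params)
  (params$b_c - params$b_h + log(params$a_c / params$a_h)) / (params$a_c + params$a_h)
}

check_biphasic <- function(params) {
  if (is.null(params$a_c) || is.null(params$a_h) ||
      is.null(params$b_c) || is.null(params$b_h)) {
    abort("biphasic parameters need fields a_c, b_c, a_h, b_h")
  }
  if (any(params$a_c <= 0) || any(params$a_h <= 0)) {
    abort("biphasic slopes a_c and a_h must be > 0")
  }
  invisible(params)
}

# Poisson negative log-likelihood (log(n!) dropped) and its gradient in the
# unconstrained parameterisation (log a_c, b_c, log a_h, b_h).
biphasic_negll <- function(theta, counts, temps) {
  a_c <- exp(theta[1]); b_c <- theta[2]; a_h <- exp(theta[3]); b_h <- theta[4]
  lam_c <- exp(-a_c * temps + b_c)
  lam_h <- exp(a_h * temps + b_h)
  lam <- lam_c + lam_h
  -sum(counts * log(lam) - lam)
}

biphasic_negll_grad <- function(theta, counts, temps) {
  a_c <- exp(theta[1]); b_c <- theta[2]; a_h <- exp(theta[3]); b_h <- theta[4]
  lam_c <- exp(-a_c * temps + b_c)
  lam_h <- exp(a_h * temps + b_h)
  lam <- lam_c + lam_h
  w <- counts / lam - 1       # d(LL)/d(lam)
  d_ac <- sum(w * lam_c * (-temps)) * a_c
  d_bc <- sum(w * lam_c)
  d_ah <- sum(w * lam_h * temps) * a_h
  d_bh <- sum(w * lam_h)
  -c(d_ac, d_bc, d_ah, d_bh)
}

#' Fit the biphasic curve to one region's counts by Poisson ML
#'
#' Maximises `sum_m n_m log lambda(T_m) - lambda(T_m)` over the four curve
#' parameters, with positivity of the slopes enforced by optimising their
#' logs. Eight deterministic starts seeded from the cold/hot data terciles
#' guard against the arm-assignment bimodality of the likelihood.
#'
#' @param counts integer vector of monthly deaths for one region.
#' @param temps matching vector of monthly mean temperatures (degC).
#' @return a `biphasic_fit` list: `a_c`, `b_c`, `a_h`, `b_h`, `t_min`,
#'   `loglik`, `converged`, `n_months`.
#' @export
fit_biphasic <- function(counts, temps) {
  if (length(counts) != length(temps)) abort("counts and temps lengths differ")
  if (length(counts) < 12) abort("need at least 12 months to fit the biphasic curve")
  if (diff(range(temps)) < 10) {
    abort("temperature range must span at least 10 degC to separate the two arms")
  }
  if (any(counts < 0)) abort("negative counts")

  log_mean <- log(mean(pmax(counts, 0.5)))
  # slope guesses from a log-linear look at the cold / hot terciles
  terc <- quantile(temps, c(1 / 3, 2 / 3))
  slope_guess <- function(sel, sign) {
    if (sum(sel) < 3) return(0.05)
    fit <- lm(log(pmax(counts[sel], 0.5)) ~ temps[sel])
    max(sign * coef(fit)[2], 0.01)
  }
  s_c <- slope_guess(temps <= terc[1], -1)
  s_h <- slope_guess(temps >= terc[2], +1)

  starts <- list()
  for (ac0 in c(s_c, 0.05)) {
    for (ah0 in c(s_h, 0.05)) {
      for (off in c(log(2), log(10))) {
        starts[[length(starts) + 1]] <-
          c(log(ac0), log_mean - off + ac0 * mean(temps),
            log(ah0), log_mean - off - ah0 * mean(temps))
      }
    }
  }

  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      optim(th0, biphasic_negll, biphasic_negll_grad,
            counts = counts, temps = temps,
            method = "L-BFGS-B",
            lower = c(log(1e-4), -50, log(1e-4), -50),
            upper = c(log(5), 50, log(5), 50),
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort("biphasic fit failed to converge from any start")
  }
  th <- best$par
  out <- list(
    a_c = exp(th[1]), b_c = th[2], a_h = exp(th[3]), b_h = th[4],
    loglik = -best$value, converged = best$convergence == 0,
    n_months = length(counts)
  )
  out$t_min <- biphasic_tmin(out)
  structure(out, class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf(
    "<biphasic_fit> a_c = %.4g, b_c = %.4g, a_h = %.4g, b_h = %.4g\n",
    x$a_c, x$b_c, x$a_h, x$b_h
  ))
  cat(sprintf("  T_min = %.2f degC, logLik = %.2f over %d months\n",
              x$t_min, x$loglik, x$n_months))
  invisible(x)
}

#' Fit biphasic curves for every region of a panel
#'
#' @param counts a `"deaths"` [monthly_panel()].
#' @param temps a matching `"temperature"` panel.
#' @return a `biphasic_panel_fit`: tibble of per-region parameters plus the
#'   fit objects.
#' @export
fit_biphasic_panel <- function(counts, temps) {
  stopifnot_same_shape(counts, temps)
  fits <- purrr::map(rownames(counts), function(id) {
    fit_biphasic(as.numeric(counts[id, ]), as.numeric(temps[id, ]))
  })
  names(fits) <- rownames(counts)
  structure(list(fits = fits, region_ids = rownames(counts)),
            class = "biphasic_panel_fit")
}

#' @export
tidy.biphasic_panel_fit <- function(x, ...) {
  purrr::map_dfr(x$region_ids, function(id) {
    f <- x$fits[[id]]
    tibble(region_id = id, a_c = f$a_c, b_c = f$b_c, a_h = f$a_h, b_h = f$b_h,
           t_min = f$t_min, loglik = f$loglik, converged = f$converged)
  })
}

#' @export
tidy.biphasic_fit <- function(x, ...) {
  tibble(term = c("a_c", "b_c", "a_h", "b_h", "t_min"),
         estimate = c(x$a_c, x$b_c, x$a_h, x$b_h, x$t_min))
}

#' @export
glance.biphasic_fit <- function(x, ...) {
  tibble(loglik = x$loglik, converged = x$converged, n_months = x$n_months)
}

#' Temperature-normalised mortality residuals
#'
#' Subtracts each region's fitted biphasic expectation from the raw counts:
#' what remains is the part of the fluctuation that temperature alone does
#' not explain.
#'
#' @param counts deaths panel.
#' @param temps temperature panel.
#' @param fits a `biphasic_panel_fit` covering every region of `counts`.
#' @return a `"residuals"` [monthly_panel()].
#' @export
temperature_residuals <- function(counts, temps, fits) {
  stopifnot_same_shape(counts, temps)
  missing <- setdiff(rownames(counts), names(fits$fits))
  if (length(missing) > 0) {
    abort(sprintf("no biphasic fit for region(s): %s", paste(missing, collapse = ", ")))
  }
  res <- unclass(counts)
  for (id in rownames(counts)) {
    res[id, ] <- counts[id, ] - biphasic_lambda(as.numeric(temps[id, ]), fits$fits[[id]])
  }
  monthly_panel(res, "residuals")
}

#' @export
#' @rdname fit_biphasic_panel
#' @param object a `biphasic_panel_fit`.
#' @param counts,temps panels used for the fit (for the data points).
#' @param regions optional subset of region ids to draw.
#' @param ... unused.
autoplot.biphasic_panel_fit <- function(object, counts, temps, regions = NULL, ...) {
  ids <- regions %||% utils::head(object$region_ids, 3)
  grid <- seq(min(temps), max(temps), length.out = 200)
  curves <- purrr::map_dfr(ids, function(id) {
    tibble(region_id = id, temp = grid,
           lambda = biphasic_lambda(grid, object$fits[[id]]))
  })
  pts <- purrr::map_dfr(ids, function(id) {
    tibble(region_id = id, temp = as.numeric(temps[id, ]),
           deaths = as.numeric(counts[id, ]))
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$temp)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$deaths), alpha = 0.5) +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$lambda), colour = "firebrick") +
    ggplot2::facet_wrap(~region_id, scales = "free_y") +
    ggplot2::labs(x = "monthly mean temperature (degC)", y = "monthly deaths",
                  title = "Biphasic temperature-mortality fits")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
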