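#' Between-region correlation matrix of monthly series
#'
#' Pearson correlations between the region time series of a panel.
#' Optionally each region is first divided by its mean over the period
#' (death *rates* rather than counts); Pearson correlation is invariant to
#' this per-region scaling, so the switch only matters for exported series.
#'
#' @param panel a [monthly_panel()] (>= 3 months).
#' @param normalise `"none"` or `"per-region-mean"`.
#' @return a `correlation_matrix`: symmetric, unit diagonal, with attribute
#'   `n_obs` = number of months used.
#' @export
correlation_matrix <- function(panel, normalise = c("none", "per-region-mean")) {
  normalise <- match.arg(normalise)
  m <- unclass(panel)
  if (ncol(m) < 3) abort("need at least 3 months to correlate")
  v <- apply(m, 1, sd)
  if (any(v == 0)) {
    abort(sprintf("zero-variance series for region(s): %s",
                  paste(rownames(m)[v == 0], collapse = ", ")))
  }
  if (normalise == "per-region-mean") m <- m / rowMeans(m)
  cm <- cor(t(m))
  structure(cm, class = c("correlation_matrix", "matrix", "array"), n_obs = ncol(m))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  s <- offdiag_summary(x)
  cat(sprintf("<correlation_matrix> %d regions, %s months; off-diagonal %.3f +/- %.3f\n",
              nrow(x), attr(x, "n_obs") %||% "?", s$mean, s$sd))
  invisible(x)
}

#' Summaries of the off-diagonal correlation structure
#'
#' Mean and (population) standard deviation over the `n(n-1)/2`
#' upper-triangle entries, plus each region's correlation degree: the mean
#' of its `n - 1` correlations with the other regions.
#'
#' @param corr a `correlation_matrix` (or plain symmetric matrix).
#' @return list with `mean`, `sd` and a tibble `degree` (`region_id`,
#'   `degree`).
#' @export
offdiag_summary <- function(corr) {
  m <- unclass(corr)
  if (nrow(m) < 2) abort("need at least 2 regions")
  up <- m[upper.tri(m)]
  deg <- (rowSums(m) - diag(m)) / (nrow(m) - 1)
  list(
    mean = mean(up),
    sd = sqrt(mean((up - mean(up))^2)),
    degree = tibble(region_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                    degree = unname(deg))
  )
}

#' Agreement between model and data correlation networks
#'
#' Pearson correlation between the vectorised upper triangles of the two
#' matrices: 1 means the model reproduces the relative strengths of every
#' regional pair exactly (up to an affine map).
#'
#' @param model_corr,data_corr conforming correlation matrices.
#' @return scalar Pearson r.
#' @export
model_data_agreement <- function(model_corr, data_corr) {
  a <- unclass(model_corr); b <- unclass(data_corr)
  if (!identical(dim(a), dim(b))) abort("correlation matrices do not conform")
  if (nrow(a) < 3) abort("need at least 3 regions (3 pairs) to compare networks")
  cor(a[upper.tri(a)], b[upper.tri(b)])
}

#' Agreement between observed and model-expected deaths
#'
#' Pearson correlation over all region-month cells between the observed
#' panel and the model expectation.
#'
#' @param observed a `"deaths"` [monthly_panel()].
#' @param expected conforming matrix of model-expected deaths.
#' @return scalar Pearson r.
#' @export
deaths_agreement <- function(observed, expected) {
  a <- unclass(observed); b <- unclass(expected)
  if (!identical(dim(a), dim(b))) abort("observed and expected panels do not conform")
  cor(as.vector(a), as.vector(b))
}

#' Correlation-degree anomaly score
#'
#' Compares each region's current correlation degree with its distribution
#' over a baseline ensemble (e.g. rolling windows of the historical panel):
#' `z_i = (degree_i - mean_i) / sd_i`. A strongly anomalous degree flags an
#' emerging systemic source of risk around that region.
#'
#' @param current a `correlation_matrix`.
#' @param baseline list of >= 10 conforming correlation matrices.
#' @return tibble `region_id, degree, baseline_mean, baseline_sd, z`
#'   (`z = NA` where the ensemble sd is zero, flagged not infinite).
#' @export
degree_anomaly <- function(current, baseline) {
  if (length(baseline) < 10) abort("need a baseline ensemble of at least 10 matrices")
  cur <- offdiag_summary(current)$degree
  degs <- vapply(baseline, function(b) offdiag_summary(b)$degree$degree,
                 numeric(nrow(cur)))
  mu <- rowMeans(degs)
  s <- apply(degs, 1, sd)
  z <- ifelse(s > 0, (cur$degree - mu) / s, NA_real_)
  if (any(s == 0)) {
    warn(sprintf("zero baseline sd for region(s) %s: z undefined",
                 paste(cur$region_id[s == 0], collapse = ", ")))
  }
  tibble(region_id = cur$region_id, degree = cur$degree,
         baseline_mean = mu, baseline_sd = s, z = z)
}

#' Rolling-window baseline ensemble of correlation matrices
#'
#' @param panel a [monthly_panel()].
#' @param window window width in months (default 36).
#' @param stride step between window starts (default 1).
#' @return list of `correlation_matrix` objects.
#' @export
rolling_correlations <- function(panel, window = 36, stride = 1) {
  n_m <- ncol(panel)
  if (n_m < window) abort("panel shorter than the window")
  starts <- seq(1, n_m - window + 1, by = stride)
  lapply(starts, function(s) {
    correlation_matrix(monthly_panel(unclass(panel)[, s:(s + window - 1), drop = FALSE],
                                     attr(panel, "kind")))
  })
}

#' @export
#' @rdname correlation_matrix
#' @param object a `correlation_matrix`.
#' @param ... unused.
autoplot.correlation_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(
    region_a = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    region_b = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    corr = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$region_a, .data$region_b, fill = .data$corr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  midpoint = 0.5, limits = c(-1, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Between-region correlations")
}

#' Export a thresholded correlation network as an edge list
#'
#' @param corr a `correlation_matrix`.
#' @param threshold minimum (absolute) correlation for an edge.
#' @return tibble `region_a, region_b, weight`.
#' @export
correlation_edges <- function(corr, threshold = 0.8) {
  m <- unclass(corr)
  idx <- which(upper.tri(m) & abs(m) >= threshold, arr.ind = TRUE)
  tibble(
    region_a = rownames(m)[idx[, 1]],
    region_b = colnames(m)[idx[, 2]],
    weight = m[idx]
  )
}
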