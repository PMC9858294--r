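#' Monthly region-by-month panels
#'
#' A `monthly_panel` is a numeric region x month matrix with region ids as
#' row names and `"YYYY-MM"` labels as column names, tagged with a `kind`
#' (`"deaths"`, `"temperature"`, `"residuals"` or `"expected"`). Death panels
#' must hold non-negative integers; all panels must be finite with no
#' missing cells.
#'
#' @param values numeric matrix, regions in rows, months in columns. Row
#'   names are region ids, column names are `"YYYY-MM"` month labels.
#' @param kind panel kind, one of `"deaths"`, `"temperature"`,
#'   `"residuals"`, `"expected"`.
#' @return a `monthly_panel` object.
#' @examples
#' m <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("2015-01", "2015-02")))
#' monthly_panel(m, "deaths")
#' @export
monthly_panel <- function(values, kind = c("deaths", "temperature", "residuals", "expected")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry region ids as rownames and month labels as colnames")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort(sprintf("%s panel contains missing or non-finite cells", kind))
  }
  if (kind == "deaths") {
    if (any(values < 0) || any(values != round(values))) {
      abort("deaths panel must contain non-negative integers")
    }
  }
  structure(values, class = c("monthly_panel", "matrix", "array"), kind = kind)
}

#' @export
print.monthly_panel <- function(x, ...) {
  cat(sprintf(
    "<monthly_panel[%s]> %d regions x %d months (%s .. %s)\n",
    attr(x, "kind"), nrow(x), ncol(x), colnames(x)[1], colnames(x)[ncol(x)]
  ))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

#' @export
#' @rdname monthly_panel
#' @param x a `monthly_panel`.
#' @param ... unused.
tidy.monthly_panel <- function(x, ...) {
  tibble(
    region_id = rep(rownames(x), times = ncol(x)),
    month = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x)),
    kind = attr(x, "kind")
  )
}

#' @export
#' @rdname monthly_panel
#' @param object a `monthly_panel`.
autoplot.monthly_panel <- function(object, ...) {
  df <- tidy(object)
  df$t <- match(df$month, colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value, colour = .data$region_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "month index", y = attr(object, "kind"),
      title = sprintf("Monthly %s by region", attr(object, "kind"))
    )
}

panel_months <- function(panel) colnames(panel)

stopifnot_same_shape <- function(a, b, what = "panels") {
  if (!identical(dim(a), dim(b)) || !identical(rownames(a), rownames(b))) {
    abort(sprintf("%s do not share the same regions/months", what))
  }
}

#' Directed traveller-flux matrices
#'
#' A `flux_matrix` stores persons/day flows with entry `[i, j]` the flow
#' from region `j` into region `i`. Entries are non-negative, the diagonal
#' is zero; the matrix need not be symmetric.
#'
#' @param values non-negative numeric matrix with region ids as dimnames.
#' @param kind one of `"commuter"`, `"episodic"`, `"total"`.
#' @return a `flux_matrix`.
#' @export
flux_matrix <- function(values, kind = c("commuter", "episodic", "total")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    abort("flux matrix must be square")
  }
  if (is.null(rownames(values))) {
    abort("flux matrix must carry region ids as dimnames")
  }
  if (anyNA(values) || any(values < 0)) {
    abort("flux entries must be non-negative and complete")
  }
  if (any(diag(values) != 0)) {
    abort("flux matrix diagonal must be zero")
  }
  structure(values, class = c("flux_matrix", "matrix", "array"), kind = kind)
}

#' @export
print.flux_matrix <- function(x, ...) {
  cat(sprintf(
    "<flux_matrix[%s]> %d regions, total %.1f persons/day\n",
    attr(x, "kind"), nrow(x), sum(x)
  ))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
  invisible(x)
}

#' @export
#' @rdname flux_matrix
#' @param x a `flux_matrix`.
#' @param ... unused.
tidy.flux_matrix <- function(x, ...) {
  tibble(
    destination_id = rep(rownames(x), times = ncol(x)),
    origin_id = rep(colnames(x), each = nrow(x)),
    flow = as.vector(unclass(x)),
    kind = attr(x, "kind")
  ) |>
    dplyr::filter(.data$destination_id != .data$origin_id)
}
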