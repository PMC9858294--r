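#' Read and validate a region attribute table
#'
#' Regions are the nodes of every model in the package: each carries a
#' resident population, a GDP (the "attractiveness" used by the gravity and
#' patient-zero models) and the coordinates of its main administrative
#' centre.
#'
#' @param path CSV file with header columns
#'   `region_id,name,population,gdp,lat,lon`.
#' @return a tibble with those six columns, validated: unique ids, positive
#'   populations and GDPs, at least two regions.
#' @export
read_region_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("region_id", "name", "population", "gdp", "lat", "lon")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("region table is missing columns: %s", paste(missing, collapse = ", ")))
  }
  validate_region_table(as_tibble(df[required]))
}

#' @rdname read_region_table
#' @param regions a region tibble (as returned by [read_region_table()] or
#'   [generate_regions()]).
#' @export
write_region_table <- function(regions, path) {
  regions <- validate_region_table(regions)
  utils::write.csv(regions, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_region_table
#' @export
validate_region_table <- function(regions) {
  if (nrow(regions) < 2) abort("need at least 2 regions")
  dup <- regions$region_id[duplicated(regions$region_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate region_id: %s", paste(unique(dup), collapse = ", ")))
  }
  bad_pop <- which(!is.finite(regions$population) | regions$population <= 0)
  if (length(bad_pop) > 0) {
    abort(sprintf("non-positive population in row(s) %s (region %s)",
                  paste(bad_pop, collapse = ", "),
                  paste(regions$region_id[bad_pop], collapse = ", ")))
  }
  bad_gdp <- which(!is.finite(regions$gdp) | regions$gdp <= 0)
  if (length(bad_gdp) > 0) {
    abort(sprintf("non-positive gdp in row(s) %s (region %s)",
                  paste(bad_gdp, collapse = ", "),
                  paste(regions$region_id[bad_gdp], collapse = ", ")))
  }
  if (any(!is.finite(regions$lat)) || any(abs(regions$lat) > 90) ||
      any(!is.finite(regions$lon)) || any(abs(regions$lon) > 180)) {
    abort("invalid capital coordinates")
  }
  as_tibble(regions)
}

#' Great-circle distance matrix between regional capitals
#'
#' Haversine distances (Earth radius 6371 km) between the main
#' administrative centres, in km.
#'
#' @inheritParams write_region_table
#' @return symmetric matrix (km) with zero diagonal, dimnames = region ids.
#' @export
distance_matrix <- function(regions) {
  regions <- validate_region_table(regions)
  n <- nrow(regions)
  pts <- cbind(regions$lon, regions$lat)
  d <- geosphere::distm(pts, pts, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371)
  })
  dimnames(d) <- list(regions$region_id, regions$region_id)
  if (any(d[upper.tri(d)] <= 0)) {
    bad <- which(d <= 0 & upper.tri(d), arr.ind = TRUE)[1, ]
    abort(sprintf("regions %s and %s have coincident capitals",
                  regions$region_id[bad[1]], regions$region_id[bad[2]]))
  }
  diag(d) <- 0
  d
}

#' Read GHCN-Daily-style station temperature readings
#'
#' @param path CSV with header columns
#'   `STATION,LATITUDE,LONGITUDE,DATE,TAVG,TMAX,TMIN` (ISO dates,
#'   temperatures in degrees C; TAVG/TMAX/TMIN may be blank but not all
#'   three at once).
#' @return tibble with columns `station_id, station_lat, station_lon, date,
#'   tavg, tmax, tmin`.
#' @export
read_station_readings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("STATION", "LATITUDE", "LONGITUDE", "DATE")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("station file is missing columns: %s", paste(missing, collapse = ", ")))
  }
  for (col in c("TAVG", "TMAX", "TMIN")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  out <- tibble(
    station_id = as.character(df$STATION),
    station_lat = as.numeric(df$LATITUDE),
    station_lon = as.numeric(df$LONGITUDE),
    date = as.Date(as.character(df$DATE), format = "%Y-%m-%d"),
    tavg = as.numeric(df$TAVG),
    tmax = as.numeric(df$TMAX),
    tmin = as.numeric(df$TMIN)
  )
  if (anyNA(out$date)) {
    abort(sprintf("invalid dates in rows %s",
                  paste(utils::head(which(is.na(out$date)), 5), collapse = ", ")))
  }
  no_temp <- is.na(out$tavg) & (is.na(out$tmax) | is.na(out$tmin))
  if (any(no_temp)) {
    abort(sprintf("rows without any usable temperature: %s",
                  paste(utils::head(which(no_temp), 5), collapse = ", ")))
  }
  out
}

#' Regional monthly temperature from the k closest weather stations
#'
#' For each region the k stations closest to the capital are selected
#' (haversine distance, ties broken by station id). Each station's monthly
#' mean daily temperature (TAVG when present, else the TMAX/TMIN midpoint)
#' is then averaged with weight proportional to the inverse of the
#' station-capital distance.
#'
#' @param stations tibble from [read_station_readings()].
#' @inheritParams write_region_table
#' @param k number of closest stations per region (default 3).
#' @return a `"temperature"` [monthly_panel()] covering every month present
#'   in the readings.
#' @export
monthly_temperature <- function(stations, regions, k = 3) {
  regions <- validate_region_table(regions)
  station_pos <- dplyr::distinct(stations, .data$station_id, .data$station_lat, .data$station_lon)
  station_pos <- dplyr::arrange(station_pos, .data$station_id)
  if (nrow(station_pos) < k) {
    abort(sprintf("only %d stations available, need k = %d", nrow(station_pos), k))
  }
  daily <- dplyr::mutate(
    stations,
    temp = dplyr::if_else(is.na(.data$tavg), (.data$tmax + .data$tmin) / 2, .data$tavg),
    month = format(.data$date, "%Y-%m")
  )
  station_monthly <- daily |>
    dplyr::group_by(.data$station_id, .data$month) |>
    dplyr::summarise(tbar = mean(.data$temp), .groups = "drop")
  months <- sort(unique(station_monthly$month))

  values <- matrix(NA_real_, nrow(regions), length(months),
                   dimnames = list(regions$region_id, months))
  for (r in seq_len(nrow(regions))) {
    d_km <- geosphere::distHaversine(
      cbind(station_pos$station_lon, station_pos$station_lat),
      c(regions$lon[r], regions$lat[r]),
      r = 6371
    )
    ord <- order(d_km, station_pos$station_id)
    sel <- ord[seq_len(k)]
    ids <- station_pos$station_id[sel]
    w <- 1 / pmax(d_km[sel], 1e-3)
    for (m in seq_along(months)) {
      tb_full <- vapply(ids, function(id) {
        v <- station_monthly$tbar[station_monthly$station_id == id &
                                    station_monthly$month == months[m]]
        if (length(v) == 0) NA_real_ else v
      }, numeric(1))
      use <- !is.na(tb_full)
      if (!any(use)) {
        abort(sprintf("region %s has no usable readings in %s from its %d stations",
                      regions$region_id[r], months[m], k))
      }
      values[r, m] <- sum(w[use] * tb_full[use]) / sum(w[use])
    }
  }
  monthly_panel(values, "temperature")
}

#' Read/write monthly panels and origin-destination matrices
#'
#' Panels are stored wide (rows = regions, columns = `YYYY-MM`); OD
#' matrices long (`origin_id,destination_id,commuters_per_day`).
#'
#' @param path file path.
#' @param kind panel kind for [monthly_panel()].
#' @return [read_monthly_panel()] a `monthly_panel`; [read_od_matrix()] a
#'   `flux_matrix` (destination in rows, origin in columns).
#' @export
read_monthly_panel <- function(path, kind = "deaths") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  monthly_panel(m, kind)
}

#' @rdname read_monthly_panel
#' @param panel a `monthly_panel`.
#' @export
write_monthly_panel <- function(panel, path) {
  df <- data.frame(region_id = rownames(panel), unclass(panel), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_monthly_panel
#' @param region_ids the full region id set (zero flows may be omitted from
#'   the file).
#' @export
read_od_matrix <- function(path, region_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("origin_id", "destination_id", "commuters_per_day")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("OD file is missing columns: %s", paste(missing, collapse = ", ")))
  }
  if (is.null(region_ids)) {
    region_ids <- sort(unique(c(df$origin_id, df$destination_id)))
  }
  m <- matrix(0, length(region_ids), length(region_ids),
              dimnames = list(region_ids, region_ids))
  for (i in seq_len(nrow(df))) {
    m[df$destination_id[i], df$origin_id[i]] <- df$commuters_per_day[i]
  }
  flux_matrix(m, "commuter")
}

#' @rdname read_monthly_panel
#' @param flux a `flux_matrix`.
#' @export
write_od_matrix <- function(flux, path) {
  df <- tidy(flux)
  df <- df[df$flow > 0, c("origin_id", "destination_id", "flow")]
  names(df)[3] <- "commuters_per_day"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
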