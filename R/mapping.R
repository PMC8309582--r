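# Gridded prediction and variance maps.

#' Predict a concentration map on a grid
#'
#' Predicts every cell centre at every grid time with one method.
#' Kriging methods also fill the kriging-variance raster; IDW leaves it
#' blank. Cells with an empty neighbourhood (possible when `radius` is
#' set) are marked missing, never zero.
#'
#' @inheritParams st_predict
#' @param grid A `grid_spec`.
#' @return An object of class `prediction_map`: the grid plus a long
#'   data.frame `(x, y, t, prediction, variance)`.
#' @export
predict_grid <- function(train, station = NULL, model = NULL,
                         method = c("ked", "sk", "ok", "idw"), grid,
                         n_max = 50, radius = NULL, idw_c = 1, idw_p = 2) {
  method <- match.arg(method)
  if (n_obs(train) == 0L) stop_stkrige("stkrige_invalid_input", "no observations")
  centers <- grid_centers(grid)
  targets <- data.frame(
    x = rep(centers$x, times = length(grid$times)),
    y = rep(centers$y, times = length(grid$times)),
    t = rep(grid$times, each = nrow(centers)))
  out <- data.frame(targets, prediction = NA_real_, variance = NA_real_)
  ok_rows <- seq_len(nrow(targets))
  if (!is.null(radius)) {
    # pre-flag cells with no observation inside the metric radius
    K <- if (!is.null(model)) model$K else sqrt(max(idw_c, 0))
    d <- train$obs
    reach <- vapply(seq_len(nrow(targets)), function(i) {
      any(metric_distance(d$x, d$y, d$t, targets$x[i], targets$y[i],
                          targets$t[i], K) <= radius)
    }, logical(1))
    ok_rows <- which(reach)
    if (length(ok_rows) < nrow(targets)) {
      log_event("mapping", "missing_cells", n = nrow(targets) - length(ok_rows))
    }
  }
  if (length(ok_rows)) {
    pr <- st_predict(train, targets[ok_rows, , drop = FALSE], model = model,
                     method = method, station = station, n_max = n_max,
                     radius = radius, idw_c = idw_c, idw_p = idw_p,
                     ked_fallback_ok = TRUE)
    out$prediction[ok_rows] <- pr$prediction
    out$variance[ok_rows] <- pr$variance
  }
  structure(list(grid = grid, method = method, data = out),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat(sprintf("<prediction_map [%s]: %dx%d cells, %d time slices, %d missing>\n",
              x$method, x$grid$n_x, x$grid$n_y, length(x$grid$times),
              sum(is.na(x$data$prediction))))
  invisible(x)
}

#' Extract one time slice of a map as a matrix
#'
#' @param map A `prediction_map`.
#' @param time One of the grid times.
#' @param what `"prediction"` or `"variance"`.
#' @return An `n_y` x `n_x` matrix; row 1 is the southern (y_min) row,
#'   column 1 the western (x_min) column.
#' @export
map_slice <- function(map, time, what = c("prediction", "variance")) {
  what <- match.arg(what)
  if (!time %in% map$grid$times) {
    stop_stkrige("stkrige_invalid_input", "time is not a grid time")
  }
  d <- map$data[map$data$t == time, ]
  matrix(d[[what]], nrow = map$grid$n_y, ncol = map$grid$n_x, byrow = TRUE)
}

#' @export
plot.prediction_map <- function(x, time = x$grid$times[1],
                                what = "prediction", ...) {
  m <- map_slice(x, time, what)
  xs <- x$grid$x_min + (seq_len(x$grid$n_x) - 0.5) * x$grid$cell_size
  ys <- x$grid$y_min + (seq_len(x$grid$n_y) - 0.5) * x$grid$cell_size
  graphics::image(xs, ys, t(m), xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("%s at t = %.1f h", what, time / 3600), ...)
  invisible(x)
}

#' Export a prediction map
#'
#' Long CSV columns `(x, y, t, prediction, variance)`, missing cells as
#' blanks; optionally one ESRI ASCII grid raster per time slice and
#' layer (`prediction`/`variance`), a plain-text georeferenced format.
#' The raster lower-left corner sits at `(x_min, y_min)`; missing cells
#' become the NODATA value.
#'
#' @param map A `prediction_map`.
#' @param csv Path of the long CSV (or `NULL` to skip).
#' @param raster_dir Directory for `.asc` rasters (or `NULL` to skip).
#' @return Invisible character vector of the files written.
#' @export
export_map <- function(map, csv = NULL, raster_dir = NULL) {
  written <- character(0)
  if (!is.null(csv)) {
    ok <- tryCatch({
      utils::write.csv(
        data.frame(x = map$data$x, y = map$data$y, t = map$data$t,
                   prediction = formatC(map$data$prediction, digits = 10, format = "g"),
                   variance = formatC(map$data$variance, digits = 10, format = "g")),
        csv, row.names = FALSE, quote = FALSE, na = "")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_stkrige("stkrige_io_error", paste0("cannot write ", csv))
    written <- c(written, csv)
  }
  if (!is.null(raster_dir)) {
    if (!dir.exists(raster_dir)) dir.create(raster_dir, recursive = TRUE)
    for (tm in map$grid$times) {
      for (what in c("prediction", "variance")) {
        m <- map_slice(map, tm, what)
        if (all(is.na(m))) next
        f <- file.path(raster_dir,
                       sprintf("%s_t%06d.asc", what, as.integer(tm / 60)))
        .write_esri_ascii(m, map$grid, f)
        written <- c(written, f)
      }
    }
  }
  invisible(written)
}

# ESRI ASCII grid: header then rows north-to-south (row 1 of the matrix
# is the southern row, so rows are written in reverse).
.write_esri_ascii <- function(m, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_x),
    sprintf("nrows %d", grid$n_y),
    sprintf("xllcorner %.6f", grid$x_min),
    sprintf("yllcorner %.6f", grid$y_min),
    sprintf("cellsize %.6f", grid$cell_size),
    "NODATA_value -9999"
  ), con)
  m[is.na(m)] <- -9999
  for (i in rev(seq_len(nrow(m)))) {
    writeLines(paste(formatC(m[i, ], digits = 10, format = "g"), collapse = " "), con)
  }
  invisible(path)
}

#' Read a map CSV written by [export_map()]
#'
#' @param path CSV path.
#' @return Data.frame `(x, y, t, prediction, variance)` with blanks as `NA`.
#' @export
read_map_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = rep("numeric", 5), na.strings = c("", "NA"))
}
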