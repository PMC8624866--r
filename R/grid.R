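#' Prediction grids
#'
#' A `pred_grid` is a regular, cell-center-registered raster: a numeric
#' `nrows x ncols` matrix whose first row is the northernmost row (ESRI
#' ASCII layout), with lower-left corner (`xll`, `yll`), square `cellsize`
#' in meters, a `nodata` sentinel, and an optional kriging `variance`
#' matrix of the same shape.
#'
#' @param xll,yll Lower-left corner of the grid (meters).
#' @param cellsize Cell edge length in meters (> 0).
#' @param nrows,ncols Grid dimensions.
#' @param values Optional `nrows x ncols` matrix (defaults to all-`nodata`).
#' @param nodata Sentinel for cells without a prediction.
#' @param variance Optional matrix of prediction variances.
#' @return A `pred_grid` object.
#' @export
pred_grid <- function(xll, yll, cellsize, nrows, ncols,
                      values = NULL, nodata = -9999, variance = NULL) {
  if (cellsize <= 0) abort("cellsize must be > 0")
  if (nrows < 1 || ncols < 1) abort("nrows and ncols must be positive")
  if (is.null(values)) values <- matrix(nodata, nrows, ncols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(nrows, ncols))) {
    abort("values matrix shape does not match nrows/ncols")
  }
  if (!is.null(variance) && !all(dim(variance) == c(nrows, ncols))) {
    abort("variance matrix shape does not match nrows/ncols")
  }
  structure(list(xll = xll, yll = yll, cellsize = cellsize,
                 nrows = nrows, ncols = ncols, values = values,
                 nodata = nodata, variance = variance),
            class = "pred_grid")
}

#' @export
print.pred_grid <- function(x, ...) {
  cat(sprintf("<pred_grid> %d x %d cells of %g m, origin (%.1f, %.1f)\n",
              x$nrows, x$ncols, x$cellsize, x$xll, x$yll))
  v <- x$values[x$values != x$nodata]
  if (length(v) > 0) {
    cat(sprintf("  values: [%g, %g], %d nodata cells\n", min(v), max(v),
                sum(x$values == x$nodata)))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' Build an empty grid covering a survey
#'
#' The bounding box of the (projected) stations is expanded by `padding`
#' on each side; cell centers start at the expanded lower-left corner and
#' step by `cellsize` until the extent is covered, so a span of `w`
#' meters yields `ceiling(w/c) + 1` columns (exactly `w/c + 1` when `w`
#' is a multiple of the cell size).
#'
#' @param s Survey tibble with projected `x`/`y`.
#' @param cellsize Cell size in meters.
#' @param padding Extra margin in meters on every side.
#' @return A `pred_grid` initialized to `nodata`.
#' @export
make_grid <- function(s, cellsize, padding = 0) {
  if (cellsize <= 0) abort("cellsize must be > 0")
  if (!"x" %in% names(s) || all(is.na(s$x))) {
    abort("survey has no projected coordinates; call project_utm() first")
  }
  xmin <- min(s$x) - padding; xmax <- max(s$x) + padding
  ymin <- min(s$y) - padding; ymax <- max(s$y) + padding
  if (xmax - xmin < 1e-9 && ymax - ymin < 1e-9) {
    abort("degenerate extent: single station with zero padding")
  }
  ncols <- ceiling((xmax - xmin) / cellsize - 1e-9) + 1
  nrows <- ceiling((ymax - ymin) / cellsize - 1e-9) + 1
  pred_grid(xll = xmin - cellsize / 2, yll = ymin - cellsize / 2,
            cellsize = cellsize, nrows = nrows, ncols = ncols)
}

#' Cell-center coordinates of a grid
#'
#' @param g A `pred_grid`.
#' @return Tibble with `row`, `col`, `x`, `y` (row 1 = northernmost).
#' @export
grid_centers <- function(g) {
  xs <- g$xll + g$cellsize / 2 + (seq_len(g$ncols) - 1) * g$cellsize
  ys <- g$yll + g$cellsize / 2 + (g$nrows - seq_len(g$nrows)) * g$cellsize
  tidyr::expand_grid(row = seq_len(g$nrows), col = seq_len(g$ncols)) |>
    dplyr::mutate(x = xs[.data$col], y = ys[.data$row])
}

#' @export
as_tibble.pred_grid <- function(x, ...) {
  out <- grid_centers(x)
  out$value <- as.vector(t(x$values))
  out$value[out$value == x$nodata] <- NA_real_
  if (!is.null(x$variance)) out$variance <- as.vector(t(x$variance))
  out
}

#' Write a grid as an ESRI ASCII raster
#'
#' Six header lines (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows north to south, values
#' printed with `%.6f`. Re-reading reproduces values to that precision.
#'
#' @param g A `pred_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("cannot write: ", path)))
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$ncols),
    sprintf("nrows %d", g$nrows),
    sprintf("xllcorner %.6f", g$xll),
    sprintf("yllcorner %.6f", g$yll),
    sprintf("cellsize %.6f", g$cellsize),
    sprintf("NODATA_value %g", g$nodata)
  ), con)
  apply(g$values, 1, function(r) {
    writeLines(paste(sprintf("%.6f", r), collapse = " "), con)
  })
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path Path to an `.asc` file written by [write_ascii_grid()] or a
#'   compatible tool.
#' @return A `pred_grid`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  m <- do.call(rbind, vals)
  pred_grid(xll = hdr$xllcorner, yll = hdr$yllcorner, cellsize = hdr$cellsize,
            nrows = hdr$nrows, ncols = hdr$ncols, values = m,
            nodata = hdr$nodata_value)
}

#' Plot a prediction grid
#'
#' @param object A `pred_grid`.
#' @param ... Unused.
#' @return A ggplot raster map of the predictions.
#' @export
autoplot.pred_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (m)", y = "Northing (m)", fill = "value")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
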