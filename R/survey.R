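#' Construct a survey tibble
#'
#' A survey is a tibble of point measurements: one row per station, with
#' identifier, WGS84 longitude/latitude, optional projected coordinates
#' (`x`, `y` in meters), a season tag (`"dry"` or `"wet"`), a logical
#' `is_pseudo` column marking neural-network-generated augmentation points,
#' and one numeric column per measured parameter (see [gw_parameters()]).
#'
#' @param df A data frame with at least `station_id`, `lon`, `lat`.
#' @return A validated survey tibble (class `gw_survey`/`tbl_df`).
#' @export
as_survey <- function(df) {
  df <- as_tibble(df)
  required <- c("station_id", "lon", "lat")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("survey is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("no records")
  if (!"season" %in% names(df)) df$season <- NA_character_
  if (!"is_pseudo" %in% names(df)) df$is_pseudo <- FALSE
  df$station_id <- as.character(df$station_id)
  df$is_pseudo <- as.logical(df$is_pseudo)
  bad_season <- !is.na(df$season) & !df$season %in% c("dry", "wet")
  if (any(bad_season)) {
    abort(paste0("season must be 'dry' or 'wet'; offending row(s): ",
                 paste(which(bad_season), collapse = ", ")))
  }
  param_cols <- intersect(names(df), .gw_parameters)
  for (p in param_cols) df[[p]] <- as.numeric(df[[p]])
  if (length(param_cols) > 0) {
    all_missing <- rowSums(!is.na(as.matrix(df[param_cols]))) == 0
    if (any(all_missing)) {
      abort(paste0("station(s) with all parameter values missing: ",
                   paste(df$station_id[all_missing], collapse = ", ")))
    }
  }
  class(df) <- c("gw_survey", class(df))
  df
}

#' Read a point survey from CSV or GeoJSON
#'
#' CSV files need a header with at least `station_id,lon,lat`; a `season`
#' column and any subset of the parameter schema may follow. Unknown numeric
#' columns are carried through with a warning. GeoJSON input must be a
#' FeatureCollection of Point features with parameters in `properties`.
#' Missing numeric cells stay missing (`NA`), never zero.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"geojson"`; guessed from the extension by default.
#' @return A survey tibble; `x`/`y` are unset until [project_utm()] is called.
#' @export
read_survey <- function(path, format = c("auto", "csv", "geojson")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      "geojson" else "csv"
  }
  df <- if (format == "csv") read_survey_csv(path) else read_survey_geojson(path)
  extra <- setdiff(names(df), c(.gw_meta_cols, .gw_parameters,
                                "barangay", "municipality", "elevation_m"))
  if (length(extra) > 0) {
    warn(paste0("unknown parameter column(s) carried through: ",
                paste(extra, collapse = ", ")))
  }
  as_survey(df)
}

read_survey_csv <- function(path) {
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA")),
    error = function(e) abort(paste0("malformed CSV: ", conditionMessage(e)))
  )
  if (nrow(df) == 0) abort("no records")
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0("malformed row ", prob$row[1], ": ", prob$expected[1],
                 " expected, got '", prob$actual[1], "'"))
  }
  for (cl in c("lon", "lat")) {
    if (cl %in% names(df) && !is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))) & !is.na(df[[cl]]))
      abort(paste0("malformed row ", if (length(bad)) bad[1] else NA,
                   ": non-numeric ", cl))
    }
  }
  df
}

read_survey_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (is.null(feats) || length(feats) == 0) abort("no records")
  rows <- purrr::imap(feats, function(f, i) {
    if (is.null(f$geometry) || !identical(f$geometry$type, "Point")) {
      abort(paste0("malformed row ", i, ": feature geometry is not a Point"))
    }
    cc <- unlist(f$geometry$coordinates)
    props <- purrr::map(f$properties %||% list(),
                        ~ if (is.null(.x)) NA else .x)
    tibble(lon = cc[1], lat = cc[2], !!!props)
  })
  df <- dplyr::bind_rows(rows)
  if (!"station_id" %in% names(df)) {
    df$station_id <- paste0("F", seq_len(nrow(df)))
  }
  df
}

#' Write a survey to CSV
#'
#' Round-trips losslessly with [read_survey()] at full double precision.
#'
#' @param s Survey tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(s, path) {
  readr::write_csv(s, path)
  invisible(path)
}

#' Measured (non-pseudo) stations of a survey
#' @param s Survey tibble.
#' @return Survey tibble without pseudo-stations.
#' @export
measured_stations <- function(s) {
  dplyr::filter(s, !.data$is_pseudo)
}
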