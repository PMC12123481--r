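# Plain-text readers/writers for the package's external formats: trap
# tables, crossing sets, spread matrices, cleaning parameters and small
# km-grid rasters. Everything round-trips through ordinary CSV so outputs
# stay inspectable and diffable.

#' Read and write yearly trap tables
#'
#' CSV schema: `year`, `x_km`, `y_km`, `catch`, `treated` (0/1).
#'
#' @param traps data.frame in the schema above.
#' @param path file path.
#' @return `read_trap_csv` returns the data.frame (with `treated` as
#'   integer); `write_trap_csv` returns `path` invisibly.
#' @export
write_trap_csv <- function(traps, path) {
  stopifnot(all(c("year", "x_km", "y_km", "catch", "treated") %in%
                  names(traps)))
  utils::write.csv(traps[, c("year", "x_km", "y_km", "catch", "treated")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trap_csv
#' @export
read_trap_csv <- function(path) {
  out <- utils::read.csv(path)
  need <- c("year", "x_km", "y_km", "catch", "treated")
  if (!all(need %in% names(out))) {
    stop("trap CSV must have columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(is.finite(out$catch)), all(out$catch >= 0))
  out
}

#' Write and read crossing sets
#'
#' CSV schema: `bearing`, `year`, `distance_km`, `missing` (0/1).
#'
#' @param crossings a `crossing_set` data.frame (see
#'   [transect_crossings]) or a stack of them.
#' @param path file path.
#' @export
write_crossings_csv <- function(crossings, path) {
  out <- crossings[, c("bearing", "year", "distance_km", "missing")]
  out$missing <- as.integer(out$missing)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_crossings_csv
#' @export
read_crossings_csv <- function(path) {
  out <- utils::read.csv(path)
  out$missing <- as.logical(out$missing)
  class(out) <- c("crossing_set", class(out))
  out
}

#' Write and read a spatio-temporal field as CSV
#'
#' Rows are locations, columns years; the first columns hold the location
#' id and region label.
#'
#' @param field an [stfield].
#' @param path file path.
#' @export
write_stfield_csv <- function(field, path) {
  df <- data.frame(location = as.character(attr(field, "locations")),
                   region = attr(field, "region"),
                   unclass(field), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stfield_csv
#' @export
read_stfield_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  stfield(vals, locations = df$location,
          years = as.numeric(colnames(vals)), region = df$region)
}

#' Write and read a km-grid raster as plain text
#'
#' A small self-describing text format: a header line
#' `nx ny cell_km x0 y0` followed by `ny` lines of `nx` values
#' (column-major in y).
#'
#' @param grid a [raster_grid].
#' @param path file path.
#' @export
write_grid_txt <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %.10g %.10g %.10g", length(grid$x),
                     length(grid$y), grid$cell_km, grid$x[1], grid$y[1]),
             con)
  utils::write.table(t(grid$values), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_txt
#' @export
read_grid_txt <- function(path) {
  hdr <- scan(path, nlines = 1, quiet = TRUE)
  vals <- as.matrix(utils::read.table(path, skip = 1))
  nx <- hdr[1]; ny <- hdr[2]; cell <- hdr[3]
  stopifnot(nrow(vals) == ny, ncol(vals) == nx)
  raster_grid(t(vals), x = hdr[4] + (seq_len(nx) - 1) * cell,
              y = hdr[5] + (seq_len(ny) - 1) * cell, cell_km = cell)
}

#' Write the tidy result table
#'
#' @param result the list returned by [run_analysis].
#' @param path file path.
#' @export
write_result_csv <- function(result, path) {
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}
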