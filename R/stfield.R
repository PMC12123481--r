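#' Spatio-temporal field container
#'
#' A `stfield` is a locations x years numeric matrix with location
#' identifiers (typically transect bearings in degrees), calendar years, and
#' a region label per location.  It is the common currency between the
#' geometry, cleaning, wavelet, coherence and Moran stages: spread rates are
#' km/yr, climate variables keep their native units (degrees C, mm).
#'
#' @param values numeric matrix, locations in rows, years in columns.
#'   `NA` marks missing observations.
#' @param locations identifiers for the rows (bearings or station ids);
#'   defaults to existing rownames or `1:nrow`.
#' @param years integer vector of column years; defaults to colnames or a
#'   unit sequence.
#' @param region character vector of region labels, length 1 (recycled) or
#'   `nrow(values)`.
#'
#' @return An object of class `stfield`: the matrix with `locations`,
#'   `years` and `region` attributes.
#' @export
stfield <- function(values, locations = NULL, years = NULL, region = "ALL") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(locations)) {
    locations <- if (!is.null(rownames(values))) rownames(values) else seq_len(nrow(values))
  }
  if (is.null(years)) {
    years <- if (!is.null(colnames(values))) as.integer(colnames(values)) else seq_len(ncol(values))
  }
  stopifnot(length(locations) == nrow(values), length(years) == ncol(values))
  if (length(region) == 1L) region <- rep(region, nrow(values))
  stopifnot(length(region) == nrow(values))
  rownames(values) <- as.character(locations)
  colnames(values) <- as.character(years)
  structure(values,
            locations = locations, years = as.numeric(years),
            region = region, class = c("stfield", "matrix", "array"))
}

#' @export
print.stfield <- function(x, ...) {
  cat(sprintf("<stfield> %d locations x %d years (%s..%s), regions: %s\n",
              nrow(x), ncol(x),
              format(min(attr(x, "years"))), format(max(attr(x, "years"))),
              paste(unique(attr(x, "region")), collapse = ", ")))
  cat(sprintf("  missing entries: %d\n", sum(is.na(x))))
  invisible(x)
}

#' @rdname stfield
#' @param x object to test.
#' @export
is_stfield <- function(x) inherits(x, "stfield")

# Rebuild an stfield after subsetting rows/columns of the bare matrix.
restfield <- function(values, template, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(unclass(template)))
  if (is.null(cols)) cols <- seq_len(ncol(unclass(template)))
  stfield(values,
          locations = attr(template, "locations")[rows],
          years = attr(template, "years")[cols],
          region = attr(template, "region")[rows])
}

#' Subset an stfield by region
#'
#' @param field an [stfield].
#' @param region region label(s) to keep.
#' @return an [stfield] with only the matching locations.
#' @export
stfield_region <- function(field, region) {
  keep <- attr(field, "region") %in% region
  if (!any(keep)) stop("no locations in region(s): ", paste(region, collapse = ", "))
  restfield(unclass(field)[keep, , drop = FALSE], field, rows = which(keep))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
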