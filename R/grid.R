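#' Categorical land-use grid
#'
#' A light container for a single-band categorical raster: an integer matrix
#' of class codes plus the cell area (hm^2 per cell), a nodata code and
#' minimal georeferencing metadata (lower-left origin, cell size, CRS label).
#'
#' @param values integer matrix of class codes; `NA` marks nodata.
#' @param cell_area area of one cell in hm^2 (> 0).
#' @param classes integer vector of valid class codes; defaults to the codes
#'   present, or 1:6 when `values` only uses codes within 1..6.
#' @param nodata integer nodata code used on disk; in memory nodata is `NA`.
#' @param xll,yll coordinates of the lower-left corner.
#' @param cellsize ground cell size (side length) in the CRS units.
#' @param crs free-text CRS label carried through, never interpreted.
#' @param year optional epoch label.
#' @return an object of class `lulc_grid`.
#' @export
lulc_grid <- function(values, cell_area = 1, classes = NULL,
                      nodata = -9999L, xll = 0, yll = 0, cellsize = 100,
                      crs = NA_character_, year = NA) {
  if (!is.matrix(values)) stop("`values` must be a matrix of class codes")
  storage.mode(values) <- "integer"
  if (!is.numeric(cell_area) || length(cell_area) != 1 || cell_area <= 0)
    stop("`cell_area` must be a single positive number (hm^2 per cell)")
  present <- sort(unique(values[!is.na(values)]))
  if (is.null(classes)) {
    classes <- if (length(present) && min(present) >= 1 && max(present) <= 6)
      1:6 else present
  }
  if (length(present) && !all(present %in% classes))
    stop("grid contains codes outside the declared class set: ",
         paste(setdiff(present, classes), collapse = ", "))
  structure(
    list(values = values, cell_area = cell_area, classes = as.integer(classes),
         nodata = as.integer(nodata), xll = xll, yll = yll,
         cellsize = cellsize, crs = crs, year = year),
    class = "lulc_grid")
}

#' @export
print.lulc_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<lulc_grid> %d x %d cells, cell_area %g hm^2, %d classes%s\n",
              d[1], d[2], x$cell_area, length(x$classes),
              if (!is.na(x$year)) paste0(", epoch ", x$year) else ""))
  invisible(x)
}

#' @export
dim.lulc_grid <- function(x) dim(x$values)

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_area, b$cell_area)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize)))
}

#' Read / write a categorical grid as an ESRI ASCII grid
#'
#' Plain-text single-band raster exchange. `write_asc()` stores integer class
#' codes with an explicit `NODATA_value`; `read_asc()` restores them as an
#' [lulc_grid()].
#'
#' @param grid an `lulc_grid`.
#' @param path file path (conventionally `.asc`).
#' @param cell_area cell area in hm^2 to attach on read (the format itself
#'   only stores the ground cell size).
#' @param year optional epoch label attached on read.
#' @return `read_asc()` returns an `lulc_grid`; `write_asc()` returns `path`
#'   invisibly.
#' @export
write_asc <- function(grid, path) {
  stopifnot(inherits(grid, "lulc_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", grid$xll),
    paste("yllcorner", grid$yll),
    paste("cellsize", grid$cellsize),
    paste("NODATA_value", grid$nodata)), con)
  write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path, cell_area = 1, year = NA) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  v <- as.matrix(read.table(path, skip = 6))
  dimnames(v) <- NULL
  storage.mode(v) <- "integer"
  v[v == val[["nodata_value"]]] <- NA_integer_
  lulc_grid(v, cell_area = cell_area, nodata = as.integer(val[["nodata_value"]]),
            xll = val[["xllcorner"]], yll = val[["yllcorner"]],
            cellsize = val[["cellsize"]], year = year)
}

#' Stack of continuous driving-factor rasters
#'
#' @param layers named list of numeric matrices, all with identical
#'   dimensions, aligned cell-for-cell with the land-use grid they describe.
#' @return an object of class `factor_stack`.
#' @export
factor_stack <- function(layers) {
  if (!length(layers)) stop("factor_stack needs at least one layer")
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("factor", seq_along(layers))
  dims <- lapply(layers, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all factor layers must share the same dimensions")
  if (any(vapply(layers, function(m) all(is.na(m)), logical(1))))
    stop("factor stack contains an all-nodata layer")
  structure(list(layers = layers, dim = dims[[1]]), class = "factor_stack")
}

#' @export
print.factor_stack <- function(x, ...) {
  cat(sprintf("<factor_stack> %d layers of %d x %d\n", length(x$layers),
              x$dim[1], x$dim[2]))
  invisible(x)
}

#' @export
length.factor_stack <- function(x) length(x$layers)
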