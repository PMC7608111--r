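#' Gridded raster layer
#'
#' A `land_grid` is a lightweight in-memory raster: a numeric matrix with a
#' simple georeference (lower-left corner, square cell size) and an explicit
#' nodata sentinel. Row 1 of the matrix is the northernmost row; cells are
#' addressed `(row, col)`. Missing cells are stored as `NA` in the matrix and
#' written to disk using the nodata sentinel; every statistic in the package
#' masks them explicitly.
#'
#' @param values Numeric matrix (row 1 = north). `NA` marks nodata.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length (degrees or abstract units).
#' @param crs Free-text label of the coordinate reference system.
#' @param nodata Sentinel value used on disk for missing cells.
#'
#' @return An object of class `land_grid`.
#' @examples
#' g <- land_grid(matrix(1:9, 3, 3))
#' grid_values(g)
#' @export
land_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                      crs = "unspecified", nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), crs = as.character(crs),
         nodata = as.numeric(nodata)),
    class = "land_grid"
  )
}

#' @export
print.land_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<land_grid> %d x %d cells, cellsize %g, origin (%g, %g)\n",
              d[1], d[2], x$cellsize, x$xll, x$yll))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  data cells: %d   range [%.4g, %.4g]\n", length(v),
                min(v), max(v)))
  } else {
    cat("  no data cells\n")
  }
  invisible(x)
}

#' @export
dim.land_grid <- function(x) dim(x$values)

#' Extract the value matrix of a grid
#' @param grid A `land_grid`.
#' @return The numeric matrix of cell values (`NA` = nodata).
#' @export
grid_values <- function(grid) {
  stopifnot(inherits(grid, "land_grid"))
  grid$values
}

#' Replace the values of a grid, keeping its georeference
#' @param grid A `land_grid` supplying shape and georeference.
#' @param values Matrix or vector recyclable to the grid's shape.
#' @return A new `land_grid`.
#' @export
grid_like <- function(grid, values) {
  stopifnot(inherits(grid, "land_grid"))
  m <- matrix(as.numeric(values), nrow(grid$values), ncol(grid$values))
  land_grid(m, grid$xll, grid$yll, grid$cellsize, grid$crs, grid$nodata)
}

#' @export
as_tibble.land_grid <- function(x, ..., value_name = "value") {
  d <- dim(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1])
  )
  out[[value_name]] <- as.vector(x$values)
  out
}

#' Read a plain-text (ESRI ASCII) raster grid
#'
#' Reads the ESRI ASCII grid format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' whitespace-separated cell values, first data row = northernmost row.
#'
#' @param path Path to the `.asc` file.
#' @param expected_shape Optional `c(nrows, ncols)`; a mismatch is an error.
#' @return A `land_grid` with nodata cells stored as `NA`.
#' @export
read_grid <- function(path, expected_shape = NULL) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("not an ASCII grid (truncated header): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed header line ", i, " in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header missing keys: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(vals), path))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  if (!is.null(expected_shape) && !all(dim(m) == expected_shape)) {
    stop(sprintf("grid %s has shape %dx%d, expected %dx%d", path,
                 nr, nc, expected_shape[1], expected_shape[2]))
  }
  land_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
            nodata = hdr$nodata_value)
}

#' Write a grid as a plain-text (ESRI ASCII) raster
#'
#' The written file round-trips through [read_grid()] value-exactly: cell
#' values are serialized with full double precision (17 significant digits).
#'
#' @param grid A `land_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "land_grid"))
  m <- grid$values
  bad <- is.finite(m) & m == grid$nodata
  if (any(bad)) stop("grid contains cells equal to the nodata sentinel ", grid$nodata)
  m[is.na(m)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Check that raster layers share one lattice
#'
#' Verifies that every grid has the same shape, cell size and origin. All
#' multi-layer operations in the package call this before combining layers.
#'
#' @param ... `land_grid` objects, or a single list of them (optionally named).
#' @return Invisibly `TRUE`; raises an error naming the first offending layer.
#' @export
assert_aligned <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && !inherits(layers[[1]], "land_grid")) {
    layers <- layers[[1]]
  }
  if (length(layers) < 2) stop("assert_aligned needs at least two layers")
  nm <- names(layers)
  if (is.null(nm)) nm <- paste0("layer", seq_along(layers))
  nm[nm == ""] <- paste0("layer", which(nm == ""))
  ref <- layers[[1]]
  stopifnot(inherits(ref, "land_grid"))
  for (i in seq_along(layers)[-1]) {
    g <- layers[[i]]
    if (!inherits(g, "land_grid")) stop(nm[i], " is not a land_grid")
    if (!all(dim(g$values) == dim(ref$values))) {
      stop(sprintf("alignment error: %s has shape %dx%d but %s has %dx%d",
                   nm[i], nrow(g$values), ncol(g$values),
                   nm[1], nrow(ref$values), ncol(ref$values)))
    }
    if (abs(g$cellsize - ref$cellsize) > 1e-12 ||
        abs(g$xll - ref$xll) > 1e-9 || abs(g$yll - ref$yll) > 1e-9) {
      stop(sprintf("alignment error: %s transform (%g, %g, %g) differs from %s (%g, %g, %g)",
                   nm[i], g$xll, g$yll, g$cellsize,
                   nm[1], ref$xll, ref$yll, ref$cellsize))
    }
  }
  invisible(TRUE)
}
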