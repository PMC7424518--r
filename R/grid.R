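#' Rectangular grid over a bounding box
#'
#' A `rect_grid` divides the box `[x_min, x_max] x [y_min, y_max]` into
#' `nx * ny` equal cells. Cells are indexed 0-based in row-major order:
#' `cell = iy * nx + ix` with `ix` counting columns from `x_min` and `iy`
#' counting rows from `y_min`. Cells are half-open `[low, high)` on each axis
#' except the last cell per axis, which is closed above so the maximum
#' coordinate is assignable.
#'
#' @param x_min,x_max,y_min,y_max Bounding box, in coordinate units.
#' @param nx,ny Number of cells along x and y (>= 1).
#' @return An object of class `rect_grid`.
#' @seealso [fit_bounds()], [assign_cells()]
#' @export
rect_grid <- function(x_min, x_max, y_min, y_max, nx, ny) {
  if (!(x_min < x_max) || !(y_min < y_max)) {
    stop("degenerate bounding box: need x_min < x_max and y_min < y_max")
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("nx and ny must be >= 1")
  structure(list(x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max,
                 nx = nx, ny = ny),
            class = "rect_grid")
}

#' @export
print.rect_grid <- function(x, ...) {
  cat(sprintf("rect_grid: %d x %d cells on [%g, %g] x [%g, %g]\n",
              x$nx, x$ny, x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

#' Fit a grid to the extent of an event table
#'
#' Builds a [rect_grid()] whose bounding box covers all events, optionally
#' padded symmetrically by a fraction of each axis range. Grid resolution is
#' deliberately a user decision — there is no general rule for choosing it,
#' and it trades spatial detail against network sparsity — so `nx` and `ny`
#' have no defaults.
#'
#' @param table A non-empty `event_table`.
#' @param nx,ny Cell counts per axis.
#' @param padding Fraction of each axis range added to both sides (default 0).
#' @return A `rect_grid`.
#' @examples
#' ev <- event_table(c(0, 10), c(0, 10), 1:2)
#' fit_bounds(ev, nx = 10, ny = 10)
#' @export
fit_bounds <- function(table, nx, ny, padding = 0) {
  if (nrow(table) == 0L) stop("cannot fit a grid to an empty event table")
  rx <- range(table$x); ry <- range(table$y)
  if (diff(rx) == 0 || diff(ry) == 0) {
    stop("degenerate extent: events span zero range on one axis; ",
         "supply an explicit rect_grid instead")
  }
  px <- diff(rx) * padding; py <- diff(ry) * padding
  rect_grid(rx[1] - px, rx[2] + px, ry[1] - py, ry[2] + py, nx, ny)
}

#' Assign events to grid cells
#'
#' Maps each event to the 0-based row-major id of the cell containing it,
#' via the floor rule `ix = floor((x - x_min) / w)` (and likewise for y),
#' with points on the top edge of the last cell per axis assigned to that
#' cell. Events outside the grid are an error that names the offending rows.
#'
#' @param table An `event_table`.
#' @param grid A `rect_grid`.
#' @return An integer vector of cell ids (class `cell_series`), one per
#'   event, with attributes `grid` and `n_cells` (number of distinct
#'   occupied cells).
#' @export
assign_cells <- function(table, grid) {
  stopifnot(inherits(grid, "rect_grid"))
  w <- (grid$x_max - grid$x_min) / grid$nx
  h <- (grid$y_max - grid$y_min) / grid$ny
  ix <- floor((table$x - grid$x_min) / w)
  iy <- floor((table$y - grid$y_min) / h)
  # closed top edge: the maximum coordinate belongs to the last cell
  ix[table$x == grid$x_max] <- grid$nx - 1L
  iy[table$y == grid$y_max] <- grid$ny - 1L
  bad <- which(ix < 0 | ix >= grid$nx | iy < 0 | iy >= grid$ny |
                 !is.finite(ix) | !is.finite(iy))
  if (length(bad)) {
    stop("events out of grid bounds at rows: ",
         paste(utils::head(bad, 20L), collapse = ", "),
         if (length(bad) > 20L) sprintf(" (and %d more)", length(bad) - 20L))
  }
  ids <- as.integer(iy * grid$nx + ix)
  structure(ids, grid = grid, n_cells = length(unique(ids)),
            class = "cell_series")
}

#' @export
print.cell_series <- function(x, ...) {
  cat(sprintf("cell_series: %d events over %d occupied cells\n",
              length(x), attr(x, "n_cells")))
  invisible(x)
}

#' Cell centers of a rectangular grid
#'
#' @param grid A `rect_grid`.
#' @param cells Integer cell ids (0-based, row-major); default all cells.
#' @return A data.frame with columns `cell`, `x`, `y` (cell-center
#'   coordinates).
#' @export
cell_centers <- function(grid, cells = seq_len(grid$nx * grid$ny) - 1L) {
  w <- (grid$x_max - grid$x_min) / grid$nx
  h <- (grid$y_max - grid$y_min) / grid$ny
  ix <- cells %% grid$nx
  iy <- cells %/% grid$nx
  data.frame(cell = cells,
             x = grid$x_min + (ix + 0.5) * w,
             y = grid$y_min + (iy + 0.5) * h)
}

#' Cell count of an icosahedral hexagonal global grid
#'
#' Icosahedral aperture-`a` hexagonal discrete global grid systems (DGGS)
#' have a closed-form cell count at resolution `r`: `10 * a^r + 2` cells (12
#' of which are pentagons inherited from the icosahedron vertices). The
#' package does not construct hexagon geometry — cell assignments from an
#' external DGGS tool are ingested with [load_cell_assignment()] — but the
#' count and mean area are analytic and useful for choosing a resolution.
#'
#' @param aperture Aperture of the DGGS (cells per parent cell between
#'   successive resolutions); 3 for the common aperture-3 hexagonal system.
#' @param resolution Non-negative integer resolution.
#' @return Number of cells (numeric).
#' @examples
#' dggs_cell_count(aperture = 3, resolution = 7)  # 21872
#' @export
dggs_cell_count <- function(aperture = 3, resolution) {
  if (resolution < 0) stop("resolution must be >= 0")
  if (aperture < 1) stop("aperture must be >= 1")
  10 * aperture^resolution + 2
}

#' Mean cell area of an icosahedral hexagonal global grid
#'
#' @inheritParams dggs_cell_count
#' @param surface_area Total surface partitioned by the grid, in km^2;
#'   defaults to the Earth's surface area (authalic sphere), 5.10072e8 km^2.
#' @return Mean cell area in km^2 (`surface_area / dggs_cell_count(...)`).
#' @examples
#' dggs_mean_cell_area(aperture = 3, resolution = 7)  # ~23322 km^2
#' @export
dggs_mean_cell_area <- function(aperture = 3, resolution,
                                surface_area = 5.10072e8) {
  surface_area / dggs_cell_count(aperture, resolution)
}

#' Load an externally computed cell assignment
#'
#' Accepts per-event cell ids computed by any external gridding tool (for
#' example a hexagonal DGGS library), so that geographic grids beyond the
#' built-in rectangular one can be used everywhere a `cell_series` is. The
#' file is delimited text with a header and a cell-id column; rows align
#' with the (sorted) event table by record order.
#'
#' @param path Delimited text file with a header; the cell-id column is
#'   `cell` if present, otherwise the last column.
#' @param n_events If supplied, the number of events the assignment must
#'   match; a length mismatch is an error.
#' @return A `cell_series` (integer ids; no `grid` attribute).
#' @export
load_cell_assignment <- function(path, n_events = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (length(header) && grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  col <- if ("cell" %in% names(raw)) "cell" else names(raw)[length(raw)]
  ids <- suppressWarnings(as.integer(raw[[col]]))
  if (anyNA(ids)) {
    stop("missing or non-integer cell id at rows: ",
         paste(utils::head(which(is.na(ids)), 20L), collapse = ", "))
  }
  if (!is.null(n_events) && length(ids) != n_events) {
    stop(sprintf("cell assignment has %d rows but the event table has %d",
                 length(ids), n_events))
  }
  structure(ids, n_cells = length(unique(ids)), class = "cell_series")
}

#' Write a cell assignment
#'
#' @param cells A `cell_series`.
#' @param path Output path (comma-delimited, columns `event`, `cell`).
#' @return `path`, invisibly.
#' @export
write_cell_assignment <- function(cells, path) {
  utils::write.csv(data.frame(event = seq_along(cells),
                              cell = as.integer(cells)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
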