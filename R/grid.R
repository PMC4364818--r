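#' Lattice representation of a classed polygon layer
#'
#' All spatial computation in hnvfmap runs on a regular lattice in a projected
#' metric coordinate system: a layer is an integer matrix of class indices
#' (0 = no class) plus the vector of class codes, the cell size in metres and
#' the coordinates of the lower-left corner. Row 1 is the northernmost row.
#' Polygon inputs are discretized onto this lattice on load (cell-centre
#' rule), so that areas are exact for any mosaic whose boundaries are aligned
#' to the lattice and accurate to one cell size otherwise.
#'
#' @param cells integer matrix of class indices into \code{codes}; 0 for
#'   cells carrying no class
#' @param codes character vector of class (or unit) codes
#' @param cellsize cell edge length in metres
#' @param origin numeric length-2, x/y of the lower-left corner
#' @param crs free-text label of the projected CRS (metre units assumed)
#' @return An object of class \code{land_grid}.
#' @export
land_grid <- function(cells, codes, cellsize, origin = c(0, 0),
                      crs = "local-metric") {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (any(cells < 0L | cells > length(codes), na.rm = TRUE))
    stop("cell values must index 'codes' (or be 0)")
  if (anyNA(cells)) stop("cells must not contain NA; use 0 for empty")
  if (!is.numeric(cellsize) || cellsize <= 0)
    stop("cellsize must be a positive number of metres")
  if (anyDuplicated(codes)) stop("codes must be unique")
  structure(list(cells = cells, codes = as.character(codes),
                 cellsize = as.numeric(cellsize),
                 origin = as.numeric(origin), crs = crs),
            class = "land_grid")
}

#' @export
print.land_grid <- function(x, ...) {
  d <- dim(x$cells)
  cat(sprintf("<land_grid> %d x %d cells @ %g m (%.2f ha), %d codes, crs '%s'\n",
              d[1], d[2], x$cellsize,
              sum(x$cells > 0L) * cell_area_ha(x), length(x$codes), x$crs))
  invisible(x)
}

#' Area of one lattice cell in hectares
#' @param grid a \code{land_grid}
#' @return Scalar, ha (planar m^2 / 10,000).
#' @export
cell_area_ha <- function(grid) grid$cellsize^2 / 1e4

#' Per-class areas of a lattice layer
#'
#' @param grid a \code{land_grid}
#' @param mask optional logical matrix restricting the tally
#' @return Named numeric vector of hectares, one entry per code (zeros kept).
#' @export
class_areas <- function(grid, mask = NULL) {
  v <- grid$cells
  if (!is.null(mask)) v <- v[mask]
  n <- tabulate(v, nbins = length(grid$codes))
  stats::setNames(n * cell_area_ha(grid), grid$codes)
}

#' Logical mask of cells carrying any of the given codes
#' @param grid a \code{land_grid}
#' @param codes character vector of codes
#' @return Logical matrix with the grid's dimensions.
#' @export
grid_mask <- function(grid, codes) {
  idx <- match(codes, grid$codes)
  if (anyNA(idx)) {
    # codes absent from the layer simply select nothing
    idx <- idx[!is.na(idx)]
  }
  matrix(grid$cells %in% idx & grid$cells > 0L, nrow = nrow(grid$cells))
}

#' Cell-centre coordinates of a lattice
#' @param grid a \code{land_grid}
#' @return List with matrices \code{x} and \code{y} (grid dimensions).
#' @keywords internal
cell_centres <- function(grid) {
  ny <- nrow(grid$cells); nx <- ncol(grid$cells); cs <- grid$cellsize
  x <- matrix(grid$origin[1] + (seq_len(nx) - 0.5) * cs, ny, nx, byrow = TRUE)
  y <- matrix(grid$origin[2] + (ny - seq_len(ny) + 0.5) * cs, ny, nx)
  list(x = x, y = y)
}

#' Empty lattice template
#'
#' @param nx,ny cell counts (columns, rows)
#' @param cellsize cell edge length, metres
#' @param origin lower-left corner
#' @param codes class codes the layer may carry
#' @param crs projected CRS label
#' @return A \code{land_grid} of zeros.
#' @export
grid_template <- function(nx, ny, cellsize, origin = c(0, 0),
                          codes = character(), crs = "local-metric") {
  land_grid(matrix(0L, ny, nx), codes, cellsize, origin, crs)
}

#' Restrict a land-cover lattice to one landscape unit
#'
#' The lattice analogue of clipping a polygon layer to a unit boundary: cells
#' whose centre falls outside the unit are blanked. Total retained area can
#' never exceed the unit area.
#'
#' @param map a \code{land_grid} land-cover layer
#' @param zones a \code{land_grid} whose codes are unit ids
#' @param unit_id the unit to clip to
#' @return A \code{land_grid} with the same dims/codes, cells outside the
#'   unit set to 0.
#' @export
clip_to_unit <- function(map, zones, unit_id) {
  stopifnot(identical(dim(map$cells), dim(zones$cells)))
  keep <- grid_mask(zones, unit_id)
  out <- map
  out$cells[!keep] <- 0L
  out
}

#' Landscape-unit table from a zone lattice
#'
#' @param zones \code{land_grid} whose codes are unit ids
#' @param names optional data.frame (unit_id, name)
#' @return data.frame: unit_id, name, t_area_ha.
#' @export
unit_table <- function(zones, names = NULL) {
  areas <- class_areas(zones)
  out <- data.frame(unit_id = zones$codes, name = zones$codes,
                    t_area_ha = as.numeric(areas), stringsAsFactors = FALSE)
  if (!is.null(names)) {
    i <- match(out$unit_id, names$unit_id)
    out$name[!is.na(i)] <- names$name[i[!is.na(i)]]
  }
  out
}
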