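# Conversion between polygon features and the lattice representation.
#
# A "feature" is list(props = named list, rings = list of 2-column coordinate
# matrices); the first ring is the exterior, later rings are holes (even-odd
# rule, so orientation is not significant on input). Rasterization uses the
# cell-centre rule via mgcv::in.out; polygonization traces the boundary edges
# of 4-connected cell regions, yielding exterior rings in counter-clockwise
# and holes in clockwise orientation.

#' Planar (shoelace) area of one ring
#' @param ring 2-column coordinate matrix (closed or open)
#' @return Signed area in squared map units (positive = counter-clockwise).
#' @keywords internal
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Rasterize polygon features onto a lattice template
#'
#' Cells are assigned the class of the feature containing their centre;
#' features are painted in order, so a later overlapping feature wins. Cells
#' covered by no feature stay 0.
#'
#' @param features list of features (see Details); each must carry the class
#'   code under \code{props[[class_field]]}
#' @param template a \code{land_grid} giving extent, cell size and codes; its
#'   code set is extended as needed unless \code{strict_codes}
#' @param class_field name of the property holding the class code
#' @param strict_codes if TRUE, a feature code absent from
#'   \code{template$codes} is an error
#' @return A \code{land_grid}.
#' @export
rasterize_features <- function(features, template, class_field = "class",
                               strict_codes = FALSE) {
  grid <- template
  ctr <- cell_centres(grid)
  ny <- nrow(grid$cells); nx <- ncol(grid$cells)
  for (f in features) {
    code <- f$props[[class_field]]
    if (is.null(code)) stop("feature without '", class_field, "' property")
    code <- as.character(code)
    k <- match(code, grid$codes)
    if (is.na(k)) {
      if (strict_codes)
        stop("class code not in registry/template: ", code)
      grid$codes <- c(grid$codes, code)
      k <- length(grid$codes)
    }
    bnd <- do.call(rbind, lapply(f$rings, function(r) rbind(r, c(NA, NA))))
    bnd <- bnd[-nrow(bnd), , drop = FALSE]
    # restrict the point-in-polygon test to the feature's bounding box
    rx <- range(bnd[, 1], na.rm = TRUE); ry <- range(bnd[, 2], na.rm = TRUE)
    sel <- ctr$x >= rx[1] & ctr$x <= rx[2] & ctr$y >= ry[1] & ctr$y <= ry[2]
    if (!any(sel)) next
    pts <- cbind(ctr$x[sel], ctr$y[sel])
    inside <- mgcv::in.out(bnd, pts)
    idx <- which(sel)[inside]
    if (length(idx)) grid$cells[idx] <- k
  }
  grid
}

# Trace the boundary of a logical cell mask into rings.
# Returns a list of polygons; each polygon is a list of closed rings
# (exterior first, counter-clockwise), one polygon per 4-connected component.
trace_mask <- function(mask, cellsize, origin) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- label_components(matrix(as.integer(mask), ny, nx))
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  polys <- vector("list", nlab)
  for (comp in seq_len(nlab)) {
    m <- lab == comp
    cells <- which(m, arr.ind = TRUE)
    r <- cells[, 1]; cc <- cells[, 2]
    yt <- ny - r + 1L; yb <- ny - r      # corner y-index (from bottom)
    xl <- cc - 1L; xr <- cc              # corner x-index
    pad <- function(dr, dc) {            # neighbour-out test
      rr <- r + dr; ccn <- cc + dc
      out <- rr < 1L | rr > ny | ccn < 1L | ccn > nx
      res <- out
      res[!out] <- !m[cbind(rr[!out], ccn[!out])]
      res
    }
    key <- function(i, j) i + j * (nx + 1L)
    # directed edges, interior on the left
    eL <- pad(0L, -1L); eR <- pad(0L, 1L); eT <- pad(-1L, 0L); eB <- pad(1L, 0L)
    from <- c(key(xl[eL], yt[eL]), key(xr[eR], yb[eR]),
              key(xr[eT], yt[eT]), key(xl[eB], yb[eB]))
    to   <- c(key(xl[eL], yb[eL]), key(xr[eR], yt[eR]),
              key(xl[eT], yt[eT]), key(xr[eB], yb[eB]))
    ne <- length(from)
    used <- logical(ne)
    ord <- order(from)
    starts <- from[ord]
    first <- match(unique(starts), starts)
    lookup <- new.env(hash = TRUE, size = length(first))
    for (i in seq_along(first)) {
      v <- as.character(starts[first[i]])
      upper <- if (i < length(first)) first[i + 1] - 1L else ne
      assign(v, ord[first[i]:upper], envir = lookup)
    }
    vx <- function(k) k %% (nx + 1L)
    vy <- function(k) k %/% (nx + 1L)
    rings <- list()
    for (e0 in seq_len(ne)) {
      if (used[e0]) next
      ring_keys <- from[e0]
      e <- e0
      repeat {
        used[e] <- TRUE
        v <- to[e]
        ring_keys <- c(ring_keys, v)
        if (v == from[e0]) break
        cand <- get(as.character(v), envir = lookup)
        cand <- cand[!used[cand]]
        if (!length(cand)) stop("boundary tracing failed to close a ring")
        if (length(cand) > 1L) {
          # corner-touch vertex: prefer the sharpest left turn to keep rings simple
          din <- c(vx(to[e]) - vx(from[e]), vy(to[e]) - vy(from[e]))
          turn <- vapply(cand, function(ce) {
            dout <- c(vx(to[ce]) - vx(from[ce]), vy(to[ce]) - vy(from[ce]))
            din[1] * dout[2] - din[2] * dout[1]
          }, numeric(1))
          cand <- cand[which.max(turn)]
        }
        e <- cand
      }
      coords <- cbind(origin[1] + vx(ring_keys) * cellsize,
                      origin[2] + vy(ring_keys) * cellsize)
      rings[[length(rings) + 1L]] <- coords
    }
    sa <- vapply(rings, ring_signed_area, numeric(1))
    ext <- which(sa > 0)
    if (length(ext) != 1L)
      stop("expected exactly one exterior ring per component")
    polys[[comp]] <- c(rings[ext], rings[-ext])
  }
  polys
}

#' Polygonize a lattice layer into features
#'
#' Each maximal 4-connected same-class cell region becomes one polygon
#' feature with exterior ring (counter-clockwise) and any holes (clockwise),
#' carrying the class code as a property. Re-rasterizing the result on the
#' same template reproduces the layer exactly.
#'
#' @param grid a \code{land_grid}
#' @param class_field property name to store the code under
#' @return List of features.
#' @export
grid_to_features <- function(grid, class_field = "class") {
  feats <- list()
  present <- sort(unique(grid$cells[grid$cells > 0L]))
  for (k in present) {
    polys <- trace_mask(grid$cells == k, grid$cellsize, grid$origin)
    for (p in polys) {
      props <- list()
      props[[class_field]] <- grid$codes[k]
      feats[[length(feats) + 1L]] <- list(props = props, rings = p)
    }
  }
  feats
}

#' Polygonize a logical mask into features
#'
#' @param mask logical matrix on the lattice of \code{grid}
#' @param grid the \code{land_grid} supplying cell size and origin
#' @param props property list attached to every feature
#' @return List of features (one per connected region), possibly empty.
#' @export
mask_to_features <- function(mask, grid, props = list()) {
  polys <- trace_mask(mask, grid$cellsize, grid$origin)
  lapply(polys, function(p) list(props = props, rings = p))
}
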