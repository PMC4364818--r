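# GeoJSON readers and writers. GeoJSON is the package's vector interchange
# format: it is plain text, round-trips exactly at fixed precision, and
# carries feature properties. Layers are rasterized onto the analysis lattice
# on load (cell-centre rule) and polygonized on write.

geographic_crs_pattern <- "(?i)(4326|wgs\\s*84|crs84|longlat|epsg:4258)"

check_projected <- function(crs) {
  if (!is.null(crs) && grepl(geographic_crs_pattern, crs, perl = TRUE))
    stop("layer is in a geographic (degree-unit) CRS ('", crs,
         "'); a projected CRS with metre units is required")
  invisible(crs)
}

#' Read a GeoJSON FeatureCollection into feature lists
#'
#' Polygon and MultiPolygon geometries are supported; Point geometries are
#' buffered into axis-aligned squares of side \code{point_buffer_m} (used for
#' species occurrences recorded as grid-square centres). Each feature becomes
#' \code{list(props, rings)}; MultiPolygon rings are flattened (the even-odd
#' rasterization rule makes this safe for disjoint parts).
#'
#' @param path GeoJSON file
#' @param crs optional CRS label overriding the file's legacy \code{crs}
#'   member; geographic CRSs are rejected
#' @param point_buffer_m side of the square substituted for Point geometries
#' @return List with \code{features} and \code{crs}.
#' @export
read_geojson <- function(path, crs = NULL, point_buffer_m = 1000) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path)
  file_crs <- tryCatch(g$crs$properties$name, error = function(e) NULL)
  crs <- crs %||% file_crs %||% "unspecified-projected"
  check_projected(crs)
  ring_mat <- function(r)
    do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
  feats <- lapply(seq_along(g$features), function(i) {
    f <- g$features[[i]]
    geom <- f$geometry
    if (is.null(geom)) stop("feature ", i, " has no geometry")
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      Point = {
        h <- point_buffer_m / 2
        x <- geom$coordinates[[1]]; y <- geom$coordinates[[2]]
        list(matrix(c(x - h, y - h, x + h, y - h, x + h, y + h,
                      x - h, y + h, x - h, y - h), ncol = 2, byrow = TRUE))
      },
      stop("unsupported geometry type '", geom$type, "' in feature ", i))
    for (r in rings)
      if (nrow(r) < 4) stop("degenerate ring in feature ", i,
                            " (fewer than 4 coordinates)")
    list(props = lapply(f$properties, function(p) p), rings = rings)
  })
  list(features = feats, crs = crs)
}

#' Write features as a GeoJSON FeatureCollection
#'
#' @param features list of features (\code{list(props, rings)}); the first
#'   ring of each feature is written as the exterior, the rest as holes
#' @param path output file
#' @param crs CRS label, stored in the legacy \code{crs} member
#' @return \code{path}, invisibly.
#' @export
write_geojson <- function(features, path, crs = "local-metric") {
  feat_json <- lapply(features, function(f) {
    list(type = "Feature",
         properties = f$props,
         geometry = list(type = "Polygon",
                         coordinates = lapply(f$rings, identity)))
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = crs)),
             features = feat_json)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 8,
                       matrix = "rowmajor")
  invisible(path)
}

# Lattice template spanning the bounding box of feature lists, with origin
# snapped down to a multiple of the cell size.
template_from_features <- function(feature_sets, cellsize,
                                   crs = "local-metric") {
  all_xy <- do.call(rbind, unlist(lapply(feature_sets, function(fs)
    lapply(fs, function(f) do.call(rbind, f$rings))), recursive = FALSE))
  x0 <- floor(min(all_xy[, 1]) / cellsize) * cellsize
  y0 <- floor(min(all_xy[, 2]) / cellsize) * cellsize
  nx <- ceiling((max(all_xy[, 1]) - x0) / cellsize)
  ny <- ceiling((max(all_xy[, 2]) - y0) / cellsize)
  grid_template(nx, ny, cellsize, c(x0, y0), crs = crs)
}

#' Load a land-cover map
#'
#' Reads a polygon GeoJSON layer whose features carry a land-cover class code
#' and rasterizes it onto the analysis lattice. Every code must resolve in
#' the registry.
#'
#' @param path GeoJSON file
#' @param registry \code{hnvf_registry}
#' @param cellsize lattice cell size (m), used when no template is given
#' @param template optional \code{land_grid} fixing extent and resolution
#'   (recommended so that all layers share one lattice)
#' @param crs optional CRS label override
#' @param class_field property holding the class code
#' @return A \code{land_grid} whose codes are the registry codes.
#' @export
load_landcover <- function(path, registry, cellsize = 10, template = NULL,
                           crs = NULL, class_field = "class") {
  gj <- read_geojson(path, crs = crs)
  codes <- vapply(gj$features,
                  function(f) as.character(f$props[[class_field]] %||% NA),
                  character(1))
  unknown <- setdiff(stats::na.omit(unique(codes)), registry$code)
  if (length(unknown))
    stop("class code(s) not in registry: ", paste(unknown, collapse = ", "))
  if (is.null(template))
    template <- template_from_features(list(gj$features), cellsize,
                                       crs = gj$crs)
  template$codes <- registry$code
  rasterize_features(gj$features, template, class_field = class_field,
                     strict_codes = TRUE)
}

#' Load administrative-unit boundaries
#'
#' @param path GeoJSON file; features carry \code{unit_id} and optionally
#'   \code{name}
#' @param cellsize,template,crs as in \code{\link{load_landcover}}
#' @return List: \code{zones} (a \code{land_grid} of unit ids) and
#'   \code{units} (data.frame unit_id, name, t_area_ha).
#' @export
load_units <- function(path, cellsize = 10, template = NULL, crs = NULL) {
  gj <- read_geojson(path, crs = crs)
  ids <- vapply(gj$features,
                function(f) as.character(f$props$unit_id %||% NA),
                character(1))
  if (anyNA(ids)) stop("unit feature without 'unit_id' property")
  nm <- vapply(gj$features, function(f)
    as.character(f$props$name %||% f$props$unit_id), character(1))
  if (is.null(template))
    template <- template_from_features(list(gj$features), cellsize,
                                       crs = gj$crs)
  template$codes <- unique(ids)
  zones <- rasterize_features(gj$features, template, class_field = "unit_id",
                              strict_codes = TRUE)
  names_df <- unique(data.frame(unit_id = ids, name = nm,
                                stringsAsFactors = FALSE))
  list(zones = zones, units = unit_table(zones, names_df))
}

#' Load a natural-constraints (ANC) layer
#'
#' @param path GeoJSON file; features carry a \code{limitation} property with
#'   value \code{none}, \code{moderate} or \code{severe}
#' @param template \code{land_grid} fixing the lattice (required so the layer
#'   aligns with the land cover)
#' @param crs optional CRS label override
#' @param missing limitation assumed where the layer has no coverage
#' @return A \code{land_grid} with codes \code{none|moderate|severe} and no
#'   empty cells.
#' @export
load_constraints <- function(path, template, crs = NULL, missing = "none") {
  levels <- c("none", "moderate", "severe")
  stopifnot(missing %in% levels)
  gj <- read_geojson(path, crs = crs)
  lim <- vapply(gj$features,
                function(f) as.character(f$props$limitation %||% NA),
                character(1))
  bad <- setdiff(stats::na.omit(unique(lim)), levels)
  if (length(bad))
    stop("unknown limitation class(es): ", paste(bad, collapse = ", "))
  template$codes <- levels
  out <- rasterize_features(gj$features, template, class_field = "limitation",
                            strict_codes = TRUE)
  out$cells[out$cells == 0L] <- match(missing, levels)
  out
}

#' Load indicator-species occurrences
#'
#' @param path GeoJSON file; features carry \code{species_id} and \code{kind}
#'   (\code{plant_grid} or \code{iba_polygon}); Point geometries are buffered
#'   to \code{grid_square_m} squares
#' @param crs optional CRS label override
#' @param grid_square_m side of the occurrence square for point records
#' @return List of occurrence features (props: species_id, kind).
#' @export
load_species <- function(path, crs = NULL, grid_square_m = 1000) {
  gj <- read_geojson(path, crs = crs, point_buffer_m = grid_square_m)
  for (i in seq_along(gj$features)) {
    p <- gj$features[[i]]$props
    if (is.null(p$species_id)) stop("occurrence ", i, " lacks species_id")
    if (is.null(p$kind) || !p$kind %in% c("plant_grid", "iba_polygon"))
      stop("occurrence ", i,
           " needs kind 'plant_grid' or 'iba_polygon'")
  }
  gj$features
}

#' Rasterize occurrence features to per-occurrence masks
#'
#' @param occurrences list of occurrence features
#' @param template \code{land_grid} defining the lattice
#' @return List of logical matrices, one per occurrence.
#' @export
occurrence_masks <- function(occurrences, template) {
  template$codes <- "occ"
  lapply(occurrences, function(f) {
    g <- rasterize_features(list(list(props = list(class = "occ"),
                                      rings = f$rings)), template)
    g$cells == 1L
  })
}
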