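# Landscape Elements metrics: patch number (NP), mean shape index (MSI),
# edge density (ED), Shannon diversity (SDI) and evenness (SEI), computed per
# landscape unit on the lattice. A patch is a maximal 4-connected region of
# one class: same-class cells sharing an edge belong to one patch, corner
# contact does not merge (the vector-dissolve adjacency rule).

# 4-connected same-value component labelling (0 = background).
# Returns an integer matrix of labels, 0 where cls is 0.
label_components <- function(cls) {
  ny <- nrow(cls); nx <- ncol(cls)
  nz <- which(cls > 0L)
  if (!length(nz)) return(matrix(0L, ny, nx))
  rank <- integer(ny * nx)
  rank[nz] <- seq_along(nz)
  edges <- integer(0)
  if (nx > 1L) {
    same <- cls[, -nx, drop = FALSE] == cls[, -1L, drop = FALSE] &
      cls[, -nx, drop = FALSE] > 0L
    pos <- which(same)
    if (length(pos)) {
      id1 <- (((pos - 1L) %/% ny)) * ny + ((pos - 1L) %% ny) + 1L
      edges <- c(edges, rbind(rank[id1], rank[id1 + ny]))
    }
  }
  if (ny > 1L) {
    same <- cls[-ny, , drop = FALSE] == cls[-1L, , drop = FALSE] &
      cls[-ny, , drop = FALSE] > 0L
    pos <- which(same)
    if (length(pos)) {
      r <- (pos - 1L) %% (ny - 1L) + 1L
      cc <- (pos - 1L) %/% (ny - 1L) + 1L
      id1 <- (cc - 1L) * ny + r
      edges <- c(edges, rbind(rank[id1], rank[id1 + 1L]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(nz), directed = FALSE)
  memb <- igraph::components(g)$membership
  out <- matrix(0L, ny, nx)
  out[nz] <- as.integer(memb)
  out
}

# Per-label boundary-edge counts; optionally also the counts of edges shared
# with cells outside `unit_mask` (the unit boundary itself).
patch_perimeters <- function(lab, unit_mask = NULL) {
  ny <- nrow(lab); nx <- ncol(lab)
  nlab <- max(lab)
  if (nlab == 0L) return(list(total = numeric(0), boundary = numeric(0)))
  pad <- matrix(0L, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- lab
  if (!is.null(unit_mask)) {
    padu <- matrix(FALSE, ny + 2L, nx + 2L)
    padu[2:(ny + 1L), 2:(nx + 1L)] <- unit_mask
  }
  core <- cbind(rep(2:(ny + 1L), nx), rep(2:(nx + 1L), each = ny))
  shifts <- list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))
  tot <- numeric(nlab); bnd <- numeric(nlab)
  for (s in shifts) {
    nb <- cbind(core[, 1] + s[1], core[, 2] + s[2])
    here <- pad[core]
    there <- pad[nb]
    edge <- here > 0L & there != here
    tot <- tot + tabulate(here[edge], nbins = nlab)
    if (!is.null(unit_mask)) {
      on_bnd <- edge & !padu[nb]
      bnd <- bnd + tabulate(here[on_bnd], nbins = nlab)
    }
  }
  list(total = tot, boundary = bnd)
}

#' Delineate patches of a clipped land-cover lattice
#'
#' Merges edge-adjacent same-class cells into patches and computes per-patch
#' planar area and perimeter. Under \code{scope = "farmland_only"} only
#' classes with role \code{farmland} or \code{off_farm_grazing} are
#' considered; all other cells are treated as matrix.
#'
#' @param map \code{land_grid}, already clipped to the unit of interest
#' @param registry \code{hnvf_registry}; required for
#'   \code{scope = "farmland_only"}
#' @param scope \code{"all_classes"} or \code{"farmland_only"}
#' @param unit_mask optional logical matrix marking cells inside the unit;
#'   when given, the perimeter share lying on the unit boundary is also
#'   reported (so edge density can exclude it)
#' @return List with \code{labels} (integer matrix) and \code{patches}
#'   (data.frame: patch_id, class, area_ha, perimeter_m,
#'   boundary_perimeter_m).
#' @export
delineate_patches <- function(map, registry = NULL,
                              scope = c("all_classes", "farmland_only"),
                              unit_mask = NULL) {
  scope <- match.arg(scope)
  cls <- map$cells
  if (scope == "farmland_only") {
    if (is.null(registry))
      stop("a registry is required for farmland_only scope")
    keep <- registry_codes(registry, role = c("farmland", "off_farm_grazing"))
    cls[!grid_mask(map, keep)] <- 0L
  }
  lab <- label_components(cls)
  nlab <- max(lab)
  if (nlab == 0L) {
    return(list(labels = lab,
                patches = data.frame(patch_id = integer(0),
                                     class = character(0),
                                     area_ha = numeric(0),
                                     perimeter_m = numeric(0),
                                     boundary_perimeter_m = numeric(0))))
  }
  ncell <- tabulate(lab[lab > 0L], nbins = nlab)
  cls_of <- cls[match(seq_len(nlab), lab)]
  per <- patch_perimeters(lab, unit_mask)
  list(labels = lab,
       patches = data.frame(
         patch_id = seq_len(nlab),
         class = map$codes[cls_of],
         area_ha = ncell * cell_area_ha(map),
         perimeter_m = per$total * map$cellsize,
         boundary_perimeter_m = (if (is.null(unit_mask)) 0
                                 else per$boundary) * map$cellsize,
         stringsAsFactors = FALSE))
}

#' Shannon diversity of class area shares
#'
#' \eqn{SDI = -\sum_i p_i \ln p_i} over the positive shares.
#'
#' @param proportions numeric vector of non-negative shares summing to 1
#' @return Non-negative scalar.
#' @export
shannon_diversity <- function(proportions) {
  p <- proportions[proportions > 0]
  if (!length(p)) stop("no classes present")
  if (any(proportions < 0)) stop("shares must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("shares must sum to 1 (got ", format(sum(proportions)), ")")
  -sum(p * log(p))
}

#' Shannon evenness
#'
#' \eqn{SEI = SDI / \ln m} for \eqn{m \ge 2} classes with positive share;
#' a single-class landscape carries no evenness information and is scored 0.
#'
#' @param sdi Shannon diversity
#' @param n_classes number of classes with positive share
#' @return Value in \eqn{[0, 1]}.
#' @export
shannon_evenness <- function(sdi, n_classes) {
  if (n_classes < 1) stop("n_classes must be at least 1")
  if (sdi < 0) stop("sdi must be non-negative")
  if (n_classes == 1) return(0)
  sei <- sdi / log(n_classes)
  if (sei > 1 + 1e-9) stop("evenness above 1: inconsistent sdi / n_classes")
  min(sei, 1)
}

#' Patch-configuration metrics for one landscape unit
#'
#' @param patches patch data.frame from \code{\link{delineate_patches}}
#' @param t_area_ha total unit area (ha), the edge-density denominator
#' @param exclude_unit_boundary drop perimeter segments coincident with the
#'   unit boundary from edge density
#' @param shape_index \code{"vector"}: circle-normalized
#'   \eqn{p / (2\sqrt{\pi a})} (1 for a circle); \code{"raster"}:
#'   \eqn{0.25\, p / \sqrt{a}} (1 for a square)
#' @return Named list: \code{np_p}, \code{msi_p}, \code{ed_p} (m/ha).
#' @export
patch_metrics <- function(patches, t_area_ha, exclude_unit_boundary = FALSE,
                          shape_index = c("vector", "raster")) {
  shape_index <- match.arg(shape_index)
  if (!nrow(patches)) {
    warning("empty patch set; returning zero metrics")
    return(list(np_p = 0L, msi_p = 0, ed_p = 0))
  }
  a_m2 <- patches$area_ha * 1e4
  p_m <- patches$perimeter_m
  si <- if (shape_index == "vector") p_m / (2 * sqrt(pi * a_m2))
        else 0.25 * p_m / sqrt(a_m2)
  ed_per <- if (exclude_unit_boundary)
    p_m - patches$boundary_perimeter_m else p_m
  list(np_p = nrow(patches), msi_p = mean(si),
       ed_p = sum(ed_per) / t_area_ha)
}

#' Landscape Elements metrics for one unit
#'
#' Composes clipping, class-share diversity, patch delineation and
#' configuration metrics. Diversity uses area shares of the classes present
#' in the chosen scope after clipping (shares below 1e-12 dropped).
#'
#' @param map \code{land_grid} land-cover layer (municipality extent)
#' @param zones \code{land_grid} of unit ids
#' @param unit_id unit to evaluate
#' @param registry \code{hnvf_registry}
#' @param scope \code{"all_classes"} or \code{"farmland_only"}
#' @param exclude_unit_boundary see \code{\link{patch_metrics}}
#' @param shape_index see \code{\link{patch_metrics}}
#' @return One-row data.frame: unit_id, scope, sdi_p, sei_p, np_p, msi_p,
#'   ed_p.
#' @export
landscape_elements <- function(map, zones, unit_id, registry,
                               scope = c("all_classes", "farmland_only"),
                               exclude_unit_boundary = FALSE,
                               shape_index = c("vector", "raster")) {
  scope <- match.arg(scope)
  shape_index <- match.arg(shape_index)
  unit_mask <- grid_mask(zones, unit_id)
  t_area_ha <- sum(unit_mask) * cell_area_ha(zones)
  if (t_area_ha <= 0) stop("unit has zero area: ", unit_id)
  clipped <- clip_to_unit(map, zones, unit_id)
  scope_map <- clipped
  if (scope == "farmland_only") {
    keep <- registry_codes(registry, role = c("farmland", "off_farm_grazing"))
    scope_map$cells[!grid_mask(scope_map, keep)] <- 0L
  }
  areas <- class_areas(scope_map)
  areas <- areas[areas > 0]
  if (length(areas)) {
    shares <- areas / sum(areas)
    shares <- shares[shares >= 1e-12]
    sdi <- shannon_diversity(shares / sum(shares))
    sei <- shannon_evenness(sdi, length(shares))
  } else {
    sdi <- 0; sei <- 0
  }
  del <- delineate_patches(clipped, registry, scope, unit_mask = unit_mask)
  pm <- if (nrow(del$patches))
    patch_metrics(del$patches, t_area_ha, exclude_unit_boundary, shape_index)
  else list(np_p = 0L, msi_p = 0, ed_p = 0)
  data.frame(unit_id = unit_id, scope = scope, sdi_p = sdi, sei_p = sei,
             np_p = pm$np_p, msi_p = pm$msi_p, ed_p = pm$ed_p,
             stringsAsFactors = FALSE)
}
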