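# Seeded generator of complete synthetic municipalities: parish tiling,
# land-cover mosaics (seeded multi-class region growing on the lattice),
# natural-constraint blobs, agrarian statistics and species occurrences,
# with planted per-parish HNVf ground truth. The profiles are built to be
# separable under the default thresholds: extensive parishes sit clearly
# below the intensity cuts, intensive ones clearly above the irrigation cut
# with a coarse low-evenness mosaic, diverse mosaics clearly above the
# evenness and edge-density cuts, and forest parishes below farmland
# dominance.

profile_catalogue <- function() {
  list(
    extensive_seminatural = list(
      shares = c(meadow = 0.30, pasture = 0.15, heath = 0.25, arable = 0.05,
                 forest_bl = 0.15, rock = 0.10),
      patch_ha = 2, lsi = c(0.02, 0.15), irrig_pct = c(0, 8),
      crops = c(fodder = 0.45, cereals = 0.25, potato = 0.20, maize = 0.10),
      label = "hnvf1"),
    mosaic_diverse = list(
      shares = c(arable = 0.14, vineyard = 0.14, orchard = 0.12,
                 meadow = 0.12, pasture = 0.10, mosaic = 0.14,
                 forest_bl = 0.12, urban = 0.12),
      patch_ha = 0.8, lsi = c(0.05, 0.15), irrig_pct = c(25, 50),
      crops = c(cereals = 0.2, vineyard = 0.2, orchard = 0.15,
                horticulture = 0.15, potato = 0.15, maize = 0.15),
      label = "hnvf2"),
    intensive = list(
      shares = c(arable = 0.85, vineyard = 0.06, forest_bl = 0.05,
                 urban = 0.04),
      patch_ha = 3, lsi = c(0.05, 0.18), irrig_pct = c(25, 50),
      crops = c(maize = 0.8, cereals = 0.2),
      label = "none"),
    forest_dominated = list(
      shares = c(forest_bl = 0.38, forest_cf = 0.26, meadow = 0.10,
                 heath = 0.10, rock = 0.16),
      patch_ha = 2, lsi = c(0.02, 0.10), irrig_pct = c(0, 5),
      crops = c(fodder = 0.7, potato = 0.3),
      label = "not_applicable"))
}

#' Synthetic-municipality scenario
#'
#' Parameters of a generated municipality: a rows-by-cols tiling of square
#' parishes, a per-parish landscape profile, the lattice resolution, and
#' species-placement settings. The default emulates a mountain municipality
#' with a west-to-east intensity gradient: diverse irrigated mosaics in the
#' west, an intensive belt, a forest-dominated band, and extensive
#' semi-natural parishes in the east.
#'
#' @param rows,cols parish tiling (n_units = rows * cols)
#' @param unit_size_m side of each square parish, metres
#' @param cellsize lattice resolution, metres
#' @param profiles character vector of length rows*cols (column-major, west
#'   to east) with values among \code{extensive_seminatural},
#'   \code{mosaic_diverse}, \code{intensive}, \code{forest_dominated};
#'   NULL selects the default gradient layout
#' @param severe_frac expected share of the territory under severe natural
#'   constraints
#' @param species_bias probability that a plant occurrence is placed in an
#'   extensive parish
#' @param n_plant_species number of indicator plant species
#' @param occ_per_species range (min, max) of occurrence squares per species
#' @param occurrence_size_m side of an occurrence square
#' @param seed integer seed driving every random draw
#' @return List of class \code{hnvf_scenario}.
#' @export
hnvf_scenario <- function(rows = 3, cols = 6, unit_size_m = 800,
                          cellsize = 10, profiles = NULL,
                          severe_frac = 0.1, species_bias = 0.8,
                          n_plant_species = 4, occ_per_species = c(3, 6),
                          occurrence_size_m = 200, seed = 1) {
  n <- rows * cols
  if (is.null(profiles)) {
    band <- function(cl) {
      if (cl <= ceiling(cols / 3)) "mosaic_diverse"
      else if (cl <= ceiling(cols / 2)) "intensive"
      else if (cl <= ceiling(2 * cols / 3)) "forest_dominated"
      else "extensive_seminatural"
    }
    profiles <- unlist(lapply(seq_len(cols),
                              function(cl) rep(band(cl), rows)))
  }
  if (length(profiles) != n)
    stop("profiles must have length rows*cols = ", n)
  bad <- setdiff(profiles, names(profile_catalogue()))
  if (length(bad)) stop("unknown profile(s): ", paste(bad, collapse = ", "))
  unit_ha <- (unit_size_m / 100)^2
  for (p in unique(profiles))
    if (profile_catalogue()[[p]]$patch_ha > unit_ha)
      stop("mean patch size exceeds the parish area for profile ", p)
  if (unit_size_m %% cellsize != 0)
    stop("unit_size_m must be a multiple of cellsize")
  structure(list(rows = rows, cols = cols, unit_size_m = unit_size_m,
                 cellsize = cellsize, profiles = profiles,
                 severe_frac = severe_frac, species_bias = species_bias,
                 n_plant_species = n_plant_species,
                 occ_per_species = occ_per_species,
                 occurrence_size_m = occurrence_size_m, seed = seed),
            class = "hnvf_scenario")
}

# Seeded region growing in one parish block: Voronoi growth around class
# seeds with multiplicative distance noise, giving irregular contiguous
# patches at the requested mean size. Seed classes are allocated to the
# target shares by largest remainder (not drawn), so realized class shares
# track the profile without multinomial noise.
grow_mosaic <- function(ny, nx, shares, n_seeds) {
  classes <- names(shares)
  shares <- shares / sum(shares)
  n_k <- floor(shares * n_seeds)
  short <- n_seeds - sum(n_k)
  if (short > 0) {
    rem <- shares * n_seeds - n_k
    n_k[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      n_k[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
  }
  n_k[n_k == 0L] <- 1L   # every class present
  seed_class <- sample(rep(classes, n_k))
  n_seeds <- length(seed_class)
  pos <- sample(ny * nx, n_seeds)
  sr <- (pos - 1L) %% ny + 1L
  sc <- (pos - 1L) %/% ny + 1L
  ri <- rep(seq_len(ny), nx)
  ci <- rep(seq_len(nx), each = ny)
  d2 <- outer(ri, sr, "-")^2 + outer(ci, sc, "-")^2
  d2 <- d2 * matrix(stats::runif(length(d2), 1, 1.6), nrow(d2))
  win <- max.col(-d2, ties.method = "first")
  matrix(seed_class[win], ny, nx)
}

#' Generate a synthetic municipality
#'
#' Builds all pipeline inputs from a scenario: the land-cover lattice, the
#' parish zone lattice, a natural-constraints lattice, per-parish agrarian
#' statistics consistent with each profile's intensity ranges, species
#' occurrences biased towards extensive parishes plus one IBA polygon over
#' an extensive parish, and the planted truth labels. Fully deterministic
#' for a fixed scenario (seed included); the caller's RNG state is
#' preserved.
#'
#' @param scenario an \code{hnvf_scenario}
#' @return List: \code{landcover}, \code{zones}, \code{units} (unit_id,
#'   name), \code{constraints}, \code{agrarian}, \code{species},
#'   \code{truth} (unit_id, profile, label), \code{registry},
#'   \code{scenario}.
#' @export
generate_municipality <- function(scenario) {
  stopifnot(inherits(scenario, "hnvf_scenario"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(scenario$seed)
  reg <- default_registry()
  cat_ <- profile_catalogue()
  cs <- scenario$cellsize
  ucell <- scenario$unit_size_m / cs
  ny <- scenario$rows * ucell
  nx <- scenario$cols * ucell
  crs <- "synthetic-metric"
  cells <- matrix(0L, ny, nx)
  zcells <- matrix(0L, ny, nx)
  unit_ids <- character(0)
  truth <- NULL
  k <- 0L
  unit_ha <- (scenario$unit_size_m / 100)^2
  for (cl in seq_len(scenario$cols)) for (rw in seq_len(scenario$rows)) {
    k <- k + 1L
    uid <- sprintf("P%02d", k)
    unit_ids <- c(unit_ids, uid)
    prof_name <- scenario$profiles[k]
    prof <- cat_[[prof_name]]
    rs <- (rw - 1L) * ucell + 1L; re <- rw * ucell
    csx <- (cl - 1L) * ucell + 1L; ce <- cl * ucell
    n_seeds <- max(length(prof$shares), round(unit_ha / prof$patch_ha))
    mosaic <- grow_mosaic(ucell, ucell, prof$shares, n_seeds)
    cells[rs:re, csx:ce] <- match(mosaic, reg$code)
    zcells[rs:re, csx:ce] <- k
    truth <- rbind(truth, data.frame(unit_id = uid, profile = prof_name,
                                     label = prof$label,
                                     stringsAsFactors = FALSE))
  }
  landcover <- land_grid(cells, reg$code, cs, c(0, 0), crs)
  zones <- land_grid(zcells, unit_ids, cs, c(0, 0), crs)

  # natural constraints: Voronoi blobs, generated on a coarser lattice
  # (4-cell granularity) and expanded -- constraint maps are coarse layers
  lim_lv <- c("none", "moderate", "severe")
  pr <- c(1 - scenario$severe_frac - 0.3, 0.3, scenario$severe_frac)
  f <- 4L
  cny <- ceiling(ny / f); cnx <- ceiling(nx / f)
  n_blob <- max(6L, round(cny * cnx * (f * cs / 100)^2 / 20))
  blob <- grow_mosaic(cny, cnx, stats::setNames(pr, lim_lv), n_blob)
  fine <- kronecker(matrix(match(blob, lim_lv), cny, cnx),
                    matrix(1L, f, f))[seq_len(ny), seq_len(nx)]
  constraints <- land_grid(fine, lim_lv, cs, c(0, 0), crs)

  # agrarian statistics per parish, matched to realized UAA
  ua <- compute_uaa(landcover, zones, reg, constraints)
  agr <- NULL
  crop_types <- c("fodder", "cereals", "maize", "potato", "vineyard",
                  "orchard", "horticulture")
  for (i in seq_len(nrow(truth))) {
    prof <- cat_[[truth$profile[i]]]
    uaa <- ua$units$uaa_ha[match(truth$unit_id[i], ua$units$unit_id)]
    lsi <- stats::runif(1, prof$lsi[1], prof$lsi[2])
    lsu_total <- lsi * uaa
    cattle <- floor(0.6 * lsu_total / 1.0)
    sheep <- round((lsu_total - cattle * 1.0) / 0.1)
    irrig_pct <- stats::runif(1, prof$irrig_pct[1], prof$irrig_pct[2])
    crops <- stats::setNames(numeric(length(crop_types)), crop_types)
    w <- prof$crops * stats::runif(length(prof$crops), 0.8, 1.2)
    crops[names(prof$crops)] <- 0.5 * uaa * w / sum(w)
    row <- data.frame(unit_id = truth$unit_id[i],
                      livestock_dairy_cows = cattle,
                      livestock_sheep = sheep,
                      irrigated_ha = round(irrig_pct / 100 * uaa, 2))
    for (ct in crop_types) row[[paste0("crop_", ct)]] <- round(crops[ct], 2)
    agr <- rbind(agr, row)
  }
  class(agr) <- c("agrarian_table", "data.frame")

  # species occurrences: plant grid squares biased to extensive parishes,
  # plus one IBA polygon covering an extensive parish (or the first parish
  # if no extensive profile is present)
  species <- list()
  ext_units <- which(truth$profile == "extensive_seminatural")
  half <- scenario$occurrence_size_m / 2
  place_in <- function(unit_idx) {
    rw <- (unit_idx - 1L) %% scenario$rows + 1L
    cl <- (unit_idx - 1L) %/% scenario$rows + 1L
    x0 <- (cl - 1L) * scenario$unit_size_m
    y0 <- (scenario$rows - rw) * scenario$unit_size_m
    cx <- stats::runif(1, x0 + half, x0 + scenario$unit_size_m - half)
    cy <- stats::runif(1, y0 + half, y0 + scenario$unit_size_m - half)
    # snap to the lattice so occurrence areas are exact
    cx <- round(cx / cs) * cs; cy <- round(cy / cs) * cs
    list(matrix(c(cx - half, cy - half, cx + half, cy - half,
                  cx + half, cy + half, cx - half, cy + half,
                  cx - half, cy - half), ncol = 2, byrow = TRUE))
  }
  for (s in seq_len(scenario$n_plant_species)) {
    n_occ <- sample(scenario$occ_per_species[1]:scenario$occ_per_species[2], 1)
    for (o in seq_len(n_occ)) {
      biased <- length(ext_units) &&
        stats::runif(1) < scenario$species_bias
      u <- if (biased) sample(ext_units, 1)
           else sample(nrow(truth), 1)
      species[[length(species) + 1L]] <-
        list(props = list(species_id = sprintf("plant_%02d", s),
                          kind = "plant_grid"),
             rings = place_in(u))
    }
  }
  iba_unit <- if (length(ext_units)) ext_units[1] else 1L
  rw <- (iba_unit - 1L) %% scenario$rows + 1L
  cl <- (iba_unit - 1L) %/% scenario$rows + 1L
  x0 <- (cl - 1L) * scenario$unit_size_m
  y0 <- (scenario$rows - rw) * scenario$unit_size_m
  s <- scenario$unit_size_m
  species[[length(species) + 1L]] <-
    list(props = list(species_id = "iba_01", kind = "iba_polygon"),
         rings = list(matrix(c(x0, y0, x0 + s, y0, x0 + s, y0 + s,
                               x0, y0 + s, x0, y0), ncol = 2, byrow = TRUE)))

  list(landcover = landcover, zones = zones,
       units = data.frame(unit_id = unit_ids, name = unit_ids,
                          stringsAsFactors = FALSE),
       constraints = constraints, agrarian = agr, species = species,
       truth = truth, registry = reg, scenario = scenario)
}

#' Write a generated municipality to disk
#'
#' Writes every input in the formats the loaders read: GeoJSON layers for
#' land cover, parish boundaries, constraints and species occurrences, the
#' agrarian CSV, the registry YAML, the truth labels CSV, and a scenario
#' JSON recording the lattice and the seed.
#'
#' @param gen output of \code{\link{generate_municipality}}
#' @param dir output directory (created if absent)
#' @return \code{dir}, invisibly.
#' @export
write_scenario <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  crs <- gen$landcover$crs
  write_geojson(grid_to_features(gen$landcover, "class"),
                file.path(dir, "landcover.geojson"), crs)
  write_geojson(grid_to_features(gen$zones, "unit_id"),
                file.path(dir, "units.geojson"), crs)
  write_geojson(grid_to_features(gen$constraints, "limitation"),
                file.path(dir, "constraints.geojson"), crs)
  write_geojson(gen$species, file.path(dir, "species.geojson"), crs)
  utils::write.csv(gen$agrarian, file.path(dir, "agrarian.csv"),
                   row.names = FALSE)
  utils::write.csv(gen$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write_registry(gen$registry, file.path(dir, "registry.yaml"))
  g <- gen$landcover
  jsonlite::write_json(list(cellsize = g$cellsize, origin = g$origin,
                            nx = ncol(g$cells), ny = nrow(g$cells),
                            crs = crs, seed = gen$scenario$seed),
                       file.path(dir, "scenario.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a municipality written by \code{\link{write_scenario}}
#'
#' @param dir directory holding the layer files
#' @return List shaped like the output of \code{\link{generate_municipality}}
#'   (without \code{scenario}; \code{truth} only if present).
#' @export
load_scenario <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "scenario.json"))
  tpl <- grid_template(meta$nx, meta$ny, meta$cellsize, meta$origin,
                       crs = meta$crs)
  registry <- read_registry(file.path(dir, "registry.yaml"))
  landcover <- load_landcover(file.path(dir, "landcover.geojson"), registry,
                              template = tpl)
  un <- load_units(file.path(dir, "units.geojson"), template = tpl)
  constraints <- load_constraints(file.path(dir, "constraints.geojson"), tpl)
  species <- load_species(file.path(dir, "species.geojson"))
  agr <- load_agrarian(file.path(dir, "agrarian.csv"))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  list(landcover = landcover, zones = un$zones,
       units = un$units[, c("unit_id", "name")], constraints = constraints,
       agrarian = agr, species = species, truth = truth, registry = registry)
}

#' Predicted HNVf label per unit from a pipeline run
#'
#' Units failing the dominance screen are \code{not_applicable}; otherwise
#' type-1 membership takes precedence over type-2; units passing neither
#' screen are \code{none}.
#'
#' @param run an \code{hnvf_run}
#' @return data.frame: unit_id, predicted.
#' @export
predict_labels <- function(run) {
  u <- run$units
  data.frame(unit_id = u$unit_id,
             predicted = ifelse(!u$eligible, "not_applicable",
                         ifelse(u$hnvf1, "hnvf1",
                         ifelse(u$hnvf2, "hnvf2", "none"))),
             stringsAsFactors = FALSE)
}

#' Planted-label recovery experiment
#'
#' Generates \code{n_seeds} municipalities (seeds \code{seed_start} onward),
#' runs the full pipeline with the given thresholds on each, and scores the
#' fraction of units whose predicted label equals the planted truth.
#'
#' @param n_seeds number of municipalities
#' @param scenario template scenario (its seed is replaced per run)
#' @param thresholds \code{hnvf_thresholds}
#' @param seed_start first seed
#' @return List: \code{accuracy} (overall fraction), \code{n_units},
#'   \code{per_seed} (data.frame seed, n_correct, n_units).
#' @export
recovery_experiment <- function(n_seeds = 100, scenario = hnvf_scenario(),
                                thresholds = hnvf_thresholds(),
                                seed_start = 1) {
  per <- NULL
  for (s in seq.int(seed_start, length.out = n_seeds)) {
    sc <- scenario
    sc$seed <- s
    gen <- generate_municipality(sc)
    run <- run_pipeline(gen$landcover, gen$zones, gen$registry, gen$agrarian,
                        constraints = gen$constraints,
                        thresholds = thresholds, seed = s)
    pred <- predict_labels(run)
    ok <- pred$predicted == gen$truth$label[match(pred$unit_id,
                                                 gen$truth$unit_id)]
    per <- rbind(per, data.frame(seed = s, n_correct = sum(ok),
                                 n_units = length(ok)))
  }
  list(accuracy = sum(per$n_correct) / sum(per$n_units),
       n_units = sum(per$n_units), per_seed = per)
}
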