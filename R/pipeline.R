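# The four-step HNVf framework: (1) UAA determination, farmland-dominance
# screening and minimum-maximum candidate mapping; (2) threshold cascades
# refining HNVf types 1 and 2; (3) indicator-species overlay and optional
# type-3 designation; (4) assembly, area accounting and trend comparison.

# Per-unit hectares of a municipality mask.
zone_areas <- function(mask, zones) {
  n <- tabulate(zones$cells[mask], nbins = length(zones$codes))
  stats::setNames(n * cell_area_ha(zones), zones$codes)
}

#' Utilized agricultural area with natural-constraint masking
#'
#' The UAA combines farmland-role classes with off-farm grazing classes
#' (e.g. grazed heathland commons), the latter restricted to areas whose
#' natural-constraint limitation is \code{none} or \code{moderate}: severely
#' constrained grazing land is excluded.
#'
#' @param map land-cover \code{land_grid}
#' @param zones unit-id \code{land_grid} on the same lattice
#' @param registry \code{hnvf_registry}
#' @param constraints optional limitation \code{land_grid}
#'   (codes none/moderate/severe); when absent no constraint masking applies
#' @param unit_names optional data.frame (unit_id, name)
#' @return List: \code{units} (data.frame unit_id, name, t_area_ha, uaa_ha,
#'   p_uaa_pct, p_forest_pct) and \code{uaa_mask} (logical matrix).
#' @export
compute_uaa <- function(map, zones, registry, constraints = NULL,
                        unit_names = NULL) {
  farm_codes <- registry_codes(registry, role = "farmland")
  if (!length(farm_codes))
    stop("registry defines no farmland-role classes")
  off_codes <- registry_codes(registry, role = "off_farm_grazing")
  forest_codes <- registry_codes(registry, role = "forest")
  farm <- grid_mask(map, farm_codes)
  off <- grid_mask(map, off_codes)
  if (!is.null(constraints)) {
    stopifnot(identical(dim(constraints$cells), dim(map$cells)))
    ok <- grid_mask(constraints, c("none", "moderate"))
    off <- off & ok
  }
  uaa_mask <- farm | off
  units <- unit_table(zones, unit_names)
  uaa <- zone_areas(uaa_mask, zones)
  forest <- zone_areas(grid_mask(map, forest_codes), zones)
  units$uaa_ha <- as.numeric(uaa[units$unit_id])
  units$p_uaa_pct <- 100 * units$uaa_ha / units$t_area_ha
  units$p_forest_pct <- 100 * as.numeric(forest[units$unit_id]) /
    units$t_area_ha
  list(units = units, uaa_mask = uaa_mask)
}

#' Farmland-dominance screening
#'
#' Units whose UAA share reaches the dominance threshold are retained for
#' HNVf assessment; the rest are flagged not applicable downstream.
#'
#' @param units data.frame with \code{p_uaa_pct}
#' @param thresholds \code{hnvf_thresholds}
#' @return \code{units} with a logical \code{eligible} column.
#' @export
dominance_screen <- function(units, thresholds = hnvf_thresholds()) {
  units$eligible <- units$p_uaa_pct >= thresholds$uaa_dominance_pct
  units
}

#' Minimum-maximum HNVf candidate envelopes
#'
#' Within the UAA, classes with minimum HNVf likelihood delimit the minimum
#' candidate extent (farmland almost certainly of high nature value); adding
#' the maximum-only classes gives the maximum extent. The minimum is by
#' construction contained in the maximum.
#'
#' @param map land-cover \code{land_grid}
#' @param zones unit-id \code{land_grid}
#' @param registry \code{hnvf_registry}
#' @param uaa_mask logical matrix from \code{\link{compute_uaa}}
#' @return List: \code{min_mask}, \code{max_mask}, and \code{areas}
#'   (data.frame unit_id, phnvf_min_ha, phnvf_max_ha).
#' @export
min_max_candidates <- function(map, zones, registry, uaa_mask) {
  min_mask <- uaa_mask & grid_mask(map, registry_codes(registry,
                                                       likelihood = "minimum"))
  max_mask <- min_mask |
    (uaa_mask & grid_mask(map, registry_codes(registry,
                                              likelihood = "maximum_only")))
  a_min <- zone_areas(min_mask, zones)
  a_max <- zone_areas(max_mask, zones)
  list(min_mask = min_mask, max_mask = max_mask,
       areas = data.frame(unit_id = zones$codes,
                          phnvf_min_ha = as.numeric(a_min),
                          phnvf_max_ha = as.numeric(a_max),
                          stringsAsFactors = FALSE))
}

check_indicator <- function(ind, units_sel, col) {
  i <- match(units_sel, ind$unit_id)
  v <- ind[[col]][i]
  bad <- units_sel[is.na(i) | is.na(v)]
  if (length(bad))
    stop("missing indicator '", col, "' for eligible unit(s): ",
         paste(bad, collapse = ", "))
  stats::setNames(v, units_sel)
}

#' HNVf type-1 selection (extensive-practice screen)
#'
#' A farmland-dominant unit is HNVf-1 when its livestock density and
#' irrigation share both stay at or below their thresholds; its HNVf-1
#' extent is its minimum candidate extent.
#'
#' @param units data.frame with \code{eligible}
#' @param indicators per-unit indicator table (needs lsi_p, irrig_p)
#' @param thresholds \code{hnvf_thresholds}
#' @return Character vector of selected unit ids.
#' @export
select_hnvf1 <- function(units, indicators, thresholds = hnvf_thresholds()) {
  el <- units$unit_id[units$eligible]
  if (!length(el)) return(character(0))
  lsi <- check_indicator(indicators, el, "lsi_p")
  irr <- check_indicator(indicators, el, "irrig_p")
  el[lsi <= thresholds$lsi_max & irr <= thresholds$irrig_max_pct]
}

#' HNVf type-2 selection (mosaic-structure screen)
#'
#' A unit qualifies as HNVf-2 when its land-cover Shannon evenness and edge
#' density both reach their thresholds, indicating a fine-grained diverse
#' mosaic. Crop-diversity indicators act as confirmation by default: units
#' whose crop Shannon diversity ranks in the bottom tercile of the eligible
#' set are flagged \code{cd_low} (and excluded only under \code{cd_strict}).
#' Missing evenness or edge-density values exclude a unit.
#'
#' @param units data.frame with \code{eligible}
#' @param indicators per-unit indicator table (needs sei_p, ed_p, sdi_c)
#' @param thresholds \code{hnvf_thresholds}
#' @param hnvf1_selected unit ids selected as HNVf-1 (used when
#'   \code{hnvf2_all_eligible} is FALSE: only units failing the intensity
#'   screen are considered)
#' @return List: \code{selected} (unit ids) and \code{cd_low} (unit ids
#'   flagged by the crop-diversity confirmation).
#' @export
select_hnvf2 <- function(units, indicators, thresholds = hnvf_thresholds(),
                         hnvf1_selected = character(0)) {
  el <- units$unit_id[units$eligible]
  if (!length(el)) return(list(selected = character(0), cd_low = character(0)))
  pool <- if (thresholds$hnvf2_all_eligible) el else setdiff(el, hnvf1_selected)
  i <- match(pool, indicators$unit_id)
  sei <- indicators$sei_p[i]
  ed <- indicators$ed_p[i]
  pass <- !is.na(sei) & !is.na(ed) &
    sei >= thresholds$sei_min & ed >= thresholds$ed_min
  selected <- pool[pass]
  cd_low <- character(0)
  if (thresholds$cd_confirmation || thresholds$cd_strict) {
    sdi_c <- indicators$sdi_c[match(el, indicators$unit_id)]
    if (!all(is.na(sdi_c))) {
      cut <- stats::quantile(sdi_c, 1 / 3, na.rm = TRUE, names = FALSE)
      cd_low <- el[!is.na(sdi_c) & sdi_c <= cut]
    }
    if (thresholds$cd_strict) selected <- setdiff(selected, cd_low)
  }
  list(selected = selected, cd_low = cd_low)
}

trend_label <- function(refined, candidate, eligible, tol) {
  ifelse(!eligible, "not_applicable",
         ifelse(refined < candidate - tol, "decrease",
                ifelse(refined > candidate + tol, "increase", "unchanged")))
}

#' Assemble the HNVf account
#'
#' Combines candidate envelopes with the refined type extents into the
#' per-unit area account, labels the candidate-versus-refined trend for
#' types 1 and 2 (at the reporting tolerance), and sums municipality totals.
#'
#' @param units data.frame with eligibility and candidate areas
#'   (phnvf_min_ha, phnvf_max_ha)
#' @param hnvf1_selected,hnvf2_selected unit-id vectors from the cascades
#' @param hnvf3_ha optional named vector of per-unit type-3 areas (ha)
#' @param thresholds \code{hnvf_thresholds} (trend tolerance)
#' @return \code{units} extended with hnvf1/2 flags, per-type areas, trends;
#'   attribute \code{totals} holds the municipality sums.
#' @export
assemble_hnvf <- function(units, hnvf1_selected, hnvf2_selected,
                          hnvf3_ha = NULL,
                          thresholds = hnvf_thresholds()) {
  u <- units
  u$hnvf1 <- u$unit_id %in% hnvf1_selected & u$eligible
  u$hnvf2 <- u$unit_id %in% hnvf2_selected & u$eligible
  u$hnvf1_ha <- ifelse(u$hnvf1, u$phnvf_min_ha, 0)
  u$hnvf2_ha <- ifelse(u$hnvf2, u$phnvf_max_ha - u$phnvf_min_ha, 0)
  u$hnvf3_ha <- if (is.null(hnvf3_ha)) numeric(nrow(u)) else
    ifelse(is.na(hnvf3_ha[u$unit_id]), 0, hnvf3_ha[u$unit_id])
  tol <- thresholds$trend_tol_ha
  u$trend1 <- trend_label(u$hnvf1_ha, u$phnvf_min_ha, u$eligible, tol)
  u$trend2 <- trend_label(u$hnvf2_ha, u$phnvf_max_ha - u$phnvf_min_ha,
                          u$eligible, tol)
  el <- u$eligible
  totals <- list(
    phnvf_min_ha = round(sum(u$phnvf_min_ha[el]), 2),
    phnvf_max_ha = round(sum(u$phnvf_max_ha[el]), 2),
    hnvf1_ha = round(sum(u$hnvf1_ha), 2),
    hnvf2_ha = round(sum(u$hnvf2_ha), 2),
    hnvf3_ha = round(sum(u$hnvf3_ha), 2),
    hnvf_total_ha = round(sum(u$hnvf1_ha + u$hnvf2_ha + u$hnvf3_ha), 2))
  attr(u, "totals") <- totals
  u
}

#' Run the full four-step HNVf pipeline
#'
#' Executes UAA determination and dominance screening, landscape metrics and
#' intensity/crop indicators with Kendall redundancy screening, the min-max
#' candidate mapping, the type-1/2 threshold cascades, the species overlay
#' with optional type-3 designation, and the final assembly. Deterministic
#' for fixed inputs and configuration.
#'
#' @param landcover land-cover \code{land_grid}
#' @param zones unit-id \code{land_grid} on the same lattice
#' @param registry \code{hnvf_registry}
#' @param agrarian an \code{agrarian_table}
#' @param constraints optional limitation \code{land_grid}
#' @param species optional list of occurrence features (see
#'   \code{\link{load_species}})
#' @param thresholds \code{hnvf_thresholds}
#' @param coefficients LSU coefficients
#' @param unit_names optional data.frame (unit_id, name)
#' @param designate_type3 if TRUE (default) species-supported UAA outside the
#'   mapped type-1/2 extent is designated HNVf-3; if FALSE only coincidence
#'   is reported
#' @param seed optional integer recorded in the manifest (the pipeline itself
#'   draws no random numbers)
#' @return An object of class \code{hnvf_run}: list with \code{units} (the
#'   area account), \code{indicators}, \code{tau}, \code{retained_indicators},
#'   \code{coincidence}, \code{masks}, \code{grid}, \code{totals},
#'   \code{thresholds}, \code{manifest}.
#' @export
run_pipeline <- function(landcover, zones, registry, agrarian,
                         constraints = NULL, species = NULL,
                         thresholds = hnvf_thresholds(),
                         coefficients = eurostat_lsu_coefficients(),
                         unit_names = NULL, designate_type3 = TRUE,
                         seed = NULL) {
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # Step 1: UAA, dominance, candidate envelopes
  ua <- step("uaa", compute_uaa(landcover, zones, registry, constraints,
                                unit_names))
  units <- step("dominance_screen", dominance_screen(ua$units, thresholds))
  cand <- step("min_max_candidates",
               min_max_candidates(landcover, zones, registry, ua$uaa_mask))
  units <- merge(units, cand$areas, by = "unit_id", sort = FALSE)
  units <- units[match(zones$codes, units$unit_id), ]

  # Step 2: indicators for eligible units, redundancy screen, cascades
  eligible <- units$unit_id[units$eligible]
  le <- step("landscape_elements", do.call(rbind, lapply(eligible, function(uid)
    landscape_elements(landcover, zones, uid, registry,
                       scope = thresholds$metric_scope,
                       exclude_unit_boundary = thresholds$exclude_unit_boundary))))
  ind <- step("indicators", indicator_table(le, agrarian, units, coefficients))
  screen <- if (length(eligible) >= 3)
    step("kendall_screen", kendall_screen(ind, thresholds$tau_max))
  else list(retained = indicator_priority(), dropped = character(0),
            tau = NULL)
  sel1 <- step("select_hnvf1", select_hnvf1(units, ind, thresholds))
  sel2 <- step("select_hnvf2",
               select_hnvf2(units, ind, thresholds, hnvf1_selected = sel1))

  sel_mask <- function(ids, base_mask) {
    if (!length(ids)) return(base_mask & FALSE)
    base_mask & grid_mask(zones, ids)
  }
  hnvf1_mask <- sel_mask(sel1, cand$min_mask)
  hnvf2_mask <- sel_mask(sel2$selected, cand$max_mask & !cand$min_mask)

  # Step 3: species overlay
  coincidence <- NULL
  hnvf3_mask <- hnvf1_mask & FALSE
  hnvf3_ha <- NULL
  if (!is.null(species) && length(species)) {
    occ <- step("species_overlay", occurrence_masks(species, zones))
    coincidence <- step("species_overlay",
                        species_coincidence(species, occ,
                                            list(hnvf1 = hnvf1_mask,
                                                 hnvf2 = hnvf2_mask)))
    if (designate_type3) {
      hnvf3_mask <- step("designate_hnvf3",
                         designate_hnvf3(occ, hnvf1_mask | hnvf2_mask,
                                         ua$uaa_mask))
      hnvf3_ha <- zone_areas(hnvf3_mask, zones)
    }
  }

  # Step 4: assembly and accounting
  units <- step("assemble",
                assemble_hnvf(units, sel1, sel2$selected, hnvf3_ha,
                              thresholds))
  units$cd_low <- units$unit_id %in% sel2$cd_low
  totals <- attr(units, "totals")
  manifest <- list(
    package = "hnvfmap",
    version = as.character(utils::packageVersion("hnvfmap")),
    seed = seed,
    thresholds = unclass(thresholds),
    lsu_coefficients = as.list(coefficients),
    n_units = nrow(units), n_eligible = sum(units$eligible),
    hnvf1_selected = sel1, hnvf2_selected = sel2$selected,
    cd_low_flagged = sel2$cd_low,
    retained_indicators = screen$retained,
    dropped_indicators = screen$dropped,
    totals = totals)
  structure(list(units = units, indicators = ind, tau = screen$tau,
                 retained_indicators = screen$retained,
                 coincidence = coincidence,
                 masks = list(uaa = ua$uaa_mask, phnvf_min = cand$min_mask,
                              phnvf_max = cand$max_mask, hnvf1 = hnvf1_mask,
                              hnvf2 = hnvf2_mask, hnvf3 = hnvf3_mask),
                 grid = landcover, zones = zones, totals = totals,
                 thresholds = thresholds, manifest = manifest),
            class = "hnvf_run")
}

#' @export
print.hnvf_run <- function(x, ...) {
  t <- x$totals
  cat("<hnvf_run> ", nrow(x$units), " units, ",
      sum(x$units$eligible), " farmland-dominant\n", sep = "")
  cat(sprintf("  candidate envelope: %.2f - %.2f ha\n",
              t$phnvf_min_ha, t$phnvf_max_ha))
  cat(sprintf("  HNVf-1 %.2f ha | HNVf-2 %.2f ha | HNVf-3 %.2f ha | total %.2f ha\n",
              t$hnvf1_ha, t$hnvf2_ha, t$hnvf3_ha, t$hnvf_total_ha))
  invisible(x)
}
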