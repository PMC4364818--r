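# Step 3: coincidence of indicator-species occurrences (plant grid squares,
# IBA polygons) with the mapped HNVf extent, and designation of
# complementary type-3 areas.

#' Species-occurrence coincidence with HNVf extents
#'
#' An occurrence is partially within a type when it overlaps that type's
#' extent with positive area, and completely within when its whole footprint
#' (within the analysis lattice) is covered by it. Complete containment
#' implies partial containment.
#'
#' @param occurrences list of occurrence features (props: species_id, kind)
#' @param masks list of per-occurrence logical matrices
#'   (\code{\link{occurrence_masks}})
#' @param type_masks named list of logical extent matrices (e.g. hnvf1,
#'   hnvf2)
#' @return data.frame: species_id, kind, n_total, then per type
#'   n_partial_<type> and n_complete_<type>.
#' @export
species_coincidence <- function(occurrences, masks, type_masks) {
  sp <- vapply(occurrences, function(f) f$props$species_id, character(1))
  kind <- vapply(occurrences, function(f) f$props$kind, character(1))
  out <- data.frame(species_id = unique(sp), stringsAsFactors = FALSE)
  out$kind <- kind[match(out$species_id, sp)]
  out$n_total <- as.integer(table(sp)[out$species_id])
  for (ty in names(type_masks)) {
    tm <- type_masks[[ty]]
    partial <- vapply(masks, function(m) any(m & tm), logical(1))
    complete <- vapply(masks, function(m) any(m) && all(tm[m]), logical(1))
    out[[paste0("n_partial_", ty)]] <-
      as.integer(tapply(partial, sp, sum)[out$species_id])
    out[[paste0("n_complete_", ty)]] <-
      as.integer(tapply(complete, sp, sum)[out$species_id])
  }
  rownames(out) <- NULL
  out
}

#' Designate complementary HNVf-3 areas
#'
#' Farmland supporting species of conservation concern that the intensity
#' and structure screens did not capture: the union of occurrence and IBA
#' footprints, intersected with the UAA, minus the mapped type-1/2 extent.
#' Empty when every species record already coincides with mapped HNVf.
#'
#' @param masks list of per-occurrence logical matrices (plants and IBAs)
#' @param hnvf12_mask logical matrix, union of the type-1 and type-2 extents
#' @param uaa_mask logical matrix of the utilized agricultural area
#' @return Logical matrix: the HNVf-3 extent.
#' @export
designate_hnvf3 <- function(masks, hnvf12_mask, uaa_mask) {
  occ_union <- Reduce(`|`, masks, init = hnvf12_mask & FALSE)
  occ_union & uaa_mask & !hnvf12_mask
}
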