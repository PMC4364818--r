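# Extensive Practices and Crop Diversity indicators, and redundancy
# screening of the indicator set by Kendall's tau-b.

#' Livestock density (LSU per hectare of UAA)
#'
#' Aggregates a herd into livestock units via per-category coefficients and
#' divides by the unit's utilized agricultural area. Low values indicate
#' grazing systems relying on semi-natural forage.
#'
#' @param livestock named numeric vector of head counts by animal category
#' @param coefficients named numeric vector, LSU per head (default Eurostat
#'   standard coefficients)
#' @param uaa_ha utilized agricultural area of the unit (ha), must be > 0
#' @return LSU/ha of UAA.
#' @export
livestock_density <- function(livestock,
                              coefficients = eurostat_lsu_coefficients(),
                              uaa_ha) {
  if (uaa_ha <= 0) stop("no utilized agricultural area")
  if (!length(livestock)) return(0)
  if (any(livestock < 0)) stop("head counts must be non-negative")
  k <- coefficients[names(livestock)]
  if (anyNA(k))
    stop("no LSU coefficient for categor",
         if (sum(is.na(k)) > 1) "ies: " else "y: ",
         paste(names(livestock)[is.na(k)], collapse = ", "))
  sum(livestock * k) / uaa_ha
}

#' Irrigation share of the UAA
#'
#' @param irrigated_ha irrigated area (ha)
#' @param uaa_ha utilized agricultural area (ha), must be > 0
#' @param cap if TRUE (default) an irrigated area exceeding the UAA is capped
#'   at 100 \% with a warning; if FALSE it is an error
#' @return Percentage of UAA, in \eqn{[0, 100]} when \code{cap}.
#' @export
irrigation_share <- function(irrigated_ha, uaa_ha, cap = TRUE) {
  if (uaa_ha <= 0) stop("no utilized agricultural area")
  if (irrigated_ha < 0) stop("irrigated area must be non-negative")
  if (irrigated_ha > uaa_ha) {
    if (!cap) stop("irrigated area exceeds UAA")
    warning("irrigated area exceeds UAA; capped at 100%")
    irrigated_ha <- uaa_ha
  }
  100 * irrigated_ha / uaa_ha
}

#' Crop-diversity indicators
#'
#' Shannon diversity and evenness over crop-area shares, and crop richness
#' (number of crop types with positive area).
#'
#' @param crops named numeric vector of cultivated areas (ha) by crop type
#' @return List: \code{sdi_c}, \code{sei_c}, \code{scrop_p}.
#' @export
crop_diversity <- function(crops) {
  if (any(crops < 0)) stop("crop areas must be non-negative")
  pos <- crops[crops > 0]
  if (!length(pos)) {
    warning("all-zero crop table")
    return(list(sdi_c = 0, sei_c = 0, scrop_p = 0L))
  }
  p <- pos / sum(pos)
  sdi <- shannon_diversity(p)
  list(sdi_c = sdi, sei_c = shannon_evenness(sdi, length(pos)),
       scrop_p = length(pos))
}

#' Default ecological-priority order of the indicator columns
#'
#' Extensive Practices before Landscape Elements before Crop Diversity;
#' within each set, table order. Used to decide which member of a correlated
#' pair the redundancy screen drops.
#'
#' @return Character vector of indicator column names.
#' @export
indicator_priority <- function() {
  c("lsi_p", "irrig_p", "sdi_p", "sei_p", "np_p", "msi_p", "ed_p",
    "sdi_c", "sei_c", "scrop_p")
}

#' Redundancy screening of an indicator table by Kendall's tau-b
#'
#' Computes the pairwise tie-corrected Kendall correlation across units and
#' drops, for every pair with \eqn{|\tau| \ge} \code{tau_max}, the indicator
#' later in the priority order. Anti-correlation is treated as equally
#' redundant (the rule applies to \eqn{|\tau|}). Constant columns have no
#' defined rank correlation; they are reported as NA and retained with a
#' warning.
#'
#' @param table data.frame of indicator values, one row per unit (non-indicator
#'   columns such as \code{unit_id} are ignored)
#' @param tau_max redundancy threshold on \eqn{|\tau|}
#' @param priority ordered character vector covering all indicator columns
#' @return List: \code{retained} (character, in priority order),
#'   \code{dropped}, \code{tau} (symmetric matrix with unit diagonal).
#' @export
kendall_screen <- function(table, tau_max = 0.7,
                           priority = indicator_priority()) {
  cols <- intersect(priority, names(table))
  extra <- setdiff(setdiff(names(table), c("unit_id", "name", "scope")),
                   priority)
  if (length(extra))
    stop("priority list does not cover indicator column(s): ",
         paste(extra, collapse = ", "))
  if (nrow(table) < 3) stop("at least 3 units are required for screening")
  x <- as.matrix(table[, cols, drop = FALSE])
  m <- length(cols)
  tau <- matrix(NA_real_, m, m, dimnames = list(cols, cols))
  constant <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(constant))
    warning("constant indicator column(s) retained, tau undefined: ",
            paste(cols[constant], collapse = ", "))
  for (i in seq_len(m)) {
    tau[i, i] <- if (constant[i]) NA_real_ else 1
    if (i < m) for (j in (i + 1):m) {
      if (constant[i] || constant[j]) next
      t_ij <- stats::cor(x[, i], x[, j], method = "kendall")
      tau[i, j] <- t_ij
      tau[j, i] <- t_ij
    }
  }
  retained <- character(0)
  dropped <- character(0)
  for (cn in cols) {
    conflict <- any(!is.na(tau[cn, retained]) &
                      abs(tau[cn, retained]) >= tau_max)
    if (conflict) dropped <- c(dropped, cn) else retained <- c(retained, cn)
  }
  list(retained = retained, dropped = dropped, tau = tau)
}

#' Assemble the per-unit indicator table
#'
#' Joins the Landscape Elements metrics with the Extensive Practices and
#' Crop Diversity indicators for a set of units.
#'
#' @param le data.frame from \code{\link{landscape_elements}} rows
#' @param agrarian an \code{agrarian_table}
#' @param units data.frame with unit_id and uaa_ha
#' @param coefficients LSU coefficients
#' @return data.frame: unit_id, sdi_p, sei_p, np_p, msi_p, ed_p, lsi_p,
#'   irrig_p, sdi_c, sei_c, scrop_p.
#' @export
indicator_table <- function(le, agrarian, units,
                            coefficients = eurostat_lsu_coefficients()) {
  out <- le[, c("unit_id", "sdi_p", "sei_p", "np_p", "msi_p", "ed_p")]
  ep <- lapply(out$unit_id, function(uid) {
    uaa <- units$uaa_ha[match(uid, units$unit_id)]
    if (is.na(uaa)) stop("unit missing from unit table: ", uid)
    lsi <- livestock_density(agrarian_record(agrarian, uid, "livestock"),
                             coefficients, uaa_ha = uaa)
    irr <- irrigation_share(
      agrarian$irrigated_ha[match(uid, agrarian$unit_id)], uaa_ha = uaa)
    cd <- crop_diversity(agrarian_record(agrarian, uid, "crops"))
    data.frame(lsi_p = lsi, irrig_p = irr, sdi_c = cd$sdi_c,
               sei_c = cd$sei_c, scrop_p = cd$scrop_p)
  })
  cbind(out, do.call(rbind, ep))
}
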