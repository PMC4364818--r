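# Tabular I/O: agrarian-statistics CSV (livestock head counts, irrigated
# area, crop areas per unit) and the result writers.

#' Read per-unit agrarian statistics
#'
#' Expected CSV layout: a \code{unit_id} column, livestock head counts in
#' columns prefixed \code{livestock_} (suffix = animal category), an
#' \code{irrigated_ha} column, and crop areas (ha) in columns prefixed
#' \code{crop_} (suffix = crop type). Missing numeric cells are read as 0
#' with a warning, matching census tables that blank zero cells.
#'
#' @param path CSV file (header row, UTF-8, "." decimal separator)
#' @return data.frame of class \code{agrarian_table}, one row per unit.
#' @export
load_agrarian <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"unit_id" %in% names(df)) stop("agrarian table needs a unit_id column")
  if (anyDuplicated(df$unit_id))
    stop("duplicated unit_id in agrarian table: ",
         paste(unique(df$unit_id[duplicated(df$unit_id)]), collapse = ", "))
  if (!"irrigated_ha" %in% names(df)) df$irrigated_ha <- 0
  num_cols <- setdiff(names(df), "unit_id")
  for (cn in num_cols) {
    v <- df[[cn]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      warning("missing values in column '", cn, "' read as 0")
      v[is.na(v)] <- 0
    }
    if (any(v < 0))
      stop("negative value in column '", cn, "', row(s) ",
           paste(which(v < 0), collapse = ", "))
    df[[cn]] <- v
  }
  class(df) <- c("agrarian_table", "data.frame")
  df
}

#' Extract the livestock or crop mapping of one unit
#'
#' @param agrarian an \code{agrarian_table}
#' @param unit_id unit to extract
#' @param what \code{"livestock"} (head counts) or \code{"crops"} (areas, ha)
#' @return Named numeric vector (category/crop-type names without prefix).
#' @export
agrarian_record <- function(agrarian, unit_id,
                            what = c("livestock", "crops")) {
  what <- match.arg(what)
  i <- match(unit_id, agrarian$unit_id)
  if (is.na(i)) stop("unit not in agrarian table: ", unit_id)
  prefix <- if (what == "livestock") "livestock_" else "crop_"
  cols <- grep(paste0("^", prefix), names(agrarian), value = TRUE)
  stats::setNames(as.numeric(agrarian[i, cols]),
                  sub(paste0("^", prefix), "", cols))
}

#' Write pipeline results to a directory
#'
#' Writes the per-unit indicator table, the per-unit HNVf area account
#' (candidate envelopes, refined type 1/2/3 areas, trends, and a totals
#' row), the per-type HNVf extents as GeoJSON layers (non-empty types only,
#' when the run carries geometry), the Kendall tau matrix, and a JSON run
#' manifest recording thresholds and options.
#'
#' @param result an \code{hnvf_run} from \code{\link{run_pipeline}}
#' @param out_dir output directory (created if absent)
#' @return Character vector of files written, invisibly.
#' @export
write_result <- function(result, out_dir) {
  stopifnot(inherits(result, "hnvf_run"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  ind <- result$indicators
  names(ind) <- sub("^sdi_p$", "SDI_p", names(ind))
  names(ind) <- sub("^sei_p$", "SEI_p", names(ind))
  names(ind) <- sub("^np_p$", "NP_p", names(ind))
  names(ind) <- sub("^msi_p$", "MSI_p", names(ind))
  names(ind) <- sub("^ed_p$", "ED_p", names(ind))
  names(ind) <- sub("^lsi_p$", "LSI_p", names(ind))
  names(ind) <- sub("^irrig_p$", "Irrig_p", names(ind))
  names(ind) <- sub("^sdi_c$", "SDI_c", names(ind))
  names(ind) <- sub("^sei_c$", "SEI_c", names(ind))
  names(ind) <- sub("^scrop_p$", "SCrop_p", names(ind))
  w(ind, "indicators.csv")

  u <- result$units
  acct <- u[, c("unit_id", "name", "t_area_ha", "uaa_ha", "p_uaa_pct",
                "p_forest_pct", "eligible", "phnvf_min_ha", "phnvf_max_ha",
                "hnvf1_ha", "trend1", "hnvf2_ha", "trend2", "hnvf3_ha")]
  tot <- data.frame(unit_id = "TOTAL", name = "", t_area_ha = sum(u$t_area_ha),
                    uaa_ha = sum(u$uaa_ha), p_uaa_pct = NA, p_forest_pct = NA,
                    eligible = NA,
                    phnvf_min_ha = sum(u$phnvf_min_ha, na.rm = TRUE),
                    phnvf_max_ha = sum(u$phnvf_max_ha, na.rm = TRUE),
                    hnvf1_ha = sum(u$hnvf1_ha, na.rm = TRUE), trend1 = "",
                    hnvf2_ha = sum(u$hnvf2_ha, na.rm = TRUE), trend2 = "",
                    hnvf3_ha = sum(u$hnvf3_ha, na.rm = TRUE))
  w(rbind(acct, tot), "hnvf_areas.csv")

  if (!is.null(result$tau)) {
    tm <- as.data.frame(result$tau)
    tm <- cbind(indicator = rownames(result$tau), tm)
    w(tm, "tau_matrix.csv")
  }
  if (!is.null(result$masks) && !is.null(result$grid)) {
    for (ty in c("hnvf1", "hnvf2", "hnvf3")) {
      m <- result$masks[[ty]]
      if (is.null(m) || !any(m)) next
      p <- file.path(out_dir, paste0(ty, ".geojson"))
      write_geojson(mask_to_features(m, result$grid,
                                     props = list(hnvf_type = ty)),
                    p, crs = result$grid$crs)
      written <- c(written, p)
    }
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(result$manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, mp)
  invisible(written)
}
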