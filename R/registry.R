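#' Land-cover class registry
#'
#' A registry maps land-cover class codes to a role in the farmed landscape and
#' to their likelihood of constituting High Nature Value farmland under the
#' minimum-maximum approach. Classes flagged \code{"minimum"} are those known
#' to consist primarily of HNV farmland (semi-natural pastures, hay meadows,
#' eligible off-farm grazing); classes flagged \code{"maximum_only"} are
#' potential HNV farmland depending on farming intensity (arable mosaics,
#' vineyards, orchards). The minimum set is by construction a subset of the
#' maximum candidate set.
#'
#' @param classes data.frame with columns \code{code}, \code{label},
#'   \code{role} (one of \code{"farmland"}, \code{"forest"},
#'   \code{"off_farm_grazing"}, \code{"other"}), \code{hnvf_likelihood}
#'   (one of \code{"minimum"}, \code{"maximum_only"}, \code{"none"}) and
#'   optionally \code{crop_group}.
#' @return An object of class \code{hnvf_registry} (a validated data.frame).
#' @export
hnvf_registry <- function(classes) {
  classes <- as.data.frame(classes, stringsAsFactors = FALSE)
  need <- c("code", "label", "role", "hnvf_likelihood")
  miss <- setdiff(need, names(classes))
  if (length(miss))
    stop("registry is missing columns: ", paste(miss, collapse = ", "))
  if (!"crop_group" %in% names(classes)) classes$crop_group <- NA_character_
  if (anyDuplicated(classes$code))
    stop("duplicated class codes in registry: ",
         paste(unique(classes$code[duplicated(classes$code)]), collapse = ", "))
  roles <- c("farmland", "forest", "off_farm_grazing", "other")
  bad <- setdiff(classes$role, roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  lik <- c("minimum", "maximum_only", "none")
  bad <- setdiff(classes$hnvf_likelihood, lik)
  if (length(bad)) stop("unknown hnvf_likelihood: ", paste(bad, collapse = ", "))
  # classes almost certainly HNV must be farmed or grazed land
  off <- classes$hnvf_likelihood == "minimum" &
    !classes$role %in% c("farmland", "off_farm_grazing")
  if (any(off))
    stop("classes with hnvf_likelihood 'minimum' must have role farmland or ",
         "off_farm_grazing: ", paste(classes$code[off], collapse = ", "))
  rownames(classes) <- NULL
  structure(classes, class = c("hnvf_registry", "data.frame"))
}

#' Illustrative default class registry
#'
#' A compact nomenclature for a mountain agro-pastoral municipality: hay
#' meadows and semi-natural pastures (minimum HNVf likelihood), grazed
#' heathland commons (off-farm grazing, minimum likelihood, subject to
#' natural-constraint masking), arable/vineyard/orchard/mixed mosaics
#' (maximum-only likelihood), forests and non-agricultural classes. It is an
#' illustrative registry for synthetic landscapes, not any particular
#' municipality's nomenclature.
#'
#' @return An \code{hnvf_registry}.
#' @export
default_registry <- function() {
  hnvf_registry(data.frame(
    code = c("meadow", "pasture", "heath", "arable", "vineyard", "orchard",
             "mosaic", "forest_bl", "forest_cf", "forest_mx", "urban",
             "water", "rock"),
    label = c("hay meadow", "semi-natural pasture", "grazed heathland",
              "arable land", "vineyard", "orchard",
              "agricultural mosaic", "broadleaved forest",
              "coniferous forest", "mixed forest", "built-up", "water",
              "bare rock"),
    role = c("farmland", "farmland", "off_farm_grazing", "farmland",
             "farmland", "farmland", "farmland", "forest", "forest",
             "forest", "other", "other", "other"),
    hnvf_likelihood = c("minimum", "minimum", "minimum", "maximum_only",
                        "maximum_only", "maximum_only", "maximum_only",
                        "none", "none", "none", "none", "none", "none"),
    crop_group = c("fodder", "fodder", NA, "cereals", "vineyard", "orchard",
                   "horticulture", NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  ))
}

#' @export
print.hnvf_registry <- function(x, ...) {
  cat("<hnvf_registry> ", nrow(x), " land-cover classes\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Class codes having a given role or HNVf likelihood
#'
#' @param registry an \code{hnvf_registry}
#' @param role optional character vector of roles to select
#' @param likelihood optional character vector of HNVf likelihood levels
#' @return Character vector of class codes.
#' @export
registry_codes <- function(registry, role = NULL, likelihood = NULL) {
  keep <- rep(TRUE, nrow(registry))
  if (!is.null(role)) keep <- keep & registry$role %in% role
  if (!is.null(likelihood))
    keep <- keep & registry$hnvf_likelihood %in% likelihood
  registry$code[keep]
}

#' Read / write a class registry as YAML
#'
#' The YAML layout is a top-level \code{classes:} sequence of mappings with
#' keys \code{code}, \code{label}, \code{role}, \code{hnvf_likelihood} and
#' optional \code{crop_group}.
#'
#' @param path file path
#' @return \code{read_registry}: an \code{hnvf_registry}.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$classes)) stop("registry YAML must contain a 'classes' key")
  rows <- lapply(y$classes, function(cl) {
    data.frame(code = cl$code, label = cl$label %||% cl$code,
               role = cl$role, hnvf_likelihood = cl$hnvf_likelihood,
               crop_group = cl$crop_group %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  hnvf_registry(do.call(rbind, rows))
}

#' @rdname read_registry
#' @param registry an \code{hnvf_registry}
#' @export
write_registry <- function(registry, path) {
  classes <- lapply(seq_len(nrow(registry)), function(i) {
    cl <- list(code = registry$code[i], label = registry$label[i],
               role = registry$role[i],
               hnvf_likelihood = registry$hnvf_likelihood[i])
    if (!is.na(registry$crop_group[i])) cl$crop_group <- registry$crop_group[i]
    cl
  })
  yaml::write_yaml(list(classes = classes), path)
  invisible(path)
}

#' Threshold configuration for the HNVf cascade
#'
#' All cut values are retained at equality: farmland dominance requires a UAA
#' share >= \code{uaa_dominance_pct}; HNVf-1 requires livestock density
#' <= \code{lsi_max} and irrigation share <= \code{irrig_max_pct}; HNVf-2
#' requires Shannon evenness >= \code{sei_min} and edge density >=
#' \code{ed_min}.
#'
#' @param uaa_dominance_pct farmland-dominance threshold, percent of unit area
#' @param lsi_max maximum livestock density, LSU per ha of UAA
#' @param irrig_max_pct maximum irrigated share, percent of UAA
#' @param sei_min minimum Shannon evenness of the land-cover mosaic
#' @param ed_min minimum edge density, m/ha
#' @param tau_max redundancy threshold on |Kendall tau-b| between indicators
#' @param metric_scope \code{"all_classes"} or \code{"farmland_only"}: which
#'   classes enter the landscape metrics
#' @param cd_confirmation if TRUE (default) crop-diversity indicators are used
#'   to flag, not exclude: units whose crop Shannon diversity ranks in the
#'   bottom tercile of eligible units are marked \code{cd_low}
#' @param cd_strict if TRUE the crop-diversity step excludes flagged units
#'   from HNVf-2 instead of only flagging them
#' @param hnvf2_all_eligible if TRUE (default) the HNVf-2 cascade considers
#'   all farmland-dominant units; if FALSE only units that failed the HNVf-1
#'   intensity screen are considered
#' @param exclude_unit_boundary if TRUE, edge segments coincident with the
#'   unit boundary are excluded from edge density
#' @param trend_tol_ha tolerance (ha) when labelling area trends
#' @return A list of class \code{hnvf_thresholds}.
#' @export
hnvf_thresholds <- function(uaa_dominance_pct = 40, lsi_max = 0.2,
                            irrig_max_pct = 15, sei_min = 0.60, ed_min = 300,
                            tau_max = 0.7,
                            metric_scope = c("all_classes", "farmland_only"),
                            cd_confirmation = TRUE, cd_strict = FALSE,
                            hnvf2_all_eligible = TRUE,
                            exclude_unit_boundary = FALSE,
                            trend_tol_ha = 0.01) {
  metric_scope <- match.arg(metric_scope)
  th <- list(uaa_dominance_pct = uaa_dominance_pct, lsi_max = lsi_max,
             irrig_max_pct = irrig_max_pct, sei_min = sei_min,
             ed_min = ed_min, tau_max = tau_max, metric_scope = metric_scope,
             cd_confirmation = cd_confirmation, cd_strict = cd_strict,
             hnvf2_all_eligible = hnvf2_all_eligible,
             exclude_unit_boundary = exclude_unit_boundary,
             trend_tol_ha = trend_tol_ha)
  num <- c("uaa_dominance_pct", "lsi_max", "irrig_max_pct", "sei_min",
           "ed_min", "tau_max", "trend_tol_ha")
  for (k in num) {
    v <- th[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("threshold ", k, " must be a single number")
  }
  for (k in c("uaa_dominance_pct", "irrig_max_pct"))
    if (is.finite(th[[k]]) && (th[[k]] < 0 || th[[k]] > 100))
      stop("threshold ", k, " must lie in [0, 100]")
  structure(th, class = "hnvf_thresholds")
}

#' @export
print.hnvf_thresholds <- function(x, ...) {
  cat("<hnvf_thresholds>\n")
  for (k in names(x)) cat(" ", k, "=", format(x[[k]]), "\n")
  invisible(x)
}

#' Eurostat-standard livestock unit coefficients
#'
#' Standard LSU-per-head coefficients used to aggregate heterogeneous herds
#' into grazing-pressure units. Overridable by supplying a complete named
#' vector wherever coefficients are accepted.
#'
#' @return Named numeric vector, LSU per head.
#' @export
eurostat_lsu_coefficients <- function() {
  c(dairy_cows = 1.0, other_cattle = 0.8, cattle_under_1y = 0.4,
    sheep = 0.1, goats = 0.1, equines = 0.8, breeding_sows = 0.5,
    other_pigs = 0.3, poultry = 0.007, rabbits = 0.02)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
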