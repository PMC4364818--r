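# Worked example: the 18-parish municipality of Melgaco (northern Portugal),
# the case study for which this framework was developed. The fixture carries
# the reference per-parish indicator values and the candidate/refined HNVf
# areas as printed in the study's municipal tables (no geometry is public),
# so the threshold cascade can be exercised and checked end to end.

#' Reference indicator and area tables for the Melgaco worked example
#'
#' Eighteen civil parishes; six fail the 40 \% farmland-dominance screen and
#' are flagged not applicable. For the twelve farmland-dominant parishes the
#' fixture carries livestock density (LSU/ha of UAA), irrigation share (\%),
#' land-cover Shannon diversity and evenness, and for the evenness survivors
#' patch number, mean shape index, edge density (m/ha) and the crop
#' indicators; plus each parish's minimum/maximum candidate areas and the
#' refined type-2 areas (ha). Refined type-2 areas are carried as data
#' because the spatial mask behind them is not derivable from the tables.
#'
#' @return List: \code{units} (unit_id, name, eligible), \code{indicators},
#'   \code{areas} (phnvf_min_ha, phnvf_max_ha, hnvf2_refined_ha).
#' @export
melgaco_table_fixture <- function() {
  units <- data.frame(
    unit_id = c("alvaredo", "castro_laboreiro", "chaviaes", "cousso",
                "cristoval", "cubalhao", "fiaes", "gave", "lamas_de_mouro",
                "pacos", "paderne", "parada_do_monte", "penso", "prado",
                "remoaes", "roussas", "sao_paio", "vila"),
    name = c("Alvaredo", "Castro Laboreiro", "Chaviães", "Cousso",
             "Cristóval", "Cubalhão", "Fiães", "Gave",
             "Lamas de Mouro", "Paços", "Paderne", "Parada do Monte",
             "Penso", "Prado", "Remoães", "Roussas", "São Paio",
             "Vila"),
    stringsAsFactors = FALSE)
  units$eligible <- !units$unit_id %in%
    c("chaviaes", "cristoval", "pacos", "paderne", "penso", "remoaes")

  ind <- data.frame(
    unit_id = c("lamas_de_mouro", "roussas", "alvaredo", "sao_paio",
                "cousso", "gave", "prado", "castro_laboreiro", "fiaes",
                "parada_do_monte", "vila", "cubalhao"),
    lsi_p = c(0.03, 0.10, 0.11, 0.11, 0.14, 0.14, 0.14, 0.16, 0.19, 0.19,
              0.19, 0.23),
    irrig_p = c(2.38, 12.94, 53.24, 11.44, 10.19, 6.16, 40.50, 2.50, 5.45,
                6.14, 34.44, 3.38),
    stringsAsFactors = FALSE)
  sei <- c(prado = 0.86, alvaredo = 0.79, cousso = 0.78, sao_paio = 0.75,
           roussas = 0.74, vila = 0.71, gave = 0.69, fiaes = 0.64,
           parada_do_monte = 0.58, cubalhao = 0.56, lamas_de_mouro = 0.48,
           castro_laboreiro = 0.45)
  sdi <- c(alvaredo = 2.68, prado = 2.63, cousso = 2.61, roussas = 2.55,
           sao_paio = 2.31, gave = 2.28, vila = 2.13, fiaes = 2.01,
           parada_do_monte = 1.97, castro_laboreiro = 1.65,
           cubalhao = 1.60, lamas_de_mouro = 1.58)
  np <- c(gave = 212, roussas = 174, sao_paio = 142, fiaes = 137,
          alvaredo = 126, cousso = 111, prado = 59, vila = 42)
  msi <- c(vila = 2.60, prado = 2.57, sao_paio = 2.47, fiaes = 2.33,
           alvaredo = 2.31, roussas = 2.22, gave = 2.09, cousso = 2.09)
  ed <- c(vila = 448.22, alvaredo = 429.37, prado = 420.47,
          roussas = 338.17, sao_paio = 318.64, cousso = 272.49,
          fiaes = 272.15, gave = 238.81)
  sdi_c <- c(sao_paio = 1.03, vila = 0.78, roussas = 0.75, prado = 0.72,
             alvaredo = 0.58, gave = 0.51, cousso = 0.32, fiaes = 0.11)
  sei_c <- c(sao_paio = 0.23, vila = 0.22, roussas = 0.17, prado = 0.18,
             alvaredo = 0.12, gave = 0.10, cousso = 0.05, fiaes = 0.02)
  scrop <- c(sao_paio = 5, vila = 5, roussas = 5, prado = 5, alvaredo = 5,
             gave = 7, cousso = 7, fiaes = 4)
  ind$sei_p <- as.numeric(sei[ind$unit_id])
  ind$sdi_p <- as.numeric(sdi[ind$unit_id])
  ind$np_p <- as.numeric(np[ind$unit_id])
  ind$msi_p <- as.numeric(msi[ind$unit_id])
  ind$ed_p <- as.numeric(ed[ind$unit_id])
  ind$sdi_c <- as.numeric(sdi_c[ind$unit_id])
  ind$sei_c <- as.numeric(sei_c[ind$unit_id])
  ind$scrop_p <- as.numeric(scrop[ind$unit_id])

  areas <- data.frame(
    unit_id = c("alvaredo", "castro_laboreiro", "cousso", "cubalhao",
                "fiaes", "gave", "lamas_de_mouro", "parada_do_monte",
                "prado", "roussas", "sao_paio", "vila"),
    phnvf_min_ha = c(4.17, 4730.33, 158.56, 673.32, 557.88, 778.99,
                     1066.22, 903.10, 0, 311.22, 298.55, 0),
    phnvf_max_ha = c(216.02, 5242.61, 294.42, 798.81, 697.85, 1006.15,
                     1176.45, 1139.98, 116.06, 517.95, 533.07, 87.10),
    hnvf2_refined_ha = c(99.03, 0, 0, 0, 0, 0, 0, 0, 79.35, 162.26,
                         196.60, 80.93),
    stringsAsFactors = FALSE)
  list(units = units, indicators = ind, areas = areas)
}

#' Run the threshold cascade on a table fixture
#'
#' Drives the type-1 and type-2 screens with per-unit indicator values and
#' candidate areas alone (no geometry): type-1 retained units contribute
#' their minimum candidate area; type-2 retained units contribute their
#' refined type-2 area when the fixture carries one, otherwise the
#' maximum-minus-minimum difference. Ineligible units are flagged not
#' applicable.
#'
#' @param fixture list with \code{units}, \code{indicators}, \code{areas}
#'   (see \code{\link{melgaco_table_fixture}})
#' @param thresholds \code{hnvf_thresholds}. For the Melgaco worked example
#'   the livestock cut is non-binding (\code{lsi_max = Inf}): the study's
#'   decision path assessed livestock density first, found it uninformative
#'   at the parish level, and applied only the irrigation share for type 1.
#' @return List: \code{units} (area account with trends), \code{hnvf1_units},
#'   \code{hnvf2_units}, \code{totals}.
#' @export
run_table_cascade <- function(fixture,
                              thresholds = hnvf_thresholds(lsi_max = Inf)) {
  u <- fixture$units
  u <- merge(u, fixture$areas, by = "unit_id", all.x = TRUE, sort = FALSE)
  u <- u[match(fixture$units$unit_id, u$unit_id), ]
  sel1 <- select_hnvf1(u, fixture$indicators, thresholds)
  sel2 <- select_hnvf2(u, fixture$indicators, thresholds,
                       hnvf1_selected = sel1)
  u$hnvf1 <- u$unit_id %in% sel1
  u$hnvf2 <- u$unit_id %in% sel2$selected
  u$hnvf1_ha <- ifelse(u$hnvf1, u$phnvf_min_ha, 0)
  refined2 <- if ("hnvf2_refined_ha" %in% names(u)) u$hnvf2_refined_ha
              else u$phnvf_max_ha - u$phnvf_min_ha
  u$hnvf2_ha <- ifelse(u$hnvf2, refined2, 0)
  tol <- thresholds$trend_tol_ha
  u$trend1 <- trend_label(u$hnvf1_ha, u$phnvf_min_ha, u$eligible, tol)
  u$trend2 <- trend_label(u$hnvf2_ha, u$phnvf_max_ha - u$phnvf_min_ha,
                          u$eligible, tol)
  u$trend1[u$eligible & is.na(u$phnvf_min_ha)] <- "not_applicable"
  totals <- list(
    hnvf1_ha = round(sum(u$hnvf1_ha, na.rm = TRUE), 2),
    hnvf2_ha = round(sum(u$hnvf2_ha, na.rm = TRUE), 2),
    hnvf_total_ha = round(sum(u$hnvf1_ha, na.rm = TRUE) +
                            sum(u$hnvf2_ha, na.rm = TRUE), 2),
    n_eligible = sum(u$eligible), n_na = sum(!u$eligible),
    n_hnvf1 = length(sel1), n_hnvf2 = length(sel2$selected))
  list(units = u, hnvf1_units = sel1, hnvf2_units = sel2$selected,
       cd_low = sel2$cd_low, totals = totals)
}
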