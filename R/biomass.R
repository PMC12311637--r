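#' Default carbon conversion factors (fg C per cell)
#'
#' Heterotrophic bacteria 20, Synechococcus 178, photosynthetic
#' picoeukaryotes 1500, heterotrophic and pigmented nanoflagellates 4700.
#' @export
default_carbon_factors <- c(HB = 20, Syn = 178, PPE = 1500,
                            HNF = 4700, PNF = 4700)

#' Convert cell abundances to carbon biomass
#'
#' Multiplies each group's abundance (cells/mL) by a per-cell carbon
#' conversion factor (fg C/cell), appending `<group>_biomass` columns in
#' fg C/mL.
#'
#' @param table data.frame with abundance columns named after the groups in
#'   `factors`.
#' @param factors named numeric vector of conversion factors; defaults to
#'   [default_carbon_factors].
#' @return the table with added biomass columns.
#' @export
abundance_to_biomass <- function(table, factors = default_carbon_factors) {
  present <- intersect(names(factors), names(table))
  if (length(present) == 0) stop("no abundance columns matching factors")
  for (g in present) {
    if (any(table[[g]] < 0, na.rm = TRUE))
      stop("negative abundance in column ", g)
    table[[paste0(g, "_biomass")]] <- table[[g]] * factors[[g]]
  }
  table
}

#' Predator/prey biomass ratios (PPBR)
#'
#' Biomass ratio of heterotrophic nanoflagellates to their prey:
#' HNF/HB (bacterivory) and HNF/PPE (herbivory on picoeukaryotes), plus
#' their log10 transforms. A proxy for trophic transfer efficiency between
#' the pico and nano size classes. Zero prey biomass yields a missing value
#' and is counted in attribute `n_undefined`.
#'
#' @param table data.frame with `HNF_biomass`, `HB_biomass`, `PPE_biomass`
#'   columns (see [abundance_to_biomass()]).
#' @return the table with columns `ppbr_hnf_hb`, `ppbr_hnf_ppe`,
#'   `log10_ppbr_hnf_hb`, `log10_ppbr_hnf_ppe`.
#' @export
ppbr <- function(table) {
  need <- c("HNF_biomass", "HB_biomass", "PPE_biomass")
  if (!all(need %in% names(table)))
    stop("biomass columns missing; run abundance_to_biomass() first")
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  table$ppbr_hnf_hb <- safe_ratio(table$HNF_biomass, table$HB_biomass)
  table$ppbr_hnf_ppe <- safe_ratio(table$HNF_biomass, table$PPE_biomass)
  table$log10_ppbr_hnf_hb <- log10(table$ppbr_hnf_hb)
  table$log10_ppbr_hnf_ppe <- log10(table$ppbr_hnf_ppe)
  attr(table, "n_undefined") <-
    sum(is.na(table$ppbr_hnf_hb)) + sum(is.na(table$ppbr_hnf_ppe))
  table
}
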