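#' Desikan-Killiany cortical parcellation labels
#'
#' The Desikan-Killiany (D-K) atlas divides each cortical hemisphere into 34
#' gyral regions. Regional thickness (mm) and surface-area (mm^2) tables used
#' throughout this package are indexed by the 68 labels returned here, in the
#' fixed order left hemisphere then right hemisphere.
#'
#' @return `dkGyri()`: character vector of the 34 gyrus names.
#'   `dkRegions()`: character vector of the 68 hemisphere-qualified labels
#'   (`lh_<gyrus>`, `rh_<gyrus>`).
#' @examples
#' length(dkRegions())
#' head(dkGyri())
#' @export
dkGyri <- function() {
    c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal",
      "cuneus", "entorhinal", "frontalpole", "fusiform",
      "inferiorparietal", "inferiortemporal", "insula",
      "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
      "lingual", "medialorbitofrontal", "middletemporal",
      "paracentral", "parahippocampal", "parsopercularis",
      "parsorbitalis", "parstriangularis", "pericalcarine",
      "postcentral", "posteriorcingulate", "precentral", "precuneus",
      "rostralanteriorcingulate", "rostralmiddlefrontal",
      "superiorfrontal", "superiorparietal", "superiortemporal",
      "supramarginal", "temporalpole", "transversetemporal")
}

#' @rdname dkGyri
#' @export
dkRegions <- function() {
    c(paste0("lh_", dkGyri()), paste0("rh_", dkGyri()))
}

#' Names of the morphometric measures handled by the package
#' @return Character vector `c("thickness", "surface_area")`.
#' @export
corticalMeasures <- function() c("thickness", "surface_area")
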