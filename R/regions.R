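#' Biogeographic region vocabulary
#'
#' The Natura 2000 BIOREGION table records nine terrestrial and five marine
#' biogeographic regions. Analyses of terrestrial representation are confined
#' to the six main terrestrial regions of continental Europe; the remaining
#' regions are either very small (e.g. Macaronesian) or marine.
#'
#' @return Character vector of canonical region names.
#' @export
#' @examples
#' n2k_regions("terrestrial6")
n2k_regions <- function(set = c("terrestrial6", "terrestrial", "marine",
                                "extended")) {
  set <- match.arg(set)
  terrestrial <- c("Alpine", "Atlantic", "BlackSea", "Boreal", "Continental",
                   "Macaronesian", "Mediterranean", "Pannonian", "Steppic")
  marine <- c("MarineAtlantic", "MarineBaltic", "MarineBlackSea",
              "MarineMacaronesian", "MarineMediterranean")
  switch(set,
    terrestrial6 = c("Alpine", "Atlantic", "Boreal", "Continental",
                     "Mediterranean", "Pannonian"),
    terrestrial  = terrestrial,
    marine       = marine,
    extended     = c(terrestrial, marine))
}

#' Default alias table mapping export spellings to canonical region names
#'
#' @return A tibble with columns `alias` and `region`.
#' @export
n2k_region_aliases <- function() {
  path <- system.file("extdata", "region_aliases.csv", package = "n2kgap")
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Path to a reference table shipped with the package
#'
#' @param name File name under `inst/extdata`.
#' @return Absolute path to the installed file.
#' @export
n2k_extdata <- function(name) {
  path <- system.file("extdata", name, package = "n2kgap")
  if (!nzchar(path)) stop("no shipped file named '", name, "'", call. = FALSE)
  path
}
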