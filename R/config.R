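#' Package configuration
#'
#' Design constants that are data, not code: printer spot size, the default
#' calibration design grid (beam thicknesses and void side lengths), HU
#' band definitions, lattice-visibility rules, the band-to-design anchor
#' table for part-solid nodule assembly, and virtual-CT defaults. Shipped
#' as JSON under `inst/extdata/default_config.json`; pass `path` to load a
#' modified configuration.
#'
#' @param path optional path to an alternative JSON configuration.
#' @return named list of configuration entries.
#' @export
nodulefab_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.json",
                        package = "nodulefab", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE) |> simplify_cfg()
}

simplify_cfg <- function(cfg) {
  num_fields <- c("spot_um", "thicknesses_um", "voids_um", "hu_air",
                  "hu_material", "visibility_threshold", "psf_sigma_mm",
                  "resin_price_per_ml")
  for (f in num_fields)
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.numeric(unlist(cfg[[f]]))
  cfg
}
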