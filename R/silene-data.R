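#' Reference tubercle measurements for 31 Silene species
#'
#' Published reference tables of seed-coat tubercle morphometry in the genus
#' *Silene*, packaged as plain-text data. The study measured width at the
#' base (W, microns), height (H, microns), slope (S = 200 H / W), maximum
#' and mean absolute curvature (micron^-1 x 1000) and their ratio for 396
#' tubercles of 31 species — 21 species with rugose (rounded, low-tubercle)
#' seeds and 10 with echinate (acute, tall-tubercle) seeds; 12 species
#' belong to *Silene* subg. *Behenantha* and 19 to subg. *Silene*.
#'
#' * `silene_species_summaries()`: one row per species with the tubercle
#'   count `n_tubercles`, seed count, seed type, subgenus, and per variable
#'   the mean, CV (percent), minimum and maximum.
#' * `silene_tubercles()`: the per-tubercle worked values for six tubercles
#'   of each of 11 representative species (66 tubercles), as printed: `W`
#'   and `H` to the micron, the rest to one decimal (mean curvature of
#'   *S. ciliata* to the integer).
#' * `silene_group_summaries()`: the pooled rugose/echinate and
#'   Behenantha/Silene comparison rows.
#'
#' @return a data.frame.
#' @examples
#' head(silene_species_summaries()[, 1:6])
#' @name silene_reference
NULL

silene_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tubermorph")
  if (path == "") stop("packaged data file not found: ", file)
  utils::read.csv(path, check.names = FALSE)
}

#' @rdname silene_reference
#' @export
silene_species_summaries <- function() silene_extdata("silene_species_summary.csv")

#' @rdname silene_reference
#' @export
silene_tubercles <- function() silene_extdata("silene_tubercles.csv")

#' @rdname silene_reference
#' @export
silene_group_summaries <- function() silene_extdata("silene_group_summary.csv")
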