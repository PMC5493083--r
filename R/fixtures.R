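#' Published Hsp90 isoxazolediamide activity table
#'
#' The published activity table for the 50-compound 3,4-isoxazolediamide
#' series: experimental pIC50 together with the pIC50 predicted by the
#' reference MLR and GA-PLS equations (see [published_models()]). Values
#' are as printed, to two decimals. The table carries no
#' calibration/validation labels (none were published).
#'
#' @return A data frame with columns `compound_id`, `pic50_exp`,
#'   `pic50_mlr`, `pic50_gapls`; 50 rows.
#' @seealso [hsp90_ic50_table()], [predict_published()]
#' @export
hsp90_activity_table <- function() {
  path <- system.file("extdata", "hsp90_pic50.csv", package = "isoqsar",
                      mustWork = TRUE)
  read.table(path, sep = ",", header = TRUE, check.names = FALSE,
             colClasses = c("character", "numeric", "numeric", "numeric"))
}

#' Published Hsp90 isoxazolediamide IC50 table
#'
#' Enzymatic IC50 values (micromolar) for the 25 docked compounds of the
#' series, with the structural subgroup (A: chloro-resorcinol amides,
#' B: isopropyl-resorcinol, C: chloro-resorcinol N-linked). Every IC50 is
#' consistent with the corresponding experimental pIC50 in
#' [hsp90_activity_table()] under the millimolar convention of
#' [ic50_to_pic50()].
#'
#' @return A data frame with columns `compound_id`, `ic50_um`, `group`;
#'   25 rows.
#' @export
hsp90_ic50_table <- function() {
  path <- system.file("extdata", "hsp90_ic50_um.csv", package = "isoqsar",
                      mustWork = TRUE)
  read.table(path, sep = ",", header = TRUE, check.names = FALSE,
             colClasses = c("character", "numeric", "character"))
}

#' Catalog of descriptors appearing in the reference models
#'
#' Names, descriptor families and short definitions for every molecular
#' descriptor used by the five elected split models and the two reference
#' equations: connectivity, GETAWAY, 3D-MoRSE, WHIM, Burden-eigenvalue,
#' Moran/Geary autocorrelation, RDF, topological and dipole descriptors.
#'
#' @return A data frame with columns `name`, `family`, `description`.
#' @export
descriptor_catalog <- function() {
  dc <- function(name, family, description) {
    data.frame(name = name, family = family, description = description,
               stringsAsFactors = FALSE)
  }
  rbind(
    dc("X5A", "connectivity", "average connectivity index of order 5"),
    dc("HATS4u", "GETAWAY", "leverage-weighted autocorrelation of lag 4, unweighted"),
    dc("Mor10m", "3D-MoRSE", "signal 10, weighted by mass"),
    dc("Mor26p", "3D-MoRSE", "signal 26, weighted by polarizability"),
    dc("Mor09u", "3D-MoRSE", "signal 09, unweighted"),
    dc("Du", "WHIM", "D total accessibility index, unweighted"),
    dc("BELe1", "Burden eigenvalue", "lowest eigenvalue n.1 of Burden matrix, weighted by Sanderson electronegativity"),
    dc("MATS6e", "2D autocorrelation", "Moran autocorrelation lag 6, weighted by Sanderson electronegativity"),
    dc("Gu", "WHIM", "total symmetry index, unweighted"),
    dc("Mor27p", "3D-MoRSE", "signal 27, weighted by polarizability"),
    dc("Mor12m", "3D-MoRSE", "signal 12, weighted by mass"),
    dc("RDF140m", "RDF", "radial distribution function 14.0, weighted by mass"),
    dc("T(N..O)", "2D atom pairs", "sum of topological distances between N..O"),
    dc("dipole y", "quantum chemical", "electric dipole component along the y axis"),
    dc("R3e+", "GETAWAY", "R maximal autocorrelation of lag 3, weighted by Sanderson electronegativity"),
    dc("R1e", "GETAWAY", "R autocorrelation of lag 1, weighted by Sanderson electronegativity"),
    dc("Mor09m", "3D-MoRSE", "signal 09, weighted by mass"),
    dc("TIE", "topological", "E-state topological parameter"),
    dc("dipole z", "quantum chemical", "electric dipole component along the z axis"),
    dc("Mor26e", "3D-MoRSE", "signal 26, weighted by Sanderson electronegativity"),
    dc("ISH", "GETAWAY", "standardized information content on the leverage equality"),
    dc("MATS1p", "2D autocorrelation", "Moran autocorrelation lag 1, weighted by polarizability"),
    dc("MATS8e", "2D autocorrelation", "Moran autocorrelation lag 8, weighted by Sanderson electronegativity"),
    dc("Ku", "WHIM", "K global shape index, unweighted"),
    dc("P2m", "WHIM", "2nd component shape directional index, weighted by mass"),
    dc("GATS4e", "2D autocorrelation", "Geary autocorrelation lag 4, weighted by Sanderson electronegativity"),
    dc("E3u", "WHIM", "3rd component accessibility directional index, unweighted"),
    dc("MATS7e", "2D autocorrelation", "Moran autocorrelation lag 7, weighted by Sanderson electronegativity"),
    dc("G1u", "WHIM", "1st component symmetry directional index, unweighted"),
    dc("RDF075m", "RDF", "radial distribution function 7.5, weighted by mass")
  )
}
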