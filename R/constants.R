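## Reference tables used by the peptide descriptors. All values are
## published constants; none are fitted within this package.

#' The 20-letter amino-acid alphabet
#' @export
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values of Kyte & Doolittle (1982), the
#' default scale for \code{\link{hydrophobicityMean}}.
#' @export
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

## Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values
## (DIWV). Rows index the first residue of the dipeptide, columns the
## second. Order: ACDEFGHIKLMNPQRSTVWY.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34),
  nrow = 20, byrow = TRUE,
  dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))

## EMBOSS pKa set (as used by the iep program and the Peptides package's
## "EMBOSS" scale). Termini plus the seven ionizable side chains.
EMBOSS_PKA <- list(
  nterm = 8.6, cterm = 3.6,
  side = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  ## side-chain charge sign at low pH: basic residues (and N-terminus) are
  ## protonated/positive, acidic ones neutral
  positive = c("H", "K", "R"))

## Average (isotope-weighted) free amino-acid masses in Daltons; residue
## mass in a chain = value - one water.
AA_MASS_FREE <- c(
  A =  89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G =  75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885)

WATER_MASS <- 18.0153

#' Residue class sets used by the proportion descriptors
#'
#' Hydrophobic/aromatic (V,I,Y,F,W,L), aromatic (F,W,Y), small (Taylor
#' classification), acidic (D,E) and basic (K,R,H) residue sets.
#' @export
RESIDUE_CLASSES <- list(
  hydro_aro = c("V","I","Y","F","W","L"),
  aromatic  = c("F","W","Y"),
  small     = c("A","G","S","T","C","P","N","D"),  # Taylor classification
  acidic    = c("D","E"),
  basic     = c("K","R","H"))

#' Illustrative marker genes for ten immune/stromal cell populations
#'
#' Default marker configuration for
#' \code{\link{markerPopulationScores}}: two canonical lineage markers
#' per population. For real data supply the marker list of your
#' deconvolution tool of choice; the downstream feature is only the
#' per-patient mean over populations.
#' @export
DEFAULT_MARKER_SETS <- list(
  T_cells                 = c("CD3D", "CD3E"),
  CD8_T_cells             = c("CD8A", "CD8B"),
  Cytotoxic_lymphocytes   = c("GZMB", "KLRD1"),
  NK_cells                = c("KLRC1", "NCR1"),
  B_lineage               = c("CD19", "MS4A1"),
  Monocytic_lineage       = c("CD14", "CSF1R"),
  Myeloid_dendritic_cells = c("CD1C", "CLEC10A"),
  Neutrophils             = c("FCGR3B", "CSF3R"),
  Endothelial_cells       = c("PECAM1", "VWF"),
  Fibroblasts             = c("COL1A1", "DCN"))

DEFAULT_HLA_GENES <- c("HLA-A", "HLA-B", "HLA-C")

## Named model feature sets. `standard` is the 22-feature default model
## (one-hot mutation descriptors and the redundant HydroAll / VarAlFrac /
## Aro columns excluded); `simple` additionally drops the two
## genomics-derived columns unavailable on external benchmark data;
## `tme` extends `standard` with the three patient-level covariates.
FEATURE_SETS <- local({
  standard <- c("SelfSim", "DAI", "CelPrev", "Expression", "ValMutRNACoef",
                "Foreignness", "PrioScore", "RankBA", "RankEL", "Stability",
                "NetMHCExp", "PropHydroAro", "Prime", "HydroCore", "PropAro",
                "CysRed", "PropSmall", "PropAcidic", "Inst", "PropBasic",
                "pI", "mw")
  list(
    standard = standard,
    simple   = setdiff(standard, c("PrioScore", "CelPrev")),
    tme      = c(standard, c("CYT", "MCPmean", "HLAexp")))
})

#' Named feature sets for the default models
#'
#' Returns the list of feature names making up one of the three built-in
#' model configurations: \code{"standard"} (the 22-feature default),
#' \code{"simple"} (drops the genomics-derived \code{PrioScore} and
#' \code{CelPrev}, for data where these are unavailable) and \code{"tme"}
#' (adds the patient-level tumor-microenvironment covariates \code{CYT},
#' \code{MCPmean}, \code{HLAexp}).
#'
#' @param name one of \code{"standard"}, \code{"simple"}, \code{"tme"}.
#' @return character vector of feature names.
#' @export
#' @examples
#' featureSet("standard")
featureSet <- function(name = c("standard", "simple", "tme")) {
  name <- match.arg(name)
  FEATURE_SETS[[name]]
}

## internal: fetch BLOSUM62 from Biostrings once per session
.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
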