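#' Canonical radiomic feature registry
#'
#' The extractor emits exactly 352 named features per lesion, split over seven
#' families: first-order histogram (HIS, 9), gray-level co-occurrence matrix
#' (COM, 11 statistics x 20 offsets = 220), run-length matrix (RLM, 5
#' statistics x 4 directions = 20), absolute gradient (GRA, 5), 2-D
#' autoregressive model (ARM, 5), Haar wavelet energies (WAV, 4 subbands x 5
#' scales = 20), and lesion geometry (GEO, 73). Feature tables, selection and
#' classification all refer to features by these names, in this order.
#'
#' COM features are named `S(dx,dy)Stat` where `dx` is the column offset and
#' `dy` the row offset with the y axis pointing down; the 20 offsets are
#' `(0,d), (d,0), (d,d), (d,-d)` for inter-pixel distances `d = 1..5`, so
#' `S(d,-d)` is the 45-degree diagonal. RLM features carry a direction prefix
#' (`Horzl_`, `Vertl_`, `45dgr_`, `135dr_`).
#'
#' @param family Optional character vector restricting the result to one or
#'   more of `"HIS"`, `"COM"`, `"RLM"`, `"GRA"`, `"ARM"`, `"WAV"`, `"GEO"`.
#' @return Character vector of feature names in canonical registry order.
#' @examples
#' length(feature_registry())        # 352
#' head(feature_registry("COM"))
#' @export
feature_registry <- function(family = NULL) {
  reg <- registry_table()
  if (!is.null(family)) {
    family <- match.arg(family, unique(reg$family), several.ok = TRUE)
    reg <- reg[reg$family %in% family, , drop = FALSE]
  }
  reg$name
}

#' Feature registry with family annotation
#'
#' @return A data frame with columns `name` and `family`, one row per
#'   registry feature, in canonical order.
#' @export
registry_table <- function() {
  if (!is.null(.registry_cache$tab)) return(.registry_cache$tab)
  his <- c("Mean", "Variance", "Skewness", "Kurtosis",
           "Perc.01%", "Perc.10%", "Perc.50%", "Perc.90%", "Perc.99%")
  com_stats <- c("AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDfMom",
                 "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc",
                 "DifEntrp")
  com <- unlist(lapply(1:5, function(d) {
    offs <- com_offsets(d)
    unlist(lapply(offs, function(o) {
      sprintf("S(%d,%d)%s", o[1], o[2], com_stats)
    }))
  }))
  rlm_stats <- c("ShrtREmp", "LngREmph", "GLevNonU", "RLNonUni", "Fraction")
  rlm <- unlist(lapply(rlm_directions(), function(d) paste0(d, "_", rlm_stats)))
  gra <- c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis", "GrNonZeros")
  arm <- c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma")
  wav <- unlist(lapply(1:5, function(s) {
    sprintf("WavEn%s_s-%d", c("LL", "LH", "HL", "HH"), s)
  }))
  tab <- data.frame(
    name = c(his, com, rlm, gra, arm, wav, geo_registry()),
    family = rep(c("HIS", "COM", "RLM", "GRA", "ARM", "WAV", "GEO"),
                 c(length(his), length(com), length(rlm), length(gra),
                   length(arm), length(wav), length(geo_registry()))),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(tab$name), nrow(tab) == 352L)
  .registry_cache$tab <- tab
  tab
}

.registry_cache <- new.env(parent = emptyenv())

# the four co-occurrence offsets (dx, dy) at inter-pixel distance d;
# y points down, so (d,-d) runs toward the upper right (the 45-degree ray)
com_offsets <- function(d) {
  list(c(0L, d), c(d, 0L), c(d, d), c(d, -d))
}

rlm_directions <- function() c("Horzl", "Vertl", "45dgr", "135dr")

# The 73-feature geometry registry. The family's composition (counts and the
# GeoW/GeoE naming for moment invariants and boundary harmonics) follows the
# MaZda-style shape-descriptor convention; each name maps to one documented
# formula in geo_features().
geo_registry <- function() {
  c(
    # global size / perimeter descriptors
    "GeoArea", "GeoPerimeter", "GeoCircularity", "GeoCompactness",
    "GeoNormPerim", "GeoEquivDiam", "GeoThickness", "GeoExtent",
    "GeoBBWidth", "GeoBBHeight", "GeoBBAspect",
    # Feret diameters
    "GeoFeretMax", "GeoFeretMin", "GeoFeretRatio", "GeoFeretMean",
    "GeoFeret0", "GeoFeret45", "GeoFeret90", "GeoFeret135",
    # principal-axis (second-moment) descriptors
    "GeoMajorAxis", "GeoMinorAxis", "GeoElongation", "GeoEccentricity",
    "GeoOrientation",
    # convexity
    "GeoConvexity", "GeoConvPerimRatio",
    # centroid radial-length statistics
    "GeoRadMean", "GeoRadSD", "GeoRadCV", "GeoRadMin", "GeoRadMax",
    "GeoRadRatio", "GeoRadSkewness", "GeoRadKurtosis", "GeoRadEntropy",
    "GeoRadAreaRatio", "GeoRadZeroCross",
    # symmetry overlap fractions
    "GeoSym180", "GeoSymMajor", "GeoSymMinor",
    # scale-normalized central moments, orders 2..4
    "GeoM20", "GeoM11", "GeoM02", "GeoM30", "GeoM21", "GeoM12", "GeoM03",
    "GeoM40", "GeoM31", "GeoM22", "GeoM13", "GeoM04",
    # rotation-invariant moment combinations (Hu 1..7, a third-order skew
    # invariant, and the fourth-order trace invariant)
    sprintf("GeoW%d", 1:9),
    # boundary radius Fourier amplitudes, harmonics 1..12, DC-normalized
    sprintf("GeoE%d", 1:12)
  )
}
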