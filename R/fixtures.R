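#' Bundled ferroptosis sub-pathway gene sets
#'
#' Five axes — overall ferroptosis (80-gene union), iron metabolism, lipid
#' peroxidation, antioxidant defense and the system Xc-/GSH/GPX4 axis — as a
#' best-effort *synthetic reconstruction* assembled from genes commonly
#' attributed to each axis in the ferroptosis literature. Memberships are an
#' editable GMT fixture (`ferroptosis_sets_synthetic.gmt`), never hard-coded:
#' pass your own curation (e.g. an exact FerrDb export) to any scoring
#' function instead when available.
#'
#' @return A [GeneSetCollection-class] of five sets whose names equal their
#'   categories.
#' @export
ferroptosisGeneSets <- function() {
  path <- system.file("extdata", "ferroptosis_sets_synthetic.gmt",
                      package = "ferroscope")
  cats <- setNames(
    c("iron_metabolism", "lipid_peroxidation", "antioxidant_defense",
      "gpx4_axis", "ferroptosis_all"),
    c("iron_metabolism", "lipid_peroxidation", "antioxidant_defense",
      "gpx4_axis", "ferroptosis_all"))
  readGMT(path, categories = cats,
          provenance = "bundled synthetic reconstruction")
}

#' Bundled transcription-factor regulons
#'
#' 23 ferroptosis-relevant transcription factors with synthetic target lists
#' (`tf_regulons_synthetic.gmt`); the GTRD-derived regulons used in real
#' analyses are user-supplied via [readGMT()].
#'
#' @return A [GeneSetCollection-class] with category `tf_regulon`.
#' @export
tfRegulons <- function() {
  path <- system.file("extdata", "tf_regulons_synthetic.gmt",
                      package = "ferroscope")
  col <- readGMT(path, provenance = "bundled synthetic regulons")
  col@sets <- lapply(col@sets, function(s) initialize(s, category = "tf_regulon"))
  col
}

#' Bundled immune cell-type signatures
#'
#' 19 immune cell-type signatures (synthetic member lists) for ssGSEA
#' deconvolution-style scoring.
#'
#' @return A [GeneSetCollection-class] with category `immune_signature`.
#' @export
immuneSignatures <- function() {
  path <- system.file("extdata", "immune_signatures_synthetic.gmt",
                      package = "ferroscope")
  col <- readGMT(path, provenance = "bundled synthetic immune signatures")
  col@sets <- lapply(col@sets, function(s)
    initialize(s, category = "immune_signature"))
  col
}

#' Bundled 16-gene prognostic signature (synthetic coefficients)
#'
#' A linear risk model over 16 ferroptosis genes with synthetic placeholder
#' coefficients (`signature_betas_synthetic.csv`); substitute fitted
#' coefficients via [readSignatureModel()] for real cohorts.
#'
#' @return A [SignatureModel-class].
#' @export
prognosticSignature <- function() {
  path <- system.file("extdata", "signature_betas_synthetic.csv",
                      package = "ferroscope")
  readSignatureModel(path, name = "ferroptosis16_synthetic",
                     note = "bundled synthetic coefficients")
}
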