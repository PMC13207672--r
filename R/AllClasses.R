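#' @import methods
#' @importFrom stats cor cor.test kruskal.test wilcox.test p.adjust pchisq pnorm
#'   pt quantile median rnorm runif rexp rbinom rnbinom sd setNames ave dist
#' @importFrom utils read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Recognised gene-set categories
#'
#' The five ferroptosis sub-pathway axes plus regulon/immune/other labels used
#' throughout the package.
#'
#' @export
GENE_SET_CATEGORIES <- c(
  "ferroptosis_all", "iron_metabolism", "lipid_peroxidation",
  "antioxidant_defense", "gpx4_axis", "tf_regulon", "immune_signature",
  "other"
)

#' GeneSet: a named, ordered set of gene symbols
#'
#' Gene symbols are compared case-sensitively after whitespace trimming;
#' iteration order is first-appearance order so downstream outputs are stable.
#'
#' @slot name set identifier, unique within a collection.
#' @slot category one of [GENE_SET_CATEGORIES].
#' @slot genes character vector of unique, non-empty gene symbols.
#' @slot description free text.
#' @export
setClass("GeneSet",
  representation(
    name = "character",
    category = "character",
    genes = "character",
    description = "character"
  ),
  prototype(category = "other", description = "")
)

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@genes) == 0L)
    msg <- c(msg, "gene set must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene symbols must be unique within a set")
  if (any(!nzchar(object@genes)))
    msg <- c(msg, "gene symbols must be non-empty strings")
  if (length(object@category) != 1L ||
      !object@category %in% GENE_SET_CATEGORIES)
    msg <- c(msg, sprintf(
      "'category' must be one of: %s",
      paste(GENE_SET_CATEGORIES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' GeneSetCollection: a registry of uniquely named gene sets
#'
#' @slot sets list of [GeneSet-class] objects, names matching each set's name.
#' @slot provenance free-text note on where the sets came from.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", provenance = "character"),
  prototype(sets = list(), provenance = "")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (!all(vapply(object@sets, is, logical(1), "GeneSet")))
      msg <- c(msg, "all elements of 'sets' must be GeneSet objects")
    else {
      nms <- vapply(object@sets, function(s) s@name, character(1))
      if (anyDuplicated(nms))
        msg <- c(msg, sprintf("duplicate set name(s): %s",
                              paste(unique(nms[duplicated(nms)]), collapse = ", ")))
      if (!identical(unname(nms), unname(names(object@sets))))
        msg <- c(msg, "list names must equal the set names")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScoreTable: per-observation signature scores
#'
#' @slot scores numeric matrix, observations in rows, signatures in columns.
#' @slot method scoring method tag, "module_score" or "ssgsea".
#' @slot params list of the parameters used (bins, control size, tau, seed...).
#' @export
setClass("ScoreTable",
  representation(scores = "matrix", method = "character", params = "list"),
  prototype(method = "module_score", params = list())
)

setValidity("ScoreTable", function(object) {
  msg <- character()
  if (!is.numeric(object@scores))
    msg <- c(msg, "'scores' must be numeric")
  if (is.null(colnames(object@scores)) && ncol(object@scores) > 0L)
    msg <- c(msg, "'scores' must have signature column names")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (!object@method %in% c("module_score", "ssgsea"))
    msg <- c(msg, "'method' must be 'module_score' or 'ssgsea'")
  if (length(msg)) msg else TRUE
})

#' CorrelationWeights: genome-wide correlation of genes with one regulator
#'
#' Holds the per-gene Spearman rho with the regulator, raw and BH-adjusted
#' p-values, and the significance mask (|rho| > rhoMin AND p < pMax, strict
#' inequalities, raw p). The regulator itself is excluded.
#'
#' @slot regulator regulator gene symbol.
#' @slot rho named numeric, per-gene rho (NA where undefined).
#' @slot p named numeric, raw two-sided p-values.
#' @slot pAdj named numeric, BH-adjusted p-values (reported, not used in mask).
#' @slot mask named logical; FALSE wherever rho or p is undefined.
#' @slot rhoMin,pMax the thresholds used.
#' @export
setClass("CorrelationWeights",
  representation(
    regulator = "character", rho = "numeric", p = "numeric",
    pAdj = "numeric", mask = "logical", rhoMin = "numeric", pMax = "numeric"
  )
)

setValidity("CorrelationWeights", function(object) {
  msg <- character()
  n <- length(object@rho)
  if (length(object@p) != n || length(object@mask) != n ||
      length(object@pAdj) != n)
    msg <- c(msg, "rho, p, pAdj and mask must have equal length")
  if (object@regulator %in% names(object@rho))
    msg <- c(msg, "regulator must be excluded from the weight vector")
  if (any(object@mask & (is.na(object@rho) | is.na(object@p))))
    msg <- c(msg, "mask must be FALSE where rho or p is undefined")
  if (length(msg)) msg else TRUE
})

#' KOResult: per-observation virtual-knockout deltas and derived summaries
#'
#' A negative delta is a predicted suppression of the ferroptosis score upon
#' regulator loss.
#'
#' @slot delta named numeric, overall KO delta per observation.
#' @slot axisDelta numeric matrix, observations x ferroptosis axes (may have
#'   zero columns when no axis had masked genes).
#' @slot responder character per observation, one of "high", "mid", "low", or
#'   NA before classification.
#' @slot cellTypeTable data.frame of per-type mean deltas (after aggregation).
#' @slot markers data.frame of responder marker statistics.
#' @slot params list (regulator, masked gene count, thresholds...).
#' @export
setClass("KOResult",
  representation(
    delta = "numeric", axisDelta = "matrix", responder = "character",
    cellTypeTable = "data.frame", markers = "data.frame", params = "list"
  ),
  prototype(
    responder = NA_character_,
    cellTypeTable = data.frame(), markers = data.frame(), params = list()
  )
)

setValidity("KOResult", function(object) {
  msg <- character()
  n <- length(object@delta)
  if (nrow(object@axisDelta) > 0L && nrow(object@axisDelta) != n)
    msg <- c(msg, "axisDelta rows must match delta length")
  if (!all(is.na(object@responder)) && length(object@responder) != n)
    msg <- c(msg, "responder labels must match delta length")
  if (length(msg)) msg else TRUE
})

#' SignatureModel: a linear gene signature (gene -> coefficient)
#'
#' @slot beta named numeric vector of coefficients, names are gene symbols.
#' @slot name model name.
#' @slot note free-text provenance note.
#' @export
setClass("SignatureModel",
  representation(beta = "numeric", name = "character", note = "character"),
  prototype(name = "signature", note = "")
)

setValidity("SignatureModel", function(object) {
  msg <- character()
  if (length(object@beta) == 0L)
    msg <- c(msg, "signature must be non-empty")
  if (is.null(names(object@beta)) || any(!nzchar(names(object@beta))))
    msg <- c(msg, "coefficients must be named by gene symbol")
  if (anyDuplicated(names(object@beta)))
    msg <- c(msg, "duplicate genes in signature")
  if (length(msg)) msg else TRUE
})

setOldClass("igraph")

#' SpatialFerro: a spatial transcriptomics dataset
#'
#' Extends \linkS4class{SummarizedExperiment}: genes in rows, spots in
#' columns; colData carries `x`, `y` array coordinates and optional `region`
#' and `cluster` labels; the symmetrised k-nearest-neighbour graph, when
#' built, lives in `metadata(x)$graph`.
#'
#' @export
setClass("SpatialFerro", contains = "SummarizedExperiment")

setValidity("SpatialFerro", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("x", "y") %in% colnames(cd)))
    msg <- c(msg, "colData must contain spot coordinates 'x' and 'y'")
  else if (anyDuplicated(paste(cd$x, cd$y, sep = "_")))
    msg <- c(msg, "spot coordinates must be unique")
  if (length(msg)) msg else TRUE
})
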