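#' @rdname GeneSet-accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))

#' @rdname GeneSet-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneSet-accessors
#' @export
setGeneric("setCategory", function(x) standardGeneric("setCategory"))

#' @rdname GeneSetCollection-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-accessors
#' @export
setGeneric("setsByCategory", function(x, category)
  standardGeneric("setsByCategory"))

#' @rdname ScoreTable-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname ScoreTable-accessors
#' @export
setGeneric("scoreMethod", function(x) standardGeneric("scoreMethod"))

#' @rdname ScoreTable-accessors
#' @export
setGeneric("scoreParams", function(x) standardGeneric("scoreParams"))

#' @rdname KOResult-accessors
#' @export
setGeneric("koDelta", function(x) standardGeneric("koDelta"))

#' @rdname KOResult-accessors
#' @export
setGeneric("koAxisDelta", function(x) standardGeneric("koAxisDelta"))

#' @rdname KOResult-accessors
#' @export
setGeneric("responderLabels", function(x) standardGeneric("responderLabels"))

#' @rdname CorrelationWeights-accessors
#' @export
setGeneric("weightMask", function(x) standardGeneric("weightMask"))

#' @rdname CorrelationWeights-accessors
#' @export
setGeneric("maskedWeights", function(x) standardGeneric("maskedWeights"))

#' @rdname SpatialFerro-accessors
#' @export
setGeneric("spotCoords", function(x) standardGeneric("spotCoords"))

#' @rdname SpatialFerro-accessors
#' @export
setGeneric("spotGraph", function(x) standardGeneric("spotGraph"))
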