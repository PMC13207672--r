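#' Regulatory-target significance mask
#'
#' A gene is designated a regulatory target when `|rho| > rhoMin` AND
#' `p < pMax`, both strict; undefined rho or p never passes.
#'
#' @param rho,p numeric vectors of equal length.
#' @param rhoMin,pMax thresholds (defaults 0.1 and 0.05).
#' @return logical vector.
#' @export
significanceMask <- function(rho, p, rhoMin = 0.1, pMax = 0.05) {
  stopifnot(length(rho) == length(p))
  out <- !is.na(rho) & !is.na(p) & abs(rho) > rhoMin & p < pMax
  names(out) <- names(rho)
  out
}

#' Genome-wide correlation weights for a regulator
#'
#' Spearman correlation of the regulator's expression with every other gene
#' across observations, with the t-approximation p-value (n - 2 df). The
#' significance mask keeps genes with `|rho| > rhoMin` AND raw `p < pMax`
#' (strict inequalities); BH-adjusted p-values are reported alongside but do
#' not enter the mask. Zero-variance genes get undefined rho and are never
#' masked.
#'
#' @param x lognorm matrix or SummarizedExperiment with a `lognorm` assay.
#' @param regulator regulator gene symbol (must be detected with nonzero
#'   variance).
#' @param rhoMin correlation magnitude threshold (default 0.1).
#' @param pMax raw p-value threshold (default 0.05).
#' @return A [CorrelationWeights-class].
#' @export
correlationWeights <- function(x, regulator, rhoMin = 0.1, pMax = 0.05) {
  m <- getLognorm(x)
  if (!regulator %in% rownames(m))
    stop("regulator '", regulator, "' not detected in the matrix")
  n <- ncol(m)
  if (n < 3L) stop("need at least 3 observations")
  regExpr <- m[regulator, ]
  if (sd(regExpr) == 0) stop("regulator has zero variance")
  others <- m[setdiff(rownames(m), regulator), , drop = FALSE]
  regRank <- rank(regExpr)
  geneRanks <- t(apply(others, 1, rank))
  sds <- apply(geneRanks, 1, sd)
  rho <- rep(NA_real_, nrow(others))
  ok <- sds > 0
  rho[ok] <- drop(cor(t(geneRanks[ok, , drop = FALSE]), regRank))
  names(rho) <- rownames(others)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  names(p) <- names(rho)
  mask <- significanceMask(rho, p, rhoMin, pMax)
  pAdj <- bhAdjust(p)
  names(pAdj) <- names(rho)
  new("CorrelationWeights", regulator = regulator, rho = rho, p = p,
      pAdj = pAdj, mask = mask, rhoMin = rhoMin, pMax = pMax)
}

#' @describeIn CorrelationWeights-accessors the significance mask
#' @param x a CorrelationWeights
#' @name CorrelationWeights-accessors
#' @aliases weightMask maskedWeights
#' @export
setMethod("weightMask", "CorrelationWeights", function(x) x@mask)

#' @rdname CorrelationWeights-accessors
#' @export
setMethod("maskedWeights", "CorrelationWeights", function(x) {
  w <- ifelse(x@mask, x@rho, 0)
  w[is.na(w)] <- 0
  names(w) <- names(x@rho)
  w
})

setMethod("show", "CorrelationWeights", function(object) {
  cat(sprintf(
    "CorrelationWeights for %s: %d gene(s), %d masked (|rho| > %g, p < %g)\n",
    object@regulator, length(object@rho), sum(object@mask),
    object@rhoMin, object@pMax))
})

#' Virtual-knockout deltas per observation
#'
#' The predicted ferroptosis score change upon regulator loss: for each
#' observation, the negated dot product of its (per-gene standardized)
#' expression with the masked correlation weights, divided by the number of
#' masked genes. Negation encodes loss of the regulator, so a negative delta
#' is a predicted suppression of ferroptosis. Per-axis deltas apply the same
#' formula restricted to masked genes inside each ferroptosis axis set.
#'
#' @param x lognorm matrix or SummarizedExperiment with a `lognorm` assay
#'   (same gene universe the weights were computed on).
#' @param weights a [CorrelationWeights-class].
#' @param sets a [GeneSetCollection-class] of ferroptosis axes (per-axis
#'   deltas are computed for every set whose category is not `tf_regulon` /
#'   `immune_signature`).
#' @param zscore standardize each gene across observations before the dot
#'   product (default TRUE, so genes contribute on comparable scales); FALSE
#'   uses the lognorm values directly.
#' @param normalizeByM divide by the masked-gene count (default TRUE, making
#'   deltas comparable across axes of different size).
#' @return A [KOResult-class] with per-observation overall and per-axis
#'   deltas.
#' @export
koDeltas <- function(x, weights, sets = ferroptosisGeneSets(),
                     zscore = TRUE, normalizeByM = TRUE) {
  m <- getLognorm(x)
  stopifnot(is(weights, "CorrelationWeights"))
  w <- maskedWeights(weights)
  common <- intersect(names(w), rownames(m))
  if (length(common) < length(w))
    warning(length(w) - length(common),
            " weighted gene(s) absent from the matrix")
  masked <- common[weights@mask[common]]
  if (length(masked) == 0L)
    stop("no masked target genes; nothing to perturb")
  z <- m[masked, , drop = FALSE]
  if (zscore) {
    mu <- rowMeans(z)
    sdv <- apply(z, 1, sd)
    sdv[sdv == 0] <- 1
    z <- (z - mu) / sdv
  }
  proj <- function(genes) {
    gg <- intersect(genes, masked)
    if (length(gg) == 0L) return(NULL)
    denom <- if (normalizeByM) length(gg) else 1
    -drop(crossprod(z[gg, , drop = FALSE], w[gg])) / denom
  }
  delta <- proj(masked)
  names(delta) <- colnames(m)
  axes <- Filter(function(s)
    !setCategory(s) %in% c("tf_regulon", "immune_signature"), geneSets(sets))
  axisCols <- list()
  for (s in axes) {
    d <- proj(geneIds(s))
    if (is.null(d)) {
      warning("axis '", setName(s), "' has no masked genes; delta absent")
    } else axisCols[[setName(s)]] <- d
  }
  axisDelta <- if (length(axisCols))
    do.call(cbind, axisCols) else matrix(numeric(0), nrow = 0, ncol = 0)
  if (length(axisCols)) rownames(axisDelta) <- colnames(m)
  new("KOResult", delta = delta, axisDelta = axisDelta,
      responder = rep(NA_character_, length(delta)),
      params = list(regulator = weights@regulator, nMasked = length(masked),
                    rhoMin = weights@rhoMin, pMax = weights@pMax,
                    zscore = zscore, normalizeByM = normalizeByM))
}

#' @describeIn KOResult-accessors overall delta per observation
#' @param x a KOResult
#' @name KOResult-accessors
#' @aliases koDelta koAxisDelta responderLabels
#' @export
setMethod("koDelta", "KOResult", function(x) x@delta)

#' @rdname KOResult-accessors
#' @export
setMethod("koAxisDelta", "KOResult", function(x) x@axisDelta)

#' @rdname KOResult-accessors
#' @export
setMethod("responderLabels", "KOResult", function(x) x@responder)

setMethod("show", "KOResult", function(object) {
  cat(sprintf("KOResult (%s): %d observation(s), %d masked gene(s)\n",
              object@params$regulator %||% "?", length(object@delta),
              object@params$nMasked %||% NA))
  if (ncol(object@axisDelta))
    cat("  axes:", paste(colnames(object@axisDelta), collapse = ", "), "\n")
  if (!all(is.na(object@responder)))
    cat("  responders:", sum(object@responder == "high"), "high /",
        sum(object@responder == "low"), "low\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate KO deltas by cell type
#'
#' Mean delta and cell count per label; labels with fewer than `minCells`
#' observations are excluded from the table and reported in the `excluded`
#' attribute.
#'
#' @param result a [KOResult-class].
#' @param labels cell-type label per observation, aligned with the deltas.
#' @param minCells minimum observations per reported type (default 5,
#'   inclusive).
#' @return data.frame: cell_type, n, mean_delta; excluded labels in
#'   `attr(, "excluded")`.
#' @export
aggregateByCellType <- function(result, labels, minCells = 5) {
  stopifnot(is(result, "KOResult"))
  delta <- result@delta
  if (length(labels) != length(delta))
    stop("labels must align with the observations")
  counts <- table(labels)
  means <- tapply(delta, labels, mean)
  tab <- data.frame(cell_type = names(counts), n = as.integer(counts),
                    mean_delta = as.numeric(means[names(counts)]))
  keep <- tab$n >= minCells
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- tab$cell_type[!keep]
  out
}

#' Classify high/mid/low KO responders by delta quartile
#'
#' High responders lie at or above the 75th percentile of the KO delta, low
#' responders at or below the 25th (percentiles by linear interpolation;
#' ties at a threshold fall on the extreme side), the remainder are mid.
#'
#' @param result a [KOResult-class] with >= 8 observations.
#' @return The [KOResult-class] with responder labels filled in.
#' @export
classifyResponders <- function(result) {
  stopifnot(is(result, "KOResult"))
  delta <- result@delta
  if (length(delta) < 8L) stop("need at least 8 observations")
  if (length(unique(delta)) == 1L)
    stop("degenerate: all deltas identical")
  q <- quantile(delta, c(0.25, 0.75), type = 7, names = FALSE)
  lab <- ifelse(delta >= q[2], "high", ifelse(delta <= q[1], "low", "mid"))
  initialize(result, responder = lab)
}

#' Marker genes separating high from low KO responders
#'
#' Per gene, a tie-corrected normal-approximation Mann-Whitney test between
#' high and low responders with BH correction across genes; direction is
#' the sign of the median difference (high - low).
#'
#' @param x lognorm matrix or SummarizedExperiment with a `lognorm` assay.
#' @param labeled a [KOResult-class] after [classifyResponders()].
#' @return data.frame: gene, statistic, p_value, p_adjusted, direction,
#'   ordered by p-value.
#' @export
responderMarkers <- function(x, labeled) {
  m <- getLognorm(x)
  stopifnot(is(labeled, "KOResult"))
  lab <- labeled@responder
  if (all(is.na(lab))) stop("run classifyResponders() first")
  if (length(lab) != ncol(m))
    stop("labels must align with the matrix observations")
  ih <- which(lab == "high"); il <- which(lab == "low")
  if (length(ih) == 0L || length(il) == 0L)
    stop("empty responder class")
  mw <- rowMannWhitney(m, ih, il)
  dirn <- apply(m[, ih, drop = FALSE], 1, median) -
    apply(m[, il, drop = FALSE], 1, median)
  out <- data.frame(gene = rownames(m), statistic = mw$statistic,
                    p_value = mw$p, p_adjusted = bhAdjust(mw$p),
                    direction = sign(dirn))
  out <- out[order(out$p_value, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Run the full virtual-knockout procedure
#'
#' Convenience wrapper: correlation weights, KO deltas, cell-type
#' aggregation, responder classification and responder markers in one call.
#'
#' @param x lognorm matrix or SummarizedExperiment with a `lognorm` assay.
#' @param regulator regulator gene symbol.
#' @param sets ferroptosis axis collection (default the bundled fixture).
#' @param cellTypes optional cell-type labels (taken from colData
#'   `cell_type` when `x` is a SummarizedExperiment).
#' @param rhoMin,pMax mask thresholds (see [correlationWeights()]).
#' @param minCells minimum cells per aggregated type (default 5).
#' @param markers also compute responder markers (default TRUE).
#' @return A list: `weights`, `result` (labeled [KOResult-class]),
#'   `cellTypeTable`, `markers`.
#' @export
virtualKO <- function(x, regulator, sets = ferroptosisGeneSets(),
                      cellTypes = NULL, rhoMin = 0.1, pMax = 0.05,
                      minCells = 5, markers = TRUE) {
  if (is.null(cellTypes) && is(x, "SummarizedExperiment") &&
      "cell_type" %in% colnames(SummarizedExperiment::colData(x)))
    cellTypes <- SummarizedExperiment::colData(x)$cell_type
  w <- correlationWeights(x, regulator, rhoMin = rhoMin, pMax = pMax)
  res <- koDeltas(x, w, sets = sets)
  res <- classifyResponders(res)
  ctt <- if (!is.null(cellTypes))
    aggregateByCellType(res, cellTypes, minCells = minCells) else NULL
  mk <- if (markers) responderMarkers(x, res) else NULL
  list(weights = w, result = res, cellTypeTable = ctt, markers = mk)
}
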