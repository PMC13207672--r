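# Extract the log-normalized expression matrix from supported inputs.
# A plain matrix is taken to already be on the lognorm scale.
getLognorm <- function(x) {
  if (is.matrix(x)) return(x)
  if (is(x, "SummarizedExperiment")) {
    if (!"lognorm" %in% SummarizedExperiment::assayNames(x))
      stop("no 'lognorm' assay present; run normalizeLogNorm() first")
    return(as.matrix(SummarizedExperiment::assay(x, "lognorm")))
  }
  stop("expected a matrix or SummarizedExperiment")
}

#' Library-size log-normalization
#'
#' Scales each observation to a common total, then log-transforms:
#' `ln(1 + count / total * scaleTarget)`. Adds a `lognorm` assay.
#'
#' @param x a \linkS4class{SummarizedExperiment} with a `counts` assay (and
#'   no `lognorm` assay yet), or a non-negative count matrix.
#' @param scaleTarget common total after scaling (default 1e4).
#' @return Same class as `x`, with the normalized layer added (for a matrix
#'   input, the normalized matrix).
#' @export
normalizeLogNorm <- function(x, scaleTarget = 1e4) {
  if (is(x, "SummarizedExperiment")) {
    if ("lognorm" %in% SummarizedExperiment::assayNames(x))
      stop("wrong layer: 'lognorm' assay already present")
    if (!"counts" %in% SummarizedExperiment::assayNames(x))
      stop("wrong layer: no 'counts' assay to normalize")
    counts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
  } else counts <- as.matrix(x)
  if (any(counts < 0)) stop("wrong layer: negative values in counts")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop("observation(s) with zero total count: ",
         paste(bad, collapse = ", "))
  }
  ln <- log1p(sweep(counts, 2, tot, "/") * scaleTarget)
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "lognorm") <- ln
    x
  } else ln
}

#' Binned-control module score
#'
#' The single-cell module score of a gene set: genes are binned by average
#' expression across observations; each set gene draws expression-matched
#' control genes from its bin (excluding set genes); the score of an
#' observation is the mean expression of the set genes minus the mean of the
#' pooled controls. Control sampling is fixed-seed deterministic.
#'
#' @param x lognorm matrix or SummarizedExperiment with a `lognorm` assay.
#' @param set a [GeneSet-class].
#' @param nBins number of average-expression bins (default 25).
#' @param nCtrl controls sampled per set gene (default 50); if a bin pool has
#'   at most `nCtrl` candidates the whole pool is used.
#' @param seed integer seed for control sampling.
#' @return Named numeric vector, one score per observation.
#' @export
moduleScore <- function(x, set, nBins = 25, nCtrl = 50, seed = 1L) {
  m <- getLognorm(x)
  if (nBins < 1) stop("nBins must be >= 1")
  stopifnot(is(set, "GeneSet"))
  setGenes <- intersect(geneIds(set), rownames(m))
  if (length(setGenes) == 0L)
    stop("no gene of set '", setName(set), "' detected in the matrix")
  avg <- rowMeans(m)
  nBinsEff <- min(nBins, nrow(m))
  bin <- ceiling(rank(avg, ties.method = "first") / (nrow(m) / nBinsEff))
  names(bin) <- rownames(m)
  notSet <- setdiff(rownames(m), geneIds(set))
  ctrl <- withSeed(seed, {
    picked <- character(0)
    for (gn in setGenes) {
      b <- bin[[gn]]
      pool <- notSet[bin[notSet] == b]
      if (length(pool) == 0L) {
        # fall back to the nearest bin that has candidates
        warning("empty control pool in bin ", b, "; using nearest bin")
        dists <- abs(bin[notSet] - b)
        pool <- notSet[dists == min(dists)]
      }
      picked <- c(picked,
                  if (length(pool) <= nCtrl) pool else sample(pool, nCtrl))
    }
    unique(picked)
  })
  if (length(ctrl) == 0L) stop("no control genes available")
  setMean <- colMeans(m[setGenes, , drop = FALSE])
  ctrlMean <- colMeans(m[ctrl, , drop = FALSE])
  setMean - ctrlMean
}

# Shared per-column machinery for ssGSEA: returns for one expression vector
# the descending order (symbol tie-break) and the tie-averaged bottom-up
# rank weights r = N - position + 1 aligned to that order.
ssgseaRankWalk <- function(expr, symbols) {
  ord <- order(-expr, symbols)
  n <- length(expr)
  rRaw <- seq(n, 1)
  # average the weights within runs of tied expression values
  r <- ave(rRaw, match(expr[ord], unique(expr[ord])), FUN = mean)
  list(ord = ord, r = r)
}

# ES for one observation given the precomputed walk and set membership.
ssgseaES <- function(walk, inSet, tau) {
  inS <- inSet[walk$ord]
  w <- walk$r^tau * inS
  denom <- sum(w)
  pin <- cumsum(w) / denom
  pout <- cumsum(!inS) / sum(!inS)
  sum(pin - pout)
}

#' Single-sample GSEA score
#'
#' Rank-weighted ECDF-difference enrichment per observation: genes are ranked
#' by expression (descending; ties get average rank weights, walk order broken
#' deterministically by symbol); the statistic is the running sum of the
#' weighted in-set ECDF minus the out-of-set ECDF, summed over all positions.
#'
#' @param x lognorm matrix or SummarizedExperiment with a `lognorm` assay.
#' @param set a [GeneSet-class]; only detected genes are used and at least
#'   one must be detected but not all genes may belong to the set.
#' @param tau rank-weight exponent (>= 0, default 0.25).
#' @param normalize divide all scores by (max - min) across observations
#'   (default TRUE).
#' @return Named numeric vector, one enrichment score per observation.
#' @export
ssgseaScore <- function(x, set, tau = 0.25, normalize = TRUE) {
  st <- ssgseaTable(x, GeneSetCollection(list(set)), tau = tau,
                    normalize = normalize)
  scoreMatrix(st)[, 1]
}

# Score every set of a collection per observation in one pass over columns.
ssgseaTable <- function(x, collection, tau = 0.25, normalize = TRUE) {
  m <- getLognorm(x)
  if (tau < 0) stop("tau must be >= 0")
  n <- nrow(m)
  symbols <- rownames(m)
  memberships <- lapply(geneSets(collection), function(s) {
    inS <- symbols %in% geneIds(s)
    k <- sum(inS)
    if (k == 0L) stop("no gene of set '", setName(s), "' detected")
    if (k == n) stop("set '", setName(s), "' covers all genes (empty complement)")
    inS
  })
  es <- matrix(NA_real_, nrow = ncol(m), ncol = length(memberships),
               dimnames = list(colnames(m), names(geneSets(collection))))
  for (j in seq_len(ncol(m))) {
    walk <- ssgseaRankWalk(m[, j], symbols)
    es[j, ] <- vapply(memberships, ssgseaES, numeric(1),
                      walk = walk, tau = tau)
  }
  if (normalize) {
    # per-signature range across observations; a monotone rescaling only
    rng <- apply(es, 2, function(v) diff(range(v)))
    rng[rng == 0] <- 1
    es <- sweep(es, 2, rng, "/")
  }
  new("ScoreTable", scores = es, method = "ssgsea",
      params = list(tau = tau, normalize = normalize))
}

#' Score a whole collection into a ScoreTable
#'
#' Applies [moduleScore()] or ssGSEA to every set of a collection, one score
#' column per signature.
#'
#' @param x lognorm matrix or SummarizedExperiment with a `lognorm` assay.
#' @param collection a [GeneSetCollection-class].
#' @param method `"module"` (binned-control score) or `"ssgsea"`.
#' @param nBins,nCtrl,seed module-score parameters (see [moduleScore()]).
#' @param tau,normalize ssGSEA parameters (see [ssgseaScore()]).
#' @return A [ScoreTable-class], observations x signatures.
#' @export
scoreCollection <- function(x, collection, method = c("module", "ssgsea"),
                            nBins = 25, nCtrl = 50, seed = 1L,
                            tau = 0.25, normalize = TRUE) {
  method <- match.arg(method)
  stopifnot(is(collection, "GeneSetCollection"))
  if (length(collection) == 0L) stop("empty collection")
  if (method == "ssgsea")
    return(ssgseaTable(x, collection, tau = tau, normalize = normalize))
  cols <- lapply(geneSets(collection), function(s)
    moduleScore(x, s, nBins = nBins, nCtrl = nCtrl, seed = seed))
  scores <- do.call(cbind, cols)
  colnames(scores) <- names(geneSets(collection))
  new("ScoreTable", scores = scores, method = "module_score",
      params = list(nBins = nBins, nCtrl = nCtrl, seed = seed))
}

#' @describeIn ScoreTable-accessors the observation x signature matrix
#' @param x a ScoreTable
#' @name ScoreTable-accessors
#' @aliases scoreMatrix scoreMethod scoreParams
#' @export
setMethod("scoreMatrix", "ScoreTable", function(x) x@scores)

#' @rdname ScoreTable-accessors
#' @export
setMethod("scoreMethod", "ScoreTable", function(x) x@method)

#' @rdname ScoreTable-accessors
#' @export
setMethod("scoreParams", "ScoreTable", function(x) x@params)

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable (%s): %d observation(s) x %d signature(s)\n",
              object@method, nrow(object@scores), ncol(object@scores)))
  if (ncol(object@scores))
    cat("  signatures:", paste(head(colnames(object@scores), 6),
                               collapse = ", "),
        if (ncol(object@scores) > 6) "..." else "", "\n")
})
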