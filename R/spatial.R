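#' Construct a SpatialFerro dataset
#'
#' @param counts gene x spot count matrix.
#' @param coords data.frame with columns `x`, `y` (array units), one row per
#'   spot, optional `region`.
#' @return A [SpatialFerro-class].
#' @export
SpatialFerro <- function(counts, coords) {
  stopifnot(nrow(coords) == ncol(counts))
  cd <- S4Vectors::DataFrame(coords, row.names = colnames(counts))
  new("SpatialFerro", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd))
}

#' @describeIn SpatialFerro-accessors spot coordinate data.frame
#' @param x a SpatialFerro
#' @name SpatialFerro-accessors
#' @aliases spotCoords spotGraph
#' @export
setMethod("spotCoords", "SpatialFerro", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(spot_id = rownames(cd), x = cd$x, y = cd$y)
})

#' @rdname SpatialFerro-accessors
#' @export
setMethod("spotGraph", "SpatialFerro", function(x)
  S4Vectors::metadata(x)$graph)

#' Per-spot ferroptosis axis scores
#'
#' Applies the binned-control module score spot-wise for each axis — the
#' same numerics as single-cell scoring (one shared code path).
#'
#' @param sp a [SpatialFerro-class] with a `lognorm` assay.
#' @param sets a [GeneSetCollection-class] (default the five bundled axes).
#' @param ... passed to [scoreCollection()].
#' @return A [ScoreTable-class], spots x axes.
#' @export
spotScores <- function(sp, sets = ferroptosisGeneSets(), ...) {
  stopifnot(is(sp, "SpatialFerro"))
  scoreCollection(sp, sets, method = "module", ...)
}

#' Build the spatial k-nearest-neighbour graph
#'
#' Each spot is connected to its k nearest Euclidean neighbours in array
#' coordinates; edges are symmetrised by union, so every node has degree
#' >= k. Distance ties are broken deterministically by spot ID order. The
#' graph is invariant under rigid transforms of the coordinates.
#'
#' @param sp a [SpatialFerro-class] with >= k + 1 spots.
#' @param k neighbours per spot (default 6).
#' @return The dataset with the graph stored in `metadata(sp)$graph`.
#' @export
buildKnnGraph <- function(sp, k = 6) {
  stopifnot(is(sp, "SpatialFerro"))
  validObject(sp)
  cd <- SummarizedExperiment::colData(sp)
  n <- nrow(cd)
  if (n < k + 1) stop("need at least k + 1 spots")
  xy <- cbind(cd$x, cd$y)
  d <- as.matrix(dist(xy))
  ids <- rownames(cd)
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))   # ties broken by spot ID order
    nb <- setdiff(ord, i)[seq_len(k)]
    edges[[i]] <- cbind(i, nb)
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- ids
  S4Vectors::metadata(sp)$graph <- g
  S4Vectors::metadata(sp)$k <- k
  sp
}

#' Cluster the spot graph
#'
#' Seeded multilevel greedy modularity maximisation (Louvain) over the kNN
#' graph — a deterministic community-detection contract under a fixed seed.
#' Precomputed labels can be injected instead via the `labels` argument
#' (e.g. output of an external Leiden run).
#'
#' @param sp a [SpatialFerro-class] after [buildKnnGraph()].
#' @param seed integer seed (the greedy merge itself is deterministic; the
#'   seed is accepted for interface stability).
#' @param labels optional externally computed cluster labels, one per spot.
#' @return The dataset with integer cluster labels (contiguous, starting at
#'   1) in `colData(sp)$cluster`.
#' @export
clusterGraph <- function(sp, seed = 1L, labels = NULL) {
  stopifnot(is(sp, "SpatialFerro"))
  if (!is.null(labels)) {
    if (length(labels) != ncol(sp)) stop("labels must have one entry per spot")
    lab <- as.integer(factor(labels))
  } else {
    g <- spotGraph(sp)
    if (is.null(g)) stop("no graph; run buildKnnGraph() first")
    if (igraph::vcount(g) == 0L) stop("empty graph")
    comm <- withSeed(seed, igraph::cluster_louvain(g))
    lab <- as.integer(factor(igraph::membership(comm)))
  }
  SummarizedExperiment::colData(sp)$cluster <- lab
  sp
}

#' Test score heterogeneity across spatial clusters or regions
#'
#' Kruskal-Wallis test of a score column across label groups, with per-label
#' medians reported.
#'
#' @param scores numeric score per spot (e.g. one [spotScores()] column).
#' @param labels cluster or region label per spot (>= 2 distinct labels).
#' @return A `TestResult` with a `medians` element (named per-label medians).
#' @export
clusterScoreTest <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must align")
  labs <- unique(labels)
  if (length(labs) < 2L) stop("need at least 2 labels")
  groups <- split(as.numeric(scores), labels)
  res <- kruskalWallis(groups)
  res$medians <- vapply(groups, median, numeric(1))
  res
}
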