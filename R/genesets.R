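#' Construct a GeneSet
#'
#' Symbols are trimmed of surrounding whitespace and deduplicated preserving
#' first occurrence; comparison is case-sensitive (alias resolution is a user
#' concern, not attempted here).
#'
#' @param name set identifier.
#' @param genes character vector of gene symbols.
#' @param category one of [GENE_SET_CATEGORIES]; default `"other"`.
#' @param description free text.
#' @return A [GeneSet-class].
#' @examples
#' gs <- GeneSet("gpx4_axis_demo", c("GPX4", "SLC7A11", "GSS"), "gpx4_axis")
#' geneIds(gs)
#' @export
GeneSet <- function(name, genes, category = "other", description = "") {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  genes <- genes[!duplicated(genes)]
  new("GeneSet", name = as.character(name), genes = genes,
      category = category, description = as.character(description))
}

#' Construct a GeneSetCollection
#'
#' @param sets a list of [GeneSet-class] objects.
#' @param provenance free-text note.
#' @return A [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets = list(), provenance = "") {
  names(sets) <- vapply(sets, function(s) s@name, character(1))
  new("GeneSetCollection", sets = sets, provenance = provenance)
}

#' @describeIn GeneSet-accessors set identifier
#' @param x a GeneSet
#' @name GeneSet-accessors
#' @aliases setName geneIds setCategory
#' @export
setMethod("setName", "GeneSet", function(x) x@name)

#' @rdname GeneSet-accessors
#' @export
setMethod("geneIds", "GeneSet", function(x) x@genes)

#' @rdname GeneSet-accessors
#' @export
setMethod("setCategory", "GeneSet", function(x) x@category)

setMethod("length", "GeneSet", function(x) length(x@genes))

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' [%s], %d genes\n", object@name,
              object@category, length(object@genes)))
  g <- object@genes
  cat("  ", paste(head(g, 8), collapse = ", "),
      if (length(g) > 8) ", ..." else "", "\n", sep = "")
})

#' @describeIn GeneSetCollection-accessors the list of sets
#' @param x a GeneSetCollection
#' @param category a category string
#' @name GeneSetCollection-accessors
#' @aliases geneSets setsByCategory
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-accessors
#' @export
setMethod("setsByCategory", "GeneSetCollection", function(x, category) {
  keep <- vapply(x@sets, function(s) s@category %in% category, logical(1))
  x@sets[keep]
})

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection with %d set(s)\n", length(object@sets)))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
  for (s in head(object@sets, 10))
    cat(sprintf("  %s [%s]: %d genes\n", s@name, s@category, length(s@genes)))
  if (length(object@sets) > 10) cat("  ...\n")
})

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then gene symbols, tab-separated.
#' Duplicate symbols within a line are deduplicated preserving first
#' occurrence. Categories default to `"other"`; pass a category map
#' (`set_name,category` CSV or a named character vector) to override.
#'
#' @param path path to a GMT file.
#' @param categories optional named character vector mapping set name to
#'   category, or a path to a two-column CSV `set_name,category`.
#' @param provenance stored in the collection; defaults to the file path.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path, categories = NULL, provenance = path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  if (is.character(categories) && length(categories) == 1L &&
      file.exists(categories) && is.null(names(categories))) {
    map <- read.csv(categories, stringsAsFactors = FALSE)
    categories <- setNames(map[[2]], map[[1]])
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- c(fields[1:2], fields[-(1:2)][nzchar(fields[-(1:2)])])
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: expected >=3 tab-separated fields", i))
    nm <- fields[1]
    cat_i <- if (!is.null(categories) && nm %in% names(categories))
      categories[[nm]] else "other"
    sets[[i]] <- GeneSet(nm, fields[-(1:2)], category = cat_i,
                         description = fields[2])
  }
  nms <- vapply(sets, setName, character(1))
  if (anyDuplicated(nms))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  GeneSetCollection(sets, provenance = provenance)
}

#' Write a collection to a GMT file
#'
#' Round-trips losslessly through [readGMT()] for names and memberships.
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  validObject(collection)
  for (s in collection@sets) validObject(s)
  desc <- vapply(collection@sets, function(s)
    if (nzchar(s@description)) s@description else "na", character(1))
  lines <- vapply(seq_along(collection@sets), function(i) {
    s <- collection@sets[[i]]
    paste(c(s@name, desc[i], s@genes), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Intersect a gene set with the detected-gene universe
#'
#' Regulons and signatures are only scored when enough of their members are
#' detected; the default minimum overlap of 5 genes follows the usual
#' reliability threshold for single-sample enrichment scoring.
#'
#' @param set a [GeneSet-class].
#' @param universe character vector of detected gene symbols.
#' @param min_overlap minimum intersection size to accept (default 5).
#' @return The filtered [GeneSet-class] when the overlap reaches
#'   `min_overlap`; otherwise a rejection record: a list with elements
#'   `set`, `overlap`, `min_overlap` and class `"geneSetRejection"`.
#' @export
filterToUniverse <- function(set, universe, min_overlap = 5) {
  stopifnot(is(set, "GeneSet"))
  if (length(universe) == 0L) stop("universe must be non-empty")
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  universe <- trimws(as.character(universe))
  kept <- set@genes[set@genes %in% universe]
  if (length(kept) >= min_overlap) {
    initialize(set, genes = kept)
  } else {
    structure(
      list(set = set@name, overlap = length(kept), min_overlap = min_overlap),
      class = "geneSetRejection")
  }
}

#' @export
print.geneSetRejection <- function(x, ...) {
  cat(sprintf("gene set '%s' rejected: overlap %d < %d\n",
              x$set, x$overlap, x$min_overlap))
  invisible(x)
}
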