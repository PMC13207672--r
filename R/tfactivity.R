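#' Score transcription-factor regulon activity per observation
#'
#' Each regulon is intersected with the detected-gene universe; regulons
#' whose overlap falls below `minOverlap` (default 5 detected targets) are
#' rejected and reported, the survivors are scored by ssGSEA.
#'
#' @param x lognorm matrix or SummarizedExperiment with a `lognorm` assay.
#' @param regulons a [GeneSetCollection-class] of TF target sets.
#' @param minOverlap minimum detected targets to score a regulon (default 5).
#' @param tau,normalize ssGSEA parameters.
#' @return A `TFActivityResult` list: `activity` ([ScoreTable-class],
#'   observations x TFs), `overlap` (named detected-target counts for all
#'   regulons), `rejected` (data.frame set/overlap).
#' @export
scoreTFActivity <- function(x, regulons, minOverlap = 5, tau = 0.25,
                            normalize = TRUE) {
  stopifnot(is(regulons, "GeneSetCollection"))
  m <- getLognorm(x)
  universe <- rownames(m)
  filtered <- lapply(geneSets(regulons), filterToUniverse,
                     universe = universe, min_overlap = minOverlap)
  keep <- vapply(filtered, is, logical(1), "GeneSet")
  overlap <- vapply(seq_along(filtered), function(i)
    if (keep[i]) length(geneIds(filtered[[i]])) else filtered[[i]]$overlap,
    numeric(1))
  names(overlap) <- names(geneSets(regulons))
  if (!any(keep))
    stop("no regulon passes the >= ", minOverlap, " detected-target filter; ",
         "overlaps: ", paste(names(overlap), overlap, sep = "=",
                             collapse = ", "))
  surv <- GeneSetCollection(filtered[keep])
  activity <- ssgseaTable(m, surv, tau = tau, normalize = normalize)
  rejected <- data.frame(set = names(overlap)[!keep],
                         overlap = unname(overlap[!keep]))
  structure(list(activity = activity, overlap = overlap,
                 rejected = rejected, minOverlap = minOverlap),
            class = "TFActivityResult")
}

#' @export
print.TFActivityResult <- function(x, ...) {
  cat(sprintf("TFActivityResult: %d regulon(s) scored, %d rejected (< %d targets)\n",
              ncol(scoreMatrix(x$activity)), nrow(x$rejected), x$minOverlap))
  invisible(x)
}

#' Rank regulators by correlation with ferroptosis resistance
#'
#' Per TF: Spearman correlation of its activity with the ferroptosis score,
#' and with ferroptosis resistance defined as the *negation* of the score
#' (scores can be <= 0, so arithmetic negation is the only well-defined
#' "inverse"). BH adjustment across TFs; ranking is by the resistance
#' correlation, which is exactly the reverse of the susceptibility ranking.
#'
#' @param activity a [ScoreTable-class] (or `TFActivityResult`) of TF
#'   activities.
#' @param score named numeric ferroptosis score per observation (names must
#'   match the activity observation IDs).
#' @return data.frame ordered by decreasing resistance correlation:
#'   tf, rho_score, rho_resistance, p_value, p_adjusted, rank. TFs with
#'   degenerate (constant) activity get NA correlations and sort last.
#' @export
correlateWithResistance <- function(activity, score) {
  if (inherits(activity, "TFActivityResult")) activity <- activity$activity
  stopifnot(is(activity, "ScoreTable"))
  act <- scoreMatrix(activity)
  if (is.null(names(score)))
    stop("score must be named by observation ID")
  if (!setequal(rownames(act), names(score)))
    stop("observation IDs of activity and score do not match")
  score <- score[rownames(act)]
  res <- lapply(colnames(act), function(tf) {
    out <- tryCatch({
      st <- spearmanTest(act[, tf], score)
      c(rho = st$estimate, p = st$p_value)
    }, error = function(e) c(rho = NA_real_, p = NA_real_))
    out
  })
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  tab <- data.frame(tf = colnames(act), rho_score = rho,
                    rho_resistance = -rho, p_value = p,
                    p_adjusted = bhAdjust(p))
  tab <- tab[order(-tab$rho_resistance, tab$tf, na.last = TRUE), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
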