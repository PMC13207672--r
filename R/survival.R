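#' Construct a SignatureModel
#'
#' @param beta named numeric vector of coefficients (names = gene symbols).
#' @param name model name.
#' @param note free-text provenance.
#' @return A [SignatureModel-class].
#' @export
SignatureModel <- function(beta, name = "signature", note = "") {
  new("SignatureModel", beta = beta, name = name, note = note)
}

setMethod("show", "SignatureModel", function(object) {
  cat(sprintf("SignatureModel '%s': %d gene(s)\n", object@name,
              length(object@beta)))
})

#' Read a gene -> coefficient signature from CSV
#'
#' Expects columns `gene` and `beta`.
#'
#' @param path CSV path.
#' @param name,note passed to [SignatureModel()].
#' @return A [SignatureModel-class].
#' @export
readSignatureModel <- function(path, name = basename(path), note = path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "beta") %in% colnames(tab)))
    stop("signature CSV must have columns 'gene' and 'beta'")
  SignatureModel(setNames(as.numeric(tab$beta), tab$gene),
                 name = name, note = note)
}

#' Read a survival cohort from CSV
#'
#' Expects columns `subject_id`, `time`, `event` plus one column per gene.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readSurvivalCohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "time", "event")
  if (!all(need %in% colnames(tab)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  validateCohort(tab)
  tab
}

validateCohort <- function(cohort) {
  if (any(cohort$time < 0)) stop("negative survival time")
  if (!all(cohort$event %in% c(0, 1))) stop("event indicator must be 0/1")
  invisible(cohort)
}

#' Apply a linear gene signature as a risk score
#'
#' score = sum over signature genes of beta_i * expression_i. Under the
#' default `available_genes` policy, genes absent from the cohort contribute
#' zero and are listed in `attr(, "missing_genes")` (a 16-gene signature can
#' be applied to a platform detecting only 11 of them); under `fail`, any
#' absent gene is an error.
#'
#' @param cohort data.frame with `time`, `event` and gene expression columns.
#' @param model a [SignatureModel-class].
#' @param missingPolicy `"available_genes"` (default) or `"fail"`.
#' @return The cohort with a `risk_score` column; missing genes in
#'   `attr(, "missing_genes")`.
#' @export
riskScore <- function(cohort, model,
                      missingPolicy = c("available_genes", "fail")) {
  missingPolicy <- match.arg(missingPolicy)
  stopifnot(is(model, "SignatureModel"))
  validObject(model)
  beta <- model@beta
  present <- intersect(names(beta), colnames(cohort))
  missing <- setdiff(names(beta), present)
  if (length(present) == 0L)
    stop("no signature gene present in the cohort")
  if (missingPolicy == "fail" && length(missing))
    stop("signature gene(s) absent from cohort: ",
         paste(missing, collapse = ", "))
  expr <- as.matrix(cohort[, present, drop = FALSE])
  cohort$risk_score <- drop(expr %*% beta[present])
  attr(cohort, "missing_genes") <- missing
  cohort
}

#' Median split into high- and low-risk groups
#'
#' high = score strictly above the median, low = score at or below it
#' (median by linear interpolation; ties deterministically assigned to the
#' low group).
#'
#' @param cohort data.frame with a `risk_score` column, >= 2 subjects.
#' @return The cohort with a `risk_group` column ("high"/"low").
#' @export
stratifyMedian <- function(cohort) {
  if (!"risk_score" %in% colnames(cohort))
    stop("run riskScore() first")
  if (nrow(cohort) < 2L) stop("need at least 2 subjects")
  s <- cohort$risk_score
  if (length(unique(s)) == 1L) stop("degenerate: all risk scores equal")
  med <- median(s)
  cohort$risk_group <- ifelse(s > med, "high", "low")
  cohort
}

#' Kaplan-Meier product-limit estimate
#'
#' @param cohort data.frame with `time` and `event`.
#' @return A `KMCurve` data.frame: time, n_risk, n_event, n_censor, surv
#'   (non-increasing, starting from S(0) = 1 at time 0).
#' @export
kmEstimate <- function(cohort) {
  if (nrow(cohort) < 1L) stop("need at least 1 subject")
  validateCohort(cohort)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = cohort)
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(fit$n, fit$n.risk),
                    n_event = c(0, fit$n.event),
                    n_censor = c(0, fit$n.censor),
                    surv = c(1, fit$surv))
  class(out) <- c("KMCurve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Chi-square statistic with hypergeometric variance at each distinct event
#' time, 1 df.
#'
#' @param groupA,groupB data.frames with `time` and `event`; each must
#'   contribute at least one event.
#' @return A `TestResult`.
#' @export
logrankTest <- function(groupA, groupB) {
  validateCohort(groupA); validateCohort(groupB)
  if (sum(groupA$event) < 1L || sum(groupB$event) < 1L)
    stop("each group needs at least one event")
  df <- rbind(data.frame(time = groupA$time, event = groupA$event, g = "A"),
              data.frame(time = groupB$time, event = groupB$event, g = "B"))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  newTestResult(sd_$chisq, p, "logrank", c(nrow(groupA), nrow(groupB)))
}

#' Harrell's concordance index
#'
#' The probability that, of a comparable subject pair, the one with the
#' higher risk score fails earlier. Pairs where the shorter time is censored
#' are not comparable; score ties count 0.5.
#'
#' @param cohort data.frame with `time`, `event` and `risk_score`.
#' @return C-index in [0, 1].
#' @export
concordanceIndex <- function(cohort) {
  if (!"risk_score" %in% colnames(cohort)) stop("run riskScore() first")
  validateCohort(cohort)
  fit <- survival::concordance(
    survival::Surv(time, event) ~ risk_score, data = cohort, reverse = TRUE)
  counts <- fit$count
  comparable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (!is.finite(fit$concordance) || comparable == 0)
    stop("no comparable pairs")
  unname(fit$concordance)
}

#' Risk-stratified survival analysis in one call
#'
#' Scores the cohort, splits at the median, and computes KM curves per
#' group, the log-rank test and the concordance index.
#'
#' @param cohort data.frame with `time`, `event` and gene columns.
#' @param model a [SignatureModel-class].
#' @param missingPolicy see [riskScore()].
#' @return list: `cohort` (scored + grouped), `km` (list of KMCurve per
#'   group), `logrank` (TestResult), `cindex`, `missing_genes`.
#' @export
survivalStratification <- function(cohort, model,
                                   missingPolicy = "available_genes") {
  scored <- riskScore(cohort, model, missingPolicy = missingPolicy)
  grouped <- stratifyMedian(scored)
  hi <- grouped[grouped$risk_group == "high", , drop = FALSE]
  lo <- grouped[grouped$risk_group == "low", , drop = FALSE]
  list(cohort = grouped,
       km = list(high = kmEstimate(hi), low = kmEstimate(lo)),
       logrank = logrankTest(hi, lo),
       cindex = concordanceIndex(grouped),
       missing_genes = attr(scored, "missing_genes"))
}
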