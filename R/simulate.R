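#' Derive a per-stage substream seed from one global seed
#'
#' A counter-based scheme: each named stage gets its own deterministic seed so
#' that running stages in a different order never perturbs another stage's
#' stream. Results stay below 2^31.
#'
#' @param seed integer global seed.
#' @param stream stage name.
#' @return An integer seed.
#' @export
substreamSeed <- function(seed, stream) {
  b <- utf8ToInt(stream)
  h <- sum(b * seq_along(b) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483629)
}

# Evaluate code under a temporary RNG state, restoring the caller's stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the single-cell count simulator
#'
#' Defines the study conditions the generator emulates: negative-binomial
#' counts with cell-type expression programs and one latent regulator driving
#' a target gene set at a planted Spearman correlation.
#'
#' @param nGenes number of genes (default 800).
#' @param nCells number of cells (default 2000).
#' @param cellTypes data.frame with columns `name`, `proportion`, `foldChange`;
#'   proportions must sum to 1. Each type gets its own program genes.
#' @param regulator regulator gene symbol (default `"NFE2L2"`).
#' @param targetSet character vector of target gene symbols coupled to the
#'   regulator's latent activity.
#' @param rhoPlanted planted Spearman correlation between regulator and each
#'   target, in (-1, 1).
#' @param coupledTypes cell types in which the coupling is active (`NULL` =
#'   all types). In uncoupled types the targets carry no regulator term.
#' @param auxSet optional second gene set coupled to the same latent activity
#'   at `auxRho` (used to plant suppressor-regulon scenarios).
#' @param auxRho planted correlation for `auxSet`.
#' @param geneNames optional full gene-name vector of length `nGenes`;
#'   defaults to the ferroptosis fixture genes padded with `GENE###` fillers.
#' @param librarySizeMean mean library size per cell (default 5000).
#' @param nbDispersion negative-binomial size parameter theta, variance
#'   mu + mu^2/theta (default 10, a realistic scRNA overdispersion).
#' @param programGenesPerType number of program genes assigned to each cell
#'   type (default 15).
#' @param seed integer seed.
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(nGenes = 800, nCells = 2000,
                      cellTypes = data.frame(
                        name = c("epithelial", "immune", "stromal"),
                        proportion = c(0.5, 0.3, 0.2),
                        foldChange = c(2, 2, 2)),
                      regulator = "NFE2L2",
                      targetSet = c("HMOX1", "NQO1", "GCLC", "GCLM", "TXNRD1",
                                    "GSS", "SLC7A11", "FTH1", "FTL", "GPX4",
                                    "PRDX1", "SESN2"),
                      rhoPlanted = 0.5,
                      coupledTypes = NULL,
                      auxSet = NULL, auxRho = 0,
                      geneNames = NULL,
                      librarySizeMean = 5000, nbDispersion = 10,
                      programGenesPerType = 15,
                      seed = 1L) {
  if (nCells < 10) stop("nCells must be >= 10")
  if (nGenes < length(targetSet) + 1L)
    stop("nGenes must exceed the number of targets")
  if (abs(sum(cellTypes$proportion) - 1) > 1e-9)
    stop("cell type proportions must sum to 1")
  if (abs(rhoPlanted) >= 1) stop("|rhoPlanted| must be < 1")
  if (regulator %in% targetSet)
    stop("regulator must not be a member of its own target set")
  if (librarySizeMean <= 0 || nbDispersion <= 0)
    stop("librarySizeMean and nbDispersion must be positive")
  if (is.null(geneNames)) {
    base <- unique(c(regulator, targetSet, auxSet,
                     geneIds(ferroptosisGeneSets()[["ferroptosis_all"]])))
    if (length(base) > nGenes)
      stop("nGenes too small for the requested named genes")
    fill <- setdiff(sprintf("GENE%03d", seq_len(nGenes)), base)
    geneNames <- c(base, fill[seq_len(nGenes - length(base))])
  }
  if (length(geneNames) != nGenes || anyDuplicated(geneNames))
    stop("geneNames must be ", nGenes, " unique symbols")
  if (!all(c(regulator, targetSet, auxSet) %in% geneNames))
    stop("regulator, targetSet and auxSet must be contained in geneNames")
  if (!is.null(coupledTypes) && !all(coupledTypes %in% cellTypes$name))
    stop("coupledTypes must name configured cell types")
  structure(list(
    nGenes = nGenes, nCells = nCells, cellTypes = cellTypes,
    regulator = regulator, targetSet = targetSet, rhoPlanted = rhoPlanted,
    coupledTypes = coupledTypes, auxSet = auxSet, auxRho = auxRho,
    geneNames = geneNames, librarySizeMean = librarySizeMean,
    nbDispersion = nbDispersion, programGenesPerType = programGenesPerType,
    seed = as.integer(seed)), class = "SimConfig")
}

# Spearman -> Pearson on the latent Gaussian scale (Greiner's relation),
# inflated for the count-sampling attenuation observed empirically at the
# default depth/dispersion. Clipped away from 1.
latentRho <- function(rho) {
  r <- 2 * sin(pi * rho / 6) * 1.42
  sign(r) * min(abs(r), 0.985)
}

# Loading amplitude of the latent activity on the log-mean scale. Kept
# moderate so the planted program stays a small fraction of library mass
# (softmax compositionality would otherwise bleed anticorrelation into
# unrelated genes).
LATENT_AMP <- 1.0

#' Simulate single-cell counts with a planted regulator
#'
#' Counts are NB(mean = libsize * softmax(baseline + cell-type program +
#' latent loading), dispersion theta). Only the regulator and its target set
#' load on the latent per-cell activity, scaled so the large-n Spearman
#' correlation between regulator and each target approaches the planted
#' value. Identical seeds give bit-identical output.
#'
#' @param config a [simConfig()] object.
#' @return A list with `se` (a \linkS4class{SummarizedExperiment} with a
#'   `counts` assay and `cell_type` colData) and `truth` (planted per-gene
#'   correlations, per-cell latent activity, labels).
#' @export
simulateSingleCell <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  g <- config$geneNames
  n <- config$nCells
  withSeed(config$seed, {
    # cell type labels
    labels <- sample(rep(config$cellTypes$name,
                         times = round(config$cellTypes$proportion * n))[
                           seq_len(n)])
    if (length(labels) < n)
      labels <- c(labels, sample(config$cellTypes$name, n - length(labels),
                                 replace = TRUE,
                                 prob = config$cellTypes$proportion))
    # per-type programs drawn from non-special genes
    special <- c(config$regulator, config$targetSet, config$auxSet)
    pool <- setdiff(g, special)
    programs <- list()
    for (i in seq_len(nrow(config$cellTypes))) {
      programs[[config$cellTypes$name[i]]] <-
        sample(pool, min(config$programGenesPerType, length(pool)))
    }
    base <- rnorm(length(g), 0, 0.5)
    names(base) <- g
    a <- rnorm(n)                              # latent regulator activity
    amp <- LATENT_AMP
    eta <- matrix(base, nrow = length(g), ncol = n, dimnames = list(g, NULL))
    for (i in seq_len(nrow(config$cellTypes))) {
      ty <- config$cellTypes$name[i]
      idx <- which(labels == ty)
      eta[programs[[ty]], idx] <- eta[programs[[ty]], idx] +
        log(config$cellTypes$foldChange[i])
    }
    eta[config$regulator, ] <- eta[config$regulator, ] + amp * a
    coupled <- if (is.null(config$coupledTypes)) rep(TRUE, n) else
      labels %in% config$coupledTypes
    plantSet <- function(eta, genes, rho) {
      rl <- latentRho(rho)
      # when coupling is restricted to some cell types, the regulator-driven
      # program is ON there: elevated mean as well as covariance
      shift <- if (all(coupled)) 0 else 0.6
      for (tg in genes) {
        eps <- rnorm(n)
        eta[tg, coupled] <- eta[tg, coupled] + shift +
          amp * (rl * a[coupled] + sqrt(1 - rl^2) * eps[coupled])
      }
      eta
    }
    eta <- plantSet(eta, config$targetSet, config$rhoPlanted)
    if (!is.null(config$auxSet))
      eta <- plantSet(eta, config$auxSet, config$auxRho)
    libsize <- config$librarySizeMean * exp(rnorm(n, 0, 0.2) - 0.02)
    prob <- exp(sweep(eta, 2, apply(eta, 2, max)))
    prob <- sweep(prob, 2, colSums(prob), "/")
    mu <- sweep(prob, 2, libsize, "*")
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = config$nbDispersion),
      nrow = nrow(mu), dimnames = list(g, sprintf("cell%04d", seq_len(n))))
    trueRho <- setNames(numeric(length(g)), g)
    trueRho[config$targetSet] <- config$rhoPlanted
    if (!is.null(config$auxSet)) trueRho[config$auxSet] <- config$auxRho
    trueRho[config$regulator] <- NA_real_
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(cell_type = labels,
                                     row.names = colnames(counts)))
    list(se = se,
         truth = list(trueRho = trueRho, latentActivity = a,
                      cellType = labels, coupled = coupled,
                      regulator = config$regulator,
                      targetSet = config$targetSet))
  })
}

#' Simulate a spatial grid with a core-to-margin score gradient
#'
#' A square array of spots partitioned into an inner core, a surrounding
#' margin ring and outer stroma (by Chebyshev radius thirds). Ferroptosis
#' panel genes have NB mean `gradientLow` in the core, `gradientHigh` at the
#' margin and their midpoint in the stroma; background genes are flat.
#'
#' @param nSpotsSide spots per side (>= 4).
#' @param gradientHigh,gradientLow NB mean of panel genes at margin / core.
#'   Equal values give a null gradient; `gradientHigh < gradientLow` is a
#'   parameter error since a positive margin contrast is the modelled
#'   geometry.
#' @param seed integer seed.
#' @param panelGenes genes carrying the gradient (default: the bundled
#'   ferroptosis union).
#' @param nBackground number of background genes without a regional
#'   gradient (default 400); their per-gene baseline means are lognormal
#'   around 2 so expression-matched control bins exist at every level.
#' @param nbDispersion NB size parameter (default 10).
#' @return A list with `sp` (a [SpatialFerro-class] with `counts` assay and
#'   `x`, `y`, `region` colData) and `truth` (region labels and means).
#' @export
simulateSpatial <- function(nSpotsSide = 8, gradientHigh = 4,
                            gradientLow = 2, seed = 1L,
                            panelGenes = NULL, nBackground = 400,
                            nbDispersion = 10) {
  if (nSpotsSide < 4) stop("nSpotsSide must be >= 4")
  if (gradientHigh < gradientLow)
    stop("gradientHigh must be >= gradientLow for a positive margin contrast")
  if (is.null(panelGenes))
    panelGenes <- geneIds(ferroptosisGeneSets()[["ferroptosis_all"]])
  coords <- expand.grid(x = seq_len(nSpotsSide), y = seq_len(nSpotsSide))
  ctr <- (nSpotsSide + 1) / 2
  rad <- pmax(abs(coords$x - ctr), abs(coords$y - ctr)) / (nSpotsSide - 1) * 2
  region <- ifelse(rad <= 1 / 3, "core",
                   ifelse(rad <= 2 / 3, "margin", "stroma"))
  meanOf <- c(core = gradientLow, margin = gradientHigh,
              stroma = (gradientLow + gradientHigh) / 2)
  genes <- c(panelGenes, sprintf("BG%03d", seq_len(nBackground)))
  nSpots <- nrow(coords)
  withSeed(seed, {
    bgMean <- exp(rnorm(nBackground, log(2), 0.5))
    mu <- matrix(rep(c(rep(2, length(panelGenes)), bgMean), nSpots),
                 nrow = length(genes), dimnames = list(genes, NULL))
    mu[panelGenes, ] <- rep(meanOf[region], each = length(panelGenes))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = nbDispersion),
                     nrow = nrow(mu),
                     dimnames = list(genes,
                                     sprintf("spot%04d", seq_len(nSpots))))
    sp <- new("SpatialFerro", SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(x = coords$x, y = coords$y,
                                     region = region,
                                     row.names = colnames(counts))))
    list(sp = sp,
         truth = list(region = region, regionMeans = meanOf,
                      panelGenes = panelGenes))
  })
}

#' Simulate a proportional-hazards survival cohort
#'
#' Signature gene expressions are standard normal; event times are
#' exponential with hazard h0 * exp(effectScale * riskscore); censoring is an
#' independent exponential clock calibrated to achieve approximately the
#' requested censoring fraction.
#'
#' @param n cohort size.
#' @param signature a [SignatureModel-class].
#' @param effectScale multiplier on the linear risk score inside the hazard.
#' @param censoringRate requested censoring fraction in [0, 1).
#' @param seed integer seed.
#' @param baselineHazard h0 (default 0.1 per time unit).
#' @return A list with `cohort` (data.frame: subject_id, time, event and one
#'   column per signature gene) and `truth` (betas, effect scale, true risk).
#' @export
simulateSurvivalCohort <- function(n, signature, effectScale = 1,
                                   censoringRate = 0.3, seed = 1L,
                                   baselineHazard = 0.1) {
  stopifnot(is(signature, "SignatureModel"))
  validObject(signature)
  if (censoringRate < 0 || censoringRate >= 1)
    stop("censoringRate must be in [0, 1)")
  beta <- signature@beta
  withSeed(seed, {
    expr <- matrix(rnorm(n * length(beta)), nrow = n,
                   dimnames = list(NULL, names(beta)))
    risk <- drop(expr %*% beta)
    rate <- baselineHazard * exp(effectScale * risk)
    tEvent <- rexp(n, rate = rate)
    if (censoringRate > 0) {
      cRate <- baselineHazard * censoringRate / (1 - censoringRate)
      tCens <- rexp(n, rate = cRate)
    } else tCens <- rep(Inf, n)
    time <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)
    cohort <- data.frame(subject_id = sprintf("subj%04d", seq_len(n)),
                         time = time, event = event,
                         check.names = FALSE)
    cohort <- cbind(cohort, as.data.frame(expr))
    list(cohort = cohort,
         truth = list(beta = beta, effectScale = effectScale,
                      baselineHazard = baselineHazard, trueRisk = risk))
  })
}

#' Permute observation assignment, destroying group structure
#'
#' Columns of every assay are permuted while observation identifiers and
#' metadata stay in place, so any association between groups and expression
#' is broken while per-gene marginals (and row sums) are preserved.
#'
#' @param x a \linkS4class{SummarizedExperiment} or a matrix.
#' @param seed integer seed.
#' @return Same class as `x`.
#' @export
nullShuffle <- function(x, seed = 1L) {
  if (is.matrix(x)) {
    if (length(x) == 0L) stop("matrix must be non-empty")
    return(withSeed(seed, {
      perm <- sample(ncol(x))
      out <- x[, perm, drop = FALSE]
      colnames(out) <- colnames(x)
      out
    }))
  }
  stopifnot(is(x, "SummarizedExperiment"))
  if (ncol(x) == 0L) stop("matrix must be non-empty")
  withSeed(seed, {
    perm <- sample(ncol(x))
    ids <- colnames(x)
    for (nm in SummarizedExperiment::assayNames(x)) {
      a <- SummarizedExperiment::assay(x, nm)[, perm, drop = FALSE]
      colnames(a) <- ids
      SummarizedExperiment::assay(x, nm) <- a
    }
    x
  })
}

#' Simulate a planted ferroptosis-suppressor regulon scenario
#'
#' One latent activity drives a transcription factor's regulon up while
#' driving a ferroptosis gene panel down, among decoy regulons made of
#' unrelated genes — the ground truth for testing whether regulon-activity
#' ranking by resistance correlation recovers the suppressor.
#'
#' @param seed integer seed.
#' @param nCells number of cells.
#' @param nDecoys number of decoy regulons (default 9).
#' @param rho planted correlation magnitude (default 0.5): the regulon
#'   couples at +rho, the ferroptosis panel at -rho.
#' @param regulonSize genes per regulon (default 10).
#' @return list: `se` (counts SummarizedExperiment), `regulons`
#'   ([GeneSetCollection-class] with the planted `TFX` plus decoys),
#'   `plantedTF` ("TFX"), `panel` (the coupled ferroptosis genes).
#' @export
simulateSuppressorScenario <- function(seed = 1L, nCells = 2000,
                                       nDecoys = 9, rho = 0.5,
                                       regulonSize = 10) {
  ferro <- geneIds(ferroptosisGeneSets()[["ferroptosis_all"]])
  panel <- setdiff(ferro, "NFE2L2")
  panel <- panel[seq_len(30)]
  tfxTargets <- sprintf("GENE%03d", 1:regulonSize)
  cfg <- simConfig(nCells = nCells, seed = seed,
                   regulator = "GENE700",
                   targetSet = panel, rhoPlanted = -rho,
                   auxSet = tfxTargets, auxRho = rho)
  sim <- simulateSingleCell(cfg)
  decoyPool <- setdiff(cfg$geneNames,
                       c(ferro, tfxTargets, "GENE700"))
  decoys <- withSeed(substreamSeed(seed, "decoys"), {
    lapply(seq_len(nDecoys), function(i)
      GeneSet(sprintf("DECOY%02d", i), sample(decoyPool, regulonSize),
              category = "tf_regulon"))
  })
  regulons <- GeneSetCollection(
    c(list(GeneSet("TFX", tfxTargets, category = "tf_regulon")), decoys),
    provenance = "planted suppressor scenario")
  list(se = sim$se, regulons = regulons, plantedTF = "TFX", panel = panel,
       truth = sim$truth)
}
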