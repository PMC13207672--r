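# Shared helpers: tiny in-code fixtures and independent oracles.

# A small deterministic lognorm-scale matrix with named genes/cells.
toyMatrix <- function(nGenes = 20, nCells = 10, seed = 42) {
  set.seed(seed)
  m <- matrix(rlnorm(nGenes * nCells, 0, 0.5), nrow = nGenes,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("c%02d", seq_len(nCells))))
  m
}

writeTempGMT <- function(lines) {
  f <- tempfile(fileext = ".gmt")
  writeLines(lines, f)
  f
}

# Independent brute-force ssGSEA oracle: literal walk over the ranking,
# re-deriving positions and tie-averaged weights from first principles.
bruteSsgseaES <- function(expr, inSet, tau) {
  stopifnot(length(expr) == length(inSet))
  n <- length(expr)
  nm <- names(expr)
  ord <- order(-expr, nm)
  exprSorted <- expr[ord]
  inS <- inSet[ord]
  # position weights r = n - position + 1, averaged over tied values
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && exprSorted[j + 1] == exprSorted[i]) j <- j + 1
    r[i:j] <- mean(n - (i:j) + 1)
    i <- j + 1
  }
  denomIn <- sum(r[inS]^tau)
  nOut <- sum(!inS)
  es <- 0; pin <- 0; pout <- 0
  for (i in seq_len(n)) {
    if (inS[i]) pin <- pin + r[i]^tau / denomIn else pout <- pout + 1 / nOut
    es <- es + (pin - pout)
  }
  es
}

# Harrell's C by explicit pair enumeration (independent of survival::).
bruteCIndex <- function(time, event, score) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # the pair is comparable if the shorter time ended in an event
    if (time[i] == time[j] && event[i] == event[j]) next
    first <- if (time[i] < time[j]) i else j
    second <- if (first == i) j else i
    if (time[i] == time[j]) { first <- which.max(c(event[i], event[j]) == 1)
      first <- c(i, j)[first]; second <- setdiff(c(i, j), first) }
    if (event[first] != 1) next
    den <- den + 1
    if (score[first] > score[second]) num <- num + 1
    else if (score[first] == score[second]) num <- num + 0.5
  }
  num / den
}

# BH step-up from the definition.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
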