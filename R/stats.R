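newTestResult <- function(statistic, p, method, sizes, direction = NA_real_,
                          extra = list()) {
  structure(c(list(statistic = unname(statistic), p_value = unname(p),
                   p_adjusted = NA_real_, method = method,
                   group_sizes = sizes, direction = direction), extra),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$method, x$statistic,
              x$p_value))
  if (!is.na(x$p_adjusted)) cat(sprintf(", p_adj = %.4g", x$p_adjusted))
  cat("\n  group sizes:", paste(x$group_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The statistic is the number of (a, b) pairs with
#' a > b plus half-ties (the `wilcox.test` W convention). The
#' `normal_approx` mode uses the tie-corrected normal approximation with
#' continuity correction; `exact` enumerates and is limited to combined
#' sample sizes of at most 25.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param mode `"normal_approx"` (default) or `"exact"`.
#' @return A `TestResult` (statistic, p_value, group sizes, direction =
#'   sign of the median difference a - b).
#' @export
mannWhitney <- function(a, b, mode = c("normal_approx", "exact")) {
  mode <- match.arg(mode)
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  if (mode == "exact" && length(a) + length(b) > 25)
    stop("exact mode limited to combined sample size <= 25")
  ht <- suppressWarnings(wilcox.test(
    a, b, alternative = "two.sided", exact = mode == "exact",
    correct = TRUE))
  newTestResult(ht$statistic, ht$p.value, "mann_whitney",
                c(length(a), length(b)),
                direction = sign(median(a) - median(b)))
}

# Vectorized tie-corrected normal-approximation Mann-Whitney over matrix
# rows: group ia vs group ib of the columns. Matches wilcox.test(correct =
# TRUE, exact = FALSE) per row. Used for responder marker tables.
rowMannWhitney <- function(m, ia, ib) {
  na <- length(ia); nb <- length(ib)
  sub <- m[, c(ia, ib), drop = FALSE]
  n <- na + nb
  r <- t(apply(sub, 1, rank))
  w <- rowSums(r[, seq_len(na), drop = FALSE]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- apply(sub, 1, function(v) {
    t <- table(v); sum(t^3 - t)
  })
  sigma2 <- na * nb / 12 * ((n + 1) - ties / (n * (n - 1)))
  z <- w - mu
  cc <- sign(z) * 0.5
  p <- 2 * pnorm(abs(z - cc) / sqrt(sigma2), lower.tail = FALSE)
  p[sigma2 == 0] <- 1
  p <- pmin(1, p)
  list(statistic = w, p = p)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H with a chi-square reference (k - 1 df). All-identical
#' values are degenerate: H = 0, p = 1, with a warning.
#'
#' @param groups a list of >= 2 numeric vectors, total length >= 3.
#' @return A `TestResult`.
#' @export
kruskalWallis <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) stop("total N must be >= 3")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    warning("all values identical; degenerate Kruskal-Wallis (H = 0, p = 1)")
    return(newTestResult(0, 1, "kruskal_wallis", lengths(groups)))
  }
  ht <- kruskal.test(values, g)
  newTestResult(ht$statistic, ht$p.value, "kruskal_wallis", lengths(groups),
                extra = list(df = unname(ht$parameter)))
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics on pooled (tie-corrected) ranks following a
#' Kruskal-Wallis test, two-sided p, BH-adjusted across all k(k-1)/2 pairs.
#'
#' @param groups a list of >= 2 numeric vectors; names label the groups.
#' @param adjust multiple-testing adjustment, only `"bh"`.
#' @return data.frame: group_i, group_j, z, p_value, p_adjusted.
#' @export
dunnPosthoc <- function(groups, adjust = c("bh")) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, factor(g, levels = names(groups)), mean)
  sizes <- lengths(groups)
  tie <- table(values)
  tieCorr <- sum(tie^3 - tie) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tieCorr
  pairs <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    se <- sqrt(v0 * (1 / sizes[[i]] + 1 / sizes[[j]]))
    z[q] <- (rbar[[i]] - rbar[[j]]) / se
    p[q] <- 2 * pnorm(-abs(z[q]))
  }
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], z = z,
             p_value = p, p_adjusted = bhAdjust(p))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of average ranks; the two-sided p-value
#' uses the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A `TestResult` with `estimate` (rho).
#' @export
spearmanTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("rho undefined: zero variance in x or y")
  ht <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE, continuity = FALSE))
  res <- newTestResult(ht$statistic, ht$p.value, "spearman",
                       c(length(x), length(y)),
                       direction = sign(unname(ht$estimate)))
  res$estimate <- unname(ht$estimate)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed, passed through).
#' @return Adjusted p-values, original order.
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
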