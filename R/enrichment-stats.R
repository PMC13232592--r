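#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing `n` items without replacement from a universe of
#' `N` items of which `K` are "hits". This is the overrepresentation p-value
#' used throughout the package (risk-gene enrichment, confounder flags,
#' lineage overlap). Evaluated through the hypergeometric CDF, which works in
#' log space internally, so extreme tails are stable.
#'
#' @param k Observed overlap (number of hits drawn). Vectorised.
#' @param K Number of hits in the universe.
#' @param n Number of draws (query set size).
#' @param N Universe size.
#' @return Probability in (0, 1]; `k = 0` returns exactly 1.
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 10)   # 1/choose(10, 5)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | k > pmin(K, n) | K > N | n > N
  if (any(bad)) {
    abort(sprintf(
      "hypergeometric bounds violated: need 0 <= k <= min(K, n) <= N, got k=%s K=%s n=%s N=%s",
      k[bad][1], K[bad][1], n[bad][1], N[bad][1]))
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pmin(p, 1)
}

#' Unconditional odds ratio of a 2x2 table
#'
#' The cross-product ratio (a*d)/(b*c), which is what published enrichment
#' statistics report (as opposed to the conditional MLE that
#' [stats::fisher.test()] estimates). Layout is rows = category, columns =
#' hit/miss.
#'
#' @param a,b,c,d Cell counts, or pass a 2x2 matrix as `a`.
#' @return Positive real; `Inf` when `b*c == 0` with `a*d > 0`; 0 in the
#'   mirrored case; `NaN` (with a warning) when both products are zero.
#' @examples
#' odds_ratio(24, 40, 4, 64)   # 9.6
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  check_table_cells(a, b, c, d)
  ad <- a * d
  bc <- b * c
  if (ad == 0 && bc == 0) {
    warn("odds ratio undefined: both diagonal products are zero")
    return(NaN)
  }
  if (bc == 0) return(Inf)
  ad / bc
}

check_table_cells <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("contingency cells must be non-negative integers")
  }
  if (sum(cells) == 0) abort("contingency table has no observations")
  invisible(TRUE)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact p-value by summing hypergeometric point probabilities over all
#' tables with the observed margins. The two-sided p follows the
#' point-probability rule: sum the probabilities of every table whose point
#' probability does not exceed the observed one, with a relative tolerance
#' of 1e-7 for ties (the convention of most implementations).
#'
#' @inheritParams odds_ratio
#' @param alternative "two.sided" (default), "greater" (enrichment of cell
#'   `a`), or "less".
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact(24, 40, 4, 64)               # < 0.001
#' fisher_exact(7, 19, 1, 25, "greater")     # ~= 0.0248
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         alternative = c("two.sided", "greater", "less")) {
  if (is.matrix(a)) {
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  alternative <- match.arg(alternative)
  check_table_cells(a, b, c, d)
  K <- a + b        # row 1 margin
  n <- a + c        # column 1 margin
  N <- a + b + c + d
  lo <- max(0L, n - (N - K))
  hi <- min(K, n)
  support <- lo:hi
  probs <- dhyper(support, K, N - K, n)
  p <- switch(alternative,
    greater   = sum(probs[support >= a]),
    less      = sum(probs[support <= a]),
    two.sided = {
      p_obs <- dhyper(a, K, N - K, n)
      sum(probs[probs <= p_obs * (1 + 1e-7)])
    })
  min(max(p, dhyper(a, K, N - K, n)), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]: monotone in the rank
#' order of the raw p-values and capped at 1. `NA`s propagate.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) && any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Combined overrepresentation score
#'
#' `ln(OR) * (-ln p)`, a display score in the spirit of enrichment dot-plot
#' sizing: zero when the odds ratio is 1 or the p-value is 1, growing with
#' both effect size and significance. Infinite odds ratios are clamped to
#' `or_cap` before scoring. Never used for significance decisions.
#'
#' @param odds_ratio Positive odds ratio(s); may be `Inf`.
#' @param p p-value(s) in (0, 1].
#' @param or_cap Clamp for infinite/huge odds ratios (default 100).
#' @return Numeric score(s).
#' @export
combined_score <- function(odds_ratio, p, or_cap = 100) {
  or <- pmin(odds_ratio, or_cap)
  score <- log(or) * (-log(p))
  score[p >= 1] <- 0
  score
}

#' Chi-square test of independence with Pearson residuals
#'
#' For an r x c count table: expected counts under independence, the
#' chi-square statistic, its (r-1)(c-1)-df p-value, and the matrix of
#' Pearson residuals (O - E)/sqrt(E), the per-cell z-scale effect measure
#' used for directionality heatmaps. Rows or columns with a zero margin are
#' dropped with a warning before testing; cells whose expected count falls
#' below `expected_floor` are flagged in the result.
#'
#' @param x Count matrix with at least 2 rows and 2 columns after dropping
#'   empty margins.
#' @param expected_floor Flag threshold for small expected counts
#'   (default 5).
#' @return A list of class `"chisq_indep"`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`, `residuals`, `low_expected` (logical matrix),
#'   `dropped` (names of removed rows/columns).
#' @examples
#' chi_square_independence(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
#' @export
chi_square_independence <- function(x, expected_floor = 5) {
  x <- as.matrix(x)
  if (any(x < 0) || any(is.na(x))) abort("counts must be non-negative and complete")
  if (sum(x) == 0) abort("contingency table has no observations")
  dropped <- character()
  empty_r <- rowSums(x) == 0
  empty_c <- colSums(x) == 0
  if (any(empty_r) || any(empty_c)) {
    dropped <- c(rownames(x)[empty_r] %||% which(empty_r),
                 colnames(x)[empty_c] %||% which(empty_c))
    warn(sprintf("dropping %d empty row(s)/column(s) before testing",
                 sum(empty_r) + sum(empty_c)))
    x <- x[!empty_r, !empty_c, drop = FALSE]
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    abort("need at least a 2x2 table after dropping empty margins")
  }
  total <- sum(x)
  expected <- outer(rowSums(x), colSums(x)) / total
  stat <- sum((x - expected)^2 / expected)
  df <- (nrow(x) - 1) * (ncol(x) - 1)
  res <- structure(
    list(statistic = stat,
         df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE),
         observed = x,
         expected = expected,
         residuals = (x - expected) / sqrt(expected),
         low_expected = expected < expected_floor,
         dropped = as.character(dropped)),
    class = "chisq_indep")
  res
}

#' @export
print.chisq_indep <- function(x, ...) {
  cat(sprintf("Chi-square test of independence: X2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  cat("Pearson residuals:\n")
  print(round(x$residuals, 3))
  invisible(x)
}

#' @rdname chi_square_independence
#' @param x A `chisq_indep` object.
#' @param ... Unused.
#' @export
tidy.chisq_indep <- function(x, ...) {
  obs <- x$observed
  rn <- rownames(obs) %||% as.character(seq_len(nrow(obs)))
  cn <- colnames(obs) %||% as.character(seq_len(ncol(obs)))
  tibble(row = rep(rn, each = length(cn)),
         col = rep(cn, times = length(rn)),
         observed = as.vector(t(obs)),
         expected = as.vector(t(x$expected)),
         residual = as.vector(t(x$residuals)),
         low_expected = as.vector(t(x$low_expected)))
}

#' @rdname chi_square_independence
#' @export
glance.chisq_indep <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         n = sum(x$observed), n_dropped = length(x$dropped))
}

#' Enrichment of a query set against named gene lists
#'
#' Workhorse behind risk-gene overrepresentation and confounder flagging:
#' for each list, the overlap with the query, the unconditional odds ratio
#' of the implied 2x2 table, the upper-tail hypergeometric p-value against
#' the given universe, and the display [combined_score()]. List members
#' absent from the universe are dropped (count recorded in the
#' `n_outside_universe` column).
#'
#' @param query Character vector of gene identifiers (deduplicated; members
#'   outside `universe` are dropped with a warning).
#' @param gene_lists Named list of character vectors.
#' @param universe Character vector defining the statistical universe.
#' @return A tibble with one row per list: `list_name`, `overlap` (k),
#'   `list_size` (K, within universe), `query_size` (n), `universe_size`
#'   (N), `odds_ratio`, `p_value`, `fdr` (BH across the lists), `score`,
#'   `n_outside_universe`.
#' @export
enrich_sets <- function(query, gene_lists, universe) {
  stopifnot(is.list(gene_lists), !is.null(names(gene_lists)))
  universe <- unique(universe)
  query <- unique(query)
  outside_q <- setdiff(query, universe)
  if (length(outside_q)) {
    warn(sprintf("%d query gene(s) outside the universe were dropped",
                 length(outside_q)))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- imap(gene_lists, function(genes, nm) {
    genes <- unique(genes)
    dropped <- length(setdiff(genes, universe))
    genes <- intersect(genes, universe)
    K <- length(genes)
    k <- length(intersect(query, genes))
    a <- k; b <- n - k; cc <- K - k; dd <- N - K - n + k
    or <- if ((a * dd) == 0 && (b * cc) == 0) NaN else if ((b * cc) == 0) Inf
          else (a * dd) / (b * cc)
    p <- hypergeom_upper_tail(k, K, n, N)
    tibble(list_name = nm, overlap = k, list_size = K, query_size = n,
           universe_size = N, odds_ratio = or, p_value = p,
           n_outside_universe = dropped)
  })
  out <- list_rbind(rows)
  out$fdr <- bh_fdr(out$p_value)
  out$score <- combined_score(out$odds_ratio, out$p_value)
  out[, c("list_name", "overlap", "list_size", "query_size", "universe_size",
          "odds_ratio", "p_value", "fdr", "score", "n_outside_universe")]
}
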