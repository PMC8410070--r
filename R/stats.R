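# Self-implemented statistical primitives used by all downstream stages:
# two-sided Wilcoxon rank-sum and signed-rank tests (exact enumeration for
# small samples, tie-corrected normal approximation with continuity
# correction otherwise), Bonferroni adjustment, the marker effect size, and
# gene-gene correlation matrices.

#' Two-sided Wilcoxon / Mann-Whitney rank-sum test
#'
#' Ties receive midranks. When `n1 + n2 <= exact_limit` and `method` is
#' `"auto"` or `"exact"`, the two-sided p-value is computed by enumerating
#' all `choose(n1+n2, n1)` assignments of the pooled midranks and counting
#' those whose rank sum deviates from its null mean at least as much as the
#' observed one. Otherwise a normal approximation with tie-corrected
#' variance and a 0.5 continuity correction is used.
#'
#' @param x,y numeric vectors (each nonempty).
#' @param exact_limit largest `n1 + n2` for which exact enumeration is used
#'   under `method = "auto"` (default 14).
#' @param method `"auto"`, `"exact"`, or `"normal_approx"`.
#' @return List of class `rank_test` with elements `statistic` (the
#'   Mann-Whitney U of `x`), `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n1`, `n2`.
#' @export
rank_sum_test <- function(x, y, exact_limit = 14,
                          method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  use_exact <- method == "exact" || (method == "auto" && n <= exact_limit)
  if (use_exact) {
    if (n > 60)
      stop("exact enumeration refused for n1 + n2 = ", n,
           "; use method = 'normal_approx'")
    p <- ranksum_exact_p(r, n1, w)
    used <- "exact"
  } else {
    p <- ranksum_normal_p(u, n1, n2, tie_sum(c(x, y)))
    used <- "normal_approx"
  }
  structure(list(statistic = u, p_value = p, method = used, n1 = n1, n2 = n2),
            class = "rank_test")
}

# Exact two-sided rank-sum p over the permutation null: dynamic program
# counting, for every (subset size k, doubled-midrank sum s), the number of
# k-subsets of the pooled midranks attaining s. Equivalent to enumerating
# all choose(n, n1) assignments; midranks are multiples of 1/2, so doubling
# makes the sums integral.
#' @noRd
ranksum_exact_p <- function(r, n1, w_obs) {
  n <- length(r)
  r2 <- as.integer(round(2 * r))
  S <- sum(r2)
  f <- matrix(0, n1 + 1, S + 1)
  f[1, 1] <- 1
  placed <- 0
  for (ri in r2) {
    placed <- placed + 1
    for (k in min(n1, placed):1)
      f[k + 1, (ri + 1):(S + 1)] <- f[k + 1, (ri + 1):(S + 1)] +
        f[k, 1:(S + 1 - ri)]
  }
  counts <- f[n1 + 1, ]
  dev <- abs(seq(0, S) - n1 * (n + 1))          # |2W - E[2W]|
  dev_obs <- abs(2 * w_obs - n1 * (n + 1))
  sum(counts[dev >= dev_obs - 1e-9]) / choose(n, n1)
}

# sum over tie groups of t^3 - t
#' @noRd
tie_sum <- function(v) {
  t <- rle(sort(v))$lengths
  sum(t^3 - t)
}

# Tie-corrected normal approximation shared by the scalar test and the
# vectorized marker scan (u, ties may be vectors).
#' @noRd
ranksum_normal_p <- function(u, n1, n2, ties) {
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - ties / (n * (n - 1)))
  mu <- n1 * n2 / 2
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  p <- ifelse(sigma2 <= 0, 1, 2 * pnorm(-pmax(z, 0)))
  pmin(pmax(p, 0), 1)
}

#' Two-sided Wilcoxon signed-rank test for paired scores
#'
#' Pairs with zero difference are dropped and their count reported. Ties
#' among nonzero absolute differences receive midranks. With at most
#' `exact_limit` informative pairs the exact two-sided p-value is computed
#' over all sign assignments (by dynamic programming over the doubled,
#' integer-valued midranks, equivalent to enumerating the `2^n` patterns);
#' otherwise a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param before,after equal-length numeric vectors of paired scores.
#' @param exact_limit largest number of informative pairs for exact mode
#'   (default 20).
#' @param method `"auto"`, `"exact"`, or `"normal_approx"`.
#' @return List of class `rank_test` with elements `statistic` (V, the sum
#'   of ranks of positive differences), `p_value`, `method`,
#'   `n_informative`, `n_zero`.
#' @export
signed_rank_test <- function(before, after, exact_limit = 20,
                             method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  if (length(before) != length(after))
    stop("before and after must have equal length")
  d <- as.numeric(after) - as.numeric(before)
  if (anyNA(d)) stop("missing values are not supported")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0)
    return(structure(list(statistic = 0, p_value = 1, method = "exact",
                          n_informative = 0L, n_zero = n_zero),
                     class = "rank_test"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  use_exact <- method == "exact" || (method == "auto" && m <= exact_limit)
  if (use_exact) {
    if (m > 30)
      stop("exact enumeration refused for ", m,
           " informative pairs; use method = 'normal_approx'")
    r2 <- as.integer(round(2 * r))   # midranks are multiples of 1/2
    S <- sum(r2)
    f <- numeric(S + 1)
    f[1] <- 1
    for (ri in r2)
      f[(ri + 1):(S + 1)] <- f[(ri + 1):(S + 1)] + f[1:(S + 1 - ri)]
    dev_obs <- abs(2 * v - S / 2)              # |V2 - E[V2]| with V2 = 2v
    devs <- abs(seq(0, S) - S / 2)
    p <- sum(f[devs >= dev_obs - 1e-9]) / 2^m
    used <- "exact"
  } else {
    ts <- tie_sum(abs(d))
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - ts / 48
    mu <- m * (m + 1) / 4
    z <- (abs(v - mu) - 0.5) / sqrt(sigma2)
    p <- if (sigma2 <= 0) 1 else min(1, 2 * pnorm(-max(z, 0)))
    used <- "normal_approx"
  }
  structure(list(statistic = v, p_value = p, method = used,
                 n_informative = m, n_zero = n_zero),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat("rank test (", x$method, "): statistic = ", format(x$statistic),
      ", p = ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Bonferroni adjustment
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @param m number of tests corrected for; defaults to `length(p)` (the
#'   genes tested within one comparison) and must be at least that.
#' @return `pmin(1, p * m)`.
#' @export
adjust_bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("m must be >= length(p)")
  pmin(1, p * m)
}

#' Marker log fold-change
#'
#' Natural-log ratio of pseudocount-shifted group means, the means taken on
#' the de-logged (`expm1`) scale of the normalized values.
#'
#' @param group_mean_expr,rest_mean_expr nonnegative mean expression of the
#'   group of interest and of the remaining cells.
#' @param pseudocount positive stabilizer (default 1).
#' @return `log((group_mean + pseudocount) / (rest_mean + pseudocount))`.
#' @export
log_fold_change <- function(group_mean_expr, rest_mean_expr, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log((group_mean_expr + pseudocount) / (rest_mean_expr + pseudocount))
}

#' Gene-gene correlation matrix across cells
#'
#' @param nm a [normalize_counts()] result (or any genes x cells matrix with
#'   symbol rownames).
#' @param genes genes to correlate ([gene_set()] or character); genes absent
#'   from the matrix are dropped with a warning, zero-variance genes are
#'   excluded and listed.
#' @param method `"pearson"` or `"spearman"`.
#' @return List of class `correlation_matrix` with elements `r` (symmetric,
#'   unit diagonal), `method`, `excluded_zero_variance`, `missing`.
#' @export
correlation_matrix <- function(nm, genes, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  values <- values_of(nm)
  if (ncol(values) < 3) stop("need at least 3 cells to correlate genes")
  genes <- genes_of(genes)
  missing <- setdiff(genes, rownames(values))
  if (length(missing))
    warning("genes absent from matrix: ", fmt_list(missing))
  genes <- intersect(genes, rownames(values))
  x <- t(as.matrix(values[genes, , drop = FALSE]))
  vars <- apply(x, 2, stats::var)
  zero_var <- colnames(x)[vars == 0]
  x <- x[, vars > 0, drop = FALSE]
  if (ncol(x) < 2)
    stop("fewer than 2 usable genes after dropping missing/zero-variance")
  r <- stats::cor(x, method = method)
  r[abs(r) > 1] <- sign(r[abs(r) > 1])  # guard numeric overshoot
  diag(r) <- 1
  structure(list(r = r, method = method,
                 excluded_zero_variance = zero_var, missing = missing),
            class = "correlation_matrix")
}

# --- vectorized rank-sum machinery for genome-wide scans ---------------------

# Precompute per-gene midranks and tie sums once per (matrix, cell subset);
# a group scan is then a single matrix product. The p-values agree exactly
# with rank_sum_test(method = "normal_approx").
#' @noRd
rank_precompute <- function(values) {
  m <- as.matrix(values)
  G <- nrow(m); n <- ncol(m)
  ranks <- matrix(0, G, n, dimnames = dimnames(m))
  ties <- numeric(G)
  for (g in seq_len(G)) {
    v <- m[g, ]
    ranks[g, ] <- rank(v)
    ties[g] <- tie_sum(v)
  }
  list(ranks = ranks, ties = ties, n = n, expm1 = expm1(m),
       nonzero = m > 0)
}

# Group-vs-rest scan: two-sided normal-approximation p, lfc on expm1 means,
# and detection fractions, for every gene at once.
#' @noRd
ranksum_scan <- function(pre, ind, pseudocount = 1) {
  ind <- as.logical(ind)
  n1 <- sum(ind); n2 <- pre$n - n1
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  w <- as.numeric(pre$ranks %*% ind)
  u <- w - n1 * (n1 + 1) / 2
  p <- ranksum_normal_p(u, n1, n2, pre$ties)
  mean_in <- as.numeric(pre$expm1 %*% ind) / n1
  mean_out <- as.numeric(pre$expm1 %*% (!ind)) / n2
  data.frame(gene = rownames(pre$ranks),
             lfc = log_fold_change(mean_in, mean_out, pseudocount),
             p_raw = p,
             pct_in = as.numeric(pre$nonzero %*% ind) / n1,
             pct_out = as.numeric(pre$nonzero %*% (!ind)) / n2,
             stringsAsFactors = FALSE)
}
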