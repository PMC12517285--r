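#' Gene-wise SAM statistics
#'
#' Two-class unpaired modified t-statistics. For gene i with group means
#' \eqn{\bar x_{i1}, \bar x_{i0}}:
#' \deqn{r_i = \bar x_{i1} - \bar x_{i0}, \quad
#'       s_i = \sqrt{a\,[\sum_{g0}(x-\bar x_0)^2 + \sum_{g1}(x-\bar x_1)^2]},
#'       \quad d_i = r_i / (s_i + s_0)}
#' with \eqn{a = (1/n_0 + 1/n_1)/(n_0 + n_1 - 2)}.
#'
#' @param matrix Numeric gene-by-sample matrix (log2 scale).
#' @param labels Named 0/1 vector covering every sample column.
#' @param s0 Non-negative fudge factor added to the gene-wise scatter.
#' @return A data frame with columns `gene_id`, `r`, `s`, `d`.
#' @export
sam_statistics <- function(matrix, labels, s0 = 0) {
  lab <- align_labels(matrix, labels)
  i0 <- which(lab == 0L); i1 <- which(lab == 1L)
  n0 <- length(i0); n1 <- length(i1)
  if (n0 < 2L || n1 < 2L)
    stop("each group needs at least 2 samples (got ", n0, " and ", n1, ")")
  m0 <- rowMeans(matrix[, i0, drop = FALSE])
  m1 <- rowMeans(matrix[, i1, drop = FALSE])
  ss0 <- rowSums((matrix[, i0, drop = FALSE] - m0)^2)
  ss1 <- rowSums((matrix[, i1, drop = FALSE] - m1)^2)
  a <- (1 / n0 + 1 / n1) / (n0 + n1 - 2)
  r <- m1 - m0
  s <- sqrt(a * (ss0 + ss1))
  denom <- s + s0
  if (any(denom == 0))
    stop("zero scatter and s0 = 0 for gene(s): ",
         paste(utils::head(rownames(matrix)[denom == 0], 5L), collapse = ", "))
  data.frame(gene_id = rownames(matrix), r = r, s = s, d = r / denom,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimate the SAM fudge factor s0
#'
#' Chooses s0 among \{0\} and the 5,10,...,100 percentiles of the gene
#' scatters s, minimizing the coefficient of variation of window-wise
#' median absolute deviations of d across s-quantile windows (at most 100
#' windows). Ties break toward the smallest candidate.
#'
#' @param r Per-gene relative differences.
#' @param s Per-gene scatters (non-negative).
#' @return The selected s0 (scalar).
#' @export
estimate_s0 <- function(r, s) {
  stopifnot(length(r) == length(s))
  if (length(s) < 20L) stop("need at least 20 genes to estimate s0")
  if (all(s == 0)) stop("all gene scatters are zero; s0 cannot be estimated")
  cand <- unique(c(0, stats::quantile(s, probs = seq(0.05, 1, by = 0.05),
                                      names = FALSE, type = 7)))
  n_win <- min(100L, max(2L, length(s) %/% 10L))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[is.finite(mads)]
    mu <- mean(mads)
    if (mu == 0) 0 else stats::sd(mads) / mu
  }, numeric(1L))
  # strict tolerance tie-break toward the smallest candidate
  best <- min(cv)
  cand[which(cv <= best + 1e-12)[1L]]
}

#' Permutation null for SAM
#'
#' Samples `n_perm` label permutations uniformly with replacement (the
#' identity permutation is permitted), recomputes all gene statistics per
#' permutation, and averages the sorted statistics across permutations to
#' give expected order statistics.  When the number of distinct label
#' assignments `choose(n, n1)` does not exceed `n_perm`, all distinct
#' assignments are enumerated instead.
#'
#' @param matrix,labels As in [sam_statistics()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed for reproducibility.
#' @param s0 Fudge factor used for the permuted statistics.
#' @param identity_only If TRUE (test hook), uses the identity permutation
#'   only, so the expected order statistics equal the sorted observed d.
#' @return List with `d_bar` (expected order statistics, ascending) and
#'   `d_perm` (gene-sorted statistics per permutation, genes x n_perm).
#' @export
sam_permutation_null <- function(matrix, labels, n_perm = 100L, seed = 1L,
                                 s0 = 0, identity_only = FALSE) {
  stopifnot(n_perm >= 1L)
  lab <- align_labels(matrix, labels)
  X <- matrix[, names(lab), drop = FALSE]
  n <- length(lab)
  n1 <- sum(lab == 1L)
  n0 <- n - n1
  if (identity_only) {
    d <- sam_statistics(matrix, labels, s0 = s0)$d
    d_perm <- matrix(sort(d), ncol = 1L)
    return(list(d_bar = d_perm[, 1L], d_perm = d_perm))
  }
  set.seed(seed)
  total <- suppressWarnings(choose(n, n1))
  if (is.finite(total) && total <= n_perm) {
    idx_sets <- utils::combn(n, n1, simplify = FALSE)
  } else {
    idx_sets <- replicate(n_perm, sample.int(n, n1), simplify = FALSE)
  }
  # vectorized across permutations: group sums via one matrix product,
  # within-group sums of squares from the total sum of squares
  ind <- matrix(0, n, length(idx_sets))
  for (b in seq_along(idx_sets)) ind[idx_sets[[b]], b] <- 1
  tot <- rowSums(X)
  tot_sq <- rowSums(X^2)
  S1 <- X %*% ind                      # genes x perms group-1 sums
  M1 <- S1 / n1
  M0 <- (tot - S1) / n0
  SS <- tot_sq - n1 * M1^2 - n0 * M0^2
  a <- (1 / n0 + 1 / n1) / (n0 + n1 - 2)
  d_perm <- (M1 - M0) / (sqrt(a * SS) + s0)
  d_perm <- apply(d_perm, 2L, sort)
  list(d_bar = rowMeans(d_perm), d_perm = d_perm)
}

#' Call differentially expressed genes at a delta threshold
#'
#' Pairs the sorted observed statistics with the expected order statistics;
#' the upper cutoff is the smallest sorted d whose excess over its expected
#' value reaches delta, the lower cutoff the largest sorted d falling short
#' by at least delta. Genes beyond either cutoff are called. The FDR is the
#' median count of permuted statistics beyond the cutoffs divided by the
#' number of calls, capped at 1.
#'
#' @param stats Data frame from [sam_statistics()].
#' @param null List from [sam_permutation_null()].
#' @param delta Non-negative threshold.
#' @return An object of class `sam_result`.
#' @export
sam_call_degs <- function(stats, null, delta) {
  stopifnot(delta >= 0, nrow(stats) == length(null$d_bar))
  ord <- order(stats$d)
  d_sorted <- stats$d[ord]
  diff_up <- d_sorted - null$d_bar
  up_idx <- which(diff_up >= delta)
  cut_up <- if (length(up_idx)) d_sorted[min(up_idx)] else Inf
  low_idx <- which(-diff_up >= delta)
  cut_low <- if (length(low_idx)) d_sorted[max(low_idx)] else -Inf
  called_up <- stats$d >= cut_up
  called_low <- stats$d <= cut_low
  deg_ids <- stats$gene_id[called_up | called_low]
  n_called <- length(deg_ids)
  if (n_called > 0L) {
    false_counts <- colSums(null$d_perm >= cut_up | null$d_perm <= cut_low)
    fdr <- min(1, stats::median(false_counts) / n_called)
  } else {
    fdr <- NA_real_
  }
  structure(list(
    table = data.frame(stats,
                       called = ifelse(called_up, "up",
                                       ifelse(called_low, "down", "no")),
                       stringsAsFactors = FALSE),
    s0 = attr(null, "s0"), delta = delta,
    cut_up = cut_up, cut_low = cut_low,
    deg_ids = deg_ids, fdr = fdr,
    expected = null$d_bar), class = "sam_result")
}

#' Run the full SAM analysis
#'
#' Convenience wrapper: statistics, fudge-factor estimation, permutation
#' null, and delta-threshold calls.
#'
#' @inheritParams sam_statistics
#' @param delta Delta threshold (app default 1).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param s0_mode `"auto"` to estimate s0, `"fixed"` to use `s0_value`.
#' @param s0_value Fixed s0 when `s0_mode = "fixed"`.
#' @return A `sam_result`.
#' @export
sam_deg <- function(matrix, labels, delta = 1, n_perm = 100L, seed = 1L,
                    s0_mode = c("auto", "fixed"), s0_value = NULL) {
  s0_mode <- match.arg(s0_mode)
  st <- sam_statistics(matrix, labels, s0 = 0)
  s0 <- if (s0_mode == "fixed") {
    stopifnot(!is.null(s0_value), s0_value >= 0)
    s0_value
  } else {
    estimate_s0(st$r, st$s)
  }
  st <- sam_statistics(matrix, labels, s0 = s0)
  null <- sam_permutation_null(matrix, labels, n_perm = n_perm, seed = seed,
                               s0 = s0)
  attr(null, "s0") <- s0
  sam_call_degs(st, null, delta)
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM result: ", nrow(x$table), " genes, delta = ", x$delta,
      ", s0 = ", signif(x$s0 %||% 0, 4), "\n",
      "  cutoffs [", signif(x$cut_low, 4), ", ", signif(x$cut_up, 4),
      "], called = ", length(x$deg_ids),
      ", FDR = ", signif(x$fdr, 3), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
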