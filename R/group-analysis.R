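#' Fit the base / node-effects / edge-effects model triple
#'
#' Fits three models to pooled-standardized data:
#' \itemize{
#' \item `fit_base`: the pooled model ignoring group membership.
#' \item `fit_node`: the pooled model augmented with a binary exogenous
#'   group variable directed into every node (group variance fixed at its
#'   sample value, group-residual covariances fixed at 0); captures
#'   group differences in baseline node levels.
#' \item `fit_edge`: a two-group model in which every path coefficient and
#'   residual (co)variance is estimated separately per group; captures
#'   group differences in edge weights.
#' }
#' Node columns are z-scored with pooled divisor-N statistics so group
#' mean differences are preserved for the node model. Likelihood-ratio
#' tests use exactly nested counterparts: the node model against itself
#' with all group paths fixed to zero, and the edge model against a
#' constrained two-group fit sharing one parameter vector.
#'
#' @param model A `sem_model` over the pathway nodes.
#' @param matrix Expression matrix (genes x samples).
#' @param labels Named 0/1 group vector covering the samples.
#' @param alpha Significance level for the invariance verdicts.
#' @return Object of class `group_model_set` with the three fits, a
#'   Fig.-style comparison table (`comparison`), and the two LRTs
#'   (`lrt_node`, `lrt_edge`).
#' @export
fit_group_models <- function(model, matrix, labels, alpha = 0.05) {
  lab <- align_labels(matrix, labels)
  p <- length(model$vars)
  n0 <- sum(lab == 0L); n1 <- sum(lab == 1L); N <- n0 + n1
  if (min(n0, n1) < p + 2L)
    warning("group sizes (", n0, ", ", n1,
            ") are small relative to p = ", p)
  X <- t(matrix[model$vars, names(lab), drop = FALSE])
  X <- zscore_cols(X)
  # base: pooled fit
  fit_base <- sem_engine(model, list(cov_n(X)), N)
  # node model: group as exogenous variable feeding every node
  vars2 <- c(model$vars, "group")
  Xg <- cbind(X, group = as.numeric(lab))
  S_node <- cov_n(Xg)
  dimnames(S_node) <- list(vars2, vars2)
  grow <- function(M, fill) {
    M2 <- matrix(fill, p + 1L, p + 1L, dimnames = list(vars2, vars2))
    M2[seq_len(p), seq_len(p)] <- M
    M2
  }
  B_free2 <- grow(model$B_free, FALSE)
  B_free2[seq_len(p), p + 1L] <- TRUE         # group -> every node
  Psi_free2 <- grow(model$Psi_free, FALSE)
  Psi_fixed2 <- grow(model$Psi_fixed, 0)
  Psi_fixed2[p + 1L, p + 1L] <- S_node["group", "group"]
  m_node <- new_sem_model(vars2, B_free2, Psi_free2, Psi_fixed2)
  fit_node <- sem_engine(m_node, list(S_node), N)
  B_free2z <- B_free2
  B_free2z[seq_len(p), p + 1L] <- FALSE       # null: no group paths
  m_node0 <- new_sem_model(vars2, B_free2z, Psi_free2, Psi_fixed2)
  fit_node0 <- sem_engine(m_node0, list(S_node), N)
  # edge model: independent per-group fits on within-group moments
  S0 <- cov_n(X[lab == 0L, , drop = FALSE])
  S1 <- cov_n(X[lab == 1L, , drop = FALSE])
  fit_e0 <- sem_engine(model, list(S0), n0, theta0 = fit_base$theta)
  fit_e1 <- sem_engine(model, list(S1), n1, theta0 = fit_base$theta)
  fit_edge <- list(fit0 = fit_e0, fit1 = fit_e1,
                   chisq = fit_e0$chisq + fit_e1$chisq,
                   df = fit_e0$df + fit_e1$df,
                   npar = 2L * model$t,
                   loglik = fit_e0$loglik + fit_e1$loglik,
                   N = N, n_list = c(n0, n1))
  # constrained two-group counterpart of the base model (for the LRT)
  fit_base2g <- sem_engine(model, list(S0, S1), c(n0, n1),
                           theta0 = fit_base$theta)
  lrt_edge <- lrt_compare(fit_base2g, fit_edge)
  lrt_node <- lrt_compare(fit_node0, fit_node)
  comparison <- rbind(
    cbind(model = "fit_base", fit_indices(fit_base)),
    cbind(model = "fit_node", fit_indices(fit_node)),
    cbind(model = "fit_edge", edge_fit_indices(fit_edge)))
  comparison$npar <- c(model$t, m_node$t, 2L * model$t)
  structure(list(fit_base = fit_base, fit_node = fit_node,
                 fit_node0 = fit_node0, fit_edge = fit_edge,
                 fit_base2g = fit_base2g, comparison = comparison,
                 lrt_node = lrt_node, lrt_edge = lrt_edge,
                 alpha = alpha, model = model),
            class = "group_model_set")
}

# indices for the assembled two-group edge fit
edge_fit_indices <- function(fe) {
  N <- fe$N
  pvalue <- if (fe$df > 0)
    stats::pchisq(fe$chisq, fe$df, lower.tail = FALSE) else 1
  idx0 <- fit_indices(fe$fit0); idx1 <- fit_indices(fe$fit1)
  p <- length(fe$fit0$model$vars)
  chisq_b <- 0
  for (fg in list(fe$fit0, fe$fit1)) {
    S <- fg$S_list[[1L]]
    chisq_b <- chisq_b + fg$N * (sum(log(diag(S))) -
                                 logdet_from_chol(chol(S)))
  }
  df_b <- 2 * (p * (p + 1) / 2 - p)
  num <- max(fe$chisq - fe$df, 0)
  den <- max(chisq_b - df_b, fe$chisq - fe$df, 0)
  sq_res <- unlist(lapply(list(fe$fit0, fe$fit1), function(fg) {
    S <- fg$S_list[[1L]]
    d <- sqrt(diag(S))
    R <- (S - fg$Sigma) / tcrossprod(d)
    R[upper.tri(R, diag = TRUE)]
  }))
  data.frame(npar = fe$npar, chisq = fe$chisq, df = fe$df, pvalue = pvalue,
             cfi = if (den == 0) 1 else 1 - num / den,
             aic = -2 * fe$loglik + 2 * fe$npar,
             bic = -2 * fe$loglik + fe$npar * log(N),
             rmsea = rmsea_value(fe$chisq, fe$df, N),
             srmr = sqrt(mean(sq_res^2)))
}

#' @export
print.group_model_set <- function(x, ...) {
  cat("group_model_set over", length(x$model$vars), "nodes\n")
  print(x$comparison, row.names = FALSE)
  cat("edge-vs-base LRT: delta_chisq = ", signif(x$lrt_edge$delta_chisq, 5),
      ", df = ", x$lrt_edge$delta_df, ", p = ",
      signif(x$lrt_edge$pvalue, 4), "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' @param fit_restricted,fit_full Objects with `chisq` and `df` fields;
#'   the restricted model must be nested in the full one on the same data.
#' @return List with `delta_chisq` (clamped at 0 with a warning if
#'   negative beyond 1e-6), `delta_df`, `pvalue`. Comparing a fit with
#'   itself yields (0, 0, 1).
#' @export
lrt_compare <- function(fit_restricted, fit_full) {
  d_chisq <- fit_restricted$chisq - fit_full$chisq
  d_df <- fit_restricted$df - fit_full$df
  if (d_df == 0 && abs(d_chisq) < 1e-6)
    return(list(delta_chisq = 0, delta_df = 0, pvalue = 1))
  if (d_df <= 0)
    stop("models are not nested: restricted df (", fit_restricted$df,
         ") must exceed full df (", fit_full$df, ")")
  if (d_chisq < 0) {
    if (d_chisq < -1e-6)
      warning("negative LRT statistic (", signif(d_chisq, 4),
              ") clamped to 0")
    d_chisq <- 0
  }
  list(delta_chisq = d_chisq, delta_df = d_df,
       pvalue = stats::pchisq(d_chisq, d_df, lower.tail = FALSE))
}

#' Group-to-node perturbation effects
#'
#' One row per node for the group -> node path of the node-effects model,
#' plus the node-invariance verdict: supported iff the node model's own
#' chi-square goodness-of-fit p-value exceeds alpha (the node-vs-base LRT
#' is reported alongside for transparency).
#'
#' @param set A `group_model_set`.
#' @return List with `table` (lhs, op, rhs, est, se, z, ci.lower,
#'   ci.upper), `verdict`, `gof_pvalue`, `lrt`.
#' @export
node_effects <- function(set) {
  stopifnot(inherits(set, "group_model_set"))
  pt <- parameter_table(set$fit_node)
  tab <- pt[pt$op == "~" & pt$rhs == "group", , drop = FALSE]
  rownames(tab) <- NULL
  gof_p <- fit_indices(set$fit_node)$pvalue
  list(table = tab,
       verdict = if (gof_p > set$alpha) "node invariance supported"
                 else "node invariance rejected",
       gof_pvalue = gof_p, lrt = set$lrt_node)
}

#' Per-edge group differences
#'
#' One row per directed edge with the group difference in path
#' coefficients from the two-group edge model:
#' d_est = beta1 - beta0, d_se = sqrt(se0^2 + se1^2), d_z = d_est/d_se and
#' the 95% Wald interval. The verdict rejects edge invariance iff the
#' edge-vs-base LRT p-value is below alpha.
#'
#' @param set A `group_model_set`.
#' @return List with `table` (lhs, op, rhs, d_est, d_se, d_z, d_lower,
#'   d_upper), `verdict`, `lrt`.
#' @export
edge_effects <- function(set) {
  stopifnot(inherits(set, "group_model_set"))
  t0 <- parameter_table(set$fit_edge$fit0)
  t1 <- parameter_table(set$fit_edge$fit1)
  sel <- t0$op == "~"
  d_est <- t1$est[sel] - t0$est[sel]
  d_se <- sqrt(t0$se[sel]^2 + t1$se[sel]^2)
  zcrit <- stats::qnorm(0.975)
  tab <- data.frame(lhs = t0$lhs[sel], op = "~", rhs = t0$rhs[sel],
                    d_est = d_est, d_se = d_se, d_z = d_est / d_se,
                    d_lower = d_est - zcrit * d_se,
                    d_upper = d_est + zcrit * d_se,
                    stringsAsFactors = FALSE)
  list(table = tab,
       verdict = if (set$lrt_edge$pvalue < set$alpha)
         "edge invariance rejected" else "edge invariance supported",
       lrt = set$lrt_edge)
}

#' Brown's method for combining dependent p-values
#'
#' Extends Fisher's method to correlated chi-square-based tests: with
#' X = -2 sum(log p_i), E = 2k and
#' V = 4k + 2 sum_\{i<j\} cov_ij, where cov_ij is approximated from the
#' correlation rho of the underlying statistics by the polynomial
#' rho (3.263 + rho (0.710 + 0.027 rho)) for rho >= 0 (mirrored for
#' negative rho), the combined p-value is the upper tail of a scaled
#' chi-square: X/c ~ chisq(f) with c = V/(2E), f = 2E^2/V. With all
#' correlations zero this reduces exactly to Fisher's combination.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @param stat_corr Optional k x k symmetric correlation matrix of the
#'   underlying test statistics (default: identity = independence).
#' @return List with X, E, V, c, f, p_combined.
#' @export
brown_combined <- function(p_values, stat_corr = NULL) {
  k <- length(p_values)
  stopifnot(k >= 1L)
  if (any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  if (is.null(stat_corr)) stat_corr <- diag(k)
  stopifnot(identical(dim(stat_corr), c(k, k)))
  if (max(abs(stat_corr - t(stat_corr))) > 1e-8)
    stop("stat_corr must be symmetric")
  X <- -2 * sum(log(p_values))
  E <- 2 * k
  cov_pair <- function(rho) {
    a <- abs(rho)
    sign(rho) * a * (3.263 + a * (0.710 + 0.027 * a))
  }
  cov_sum <- 0
  if (k > 1L)
    for (i in seq_len(k - 1L))
      for (j in (i + 1L):k)
        cov_sum <- cov_sum + cov_pair(stat_corr[i, j])
  V <- 4 * k + 2 * cov_sum
  cc <- V / (2 * E)
  f <- 2 * E^2 / V
  list(X = X, E = E, V = V, c = cc, f = f,
       p_combined = stats::pchisq(X / cc, f, lower.tail = FALSE))
}
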