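# ---- internal linear-algebra helpers -------------------------------------

chol_or_null <- function(M) tryCatch(chol(M), error = function(e) NULL)

logdet_from_chol <- function(R) 2 * sum(log(diag(R)))

# z-score columns using divisor-N standard deviations, so the resulting
# covariance (divisor N) is exactly a correlation matrix
zscore_cols <- function(X) {
  n <- nrow(X)
  ctr <- sweep(X, 2L, colMeans(X))
  sds <- sqrt(colSums(ctr^2) / n)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  sweep(ctr, 2L, sds, "/")
}

cov_n <- function(X) {
  ctr <- sweep(X, 2L, colMeans(X))
  crossprod(ctr) / nrow(X)
}

# derivative matrices dSigma/dtheta_k as a list of p x p matrices
sigma_derivs <- function(A, Sigma, idx) {
  derivs <- vector("list", idx$n_beta + idx$n_psi)
  for (k in seq_len(idx$n_beta)) {
    i <- idx$beta[k, 1L]; j <- idx$beta[k, 2L]
    Ck <- tcrossprod(A[, i], Sigma[j, ])
    derivs[[k]] <- Ck + t(Ck)
  }
  for (k in seq_len(idx$n_psi)) {
    i <- idx$psi[k, 1L]; j <- idx$psi[k, 2L]
    D <- tcrossprod(A[, i], A[, j])
    derivs[[idx$n_beta + k]] <- if (i == j) D else D + t(D)
  }
  derivs
}

# expected-information matrix of the ML fit function:
# H[k, l] = tr(Sigma^-1 dSigma_k Sigma^-1 dSigma_l)
expected_info <- function(Sigma_inv, derivs) {
  t_par <- length(derivs)
  V <- lapply(derivs, function(D) Sigma_inv %*% D %*% Sigma_inv)
  H <- matrix(0, t_par, t_par)
  for (k in seq_len(t_par))
    for (l in k:t_par)
      H[k, l] <- H[l, k] <- sum(V[[k]] * derivs[[l]])
  H
}

# evaluate the (possibly multigroup) ML discrepancy and its gradient
# at theta; returns NULL if Sigma is not PD or (I - B) is singular
sem_objective <- function(model, theta, idx, S_list, w) {
  mats <- theta_to_matrices(model, theta, idx)
  p <- length(model$vars)
  IB <- diag(p) - mats$B
  A <- tryCatch(solve(IB), error = function(e) NULL)
  if (is.null(A)) return(NULL)
  Sigma <- A %*% mats$Psi %*% t(A)
  Sigma <- (Sigma + t(Sigma)) / 2
  R <- chol_or_null(Sigma)
  if (is.null(R)) return(NULL)
  Sigma_inv <- chol2inv(R)
  logdet_S <- logdet_from_chol(R)
  F_tot <- 0
  W_tot <- matrix(0, p, p)
  for (g in seq_along(S_list)) {
    S <- S_list[[g]]
    F_g <- logdet_S - attr(S, "logdet") + sum(S * Sigma_inv) - p
    F_tot <- F_tot + w[g] * F_g
    W_tot <- W_tot + w[g] * (Sigma_inv - Sigma_inv %*% S %*% Sigma_inv)
  }
  GB <- 2 * t(Sigma %*% W_tot %*% A)      # dF/dB[i, j]
  GP <- t(A) %*% W_tot %*% A              # dF/dPsi (halved off-diagonal)
  grad <- numeric(idx$n_beta + idx$n_psi)
  if (idx$n_beta) grad[seq_len(idx$n_beta)] <- GB[idx$beta]
  if (idx$n_psi) {
    gp <- GP[idx$psi]
    off <- idx$psi[, 1L] != idx$psi[, 2L]
    gp[off] <- 2 * gp[off]
    grad[idx$n_beta + seq_len(idx$n_psi)] <- gp
  }
  list(F = F_tot, grad = grad, A = A, Sigma = Sigma, Sigma_inv = Sigma_inv,
       B = mats$B, Psi = mats$Psi)
}

# Fisher-scoring minimizer of the ML discrepancy
sem_engine <- function(model, S_list, n_list, theta0 = NULL,
                       max_iter = 10000L, tol = 1e-6) {
  idx <- param_index(model)
  N <- sum(n_list)
  w <- n_list / N
  p <- length(model$vars)
  for (g in seq_along(S_list)) {
    R <- chol_or_null(S_list[[g]])
    if (is.null(R))
      stop("sample covariance matrix (group ", g, ") is not positive definite")
    attr(S_list[[g]], "logdet") <- logdet_from_chol(R)
  }
  if (is.null(theta0)) {
    S_pool <- Reduce(`+`, Map(`*`, S_list, w))
    theta0 <- numeric(idx$n_beta + idx$n_psi)
    if (idx$n_psi) {
      v <- ifelse(idx$psi[, 1L] == idx$psi[, 2L],
                  diag(S_pool)[idx$psi[, 1L]], 0)
      theta0[idx$n_beta + seq_len(idx$n_psi)] <- v
    }
  }
  theta <- theta0
  ob <- sem_objective(model, theta, idx, S_list, w)
  if (is.null(ob))
    stop("starting values give a non-positive-definite implied covariance")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(ob$grad)) < tol) { converged <- TRUE; break }
    derivs <- sigma_derivs(ob$A, ob$Sigma, idx)
    H <- expected_info(ob$Sigma_inv, derivs)
    step <- tryCatch(solve(H, ob$grad), error = function(e) NULL)
    if (is.null(step)) {
      ridge <- 1e-8 * max(diag(H), 1)
      step <- solve(H + diag(ridge, nrow(H)), ob$grad)
    }
    alpha <- 1
    improved <- FALSE
    for (half in 1:40) {
      cand <- theta - alpha * step
      ob2 <- sem_objective(model, cand, idx, S_list, w)
      if (!is.null(ob2) && ob2$F <= ob$F + 1e-14) {
        theta <- cand; ob <- ob2; improved <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!improved) break  # stalled; convergence judged by the gradient
  }
  if (!converged && max(abs(ob$grad)) < tol) converged <- TRUE
  if (!converged)
    stop("ML estimation did not converge after ", iter,
         " iterations (gradient max ", signif(max(abs(ob$grad)), 3), ")")
  derivs <- sigma_derivs(ob$A, ob$Sigma, idx)
  H <- expected_info(ob$Sigma_inv, derivs)
  acov <- tryCatch((2 / N) * solve(H), error = function(e) {
    warning("information matrix singular at the solution; SEs unavailable")
    matrix(NA_real_, length(theta), length(theta))
  })
  se <- sqrt(pmax(diag(acov), 0))
  loglik <- 0
  for (g in seq_along(S_list))
    loglik <- loglik - (n_list[g] / 2) *
      (p * log(2 * pi) + logdet_from_chol(chol(ob$Sigma)) +
       sum(S_list[[g]] * ob$Sigma_inv))
  structure(list(
    model = model, S_list = S_list, n_list = n_list, N = N,
    theta = theta, se = se, z = theta / se,
    B = ob$B, Psi = ob$Psi, Sigma = ob$Sigma,
    F_ml = ob$F, chisq = N * ob$F,
    df = length(S_list) * p * (p + 1) / 2 - model$t,
    npar = model$t, loglik = loglik,
    converged = converged, iterations = iter,
    grad_norm = max(abs(ob$grad)), idx = idx), class = "sem_fit")
}

#' Fit a structural equation model by maximum likelihood
#'
#' Variables are z-scored (divisor-N standard deviations), the sample
#' covariance S uses divisor N, and the discrepancy
#' \deqn{F_{ML} = \ln|\Sigma| - \ln|S| + tr(S\Sigma^{-1}) - p}
#' is minimized by Fisher scoring with analytic gradients from the fixed
#' deterministic start B = 0, Psi = diag(S). The model chi-square is
#' N * F_ML; standard errors come from the inverse expected-information
#' matrix scaled by 1/N.
#'
#' @param model A `sem_model`.
#' @param data Expression matrix (genes x samples) containing every model
#'   variable as a row; or `NULL` when `S` is supplied.
#' @param samples Optional character/integer vector selecting sample
#'   columns.
#' @param S Optional sample covariance matrix (divisor N) to fit directly.
#' @param n Sample size (required with `S`).
#' @param standardize Z-score the data columns first (default TRUE;
#'   ignored when `S` is given).
#' @param max_iter,tol Optimizer controls (gradient infinity-norm
#'   convergence tolerance).
#' @return Object of class `sem_fit`.
#' @export
fit_ml <- function(model, data = NULL, samples = NULL, S = NULL, n = NULL,
                   standardize = TRUE, max_iter = 10000L, tol = 1e-6) {
  if (is.null(S)) {
    stopifnot(!is.null(data))
    miss <- setdiff(model$vars, rownames(data))
    if (length(miss))
      stop("model variable(s) missing from data: ",
           paste(miss, collapse = ", "))
    X <- t(data[model$vars, , drop = FALSE])
    if (!is.null(samples)) X <- X[samples, , drop = FALSE]
    n <- nrow(X)
    if (standardize) X <- zscore_cols(X)
    S <- cov_n(X)
  } else {
    stopifnot(!is.null(n))
    stopifnot(identical(dim(S), c(length(model$vars), length(model$vars))))
    dimnames(S) <- list(model$vars, model$vars)
  }
  p <- length(model$vars)
  if (n <= p)
    warning("sample size (", n, ") does not exceed the number of variables (",
            p, "); estimates may be unstable")
  sem_engine(model, list(S), n, max_iter = max_iter, tol = tol)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("sem_fit: ", length(x$model$vars), " variables, npar = ", x$npar,
      ", N = ", x$N, "\n  chisq(", x$df, ") = ", signif(x$chisq, 6),
      ", F_ml = ", signif(x$F_ml, 6),
      ", converged in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Goodness-of-fit indices for a fitted SEM
#'
#' Computes the chi-square test, RMSEA
#' \eqn{\sqrt{\max(\chi^2 - df, 0)/(df\,N)}}, SRMR (root mean squared
#' residual between sample and implied correlation matrices over the
#' p(p+1)/2 unique cells, diagonal included), CFI against the independence
#' baseline (free variances only), AIC and BIC. With df = 0 the
#' conventions rmsea = 0 and pvalue = 1 apply.
#'
#' @param fit A converged `sem_fit`.
#' @return Data frame row with npar, chisq, df, pvalue, cfi, aic, bic,
#'   rmsea, srmr.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"), fit$converged)
  chisq <- fit$chisq; df <- fit$df; N <- fit$N
  p <- length(fit$model$vars)
  pvalue <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else 1
  rmsea <- rmsea_value(chisq, df, N)
  # baseline independence model: per-group free variances only
  chisq_b <- 0
  for (g in seq_along(fit$S_list)) {
    S <- fit$S_list[[g]]
    F_b <- sum(log(diag(S))) - logdet_from_chol(chol(S))
    chisq_b <- chisq_b + fit$n_list[g] * F_b
  }
  G <- length(fit$S_list)
  df_b <- G * p * (p + 1) / 2 - G * p
  num <- max(chisq - df, 0)
  den <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  sq_res <- unlist(lapply(fit$S_list, function(S) {
    d <- sqrt(diag(S))
    R <- (S - fit$Sigma) / tcrossprod(d)
    R[upper.tri(R, diag = TRUE)]
  }))
  srmr <- sqrt(mean(sq_res^2))
  data.frame(npar = fit$npar, chisq = chisq, df = df, pvalue = pvalue,
             cfi = cfi, aic = -2 * fit$loglik + 2 * fit$npar,
             bic = -2 * fit$loglik + fit$npar * log(N),
             rmsea = rmsea, srmr = srmr)
}

#' RMSEA from a chi-square statistic
#'
#' @param chisq,df,N Chi-square value, degrees of freedom, total sample
#'   size.
#' @return `sqrt(max(chisq - df, 0) / (df * N))`; 0 when df = 0.
#' @export
rmsea_value <- function(chisq, df, N) {
  if (df == 0) return(0)
  sqrt(max(chisq - df, 0) / (df * N))
}

#' Parameter estimates table
#'
#' One row per free parameter with lavaan-style columns: `lhs ~ rhs` for a
#' path coefficient (lhs regressed on rhs) and `lhs ~~ rhs` for a residual
#' (co)variance; est, se, z = est/se and the 95% Wald interval
#' est +/- 1.959964 se.
#'
#' @param fit A converged `sem_fit`.
#' @return Data frame with columns lhs, op, rhs, est, se, z, ci.lower,
#'   ci.upper.
#' @export
parameter_table <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"), fit$converged)
  lab <- param_labels(fit$model, fit$idx)
  zcrit <- stats::qnorm(0.975)
  data.frame(lab, est = fit$theta, se = fit$se, z = fit$theta / fit$se,
             ci.lower = fit$theta - zcrit * fit$se,
             ci.upper = fit$theta + zcrit * fit$se,
             stringsAsFactors = FALSE)
}

#' Modification indices
#'
#' Univariate score (Lagrange-multiplier) statistics for currently fixed
#' parameters: the expected chi-square decrease if the parameter were
#' freed, with the expected parameter change (EPC). Computed at the ML
#' solution from the analytic gradient and the efficient information
#' (curvature adjusted for the free parameters).
#'
#' @param fit A converged `sem_fit`.
#' @param candidates Optional data frame with columns lhs, op, rhs
#'   restricting the candidate set; default = all fixed beta (i != j) and
#'   all fixed off-diagonal psi.
#' @return Data frame (lhs, op, rhs, mi, epc) sorted by mi descending.
#' @export
modification_indices <- function(fit, candidates = NULL) {
  stopifnot(inherits(fit, "sem_fit"), fit$converged)
  model <- fit$model
  p <- length(model$vars)
  if (is.null(candidates)) {
    cand <- NULL
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i != j && !model$B_free[i, j])
        cand <- rbind(cand, data.frame(lhs = model$vars[i], op = "~",
                                       rhs = model$vars[j],
                                       stringsAsFactors = FALSE))
    }
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i < j && !model$Psi_free[i, j])
        cand <- rbind(cand, data.frame(lhs = model$vars[i], op = "~~",
                                       rhs = model$vars[j],
                                       stringsAsFactors = FALSE))
    }
    candidates <- cand
  }
  if (is.null(candidates) || nrow(candidates) == 0L)
    return(data.frame(lhs = character(), op = character(),
                      rhs = character(), mi = numeric(), epc = numeric(),
                      stringsAsFactors = FALSE))
  # drop candidates that are already free
  lab_free <- param_labels(model, fit$idx)
  key <- function(d) ifelse(d$op == "~~",
                            paste(pmin(d$lhs, d$rhs), d$op,
                                  pmax(d$lhs, d$rhs)),
                            paste(d$lhs, d$op, d$rhs))
  candidates <- candidates[!key(candidates) %in% key(lab_free), ,
                           drop = FALSE]
  w <- fit$n_list / fit$N
  ob <- sem_objective(model, fit$theta, fit$idx, fit$S_list, w)
  derivs <- sigma_derivs(ob$A, ob$Sigma, fit$idx)
  H_free <- expected_info(ob$Sigma_inv, derivs)
  H_free_inv <- tryCatch(solve(H_free), error = function(e) NULL)
  if (is.null(H_free_inv))
    stop("information matrix of the free parameters is singular")
  W_tot <- matrix(0, p, p)
  for (g in seq_along(fit$S_list))
    W_tot <- W_tot + w[g] *
      (ob$Sigma_inv - ob$Sigma_inv %*% fit$S_list[[g]] %*% ob$Sigma_inv)
  A <- ob$A; Sigma <- ob$Sigma; Sigma_inv <- ob$Sigma_inv
  SWA <- Sigma %*% W_tot %*% A
  AWA <- t(A) %*% W_tot %*% A
  vi <- function(nm) match(nm, model$vars)
  out <- candidates
  out$mi <- NA_real_; out$epc <- NA_real_
  for (r in seq_len(nrow(candidates))) {
    i <- vi(candidates$lhs[r]); j <- vi(candidates$rhs[r])
    if (anyNA(c(i, j))) stop("unknown variable in candidate list, row ", r)
    if (candidates$op[r] == "~") {
      g_c <- 2 * SWA[j, i]
      Ck <- tcrossprod(A[, i], Sigma[j, ])
      D_c <- Ck + t(Ck)
    } else {
      g_c <- 2 * AWA[i, j]
      D <- tcrossprod(A[, i], A[, j])
      D_c <- D + t(D)
    }
    V_c <- Sigma_inv %*% D_c %*% Sigma_inv
    H_cc <- sum(V_c * D_c)
    H_cf <- vapply(derivs, function(Dk) sum(V_c * Dk), numeric(1L))
    h_eff <- H_cc - drop(H_cf %*% H_free_inv %*% H_cf)
    if (!is.finite(h_eff) || h_eff <= 1e-12) {
      warning("singular efficient information for candidate ",
              candidates$lhs[r], " ", candidates$op[r], " ",
              candidates$rhs[r], "; skipped")
      next
    }
    out$mi[r] <- (fit$N / 2) * g_c^2 / h_eff
    out$epc[r] <- -g_c / h_eff
  }
  out <- out[!is.na(out$mi), , drop = FALSE]
  out[order(-out$mi), , drop = FALSE]
}

#' Add paths to a fitted model and refit
#'
#' Augments the model with new directed paths and/or bidirected residual
#' covariances and refits to the same sample moments, warm-started from
#' the previous solution.
#'
#' @param fit A converged `sem_fit`.
#' @param new_edges Data frame with columns lhs, op ("~" or "~~"), rhs; a
#'   row `Y ~ X` frees the path X -> Y.
#' @return The refitted `sem_fit`.
#' @export
add_paths_refit <- function(fit, new_edges) {
  stopifnot(inherits(fit, "sem_fit"))
  model <- fit$model
  B_free <- model$B_free
  Psi_free <- model$Psi_free
  for (r in seq_len(NROW(new_edges))) {
    i <- match(new_edges$lhs[r], model$vars)
    j <- match(new_edges$rhs[r], model$vars)
    if (anyNA(c(i, j)))
      stop("unknown variable in addition: ", new_edges$lhs[r], " / ",
           new_edges$rhs[r])
    if (new_edges$op[r] == "~") {
      if (B_free[i, j]) stop("duplicate path addition: ",
                             new_edges$lhs[r], " ~ ", new_edges$rhs[r])
      B_free[i, j] <- TRUE
    } else if (new_edges$op[r] == "~~") {
      if (Psi_free[i, j]) stop("duplicate covariance addition: ",
                               new_edges$lhs[r], " ~~ ", new_edges$rhs[r])
      Psi_free[i, j] <- Psi_free[j, i] <- TRUE
    } else stop("unknown operator: ", new_edges$op[r])
  }
  model2 <- new_sem_model(model$vars, B_free, Psi_free, model$Psi_fixed)
  idx2 <- param_index(model2)
  theta0 <- numeric(idx2$n_beta + idx2$n_psi)
  # warm start: carry over old estimates by parameter location
  old <- theta_to_matrices(model, fit$theta, fit$idx)
  if (idx2$n_beta) theta0[seq_len(idx2$n_beta)] <- old$B[idx2$beta]
  if (idx2$n_psi)
    theta0[idx2$n_beta + seq_len(idx2$n_psi)] <- old$Psi[idx2$psi]
  sem_engine(model2, fit$S_list, fit$n_list, theta0 = theta0)
}
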