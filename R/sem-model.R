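#' Build an observed-variable SEM from a pathway graph
#'
#' Each node becomes an observed variable; a directed edge j -> i frees the
#' path coefficient beta_ij (row i, column j of B); a bidirected pair frees
#' the residual covariance psi_ij. Residual variances (diagonal of Psi) are
#' always free. Fixed entries are exactly 0 unless overridden (used
#' internally for the exogenous group variable). The model covariance is
#' \deqn{\Sigma(\theta) = (I - B)^{-1} \Psi (I - B)^{-T}.}
#'
#' @param graph A `pathway_graph`.
#' @return Object of class `sem_model` with fields `vars`, `B_free`,
#'   `Psi_free`, `Psi_fixed`, `t` (free parameter count), `df`.
#' @export
build_sem_model <- function(graph) {
  vars <- graph$nodes
  p <- length(vars)
  if (p == 0L) stop("empty graph: no variables")
  B_free <- matrix(FALSE, p, p, dimnames = list(vars, vars))
  for (e in seq_len(nrow(graph$directed)))
    B_free[graph$directed$target[e], graph$directed$source[e]] <- TRUE
  Psi_free <- diag(p) == 1
  dimnames(Psi_free) <- list(vars, vars)
  for (e in seq_len(nrow(graph$bidirected))) {
    Psi_free[graph$bidirected$n1[e], graph$bidirected$n2[e]] <- TRUE
    Psi_free[graph$bidirected$n2[e], graph$bidirected$n1[e]] <- TRUE
  }
  new_sem_model(vars, B_free, Psi_free)
}

# internal constructor shared by build_sem_model and the group models
new_sem_model <- function(vars, B_free, Psi_free, Psi_fixed = NULL) {
  p <- length(vars)
  if (is.null(Psi_fixed))
    Psi_fixed <- matrix(0, p, p, dimnames = list(vars, vars))
  t_par <- sum(B_free) + sum(diag(Psi_free)) +
    sum(Psi_free[lower.tri(Psi_free)])
  df <- p * (p + 1) / 2 - t_par
  if (df < 0)
    stop("model not identified: ", t_par, " free parameters exceed ",
         p * (p + 1) / 2, " sample moments for p = ", p, " variables")
  structure(list(vars = vars, B_free = B_free, Psi_free = Psi_free,
                 Psi_fixed = Psi_fixed, t = t_par, df = df),
            class = "sem_model")
}

#' @export
print.sem_model <- function(x, ...) {
  cat("sem_model: ", length(x$vars), " variables, ", sum(x$B_free),
      " free paths, ",
      sum(diag(x$Psi_free)) + sum(x$Psi_free[lower.tri(x$Psi_free)]),
      " free (co)variances; t = ", x$t, ", df = ", x$df, "\n", sep = "")
  invisible(x)
}

# internal: index bookkeeping for the parameter vector
# order: free beta (column-major over B_free), then free psi
# (lower triangle incl. diagonal, column-major)
param_index <- function(model) {
  p <- length(model$vars)
  bidx <- which(model$B_free)
  lower <- which(lower.tri(model$Psi_free, diag = TRUE) & model$Psi_free)
  ij <- function(lin) cbind((lin - 1L) %% p + 1L, (lin - 1L) %/% p + 1L)
  list(beta = ij(bidx), psi = ij(lower),
       n_beta = length(bidx), n_psi = length(lower))
}

theta_to_matrices <- function(model, theta, idx = param_index(model)) {
  p <- length(model$vars)
  B <- matrix(0, p, p, dimnames = list(model$vars, model$vars))
  if (idx$n_beta) B[idx$beta] <- theta[seq_len(idx$n_beta)]
  Psi <- model$Psi_fixed
  if (idx$n_psi) {
    v <- theta[idx$n_beta + seq_len(idx$n_psi)]
    Psi[idx$psi] <- v
    Psi[idx$psi[, c(2, 1), drop = FALSE]] <- v
  }
  list(B = B, Psi = Psi)
}

param_labels <- function(model, idx = param_index(model)) {
  v <- model$vars
  lab <- function(m, op) data.frame(lhs = v[m[, 1L]], op = op,
                                    rhs = v[m[, 2L]],
                                    stringsAsFactors = FALSE)
  rbind(if (idx$n_beta) lab(idx$beta, "~"),
        if (idx$n_psi) lab(idx$psi, "~~"))
}
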