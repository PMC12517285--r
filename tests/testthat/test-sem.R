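test_that("model construction counts parameters and guards identification", {
  # 3-node chain: t = 2 paths + 3 variances = 5, df = 6 - 5 = 1
  g <- pathway_graph("c3", directed = data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = 1L))
  m <- build_sem_model(g)
  expect_equal(m$t, 5)
  expect_equal(m$df, 1)
  # edgeless p-node graph: df = p(p+1)/2 - p
  g0 <- pathway_graph("iso", nodes = paste0("n", 1:4))
  expect_equal(build_sem_model(g0)$df, 10 - 4)
  # directed + bidirected on 2 nodes: t = 4 > 3 moments
  g2 <- pathway_graph("over", directed = data.frame(
    source = "A", target = "B", sign = 1L),
    bidirected = data.frame(n1 = "A", n2 = "B"))
  expect_error(build_sem_model(g2), "not identified")
})

test_that("saturated and perfect-fit models recover exactly", {
  set.seed(20)
  nodes <- c("A", "B", "C")
  # saturated: all covariances free -> F = 0, Sigma == S
  gsat <- pathway_graph("sat", bidirected = data.frame(
    n1 = c("A", "A", "B"), n2 = c("B", "C", "C")), nodes = nodes)
  msat <- build_sem_model(gsat)
  expect_equal(msat$df, 0)
  dat <- matrix(rnorm(3 * 50), 3, 50,
                dimnames = list(nodes, paste0("s", 1:50)))
  fsat <- fit_ml(msat, dat)
  expect_lt(abs(fsat$chisq), 1e-8)
  expect_lt(max(abs(fsat$Sigma - fsat$S_list[[1]])), 1e-8)
  idx <- fit_indices(fsat)
  expect_equal(idx$rmsea, 0)
  expect_equal(idx$pvalue, 1)
  # perfect-fit identity: S = Sigma(theta*) recovers theta*
  gch <- pathway_graph("c3", directed = data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = 1L))
  mch <- build_sem_model(gch)
  B <- matrix(0, 3, 3); B[2, 1] <- 0.6; B[3, 2] <- -0.4
  Psi <- diag(c(1, 0.5, 0.8))
  A <- solve(diag(3) - B)
  S_star <- A %*% Psi %*% t(A)
  fit <- fit_ml(mch, S = S_star, n = 100)
  expect_lt(abs(fit$chisq), 1e-8)
  expect_equal(fit$theta, c(0.6, -0.4, 1, 0.5, 0.8), tolerance = 1e-6)
})

test_that("ML equals equation-wise least squares on recursive models", {
  set.seed(21)
  for (fx_name in c("chain5", "diamond")) {
    g <- fixture_pathways()[[fx_name]]$graph
    model <- build_sem_model(g)
    p <- length(model$vars)
    B <- matrix(0, p, p, dimnames = list(model$vars, model$vars))
    B[model$B_free] <- runif(sum(model$B_free), 0.3, 0.7)
    Psi <- diag(p); dimnames(Psi) <- list(model$vars, model$vars)
    spec <- simulation_spec(B, B, Psi, n0 = 100, n1 = 100,
                            seed = sample.int(1e6, 1))
    sim <- simulate_from_sem(spec)
    fit <- fit_ml(model, sim$matrix)
    pt <- parameter_table(fit)
    X <- pathsem:::zscore_cols(t(sim$matrix[model$vars, ]))
    for (v in model$vars) {
      parents <- model$vars[model$B_free[v, ]]
      if (!length(parents)) next
      ols <- coef(lm(X[, v] ~ X[, parents, drop = FALSE]))[-1]
      est <- pt$est[pt$op == "~" & pt$lhs == v]
      names(est) <- pt$rhs[pt$op == "~" & pt$lhs == v]
      expect_equal(unname(est[parents]), unname(ols), tolerance = 1e-6)
    }
  }
})

test_that("parameter table identities and CI coverage", {
  set.seed(22)
  g <- pathway_graph("ab", directed = data.frame(
    source = "A", target = "B", sign = 1L))
  model <- build_sem_model(g)
  sim <- simulate_from_sem(simulation_spec(
    matrix(c(0, 0.5, 0, 0), 2, 2, byrow = FALSE,
           dimnames = list(c("A", "B"), c("A", "B"))),
    Psi = diag(c(1, 0.75)), n0 = 100, n1 = 100, seed = 4))
  fit <- fit_ml(model, sim$matrix)
  pt <- parameter_table(fit)
  expect_equal(pt$z, pt$est / pt$se, tolerance = 1e-9)
  expect_equal(pt$ci.upper - pt$est, 1.959964 * pt$se, tolerance = 1e-6)
  # coverage of the standardized path (true value 0.5) over replicates
  covered <- vapply(1:100, function(i) {
    sim <- simulate_from_sem(simulation_spec(
      matrix(c(0, 0.5, 0, 0), 2, 2,
             dimnames = list(c("A", "B"), c("A", "B"))),
      Psi = diag(c(1, 0.75)), n0 = 250, n1 = 250, seed = 1000 + i))
    pt <- parameter_table(fit_ml(model, sim$matrix))
    pt$ci.lower[1] <= 0.5 && 0.5 <= pt$ci.upper[1]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("fit indices track their formulas", {
  set.seed(23)
  w <- chain5_world(seed = 30)
  model <- build_sem_model(w$graph)
  fit <- fit_ml(model, w$matrix)
  idx <- fit_indices(fit)
  expect_equal(idx$rmsea, rmsea_value(fit$chisq, fit$df, fit$N))
  expect_equal(idx$aic, -2 * fit$loglik + 2 * fit$npar)
  expect_equal(idx$bic, -2 * fit$loglik + fit$npar * log(fit$N))
  expect_true(idx$cfi >= 0 && idx$cfi <= 1)
  expect_true(idx$srmr >= 0)
  # srmr recomputation from residual correlations
  S <- fit$S_list[[1]]
  d <- sqrt(diag(S))
  R <- (S - fit$Sigma) / tcrossprod(d)
  expect_equal(idx$srmr,
               sqrt(mean(R[upper.tri(R, diag = TRUE)]^2)),
               tolerance = 1e-12)
})

test_that("modification indices find an omitted path; nesting holds", {
  set.seed(24)
  nodes <- c("A", "B", "C", "D", "E")
  model <- build_sem_model(fixture_pathways()$chain5$graph)
  B <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  for (k in 1:4) B[k + 1, k] <- 0.5
  B[3, 1] <- 0.7
  Psi <- diag(5); dimnames(Psi) <- list(nodes, nodes)
  sim <- simulate_from_sem(simulation_spec(B, B, Psi, n0 = 250, n1 = 250,
                                           seed = 31))
  fit <- fit_ml(model, sim$matrix)
  mi <- suppressWarnings(modification_indices(fit))
  # already-free parameters never appear as candidates
  expect_false(any(mi$op == "~" & mi$lhs == "B" & mi$rhs == "A"))
  # the omitted path attains the maximal MI (ties with equivalent
  # one-parameter modifications are possible)
  mi_omit <- mi$mi[mi$op == "~" & mi$lhs == "C" & mi$rhs == "A"]
  expect_equal(mi_omit, max(mi$mi), tolerance = 1e-6)
  expect_true(all(mi$mi >= 0))
  expect_true(all(diff(mi$mi) <= 1e-9))  # sorted descending
  # freeing paths: chisq non-increasing, df drops by number added
  fit2 <- add_paths_refit(fit, data.frame(lhs = "C", op = "~", rhs = "A"))
  expect_lte(fit2$chisq, fit$chisq + 1e-8)
  expect_equal(fit2$df, fit$df - 1)
  expect_error(add_paths_refit(fit2, data.frame(lhs = "C", op = "~",
                                                rhs = "A")), "duplicate")
  # empty addition list returns an equivalent fit
  fit3 <- add_paths_refit(fit, data.frame(lhs = character(),
                                          op = character(),
                                          rhs = character()))
  expect_lt(abs(fit3$chisq - fit$chisq), 1e-8)
  # iterative additions give a monotone non-increasing chisq sequence
  cur <- fit
  seq_chisq <- cur$chisq
  for (step in 1:3) {
    mi_cur <- suppressWarnings(modification_indices(cur))
    if (!nrow(mi_cur) || cur$df == 0) break
    cur <- add_paths_refit(cur, mi_cur[1, c("lhs", "op", "rhs")])
    seq_chisq <- c(seq_chisq, cur$chisq)
  }
  expect_true(all(diff(seq_chisq) <= 1e-8))
})

test_that("cyclic models fit as long as (I - B) stays invertible", {
  set.seed(25)
  g <- fixture_pathways()$`inhibit-loop`$graph
  model <- build_sem_model(g)
  nodes <- g$nodes
  B <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  B[2, 1] <- 0.5; B[3, 2] <- 0.5; B[1, 3] <- -0.3
  Psi <- diag(3); dimnames(Psi) <- list(nodes, nodes)
  sim <- simulate_from_sem(simulation_spec(B, B, Psi, n0 = 300, n1 = 300,
                                           seed = 32))
  fit <- fit_ml(model, sim$matrix)
  expect_true(fit$converged)
  expect_equal(fit$df, 0)  # 3 paths + 3 variances = 6 = moments
  expect_lt(abs(fit$chisq), 1e-6)
})
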