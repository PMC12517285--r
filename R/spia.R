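#' Over-representation p-value (hypergeometric tail)
#'
#' Probability of observing at least `m` differentially expressed genes on
#' a pathway of `k` genes when `D` of the `G` universe genes are DE.
#'
#' @param m DE genes on the pathway.
#' @param k Pathway genes present in the universe.
#' @param D Total DE genes in the universe.
#' @param G Universe size.
#' @return Upper-tail probability P(X >= m), X ~ Hypergeometric(G, D, k).
#' @export
ora_pnde <- function(m, k, D, G) {
  stopifnot(D <= G, k <= G, m >= 0)
  if (m > min(k, D))
    stop("m = ", m, " exceeds min(k, D) = ", min(k, D))
  stats::phyper(m - 1, D, G - D, k, lower.tail = FALSE)
}

# internal: signed, out-degree-normalized influence matrix M[i, j]
influence_matrix <- function(graph) {
  p <- length(graph$nodes)
  M <- matrix(0, p, p, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$directed)) {
    outdeg <- table(factor(graph$directed$source, levels = graph$nodes))
    for (e in seq_len(nrow(graph$directed))) {
      j <- graph$directed$source[e]; i <- graph$directed$target[e]
      M[i, j] <- graph$directed$sign[e] / outdeg[[j]]
    }
  }
  M
}

#' Topological perturbation factors
#'
#' Solves the linear propagation system PF = dE + M PF, where
#' M[i, j] = sign(j -> i) / outdegree(j), yielding each gene's perturbation
#' factor, its net accumulation Acc = PF - dE, and the total accumulation
#' tA = sum(Acc).
#'
#' @param graph A `pathway_graph`.
#' @param delta_e Named (or graph-ordered) vector of log2 fold-changes, 0
#'   for non-DE genes.
#' @return List with `pf`, `acc`, `ta`.
#' @export
perturbation_factors <- function(graph, delta_e) {
  p <- length(graph$nodes)
  if (p == 0L) stop("empty pathway graph")
  de <- if (!is.null(names(delta_e))) {
    stopifnot(all(graph$nodes %in% names(delta_e)))
    delta_e[graph$nodes]
  } else {
    stopifnot(length(delta_e) == p)
    stats::setNames(delta_e, graph$nodes)
  }
  M <- influence_matrix(graph)
  A <- diag(p) - M
  pf <- tryCatch(solve(A, de),
                 error = function(e)
                   stop("singular (I - M) for pathway '", graph$name, "'"))
  acc <- pf - de
  list(pf = stats::setNames(pf, graph$nodes),
       acc = stats::setNames(acc, graph$nodes), ta = sum(acc))
}

#' Bootstrap p-value for the total accumulation
#'
#' The null redistributes `n_de` fold-change values drawn from the
#' DE-value pool onto uniformly chosen pathway genes; the observed tA is
#' compared two-sidedly against the median-centered bootstrap
#' distribution, with an add-one correction.
#'
#' @param graph A `pathway_graph`.
#' @param ta_obs Observed total accumulation.
#' @param de_pool Pool of DE log2 fold-changes to resample from.
#' @param n_de Number of DE genes to place on the pathway per iteration.
#' @param n_boot Bootstrap iterations (>= 100).
#' @param seed RNG seed.
#' @return The bootstrap p-value pPERT.
#' @export
ppert_bootstrap <- function(graph, ta_obs, de_pool, n_de, n_boot = 2000L,
                            seed = 1L) {
  stopifnot(n_de >= 1L, length(de_pool) >= 1L, n_boot >= 100L)
  p <- length(graph$nodes)
  M <- influence_matrix(graph)
  # tA is linear in dE: tA = w' dE with w = colSums((I - M)^-1 - I)
  w <- colSums(solve(diag(p) - M) - diag(p))
  set.seed(seed)
  ta_b <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(p, min(n_de, p))
    vals <- sample(de_pool, length(idx), replace = TRUE)
    sum(w[idx] * vals)
  }, numeric(1L))
  med <- stats::median(ta_b)
  (sum(abs(ta_b - med) >= abs(ta_obs - med)) + 1) / (n_boot + 1)
}

#' Combine over-representation and perturbation p-values
#'
#' Uses the product combination: for c = pNDE * pPERT,
#' pG = c - c * log(c).
#'
#' @param pnde,ppert p-values in (0, 1].
#' @return Combined global p-value pG in (0, 1].
#' @export
combine_global_p <- function(pnde, ppert) {
  if (any(c(pnde, ppert) <= 0) || any(c(pnde, ppert) > 1))
    stop("p-values must lie in (0, 1]")
  cc <- pnde * ppert
  cc - cc * log(cc)
}

#' Rank pathways by combined perturbation evidence
#'
#' For each pathway: k = pathway genes on the array, m = called DEGs on the
#' pathway, pNDE = hypergeometric tail, tA from the propagation model with
#' dE = SAM relative differences of called DEGs (0 elsewhere), pPERT by
#' bootstrap, pG by the product combination, BH-adjusted across pathways.
#' Pathways with a singular propagation system are dropped with a warning.
#'
#' @param pathways List of `pathway_graph` objects.
#' @param sam A `sam_result` (supplies DEG calls and fold-changes).
#' @param matrix Expression matrix defining the gene universe (its rows).
#' @param n_boot,seed Bootstrap parameters.
#' @return Data frame sorted by pG (ties broken by name) with columns
#'   pathway, k, m, pNDE, tA, pPERT, pG, pG_fdr, status.
#' @export
rank_pathways <- function(pathways, sam, matrix, n_boot = 2000L, seed = 1L) {
  if (length(pathways) == 0L) stop("empty pathway list")
  universe <- rownames(matrix)
  G <- length(universe)
  degs <- intersect(sam$deg_ids, universe)
  D <- length(degs)
  r_all <- stats::setNames(sam$table$r, sam$table$gene_id)
  de_pool <- r_all[degs]
  rows <- lapply(seq_along(pathways), function(ix) {
    pw <- pathways[[ix]]
    on_array <- intersect(pw$nodes, universe)
    k <- length(on_array)
    m <- length(intersect(on_array, degs))
    pnde <- if (k == 0L || D == 0L) 1 else ora_pnde(m, k, D, G)
    de <- stats::setNames(rep(0, length(pw$nodes)), pw$nodes)
    de[intersect(pw$nodes, degs)] <- r_all[intersect(pw$nodes, degs)]
    res <- tryCatch({
      pf <- perturbation_factors(pw, de)
      ppert <- if (m >= 1L && length(de_pool))
        ppert_bootstrap(pw, pf$ta, de_pool, m, n_boot = n_boot,
                        seed = seed)
      else 1
      list(ta = pf$ta, ppert = ppert, status = "ok")
    }, error = function(e) {
      warning("pathway '", pw$name, "' dropped: ", conditionMessage(e))
      list(ta = NA_real_, ppert = NA_real_, status = "singular")
    })
    data.frame(pathway = pw$name, k = k, m = m, pNDE = pnde, tA = res$ta,
               pPERT = res$ppert,
               pG = if (res$status == "ok") combine_global_p(pnde, res$ppert)
                    else NA_real_,
               status = res$status, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$pG_fdr <- NA_real_
  ok <- tab$status == "ok"
  tab$pG_fdr[ok] <- stats::p.adjust(tab$pG[ok], method = "BH")
  tab[order(tab$pG, tab$pathway, na.last = TRUE), , drop = FALSE]
}
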