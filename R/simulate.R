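#' Specify a two-group linear SEM simulation
#'
#' The generative model for a sample in group g is
#' \deqn{y = (I - B_g)^{-1}(\gamma g + \zeta), \quad \zeta \sim N(0, \Psi),}
#' embedded in a background of independent Gaussian genes, a subset of
#' which receives a mean shift in group 1.
#'
#' @param B0,B1 Group-specific path-coefficient matrices (square, with
#'   dimnames naming the pathway genes); `B1` defaults to `B0`.
#' @param Psi Residual covariance (symmetric positive definite).
#' @param gamma Group-to-node effect vector (recycled scalar allowed).
#' @param n0,n1 Group sample sizes.
#' @param n_background Number of null background genes.
#' @param n_shifted Background genes receiving a mean shift in group 1.
#' @param shift Mean shift (log2 units).
#' @param noise_sd Background noise standard deviation.
#' @param seed RNG seed.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(B0, B1 = B0, Psi, gamma = 0, n0, n1,
                            n_background = 0L, n_shifted = 0L, shift = 0,
                            noise_sd = 1, seed = 1L) {
  p <- nrow(B0)
  stopifnot(identical(dim(B0), dim(B1)), identical(dim(Psi), dim(B0)),
            n0 > 0, n1 > 0, n_shifted <= n_background)
  if (is.null(rownames(B0))) {
    nm <- paste0("g", seq_len(p))
    dimnames(B0) <- dimnames(B1) <- dimnames(Psi) <- list(nm, nm)
  }
  gamma <- rep_len(gamma, p)
  for (B in list(B0, B1))
    if (abs(det(diag(p) - B)) < 1e-12)
      stop("(I - B) is singular for a group")
  if (max(abs(Psi - t(Psi))) > 1e-12 || is.null(chol_or_null(Psi)))
    stop("Psi must be symmetric positive definite")
  structure(list(B0 = B0, B1 = B1, Psi = Psi, gamma = gamma,
                 n0 = as.integer(n0), n1 = as.integer(n1),
                 n_background = as.integer(n_background),
                 n_shifted = as.integer(n_shifted), shift = shift,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate expression data from a structural model
#'
#' @param spec A `simulation_spec`.
#' @return List with `matrix` (genes x samples: pathway genes first, then
#'   background genes `bg...`) and `labels` (named 0/1 vector). Sample
#'   column order is randomized within group; reproducible for a fixed
#'   seed.
#' @export
simulate_from_sem <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  p <- nrow(spec$B0)
  genes <- rownames(spec$B0)
  cP <- chol(spec$Psi)
  draw_group <- function(n, B, g) {
    A <- solve(diag(p) - B)
    Z <- matrix(stats::rnorm(n * p), n, p) %*% cP   # zeta
    Y <- (Z + matrix(spec$gamma * g, n, p, byrow = TRUE)) %*% t(A)
    t(Y)
  }
  Y0 <- draw_group(spec$n0, spec$B0, 0)
  Y1 <- draw_group(spec$n1, spec$B1, 1)
  nb <- spec$n_background
  if (nb > 0L) {
    bg_names <- sprintf("bg%04d", seq_len(nb))
    BG0 <- matrix(stats::rnorm(nb * spec$n0, sd = spec$noise_sd), nb,
                  spec$n0)
    BG1 <- matrix(stats::rnorm(nb * spec$n1, sd = spec$noise_sd), nb,
                  spec$n1)
    if (spec$n_shifted > 0L)
      BG1[seq_len(spec$n_shifted), ] <-
        BG1[seq_len(spec$n_shifted), , drop = FALSE] + spec$shift
    Y0 <- rbind(Y0, BG0); Y1 <- rbind(Y1, BG1)
    genes <- c(genes, bg_names)
  }
  s0 <- paste0("ctrl", seq_len(spec$n0))[sample.int(spec$n0)]
  s1 <- paste0("case", seq_len(spec$n1))[sample.int(spec$n1)]
  M <- cbind(Y0, Y1)
  dimnames(M) <- list(genes, c(s0, s1))
  labels <- stats::setNames(c(rep(0L, spec$n0), rep(1L, spec$n1)),
                            c(s0, s1))
  list(matrix = M, labels = labels)
}

#' Bundled pathway graph fixtures
#'
#' Four small graphs with matching protein-family maps:
#' \describe{
#' \item{chain5}{A -> B -> C -> D -> E, all activation.}
#' \item{diamond}{Two activation branches A -> B -> D and A -> C -> D.}
#' \item{inhibit-loop}{A -> B -> C with an inhibiting edge C -> A closing
#'   the cycle.}
#' \item{fcgamma-toy}{A 12-node phagocytosis-like toy graph whose four
#'   designated DEGs are CRKL, ARF6, PLA2G4A and ARPC4.}
#' }
#'
#' @return Named list; each element has `graph` (a `pathway_graph`),
#'   `family` (named character map) and `deg_ids`.
#' @export
fixture_pathways <- function() {
  chain <- function(nodes, signs = rep(1L, length(nodes) - 1L), name) {
    pathway_graph(name, directed = data.frame(
      source = nodes[-length(nodes)], target = nodes[-1L], sign = signs))
  }
  chain5 <- chain(c("A", "B", "C", "D", "E"), name = "chain5")
  diamond <- pathway_graph("diamond", directed = data.frame(
    source = c("A", "B", "A", "C"), target = c("B", "D", "C", "D"),
    sign = 1L))
  loop <- pathway_graph("inhibit-loop", directed = data.frame(
    source = c("A", "B", "C"), target = c("B", "C", "A"),
    sign = c(1L, 1L, -1L)))
  fc_edges <- data.frame(
    source = c("FCGR1A", "FCGR1A", "SYK",  "SYK",   "CRKL", "CRKL",
               "PIP5K1C", "RAC1", "WASF2", "ARPC4", "PLCG1", "PRKCA"),
    target = c("SYK",    "PLCG1",  "CRKL", "PIP5K1C", "ARF6", "RAC1",
               "PLA2G4A", "WASF2", "ARPC4", "ARPC5", "PRKCA", "PLA2G4A"),
    sign   = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, -1L),
    stringsAsFactors = FALSE)
  fcg <- pathway_graph("fcgamma-toy", directed = fc_edges)
  list(
    chain5 = list(graph = chain5,
                  family = c(B = "famBC", C = "famBC"),
                  deg_ids = c("A", "E")),
    diamond = list(graph = diamond,
                   family = c(B = "branch", C = "branch"),
                   deg_ids = c("A", "D")),
    `inhibit-loop` = list(graph = loop, family = character(0),
                          deg_ids = c("A", "C")),
    `fcgamma-toy` = list(
      graph = fcg,
      family = c(WASF2 = "ARP_actin", ARPC5 = "ARP_actin"),
      deg_ids = c("CRKL", "ARF6", "PLA2G4A", "ARPC4")))
}

# chain coefficient matrices with pooled-unit-variance residuals:
# node k has variance ~1 in each group when betas are equal, and pooled
# variance ~1 when they differ symmetrically
chain_sem_matrices <- function(nodes, beta0, beta1 = beta0) {
  p <- length(nodes)
  B0 <- B1 <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (k in seq_len(p - 1L)) {
    B0[k + 1L, k] <- beta0[k]
    B1[k + 1L, k] <- beta1[k]
  }
  psi <- c(1, 1 - (beta0[seq_len(p - 1L)]^2 + beta1[seq_len(p - 1L)]^2) / 2)
  Psi <- diag(psi)
  dimnames(Psi) <- list(nodes, nodes)
  list(B0 = B0, B1 = B1, Psi = Psi)
}

#' Scenario registry
#'
#' @return Sorted character vector of bundled end-to-end scenario names.
#' @export
scenario_registry <- function() sort(c("null", "perturbed-chain"))

#' Generate a ready-to-run end-to-end scenario
#'
#' \describe{
#' \item{null}{chain5 (all path coefficients 0.5) with no group effects
#'   anywhere, 2000 background genes, none shifted; 150 samples/group.}
#' \item{perturbed-chain}{chain5 with the C ~ B path differing between
#'   groups (0.25 vs 0.75, difference 0.5 on the standardized scale),
#'   group-to-node effects making the chain genes differentially
#'   expressed, embedded in 2000 background genes with 40 mean-shifted
#'   genes (shift 1.5); 150 samples/group, plus 20 null pathways of 5
#'   random background genes each.}
#' }
#'
#' @param name Scenario name from [scenario_registry()].
#' @param seed RNG seed.
#' @return List with `matrix`, `labels`, `pathways` (list of
#'   `pathway_graph`), `spec` and `truth` (machine-readable ground truth).
#' @export
end_to_end_scenario <- function(name, seed = 1L) {
  if (!name %in% scenario_registry())
    stop("unknown scenario '", name, "'; registry: ",
         paste(scenario_registry(), collapse = ", "))
  nodes <- c("A", "B", "C", "D", "E")
  fx <- fixture_pathways()
  if (name == "null") {
    m <- chain_sem_matrices(nodes, beta0 = rep(0.5, 4))
    spec <- simulation_spec(m$B0, m$B1, m$Psi, gamma = 0, n0 = 150,
                            n1 = 150, n_background = 2000L,
                            n_shifted = 0L, shift = 0, seed = seed)
    sim <- simulate_from_sem(spec)
    return(list(matrix = sim$matrix, labels = sim$labels,
                pathways = list(fx$chain5$graph), spec = spec,
                truth = list(group_effects = FALSE,
                             perturbed_edge = NULL, d_true = 0)))
  }
  # perturbed-chain
  beta0 <- c(0.5, 0.25, 0.5, 0.5)
  beta1 <- c(0.5, 0.75, 0.5, 0.5)
  m <- chain_sem_matrices(nodes, beta0, beta1)
  gamma <- c(1.0, 0.8, 0.8, 0.8, 0.8)
  spec <- simulation_spec(m$B0, m$B1, m$Psi, gamma = gamma, n0 = 150,
                          n1 = 150, n_background = 2000L, n_shifted = 40L,
                          shift = 1.5, seed = seed)
  sim <- simulate_from_sem(spec)
  # 20 null pathways over random background genes
  set.seed(seed + 1000L)
  bg <- grep("^bg", rownames(sim$matrix), value = TRUE)
  null_pw <- lapply(seq_len(20L), function(i) {
    g <- sample(bg, 5L)
    pathway_graph(sprintf("null%02d", i), directed = data.frame(
      source = g[-5L], target = g[-1L], sign = 1L))
  })
  list(matrix = sim$matrix, labels = sim$labels,
       pathways = c(list(fx$chain5$graph), null_pw), spec = spec,
       truth = list(group_effects = TRUE,
                    perturbed_edge = c(lhs = "C", rhs = "B"),
                    d_true = 0.5, de_pathway = "chain5",
                    shifted_genes = sprintf("bg%04d", 1:40)))
}
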