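test_that("SIF reading maps relations to signs and bidirected pairs", {
  f <- write_tmp(c("A\tactivation\tB", "B\tinhibition\tC",
                   "A\tcovariance\tC"), ext = ".sif")
  g <- read_pathway_graph(f)
  expect_setequal(g$nodes, c("A", "B", "C"))
  expect_equal(g$directed$sign[g$directed$source == "A"], 1L)
  expect_equal(g$directed$sign[g$directed$source == "B"], -1L)
  expect_identical(g$bidirected, data.frame(n1 = "A", n2 = "C",
                                            stringsAsFactors = FALSE))
  bad <- write_tmp(c("A\tbinds\tB"), ext = ".sif")
  expect_error(read_pathway_graph(bad), "unknown relation 'binds'")
})

test_that("write/read round-trip preserves a 20-edge graph", {
  set.seed(6)
  nodes <- paste0("n", 1:12)
  e <- data.frame(source = sample(nodes, 20, TRUE),
                  target = sample(nodes, 20, TRUE),
                  sign = sample(c(-1L, 1L), 20, TRUE))
  e <- e[e$source != e$target, ]
  e <- e[!duplicated(paste(e$source, e$target)), ]
  g <- pathway_graph("toy", directed = e,
                     bidirected = data.frame(n1 = "n1", n2 = "n2"),
                     nodes = c(nodes, "iso"))
  f <- tempfile(fileext = ".sif")
  write_pathway_graph(g, f)
  expect_identical_graph(read_pathway_graph(f), g)
})

test_that("graph invariants are enforced at construction", {
  expect_error(pathway_graph("x", directed = data.frame(
    source = "A", target = "A", sign = 1L)), "self-loop")
  expect_error(pathway_graph("x", directed = data.frame(
    source = c("A", "A"), target = c("B", "B"), sign = c(1L, -1L))),
    "duplicate")
  expect_error(pathway_graph("x", directed = data.frame(
    source = "A", target = "B", sign = 2L)), "sign")
})

test_that("annotate_degs flags exactly the present DEGs, idempotently", {
  fx <- fixture_pathways()$`fcgamma-toy`
  g <- annotate_degs(fx$graph, fx$deg_ids)
  expect_identical(sort(names(g$is_deg)[g$is_deg]),
                   sort(c("CRKL", "ARF6", "PLA2G4A", "ARPC4")))
  expect_identical(annotate_degs(g, fx$deg_ids)$is_deg, g$is_deg)
  g0 <- annotate_degs(fx$graph, c("NOPE1", "NOPE2"))
  expect_false(any(g0$is_deg))
})

test_that("shortest-path module extraction keeps ties and uses fallback", {
  chain <- pathway_graph("chain", directed = data.frame(
    source = c("A", "B"), target = c("B", "C"), sign = 1L))
  mod <- extract_perturbation_module(chain, c("A", "C"))
  expect_setequal(mod$nodes, c("A", "B", "C"))
  expect_equal(nrow(mod$directed), 2L)
  # diamond: both tied length-2 paths retained
  diamond <- fixture_pathways()$diamond$graph
  mod2 <- extract_perturbation_module(diamond, c("A", "D"))
  expect_setequal(mod2$nodes, c("A", "B", "C", "D"))
  # direction reversal yields the same module as the forward case
  rev_chain <- pathway_graph("rev", directed = data.frame(
    source = c("C", "B"), target = c("B", "A"), sign = 1L))
  mod3 <- extract_perturbation_module(rev_chain, c("A", "C"))
  expect_setequal(mod3$nodes, c("A", "B", "C"))
  # undirected fallback when no directed path in either direction
  vee <- pathway_graph("vee", directed = data.frame(
    source = c("B", "B"), target = c("A", "C"), sign = 1L))
  mod4 <- extract_perturbation_module(vee, c("A", "C"))
  expect_setequal(mod4$nodes, c("A", "B", "C"))
  # module is a subgraph containing all DEGs
  fx <- fixture_pathways()$`fcgamma-toy`
  mod5 <- extract_perturbation_module(fx$graph, fx$deg_ids)
  expect_true(all(mod5$nodes %in% fx$graph$nodes))
  expect_true(all(fx$deg_ids %in% mod5$nodes))
  expect_error(extract_perturbation_module(chain, character(0)), "no DEG")
})

test_that("family merging averages z-scored members and guards signs", {
  g <- pathway_graph("fam", directed = data.frame(
    source = c("A", "B", "C"), target = c("B", "D", "D"),
    sign = c(1L, 1L, 1L)))
  g <- annotate_degs(g, c("A", "D"))
  set.seed(8)
  base <- rnorm(30)
  m <- rbind(A = rnorm(30), B = 2 * base + 5, C = -1 + 0.5 * base,
             D = rnorm(30))
  colnames(m) <- paste0("s", 1:30)
  fam <- c(B = "famBC", C = "famBC")
  out <- merge_pir_superfamilies(g, m, fam)
  expect_setequal(out$graph$nodes, c("A", "famBC", "D"))
  # perfectly correlated members: merged profile = either z-scored member
  z <- (base - mean(base)) / sd(base)
  expect_equal(unname(out$matrix["famBC", ]), unname(z), tolerance = 1e-12)
  # empty family map is the identity
  out0 <- merge_pir_superfamilies(g, m, character(0))
  expect_identical(out0$graph$nodes, g$nodes)
  # DEG members are never merged
  fam2 <- c(A = "famAD", D = "famAD")
  out2 <- merge_pir_superfamilies(g, m, fam2)
  expect_setequal(out2$graph$nodes, c("A", "B", "C", "D"))
  # node count arithmetic: |nodes| - members + families
  expect_equal(length(out$graph$nodes), 4L - 2L + 1L)
  # sign conflict after merge is an error
  g2 <- annotate_degs(pathway_graph("conf", directed = data.frame(
    source = c("A", "A"), target = c("B", "C"), sign = c(1L, -1L))),
    c("A"))
  expect_error(merge_pir_superfamilies(g2, m, fam), "sign conflict")
})

test_that("partial-correlation pruning keeps true edges, drops spurious", {
  set.seed(10)
  n <- 500
  x <- rnorm(n); y <- 0.8 * x + rnorm(n, sd = 0.6)
  z <- 0.8 * y + rnorm(n, sd = 0.6)
  m <- rbind(X = x, Y = y, Z = z)
  colnames(m) <- paste0("s", 1:n)
  g <- pathway_graph("chainplus", directed = data.frame(
    source = c("X", "Y", "X"), target = c("Y", "Z", "Z"), sign = 1L))
  pruned <- prune_by_partial_correlation(g, m, alpha = 0.05)
  keys <- paste(pruned$directed$source, pruned$directed$target)
  expect_true(all(c("X Y", "Y Z") %in% keys))
  expect_false("X Z" %in% keys)
  # strongly correlated single-parent edge at n = 100 is kept
  set.seed(11)
  x2 <- rnorm(100); y2 <- 0.9 * x2 + rnorm(100, sd = sqrt(1 - 0.81))
  m2 <- rbind(X = x2, Y = y2); colnames(m2) <- paste0("s", 1:100)
  g2 <- pathway_graph("one", directed = data.frame(
    source = "X", target = "Y", sign = 1L))
  p2 <- prune_by_partial_correlation(g2, m2, alpha = 0.05)
  expect_equal(nrow(p2$directed), 1L)
  # alpha = 1 is the identity on edges; pruning never adds edges
  p3 <- prune_by_partial_correlation(g, m, alpha = 1)
  expect_equal(nrow(p3$directed), nrow(g$directed))
  expect_lte(nrow(pruned$directed), nrow(g$directed))
  expect_error(prune_by_partial_correlation(
    g, m[, 1:4], alpha = 0.05), "insufficient")
})
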