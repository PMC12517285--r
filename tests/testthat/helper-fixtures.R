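# shared helpers: tiny files and canonical simulation worlds

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

tiny_expression_file <- function() {
  write_tmp(c("gene_id\ts1\ts2",
              "g1\t1.0\t2.0",
              "g2\t3.5\t4.5",
              "g3\t5.0\t6.0"))
}

# chain5 world: correctly specified 5-node chain, unit pooled variances
chain5_world <- function(beta0 = rep(0.5, 4), beta1 = beta0, gamma = 0,
                         n0 = 100, n1 = 100, seed = 1, ...) {
  nodes <- c("A", "B", "C", "D", "E")
  m <- pathsem:::chain_sem_matrices(nodes, beta0, beta1)
  spec <- simulation_spec(m$B0, m$B1, m$Psi, gamma = gamma, n0 = n0,
                          n1 = n1, seed = seed, ...)
  c(simulate_from_sem(spec), list(spec = spec,
    graph = fixture_pathways()$chain5$graph))
}

expect_identical_graph <- function(g1, g2) {
  expect_setequal(g1$nodes, g2$nodes)
  key <- function(g) sort(paste(g$directed$source, g$directed$sign,
                                g$directed$target))
  expect_identical(key(g1), key(g2))
  bkey <- function(g) sort(paste(g$bidirected$n1, g$bidirected$n2))
  expect_identical(bkey(g1), bkey(g2))
}
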