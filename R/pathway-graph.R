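#' Construct a pathway graph
#'
#' A pathway graph is a signed directed gene graph with optional bidirected
#' edges standing for free residual covariances due to unmeasured common
#' causes. Directed edges carry sign +1 (activation) or -1 (inhibition).
#'
#' @param name Pathway label.
#' @param directed Data frame with columns `source`, `target`, `sign`.
#' @param bidirected Data frame with columns `n1`, `n2` (unordered pairs).
#' @param nodes Optional character vector of nodes (isolated nodes allowed);
#'   nodes appearing in edges are always included, in edge order.
#' @return Object of class `pathway_graph` with fields `name`, `nodes`,
#'   `is_deg` (named logical), `directed`, `bidirected`.
#' @export
pathway_graph <- function(name, directed = NULL, bidirected = NULL,
                          nodes = NULL) {
  directed <- if (is.null(directed) || nrow(directed) == 0L)
    data.frame(source = character(), target = character(), sign = integer(),
               stringsAsFactors = FALSE)
  else data.frame(source = as.character(directed$source),
                  target = as.character(directed$target),
                  sign = as.integer(directed$sign),
                  stringsAsFactors = FALSE)
  bidirected <- if (is.null(bidirected) || nrow(bidirected) == 0L)
    data.frame(n1 = character(), n2 = character(), stringsAsFactors = FALSE)
  else {
    b <- data.frame(n1 = as.character(bidirected$n1),
                    n2 = as.character(bidirected$n2),
                    stringsAsFactors = FALSE)
    swap <- b$n1 > b$n2
    tmp <- b$n1[swap]; b$n1[swap] <- b$n2[swap]; b$n2[swap] <- tmp
    unique(b)
  }
  if (any(directed$source == directed$target))
    stop("self-loop directed edge on: ",
         paste(directed$source[directed$source == directed$target],
               collapse = ", "))
  if (!all(directed$sign %in% c(-1L, 1L)))
    stop("directed edge signs must be +1 or -1")
  key <- paste(directed$source, directed$target)
  if (anyDuplicated(key))
    stop("duplicate directed edge: ", key[duplicated(key)][1L])
  if (any(bidirected$n1 == bidirected$n2))
    stop("bidirected self-pair on: ",
         bidirected$n1[bidirected$n1 == bidirected$n2][1L])
  all_nodes <- unique(c(as.character(nodes),
                        directed$source, directed$target,
                        bidirected$n1, bidirected$n2))
  structure(list(name = name, nodes = all_nodes,
                 is_deg = stats::setNames(rep(FALSE, length(all_nodes)),
                                          all_nodes),
                 directed = directed, bidirected = bidirected),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph '", x$name, "': ", length(x$nodes), " nodes, ",
      nrow(x$directed), " directed edges, ", nrow(x$bidirected),
      " bidirected pairs, ", sum(x$is_deg), " DEGs\n", sep = "")
  invisible(x)
}

# internal: igraph view of the directed part (bidirected pairs excluded)
as_igraph_directed <- function(graph) {
  igraph::graph_from_data_frame(
    graph$directed[, c("source", "target")],
    directed = TRUE,
    vertices = data.frame(name = graph$nodes, stringsAsFactors = FALSE))
}

#' Read a pathway graph from SIF or GraphML
#'
#' The SIF dialect is a 3-column TSV `source  relation  target` with
#' relation in \{activation, inhibition, covariance\}. Lines with a single
#' field declare isolated nodes. GraphML files must carry an edge attribute
#' `relation` (same tokens) or `sign` (+1/-1).
#'
#' @param path Input file.
#' @param format `"sif"` or `"graphml"`; default inferred from extension.
#' @param name Pathway label; defaults to the file base name.
#' @return A `pathway_graph`.
#' @export
read_pathway_graph <- function(path, format = NULL, name = NULL) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "sif"
  if (is.null(name))
    name <- sub("\\.[^.]+$", "", basename(path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    ed <- igraph::as_data_frame(g, what = "edges")
    attrs <- names(ed)
    sign <- if ("sign" %in% attrs) as.integer(ed$sign)
    else if ("relation" %in% attrs)
      ifelse(ed$relation == "inhibition", -1L,
             ifelse(ed$relation == "activation", 1L, NA_integer_))
    else rep(1L, nrow(ed))
    bid <- if ("relation" %in% attrs) ed$relation == "covariance"
    else rep(FALSE, nrow(ed))
    if (anyNA(sign[!bid])) stop("unknown relation token in GraphML edge")
    return(pathway_graph(
      name,
      directed = data.frame(source = ed$from[!bid], target = ed$to[!bid],
                            sign = sign[!bid]),
      bidirected = data.frame(n1 = ed$from[bid], n2 = ed$to[bid]),
      nodes = igraph::V(g)$name))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  iso <- vapply(fields, length, integer(1L)) == 1L
  bad <- !iso & lengths(fields) != 3L
  if (any(bad))
    stop("SIF line ", which(bad)[1L], " does not have 3 fields")
  ed <- fields[!iso]
  rel <- vapply(ed, `[[`, character(1L), 2L)
  unknown <- !rel %in% c("activation", "inhibition", "covariance")
  if (any(unknown))
    stop("unknown relation '", rel[unknown][1L], "' at SIF line ",
         which(!iso)[unknown][1L])
  src <- vapply(ed, `[[`, character(1L), 1L)
  tgt <- vapply(ed, `[[`, character(1L), 3L)
  bid <- rel == "covariance"
  pathway_graph(
    name,
    directed = data.frame(source = src[!bid], target = tgt[!bid],
                          sign = ifelse(rel[!bid] == "inhibition", -1L, 1L)),
    bidirected = data.frame(n1 = src[bid], n2 = tgt[bid]),
    nodes = unlist(fields[iso]))
}

#' Write a pathway graph in the SIF dialect
#'
#' @param graph A `pathway_graph`.
#' @param path Output file.
#' @export
write_pathway_graph <- function(graph, path) {
  rel <- ifelse(graph$directed$sign < 0, "inhibition", "activation")
  lines <- c(
    if (nrow(graph$directed))
      paste(graph$directed$source, rel, graph$directed$target, sep = "\t"),
    if (nrow(graph$bidirected))
      paste(graph$bidirected$n1, "covariance", graph$bidirected$n2,
            sep = "\t"))
  touched <- unique(c(graph$directed$source, graph$directed$target,
                      graph$bidirected$n1, graph$bidirected$n2))
  lines <- c(lines, setdiff(graph$nodes, touched))
  writeLines(lines, path)
  invisible(path)
}

#' Flag differentially expressed genes on a graph
#'
#' @param graph A `pathway_graph`.
#' @param deg_ids Character vector of DEG identifiers.
#' @return The graph with `is_deg` set to membership in `deg_ids`.
#' @export
annotate_degs <- function(graph, deg_ids) {
  graph$is_deg <- stats::setNames(graph$nodes %in% deg_ids, graph$nodes)
  graph
}

#' Extract the shortest-path perturbation module
#'
#' The module consists of all nodes lying on any shortest directed path
#' between any ordered pair of DEGs (all tied shortest paths are kept).
#' For DEG pairs with no directed path in either direction, the shortest
#' undirected path serves as fallback. Edges are those induced by the
#' retained node set.
#'
#' @param graph A `pathway_graph` with DEG annotations (or supply
#'   `deg_ids`).
#' @param deg_ids Optional DEG list; defaults to the graph's flags.
#' @return A `pathway_graph` restricted to the module, DEG-annotated.
#' @export
extract_perturbation_module <- function(graph, deg_ids = NULL) {
  if (!is.null(deg_ids)) graph <- annotate_degs(graph, deg_ids)
  degs <- names(graph$is_deg)[graph$is_deg]
  if (length(degs) == 0L) stop("no DEG present in graph '", graph$name, "'")
  ig <- as_igraph_directed(graph)
  keep <- character(0)
  if (length(degs) >= 2L) {
    pairs <- utils::combn(degs, 2L, simplify = FALSE)
    for (pr in pairs) {
      fwd <- suppressWarnings(
        igraph::all_shortest_paths(ig, pr[1L], pr[2L], mode = "out")$vpaths)
      bwd <- suppressWarnings(
        igraph::all_shortest_paths(ig, pr[2L], pr[1L], mode = "out")$vpaths)
      paths <- c(fwd, bwd)
      if (length(paths) == 0L)
        paths <- suppressWarnings(
          igraph::all_shortest_paths(ig, pr[1L], pr[2L], mode = "all")$vpaths)
      for (p in paths) keep <- c(keep, igraph::V(ig)$name[as.integer(p)])
    }
  }
  keep <- unique(c(degs, keep))
  keep <- graph$nodes[graph$nodes %in% keep]  # preserve declaration order
  sub <- pathway_graph(
    graph$name,
    directed = graph$directed[graph$directed$source %in% keep &
                              graph$directed$target %in% keep, ],
    bidirected = graph$bidirected[graph$bidirected$n1 %in% keep &
                                  graph$bidirected$n2 %in% keep, ],
    nodes = keep)
  annotate_degs(sub, degs)
}

#' Merge non-DEG module nodes into protein-family nodes
#'
#' Non-DEG nodes sharing a family label collapse into one node named by the
#' family; the merged node's expression profile is the per-sample mean of
#' the z-scored member profiles. Edges re-attach to the merged node with
#' sign preserved; a sign conflict for the same ordered pair is an error.
#' DEG nodes are never merged.
#'
#' @param graph A DEG-annotated `pathway_graph`.
#' @param matrix Expression matrix containing every module gene.
#' @param fam Named character vector gene_id -> family_id (partial).
#' @return List with `graph` (merged) and `matrix` (expression rows for the
#'   merged graph's nodes, merged profiles included).
#' @export
merge_pir_superfamilies <- function(graph, matrix, fam) {
  miss <- setdiff(graph$nodes, rownames(matrix))
  if (length(miss))
    stop("module gene(s) missing from expression matrix: ",
         paste(miss, collapse = ", "))
  if (length(fam) == 0L)
    return(list(graph = graph, matrix = matrix[graph$nodes, , drop = FALSE]))
  fam <- fam[names(fam) %in% graph$nodes]
  mergeable <- names(fam)[!graph$is_deg[names(fam)]]
  groups <- split(mergeable, fam[mergeable])
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L)
    return(list(graph = graph, matrix = matrix[graph$nodes, , drop = FALSE]))
  rename <- stats::setNames(graph$nodes, graph$nodes)
  zscore <- function(x) {
    sdx <- stats::sd(x)
    if (sdx == 0) stop("zero-variance member profile: cannot z-score")
    (x - mean(x)) / sdx
  }
  merged_rows <- list()
  for (fid in names(groups)) {
    members <- groups[[fid]]
    rename[members] <- fid
    prof <- colMeans(t(apply(matrix[members, , drop = FALSE], 1L, zscore)))
    merged_rows[[fid]] <- prof
  }
  dir <- graph$directed
  dir$source <- rename[dir$source]
  dir$target <- rename[dir$target]
  dir <- dir[dir$source != dir$target, , drop = FALSE]
  key <- paste(dir$source, dir$target)
  for (k in unique(key[duplicated(key)])) {
    sg <- unique(dir$sign[key == k])
    if (length(sg) > 1L)
      stop("sign conflict after family merge on edge: ", k)
  }
  dir <- dir[!duplicated(key), , drop = FALSE]
  bid <- graph$bidirected
  bid$n1 <- rename[bid$n1]
  bid$n2 <- rename[bid$n2]
  bid <- bid[bid$n1 != bid$n2, , drop = FALSE]
  new_nodes <- unique(rename[graph$nodes])
  g2 <- pathway_graph(graph$name, directed = dir, bidirected = bid,
                      nodes = new_nodes)
  g2 <- annotate_degs(g2, names(graph$is_deg)[graph$is_deg])
  kept <- setdiff(new_nodes, names(merged_rows))
  m2 <- rbind(matrix[kept, , drop = FALSE],
              do.call(rbind, merged_rows))
  m2 <- m2[new_nodes, , drop = FALSE]
  list(graph = g2, matrix = m2)
}

#' Prune graph edges by partial correlation
#'
#' For each directed edge j -> i the sample partial correlation of (i, j)
#' given the other parents of i is tested with the Fisher z transform at
#' effective degrees of freedom n - |conditioning| - 3; the edge is kept
#' iff p < alpha. Bidirected pairs are tested as marginal correlations.
#' All tests use the original graph, so pruning is order-independent.
#'
#' @param graph A `pathway_graph`.
#' @param matrix Expression matrix containing every graph node.
#' @param alpha Significance level for retention.
#' @param conditioning `"parents"` (default) conditions on the child's
#'   other parents; `"all"` conditions on all other graph nodes.
#' @return The pruned `pathway_graph` (p-values attached as attribute
#'   `"edge_tests"`).
#' @export
prune_by_partial_correlation <- function(graph, matrix, alpha = 0.05,
                                         conditioning = c("parents", "all")) {
  conditioning <- match.arg(conditioning)
  miss <- setdiff(graph$nodes, rownames(matrix))
  if (length(miss))
    stop("graph node(s) missing from expression matrix: ",
         paste(miss, collapse = ", "))
  X <- t(matrix[graph$nodes, , drop = FALSE])
  if (any(apply(X, 2L, stats::sd) == 0))
    stop("zero-variance node(s): ",
         paste(graph$nodes[apply(X, 2L, stats::sd) == 0], collapse = ", "))
  n <- nrow(X)
  pcor_test <- function(i, j, cond) {
    if (n <= length(cond) + 3L)
      stop("insufficient samples (n = ", n, ") for conditioning set of size ",
           length(cond))
    if (length(cond) == 0L) {
      rho <- stats::cor(X[, i], X[, j])
    } else {
      ri <- stats::lm.fit(cbind(1, X[, cond, drop = FALSE]), X[, i])$residuals
      rj <- stats::lm.fit(cbind(1, X[, cond, drop = FALSE]), X[, j])$residuals
      rho <- stats::cor(ri, rj)
    }
    rho <- max(min(rho, 1 - 1e-12), -1 + 1e-12)
    z <- atanh(rho) * sqrt(n - length(cond) - 3)
    2 * stats::pnorm(-abs(z))
  }
  keep_dir <- logical(nrow(graph$directed))
  p_dir <- numeric(nrow(graph$directed))
  for (e in seq_len(nrow(graph$directed))) {
    i <- graph$directed$target[e]; j <- graph$directed$source[e]
    cond <- if (conditioning == "parents")
      setdiff(graph$directed$source[graph$directed$target == i], j)
    else setdiff(graph$nodes, c(i, j))
    p_dir[e] <- pcor_test(i, j, cond)
    keep_dir[e] <- p_dir[e] < alpha
  }
  keep_bid <- logical(nrow(graph$bidirected))
  p_bid <- numeric(nrow(graph$bidirected))
  for (e in seq_len(nrow(graph$bidirected))) {
    p_bid[e] <- pcor_test(graph$bidirected$n1[e], graph$bidirected$n2[e],
                          character(0))
    keep_bid[e] <- p_bid[e] < alpha
  }
  out <- pathway_graph(graph$name,
                       directed = graph$directed[keep_dir, , drop = FALSE],
                       bidirected = graph$bidirected[keep_bid, , drop = FALSE],
                       nodes = graph$nodes)
  out <- annotate_degs(out, names(graph$is_deg)[graph$is_deg])
  attr(out, "edge_tests") <- list(directed_p = p_dir, bidirected_p = p_bid)
  out
}
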