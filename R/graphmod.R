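#' Read a weighted edge list
#'
#' @param path TSV with columns node_a, node_b, combined_score (header
#'   optional; detected from the first line).
#' @param min_score optional combined-score floor applied before building
#'   the graph.
#' @return an [igraph::graph] with edge attribute `combined_score`.
#' @export
read_edge_list <- function(path, min_score = NULL) {
  first <- readLines(path, n = 1L)
  header <- grepl("node_a", first, fixed = TRUE)
  e <- utils::read.table(path, sep = "\t", header = header,
                         col.names = c("node_a", "node_b", "combined_score"),
                         colClasses = c("character", "character", "numeric"))
  edge_graph(e, min_score)
}

#' Build an igraph from an edge data.frame
#'
#' Drops self-loops and duplicate undirected edges; optionally filters on
#' combined score.
#'
#' @param edges data.frame: node_a, node_b, combined_score.
#' @param min_score optional score floor.
#' @return undirected [igraph::graph].
#' @export
edge_graph <- function(edges, min_score = NULL) {
  if (!is.null(min_score))
    edges <- edges[edges$combined_score >= min_score, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Maximal k-core of a graph
#'
#' Iterative peeling: the maximal subgraph in which every vertex has
#' degree at least `k` (possibly empty).
#'
#' @param graph an igraph object.
#' @param k minimum degree.
#' @return the induced subgraph.
#' @export
k_core <- function(graph, k) {
  core <- igraph::coreness(graph)
  igraph::induced_subgraph(graph, which(core >= k))
}

graph_density <- function(graph) {
  nv <- igraph::vcount(graph)
  if (nv < 2L) return(0)
  2 * igraph::ecount(graph) / (nv * (nv - 1))
}

#' MCODE vertex weights
#'
#' A vertex below the degree cutoff weighs 0. Otherwise its weight is the
#' core-clustering coefficient of its closed neighborhood `N[v]`: the
#' density of the highest k-core of `N[v]`, multiplied by that core's
#' `k`. Dense local neighborhoods therefore weigh heavily and seed module
#' growth.
#'
#' @param graph an igraph object (simple, undirected).
#' @param degree_cutoff minimum degree (default 2).
#' @return named numeric vector of weights.
#' @export
vertex_weights <- function(graph, degree_cutoff = 2L) {
  deg <- igraph::degree(graph)
  w <- stats::setNames(numeric(igraph::vcount(graph)),
                       igraph::V(graph)$name)
  for (v in which(deg >= degree_cutoff)) {
    nb <- igraph::induced_subgraph(
      graph, c(v, as.integer(igraph::neighbors(graph, v))))
    core <- igraph::coreness(nb)
    k_max <- max(core)
    core_sub <- igraph::induced_subgraph(nb, which(core >= k_max))
    w[v] <- k_max * graph_density(core_sub)
  }
  w
}

#' MCODE parameters
#'
#' @param degree_cutoff minimum degree for a vertex to be weighted
#'   (default 2).
#' @param node_score_cutoff growth tolerance: a neighbor joins a module
#'   when its weight is at least `seed_weight * (1 - node_score_cutoff)`
#'   (default 0.2).
#' @param k_core a module must contain a core of this order (default 2).
#' @param score_cutoff reporting filter on the module score (default 3.0).
#' @param fluff,haircut optional post-processing (both off by default).
#' @return object of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, score_cutoff = 3.0,
                         fluff = FALSE, haircut = FALSE) {
  if (node_score_cutoff < 0 || node_score_cutoff > 1)
    stop("node_score_cutoff must be in [0, 1]")
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core), score_cutoff = score_cutoff,
                 fluff = isTRUE(fluff), haircut = isTRUE(haircut)),
            class = "mcode_params")
}

#' Detect dense modules by molecular complex detection (MCODE)
#'
#' Vertices are weighted by [vertex_weights()]; seeds are visited in
#' decreasing weight. From each unvisited seed, the module grows by
#' breadth-first traversal, adding unvisited neighbors whose weight is at
#' least `seed_weight * (1 - node_score_cutoff)`; every included vertex
#' is marked visited, so modules are vertex-disjoint. Modules lacking a
#' `k_core`-core are dropped. The module score is density x |V|; modules
#' at or above `score_cutoff` form the primary list, the rest are kept in
#' a secondary list. Ordering: score desc, then size desc, then seed id.
#'
#' @param graph an igraph object.
#' @param params an [mcode_params()].
#' @return object of class `mcode_result`: `modules` and
#'   `below_cutoff`, each a list of records (members, seed, score,
#'   density), plus `params`.
#' @export
find_complexes <- function(graph, params = mcode_params()) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  w <- vertex_weights(graph, params$degree_cutoff)
  order_idx <- order(-w, igraph::V(graph)$name)
  visited <- rep(FALSE, igraph::vcount(graph))
  haircut_deg <- function(members) {
    if (!params$haircut) return(members)
    repeat {
      sub <- igraph::induced_subgraph(graph, members)
      low <- igraph::degree(sub) < 2L
      if (!any(low) || sum(!low) < 2L) return(members)
      members <- members[!low]
    }
  }
  modules <- list()
  for (seed in order_idx) {
    if (visited[seed] || w[seed] <= 0) next
    threshold <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nbrs <- unique(unlist(lapply(frontier, function(v)
        as.integer(igraph::neighbors(graph, v)))))
      nbrs <- nbrs[!visited[nbrs] & w[nbrs] >= threshold]
      visited[nbrs] <- TRUE
      members <- c(members, nbrs)
      frontier <- nbrs
    }
    if (length(members) < 2L) next
    members <- haircut_deg(members)
    sub <- igraph::induced_subgraph(graph, members)
    if (igraph::vcount(k_core(sub, params$k_core)) == 0L) next
    if (params$fluff) {
      extra <- setdiff(unique(unlist(lapply(members, function(v)
        as.integer(igraph::neighbors(graph, v))))), members)
      keepx <- extra[vapply(extra, function(v) {
        nb <- igraph::induced_subgraph(
          graph, c(v, as.integer(igraph::neighbors(graph, v))))
        graph_density(nb) > 0.5
      }, logical(1L))]
      members <- c(members, keepx)  # fluffed vertices stay seed-eligible
      sub <- igraph::induced_subgraph(graph, members)
    }
    modules[[length(modules) + 1L]] <- list(
      members = sort(igraph::V(graph)$name[members]),
      seed = igraph::V(graph)$name[seed],
      score = graph_density(sub) * igraph::vcount(sub),
      density = graph_density(sub))
  }
  if (length(modules)) {
    ord <- order(-vapply(modules, `[[`, 0, "score"),
                 -vapply(modules, function(m) length(m$members), 0L),
                 vapply(modules, `[[`, "", "seed"))
    modules <- modules[ord]
  }
  above <- vapply(modules, function(m) m$score >= params$score_cutoff,
                  logical(1L))
  structure(list(modules = modules[above],
                 below_cutoff = modules[!above], params = params),
            class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat("mcode_result:", length(x$modules), "module(s) at score >=",
      x$params$score_cutoff, "\n")
  for (m in x$modules)
    cat("  seed", m$seed, "| score", round(m$score, 2), "|",
        length(m$members), "members:",
        paste(utils::head(m$members, 8L), collapse = ", "),
        if (length(m$members) > 8L) "..." else "", "\n")
  invisible(x)
}
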