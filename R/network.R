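#' Build the thresholded PPI graph over a protein set
#'
#' Restricts an interaction edge list to the given proteins and keeps an
#' edge iff its combined score strictly exceeds the threshold. Proteins
#' with no surviving interaction remain in the graph as isolated nodes,
#' so connectivity fractions can be reported.
#'
#' @param edges canonical edge list from [read_edge_list()] /
#'   [edge_list()].
#' @param node_ids proteins to include (e.g. the DEPs).
#' @param score_threshold strict lower bound on the combined score
#'   (default 0.15).
#' @return an undirected simple `igraph` graph with a `combined_score`
#'   edge attribute.
#' @export
build_ppi_graph <- function(edges, node_ids, score_threshold = 0.15) {
  keep <- edges$node_a %in% node_ids & edges$node_b %in% node_ids &
    edges$combined_score > score_threshold
  g <- igraph::graph_from_data_frame(
    edges[keep, c("node_a", "node_b", "combined_score"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = unique(node_ids)))
  igraph::E(g)$combined_score <- edges$combined_score[keep]
  g
}

#' Node degree
#' @param graph an `igraph` graph from [build_ppi_graph()].
#' @return named integer vector.
#' @export
degree_centrality <- function(graph) {
  igraph::degree(graph, loops = FALSE)
}

#' Shortest-path betweenness centrality
#'
#' Exact unweighted betweenness (Brandes), unnormalized, endpoints
#' excluded, each unordered pair counted once — the raw-count convention
#' of the usual hub-ranking tools.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(graph) {
  igraph::betweenness(graph, directed = FALSE, weights = NA,
                      normalized = FALSE)
}

#' Maximum neighborhood component (MNC)
#'
#' For each node, the size of the largest connected component of the
#' subgraph induced by its open neighborhood (the node itself excluded).
#'
#' @inheritParams degree_centrality
#' @return named integer vector; 0 for isolated nodes.
#' @export
mnc <- function(graph) {
  vs <- igraph::V(graph)
  out <- stats::setNames(integer(length(vs)), names(vs))
  for (v in seq_along(vs)) {
    nb <- igraph::neighbors(graph, v)
    if (length(nb) == 0L) next
    sub <- igraph::induced_subgraph(graph, nb)
    out[v] <- max(igraph::components(sub)$csize)
  }
  out
}

#' Edge percolated component (EPC)
#'
#' Monte-Carlo percolation centrality: in each replicate every edge is
#' retained independently with probability `keep_prob`; a node's score is
#' the average, over replicates, of the number of *other* nodes left in
#' its connected component. Deterministic given the seed.
#'
#' @inheritParams degree_centrality
#' @param replicates number of percolation replicates (default 1000).
#' @param keep_prob edge retention probability in `[0,1]` (default 0.5).
#' @param seed integer seed for the percolation draws.
#' @return named numeric vector.
#' @export
epc <- function(graph, replicates = 1000L, keep_prob = 0.5, seed = 1L) {
  if (keep_prob < 0 || keep_prob > 1) stop("keep_prob must be in [0,1]")
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  acc <- numeric(n)
  set.seed(as.integer(seed))
  for (r in seq_len(replicates)) {
    kept <- which(stats::runif(m) < keep_prob)
    sub <- igraph::subgraph_from_edges(graph, kept,
                                       delete.vertices = FALSE)
    comp <- igraph::components(sub)
    acc <- acc + comp$csize[comp$membership] - 1
  }
  stats::setNames(acc / replicates, igraph::V(graph)$name)
}

#' MCODE parameters
#'
#' Defaults follow the standard molecular-complex-detection settings:
#' node score cutoff 0.2, degree cutoff 2, k-core 2, max depth 100, and a
#' complex-score filter of "score > 5".
#'
#' @param node_score_cutoff fraction by which a member's weight may fall
#'   below the seed's weight.
#' @param degree_cutoff minimum degree for a node to be weighted.
#' @param k_core core level a complex must contain to be kept.
#' @param max_depth BFS depth limit from the seed.
#' @param complex_score_min strict lower bound on reported complex scores.
#' @return an `MCODEParams` list.
#' @export
mcode_params <- function(node_score_cutoff = 0.2, degree_cutoff = 2L,
                         k_core = 2L, max_depth = 100L,
                         complex_score_min = 5) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff <= 1,
            degree_cutoff >= 0, k_core >= 1, max_depth >= 1)
  structure(list(node_score_cutoff = node_score_cutoff,
                 degree_cutoff = as.integer(degree_cutoff),
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth),
                 complex_score_min = complex_score_min),
            class = "MCODEParams")
}

# density of a simple undirected graph, self-loops excluded
.graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# highest k-core of a graph: the subgraph induced by nodes of maximal
# coreness; returns list(k, vids) or NULL for an empty graph
.highest_kcore <- function(g) {
  if (igraph::vcount(g) == 0L) return(NULL)
  core <- igraph::coreness(g)
  k <- max(core)
  list(k = k, vids = which(core == k))
}

#' Molecular complex detection (MCODE)
#'
#' Density-based module finding in three stages. (1) Vertex weighting:
#' each node with degree >= `degree_cutoff` is weighted by
#' `k * density(highest k-core)` of the subgraph induced by its closed
#' neighborhood; lower-degree nodes get weight 0. (2) Complex prediction:
#' seeds are visited in decreasing weight; from each unassigned seed a
#' breadth-first search (depth limited by `max_depth`) includes
#' unassigned neighbours whose weight is at least
#' `w(seed) * (1 - node_score_cutoff)`; every node joins at most one
#' complex. (3) Filtering: complexes that do not contain a `k_core`-core
#' are discarded; a complex's score is its density times its node count,
#' and only complexes with score strictly above `complex_score_min` are
#' reported. Fluff and haircut post-processing are not applied.
#'
#' @inheritParams degree_centrality
#' @param params an [mcode_params()].
#' @return list with `complexes` (a `data.frame` of `complex_id`, `score`,
#'   `n_nodes`, `members` as a semicolon string), `membership` (list of
#'   member-id vectors), and `node_score`: per node, the score of its
#'   containing reported complex (0 if none).
#' @export
mcode <- function(graph, params = mcode_params()) {
  n <- igraph::vcount(graph)
  ids <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  w <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < params$degree_cutoff) next
    nb <- c(v, as.integer(igraph::neighbors(graph, v)))
    sub <- igraph::induced_subgraph(graph, nb)
    hk <- .highest_kcore(sub)
    if (is.null(hk) || hk$k == 0L) next
    core_sub <- igraph::induced_subgraph(sub, hk$vids)
    w[v] <- hk$k * .graph_density(core_sub)
  }
  assigned <- logical(n)
  complexes <- list()
  for (seed in order(-w)) {
    if (assigned[seed] || w[seed] <= 0) next
    thresh <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- integer()
      for (u in frontier) {
        for (nb in as.integer(igraph::neighbors(graph, u))) {
          if (!assigned[nb] && w[nb] >= thresh) {
            assigned[nb] <- TRUE
            members <- c(members, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    complexes[[length(complexes) + 1L]] <- members
  }
  node_score <- stats::setNames(numeric(n), ids)
  rows <- list()
  kept <- list()
  for (members in complexes) {
    sub <- igraph::induced_subgraph(graph, members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    score <- .graph_density(sub) * length(members)
    if (score <= params$complex_score_min) next
    kept[[length(kept) + 1L]] <- ids[members]
    node_score[members] <- score
    rows[[length(rows) + 1L]] <-
      data.frame(score = score, n_nodes = length(members),
                 members = paste(sort(ids[members]), collapse = ";"),
                 stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(score = numeric(), n_nodes = integer(),
                         members = character(), stringsAsFactors = FALSE)
  ord <- order(-tab$score)
  tab <- tab[ord, , drop = FALSE]
  kept <- kept[ord]
  tab <- cbind(complex_id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  list(complexes = tab, membership = kept, node_score = node_score)
}

#' Compute the full per-node centrality table
#'
#' @inheritParams degree_centrality
#' @param epc_replicates,epc_keep_prob,epc_seed EPC Monte-Carlo settings.
#' @param mcode_params an [mcode_params()].
#' @return `data.frame` with columns `protein`, `betweenness`, `mnc`,
#'   `degree`, `epc`, `mcode` (score of the node's reported complex, 0 if
#'   none).
#' @export
centrality_table <- function(graph, epc_replicates = 1000L,
                             epc_keep_prob = 0.5, epc_seed = 1L,
                             mcode_params = proteopanel::mcode_params()) {
  data.frame(protein = igraph::V(graph)$name,
             betweenness = unname(betweenness_centrality(graph)),
             mnc = unname(mnc(graph)),
             degree = unname(degree_centrality(graph)),
             epc = unname(epc(graph, epc_replicates, epc_keep_prob,
                              epc_seed)),
             mcode = unname(mcode(graph, mcode_params)$node_score),
             stringsAsFactors = FALSE)
}

#' Select hub proteins by four-way top-n intersection
#'
#' Ranks nodes separately by degree, EPC, betweenness and MNC (descending,
#' ties broken by node id ascending), takes exactly the top `top_n` of
#' each, and intersects the four lists. With fewer than `top_n` nodes, all
#' nodes are used.
#'
#' @param centralities a [centrality_table()].
#' @param top_n list length per metric (default 10).
#' @return list with `hubs` (character vector, ranked by degree), `table`
#'   (centrality rows of the hubs) and `top` (the per-metric top-n id
#'   lists).
#' @export
select_hubs <- function(centralities, top_n = 10L) {
  metrics <- c("degree", "epc", "betweenness", "mnc")
  n_take <- min(top_n, nrow(centralities))
  top <- lapply(metrics, function(m) {
    ord <- order(-centralities[[m]], centralities$protein)
    centralities$protein[ord][seq_len(n_take)]
  })
  names(top) <- metrics
  hubs <- Reduce(intersect, top)
  tab <- centralities[match(hubs, centralities$protein), , drop = FALSE]
  tab <- tab[order(-tab$degree, tab$protein), , drop = FALSE]
  rownames(tab) <- NULL
  list(hubs = tab$protein, table = tab, top = top)
}
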