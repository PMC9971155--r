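#' Build a weighted social graph from an association matrix
#'
#' Nodes are individuals (with a `sex` display attribute); edges connect
#' every dyad with a positive index, weighted by it. Zero-weight dyads
#' are omitted; isolated individuals are retained as nodes.
#'
#' @param matrix an `association_matrix`.
#' @param roster the matching `roster` (provides sex attributes).
#' @return an `igraph` graph with vertex attributes `name`, `sex` and
#'   graph attribute `measure`.
#' @export
build_social_graph <- function(matrix, roster) {
  ids <- rownames(matrix)
  if (!all(ids %in% roster$id)) {
    stop_dyadnet("sociogram", "matrix ids missing from roster: %s",
                 paste(setdiff(ids, roster$id), collapse = ", "))
  }
  m <- unclass(matrix)
  m[is.na(m)] <- 0
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  sex <- stats::setNames(roster$sex, roster$id)
  igraph::V(g)$sex <- unname(sex[ids])
  g <- igraph::set_graph_attr(g, "measure",
                              attr(matrix, "measure") %||% NA_character_)
  g
}

#' Weighted Fruchterman-Reingold layout
#'
#' Force-directed layout in which heavier (stronger-association) edges
#' pull their endpoints closer. Deterministic given `seed`.
#'
#' @param graph an igraph graph with a `weight` edge attribute.
#' @param seed integer seed.
#' @return numeric matrix of 2D coordinates, one row per node.
#' @export
layout_sociogram <- function(graph, seed = 1) {
  if (igraph::vcount(graph) == 1L) {
    return(matrix(0, 1, 2, dimnames = list(igraph::V(graph)$name, NULL)))
  }
  set.seed(seed)
  w <- igraph::E(graph)$weight
  coords <- igraph::layout_with_fr(graph, weights = if (length(w)) w else NULL)
  rownames(coords) <- igraph::V(graph)$name
  coords
}

#' Potts-model Hamiltonian of a partition
#'
#' The configuration-null Hamiltonian
#' `H = -sum_{i<j} (w_ij - gamma * s_i s_j / (2m)) * [c_i == c_j]`,
#' where `s_i` is node strength and `2m` the total weight. Lower is
#' better; spinglass community detection minimizes this quantity.
#'
#' @param graph an igraph graph with edge weights.
#' @param membership integer/character vector of community labels in
#'   vertex order.
#' @param gamma resolution parameter (default 1).
#' @return the Hamiltonian (scalar).
#' @export
graph_hamiltonian <- function(graph, membership, gamma = 1) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(0)
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  s <- rowSums(A)
  two_m <- sum(s)
  if (two_m == 0) return(0)
  same <- outer(membership, membership, `==`)
  P <- outer(s, s) / two_m
  -sum(((A - gamma * P) * same)[upper.tri(A)])
}

# Generalized modularity matrix for one component: B = W - gamma * P
# with the configuration null P = s s' / 2m.
modularity_matrix <- function(graph, gamma) {
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  s <- rowSums(A)
  A - gamma * outer(s, s) / sum(s)
}

# One annealing run over spin configurations: single-node spin flips
# with Metropolis acceptance, geometric cooling, followed by a greedy
# single-node refinement pass (local optimality under node moves).
anneal_spins <- function(B, max_spins, start_temp, stop_temp, cool_fact) {
  n <- nrow(B)
  mem <- seq_len(min(n, max_spins))
  if (n > max_spins) mem <- c(mem, sample.int(max_spins, n - max_spins,
                                              replace = TRUE))
  gain <- function(v, target, mem) {
    others <- seq_len(n)[-v]
    sum(B[v, others[mem[others] == target]])
  }
  temp <- start_temp
  while (temp > stop_temp) {
    for (step in seq_len(n)) {
      v <- sample.int(n, 1)
      labels <- unique(mem)
      fresh <- setdiff(seq_len(min(n, max_spins)), labels)
      cand <- c(setdiff(labels, mem[v]), fresh[seq_len(min(1, length(fresh)))])
      if (!length(cand)) next
      tgt <- cand[sample.int(length(cand), 1)]
      dH <- gain(v, mem[v], mem) - gain(v, tgt, mem)  # H decrease if < 0
      if (dH <= 0 || stats::runif(1) < exp(-dH / temp)) mem[v] <- tgt
    }
    temp <- temp * cool_fact
  }
  # greedy refinement until single-node local optimality
  repeat {
    improved <- FALSE
    for (v in seq_len(n)) {
      best_gain <- gain(v, mem[v], mem)
      targets <- setdiff(unique(c(mem, max(mem) + 1L)), mem[v])
      for (tgt in targets) {
        gv <- gain(v, tgt, mem)
        if (gv > best_gain + 1e-12) {
          mem[v] <- tgt
          best_gain <- gv
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  match(mem, unique(mem))
}

#' Spinglass community detection
#'
#' Partitions each connected component by simulated annealing of the
#' Potts-model Hamiltonian
#' `H = -sum_{i<j} (w_ij - gamma * p_ij) delta(c_i, c_j)` with the
#' configuration null model `p_ij = s_i s_j / 2m` (the generalized
#' modularity objective); components without edges become singleton
#' communities. Deterministic given `seed`.
#'
#' @param graph an igraph graph with a `weight` edge attribute.
#' @param gamma resolution parameter (default 1).
#' @param max_spins maximum number of communities per component
#'   (default 25).
#' @param seed integer seed.
#' @param start_temp,stop_temp,cool_fact annealing schedule (start
#'   temperature 1, geometric cooling 0.99, stop at 0.01).
#' @param n_restarts independent annealing runs per component; the
#'   partition with the lowest Hamiltonian is kept (simulated annealing
#'   is stochastic, and restarts make the attained optimum reliable on
#'   small graphs).
#' @return list with `membership` (named integer vector over all nodes),
#'   `hamiltonian` (summed over components) and `n_communities`.
#' @export
spinglass_communities <- function(graph, gamma = 1, max_spins = 25, seed = 1,
                                  start_temp = 1, stop_temp = 0.01,
                                  cool_fact = 0.99, n_restarts = 5) {
  set.seed(seed)
  comps <- igraph::decompose(graph)
  if (length(comps) > 1L) {
    message(sprintf("[sociogram] graph has %d components; spinglass run per component",
                    length(comps)))
  }
  membership <- stats::setNames(integer(igraph::vcount(graph)),
                                igraph::V(graph)$name)
  offset <- 0L
  H <- 0
  for (cg in comps) {
    nodes <- igraph::V(cg)$name
    if (igraph::ecount(cg) == 0L) {
      membership[nodes] <- offset + 1L
      offset <- offset + 1L
      next
    }
    B <- modularity_matrix(cg, gamma)
    best_mem <- NULL
    best_H <- Inf
    for (r in seq_len(max(1L, n_restarts))) {
      mem <- anneal_spins(B, max_spins, start_temp, stop_temp, cool_fact)
      H_r <- graph_hamiltonian(cg, mem, gamma = gamma)
      if (H_r < best_H) { best_H <- H_r; best_mem <- mem }
    }
    membership[nodes] <- offset + best_mem
    H <- H + best_H
    offset <- offset + max(best_mem)
  }
  list(membership = membership, hamiltonian = H,
       n_communities = length(unique(membership)))
}

#' Export a social graph
#'
#' GraphML (standard XML graph format) or a delimited edge list
#' (`from`, `to`, `weight`); node attributes (sex, community, layout
#' coordinates) travel with the GraphML export.
#'
#' @param graph an igraph graph.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    utils::write.table(el, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an exported edge list back into a graph
#'
#' @param path edge-list file written by [export_graph()].
#' @return an igraph graph.
#' @export
import_edgelist <- function(path) {
  el <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE)
}

#' Draw a sociogram
#'
#' Nodes coloured by sex (red = females, blue = males), edge width
#' proportional to tie strength, optional community shading.
#'
#' @param graph an igraph graph from [build_social_graph()].
#' @param layout coordinates from [layout_sociogram()].
#' @param communities optional result of [spinglass_communities()].
#' @param ... passed to `plot.igraph`.
#' @return the graph, invisibly.
#' @export
plot_sociogram <- function(graph, layout = layout_sociogram(graph),
                           communities = NULL, ...) {
  cols <- ifelse(igraph::V(graph)$sex == "F", "red", "blue")
  w <- igraph::E(graph)$weight
  mark <- NULL
  if (!is.null(communities)) {
    mem <- communities$membership[igraph::V(graph)$name]
    mark <- split(seq_along(mem), mem)
  }
  igraph::plot.igraph(graph, layout = layout, vertex.color = cols,
                      vertex.label.cex = 0.7,
                      edge.width = if (length(w)) 1 + 6 * w else 1,
                      mark.groups = mark, ...)
  invisible(graph)
}
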