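#' Solve the minimum s-t cut and recover the boundary
#'
#' Computes a maximum flow on the segmentation graph (igraph's max-flow
#' solver; infinite capacities are replaced by a sentinel exceeding the sum
#' of all finite capacities, so no infinite arc is ever cut). The source side
#' of the minimum cut is a minimum-cost closed set; among the — possibly
#' many — minimum closed sets the package deterministically returns the
#' MAXIMAL one, i.e. the complement of the nodes that can still reach the
#' sink in the residual graph. Closed sets form a lattice and the objective
#' is modular, so this maximal optimum is unique; it is the outermost optimal
#' contour, which is what makes homogeneous objects segment out to their
#' border rather than collapse onto the seed.
#'
#' @param graph a `segmentation_graph` from [build_segmentation_graph()] or
#'   [graph_from_costs()].
#' @return An object of class `cut_boundary`: list with `boundary` (integer
#'   vector, per-ray level of the uppermost source-side node, 1-based),
#'   `total_cost` (`sum(cost[r, boundary[r]])`), `flow_value`, `delta`,
#'   `n_rays`, `n_nodes` and the originating `grid` (may be `NULL`).
#' @export
solve_min_cut <- function(graph) {
  if (!inherits(graph, "segmentation_graph")) {
    stop("`graph` must be a segmentation_graph", call. = FALSE)
  }
  arcs <- graph$arcs
  n_all <- graph$n_rays * graph$n_nodes + 2L
  base <- arcs$tail == graph$source & !is.finite(arcs$capacity)
  if (sum(base) < graph$n_rays) {
    stop("malformed graph: missing base terminal arcs", call. = FALSE)
  }
  finite <- is.finite(arcs$capacity)
  sentinel <- sum(arcs$capacity[finite]) + 1
  cap <- ifelse(finite, arcs$capacity, sentinel)
  g <- igraph::graph_from_edgelist(cbind(arcs$tail, arcs$head), directed = TRUE)
  if (igraph::vcount(g) < n_all) g <- igraph::add_vertices(g, n_all - igraph::vcount(g))
  mf <- igraph::max_flow(g, source = graph$source, target = graph$sink,
                         capacity = cap)
  if (mf$value >= sentinel) {
    stop("no finite cut exists; graph is malformed", call. = FALSE)
  }
  # residual graph: forward where capacity remains, backward where flow > 0
  flow <- mf$flow
  res_fwd <- cbind(arcs$tail, arcs$head)[cap - flow > 1e-9, , drop = FALSE]
  res_bwd <- cbind(arcs$head, arcs$tail)[flow > 1e-9, , drop = FALSE]
  rg <- igraph::graph_from_edgelist(rbind(res_fwd, res_bwd), directed = TRUE)
  if (igraph::vcount(rg) < n_all) rg <- igraph::add_vertices(rg, n_all - igraph::vcount(rg))
  reach_t <- as.integer(igraph::subcomponent(rg, graph$sink, mode = "in"))
  src_side <- setdiff(seq_len(n_all), reach_t)
  if (!(graph$source %in% src_side) || (graph$sink %in% src_side)) {
    stop("inconsistent max-flow result", call. = FALSE)
  }
  nodes <- src_side[src_side <= graph$n_rays * graph$n_nodes]
  ray_of <- (nodes - 1L) %/% graph$n_nodes + 1L
  z_of <- (nodes - 1L) %% graph$n_nodes + 1L
  boundary <- vapply(seq_len(graph$n_rays),
                     function(r) max(z_of[ray_of == r]), integer(1L))
  new_cut_boundary(boundary, graph)
}

new_cut_boundary <- function(boundary, graph, flow_value = NA_real_) {
  structure(
    list(boundary = as.integer(boundary),
         total_cost = sum(graph$cost[cbind(seq_len(graph$n_rays), boundary)]),
         delta = graph$delta, n_rays = graph$n_rays, n_nodes = graph$n_nodes,
         grid = graph$grid),
    class = "cut_boundary"
  )
}

#' Exhaustive minimum-surface oracle
#'
#' Enumerates every assignment of one boundary level per ray, keeps the
#' feasible ones (circularly adjacent levels differ by at most `delta`) and
#' returns a minimizer of the summed boundary costs. Ties are broken by the
#' lexicographically smallest configuration. Intended as an independent
#' check of [solve_min_cut()] on small instances.
#'
#' @param cost `n_rays` x `n_nodes` cost matrix.
#' @param delta integer smoothness parameter.
#' @param max_configs enumeration guard; errors if `n_nodes ^ n_rays`
#'   exceeds it.
#' @return A `cut_boundary` (same structure as [solve_min_cut()]).
#' @export
brute_force_min_surface <- function(cost, delta, max_configs = 1e6) {
  cost <- as.matrix(cost)
  n_rays <- nrow(cost); n_nodes <- ncol(cost)
  if (n_nodes^n_rays > max_configs) {
    stop("instance too large for exhaustive enumeration", call. = FALSE)
  }
  configs <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), n_rays),
                                   KEEP.OUT.ATTRS = FALSE))
  feasible <- rep(TRUE, nrow(configs))
  for (r in seq_len(n_rays)) {
    rn <- r %% n_rays + 1L
    feasible <- feasible & abs(configs[, r] - configs[, rn]) <= delta
  }
  configs <- configs[feasible, , drop = FALSE]
  total <- rowSums(matrix(cost[cbind(rep(seq_len(n_rays), each = nrow(configs)),
                                     as.vector(configs))],
                          nrow = nrow(configs)))
  best <- which(total <= min(total) + 0)
  if (length(best) > 1L) {
    ord <- do.call(order, as.data.frame(configs[best, , drop = FALSE]))
    best <- best[ord[1L]]
  }
  g <- list(cost = cost, delta = as.integer(delta), n_rays = n_rays,
            n_nodes = n_nodes, grid = NULL)
  new_cut_boundary(configs[best, ], g)
}
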