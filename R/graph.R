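#' Mean object intensity around the seed
#'
#' Estimates the average gray value of the object from a small `d` x `d`
#' pixel window centered on the seed point, which is assumed to lie inside
#' the object. The window is clipped at the image borders. For even `d` the
#' window extends one pixel less on the +x/+y side.
#'
#' @param image numeric intensity matrix (row = y, column = x).
#' @param seed numeric `c(x, y)`, 0-based pixel coordinates.
#' @param d window side length in pixels (>= 1, default 5).
#' @return Mean intensity in the clipped window.
#' @export
mean_object_intensity <- function(image, seed, d = 5L) {
  if (d < 1L) stop("`d` must be at least 1", call. = FALSE)
  px <- floor(seed + 0.5)
  if (px[1L] < 0 || px[1L] >= ncol(image) || px[2L] < 0 || px[2L] >= nrow(image)) {
    stop("seed point lies outside the image", call. = FALSE)
  }
  if (d %% 2L == 1L) {
    lo <- -((d - 1L) %/% 2L); hi <- (d - 1L) %/% 2L
  } else {
    lo <- -(d %/% 2L); hi <- d %/% 2L - 1L
  }
  xs <- max(0L, px[1L] + lo):min(ncol(image) - 1L, px[1L] + hi)
  ys <- max(0L, px[2L] + lo):min(nrow(image) - 1L, px[2L] + hi)
  mean(image[ys + 1L, xs + 1L])
}

#' Per-node cost from image intensity
#'
#' The node cost is the absolute difference between the image intensity at
#' the node position and the estimated object mean. Positions are looked up
#' with nearest-neighbor rounding; positions outside the image are clamped to
#' the nearest in-bounds pixel.
#'
#' @param image numeric intensity matrix.
#' @param positions two-column matrix (or data frame) of x, y positions in
#'   0-based pixel coordinates.
#' @param mean_intensity object mean from [mean_object_intensity()].
#' @return Numeric vector of costs, one per position.
#' @export
node_cost <- function(image, positions, mean_intensity) {
  p <- as.matrix(positions)
  x <- pmin(pmax(floor(p[, 1L] + 0.5), 0), ncol(image) - 1L)
  y <- pmin(pmax(floor(p[, 2L] + 0.5), 0), nrow(image) - 1L)
  abs(image[cbind(y + 1L, x + 1L)] - mean_intensity)
}

#' Terminal weights from a per-ray cost sequence
#'
#' The first node of a ray keeps its cost; every later node gets the
#' difference to its inner neighbor: `w[1] = c[1]`, `w[z] = c[z] - c[z-1]`.
#' Prefix sums of the weights therefore reproduce the costs exactly, so a
#' closed set whose uppermost node on a ray is `z` contributes `c[z]` to the
#' objective. Weights may be negative.
#'
#' @param costs numeric cost sequence along one ray (inner to outer).
#' @return Numeric weight sequence of the same length.
#' @export
terminal_weights <- function(costs) {
  if (length(costs) == 0L) stop("empty cost sequence", call. = FALSE)
  c(costs[1L], diff(costs))
}

node_id <- function(ray, node, n_nodes) (ray - 1L) * n_nodes + node

#' Infinite intra-column arcs
#'
#' One infinite-capacity arc from every node to its inner neighbor on the
#' same ray: including a node in the closed set drags everything below it
#' along, so the source side is radially contiguous.
#'
#' @param n_rays,n_nodes grid dimensions.
#' @return Tibble of arcs with columns `tail`, `head`, `capacity` (`Inf`);
#'   node ids are `(ray - 1) * n_nodes + node`.
#' @export
build_intra_arcs <- function(n_rays, n_nodes) {
  if (n_nodes < 2L) {
    return(tibble::tibble(tail = integer(), head = integer(), capacity = numeric()))
  }
  r <- rep(seq_len(n_rays), each = n_nodes - 1L)
  z <- rep(2:n_nodes, times = n_rays)
  tibble::tibble(tail = node_id(r, z, n_nodes),
                 head = node_id(r, z - 1L, n_nodes),
                 capacity = Inf)
}

#' Infinite inter-column smoothness arcs
#'
#' Every node sends an infinite arc to each circularly adjacent ray, at the
#' level `max(1, z - delta)`. A finite-cost cut can therefore never let the
#' boundary levels of adjacent rays differ by more than `delta`; smaller
#' `delta` stiffens the contour toward the template shape.
#'
#' @inheritParams build_intra_arcs
#' @param delta non-negative integer stiffness parameter.
#' @return Tibble of `2 * n_rays * n_nodes` arcs (`tail`, `head`, `capacity`).
#' @export
build_inter_arcs <- function(n_rays, n_nodes, delta) {
  if (delta < 0 || delta != round(delta)) {
    stop("`delta` must be a non-negative integer", call. = FALSE)
  }
  if (n_rays < 3L) stop("`n_rays` must be at least 3", call. = FALSE)
  r <- rep(seq_len(n_rays), each = n_nodes)
  z <- rep(seq_len(n_nodes), times = n_rays)
  zt <- pmax(1L, z - as.integer(delta))
  nxt <- r %% n_rays + 1L
  prv <- (r - 2L) %% n_rays + 1L
  tibble::tibble(
    tail = c(node_id(r, z, n_nodes), node_id(r, z, n_nodes)),
    head = c(node_id(nxt, zt, n_nodes), node_id(prv, zt, n_nodes)),
    capacity = Inf
  )
}

#' Terminal arcs from node weights
#'
#' Standard minimum-closed-set reduction: a node with negative weight gets an
#' arc from the source with capacity `-w`; a node with positive weight gets
#' an arc to the sink with capacity `w` (zero-weight nodes get none). One
#' additional infinite arc from the source to the innermost node of every ray
#' guarantees a non-empty result, consistent with the seed lying inside the
#' object.
#'
#' @param weights `n_rays` x `n_nodes` matrix of terminal weights.
#' @return Tibble of arcs; the source id is `n_rays * n_nodes + 1`, the sink
#'   id `n_rays * n_nodes + 2`.
#' @export
attach_terminal_arcs <- function(weights) {
  w <- as.matrix(weights)
  n_rays <- nrow(w); n_nodes <- ncol(w)
  n <- n_rays * n_nodes
  s <- n + 1L; t <- n + 2L
  ids <- matrix(seq_len(n), nrow = n_rays, ncol = n_nodes, byrow = TRUE)
  neg <- which(w < 0)
  pos <- which(w > 0)
  tibble::tibble(
    tail = c(rep(s, length(neg)), ids[pos], rep(s, n_rays)),
    head = c(ids[neg], rep(t, length(pos)), ids[, 1L]),
    capacity = c(-w[neg], w[pos], rep(Inf, n_rays))
  )
}

#' Build the full segmentation graph
#'
#' Combines a sampled node grid and an intensity image into the directed
#' graph whose minimum s-t cut segments the object: per-node costs
#' `|I - mean|`, telescoped terminal weights, infinite intra-column arcs and
#' infinite inter-column arcs at stiffness `delta`.
#'
#' @param grid a `ray_node_grid` from [sample_nodes()].
#' @param image numeric intensity matrix.
#' @param delta integer smoothness parameter.
#' @param mean_intensity object mean; estimated with
#'   [mean_object_intensity()] at the grid's seed when `NULL`.
#' @param window window size `d` for the mean estimate.
#' @return An object of class `segmentation_graph`: list with `arcs` (tibble
#'   `tail`, `head`, `capacity`; infinite capacities stored as `Inf`), `cost`
#'   and `weight` (`n_rays` x `n_nodes` matrices), `n_rays`, `n_nodes`,
#'   `delta`, `source`, `sink` and the originating `grid`.
#' @export
build_segmentation_graph <- function(grid, image, delta,
                                     mean_intensity = NULL, window = 5L) {
  n_rays <- attr(grid, "n_rays")
  n_nodes <- attr(grid, "n_nodes")
  if (is.null(mean_intensity)) {
    mean_intensity <- mean_object_intensity(image, attr(grid, "seed"), window)
  }
  cost_vec <- node_cost(image, cbind(grid$x, grid$y), mean_intensity)
  cost <- matrix(cost_vec, nrow = n_rays, ncol = n_nodes, byrow = TRUE)
  weight <- if (n_nodes == 1L) cost else t(apply(cost, 1L, terminal_weights))
  arcs <- dplyr::bind_rows(
    build_intra_arcs(n_rays, n_nodes),
    build_inter_arcs(n_rays, n_nodes, delta),
    attach_terminal_arcs(weight)
  )
  structure(
    list(arcs = arcs, cost = cost, weight = weight,
         n_rays = n_rays, n_nodes = n_nodes, delta = as.integer(delta),
         source = n_rays * n_nodes + 1L, sink = n_rays * n_nodes + 2L,
         mean_intensity = mean_intensity, grid = grid),
    class = "segmentation_graph"
  )
}

#' Build a segmentation graph directly from a cost table
#'
#' Bypasses the image: takes a ready-made `n_rays` x `n_nodes` cost matrix.
#' Used for solver verification against the exhaustive oracle.
#'
#' @param cost numeric cost matrix (rows = rays, columns = node levels,
#'   inner to outer).
#' @param delta integer smoothness parameter.
#' @return A `segmentation_graph`.
#' @export
graph_from_costs <- function(cost, delta) {
  cost <- as.matrix(cost)
  n_rays <- nrow(cost); n_nodes <- ncol(cost)
  weight <- if (n_nodes == 1L) cost else t(apply(cost, 1L, terminal_weights))
  arcs <- dplyr::bind_rows(
    build_intra_arcs(n_rays, n_nodes),
    build_inter_arcs(n_rays, n_nodes, delta),
    attach_terminal_arcs(weight)
  )
  structure(
    list(arcs = arcs, cost = cost, weight = weight,
         n_rays = n_rays, n_nodes = n_nodes, delta = as.integer(delta),
         source = n_rays * n_nodes + 1L, sink = n_rays * n_nodes + 2L,
         mean_intensity = NA_real_, grid = NULL),
    class = "segmentation_graph"
  )
}

#' Count inter-column arcs crossed by a cut between two adjacent rays
#'
#' For two adjacent node columns built with the `delta` inter-arc rule
#' (each node arcs to the neighbor column at level `max(1, z - delta)`, in
#' both directions), counts the arcs whose endpoints lie on opposite sides of
#' a cut that keeps levels `<= z1` on the first column and `<= z2` on the
#' second. Both arc directions are counted, matching the geometric
#' crossed-arc reading. With `directed = TRUE` only arcs running from the
#' source side to the sink side are counted; that directed count is
#' `max(0, z1 - z2 - delta) + max(0, z2 - z1 - delta)`, which is what decides
#' whether a cut is finite.
#'
#' @param z1,z2 boundary levels on the two columns (1-based, in 1..n_nodes).
#' @param delta inter-column stiffness parameter.
#' @param n_nodes nodes per column.
#' @param directed count only source-to-sink arcs?
#' @return Integer arc count.
#' @export
count_crossing_arcs <- function(z1, z2, delta, n_nodes, directed = FALSE) {
  stopifnot(z1 >= 1L, z1 <= n_nodes, z2 >= 1L, z2 <= n_nodes)
  z <- seq_len(n_nodes)
  zt <- pmax(1L, z - as.integer(delta))
  # column 1 -> column 2 and column 2 -> column 1
  tail_in <- c(z <= z1, z <= z2)
  head_in <- c(zt <= z2, zt <= z1)
  if (directed) sum(tail_in & !head_in) else sum(tail_in != head_in)
}

#' Export a segmentation graph as a plain edge list
#'
#' Writes one "tail head capacity" line per arc (node ids as in
#' [build_intra_arcs()]; the source and sink are written as `s` and `t`,
#' infinite capacities as `inf`). Debugging aid.
#'
#' @param graph a `segmentation_graph`.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path) {
  lab <- function(id) ifelse(id == graph$source, "s",
                      ifelse(id == graph$sink, "t", as.character(id)))
  cap <- ifelse(is.finite(graph$arcs$capacity),
                format(graph$arcs$capacity, trim = TRUE), "inf")
  writeLines(paste(lab(graph$arcs$tail), lab(graph$arcs$head), cap), path)
  invisible(path)
}
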