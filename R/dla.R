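#' Grow a 2D lattice diffusion-limited aggregate
#'
#' Random walkers are launched on a circle just outside the cluster, walk on
#' the 4-connected lattice, are discarded far from the cluster and stick at
#' the first site face-adjacent to it. The unequal dichotomy of the
#' resulting branched aggregates is what the ramuli chorii need; the
#' aggregate itself is only a topology source (its jagged paths are replaced
#' by straight chords between branching points, see [skeletonize()]).
#'
#' @param n_particles number of walkers to attach (the aggregate then has
#'   `n_particles + 1` sites including the seed).
#' @param rng_seed integer seed; growth is deterministic given the seed.
#' @param launch_margin walkers start at (cluster radius + margin) sites.
#' @param kill_factor walkers beyond `kill_factor` x launch radius are
#'   relaunched.
#' @param max_attempts_per_particle walker budget; exhausted budget raises
#'   an error reporting how many particles attached.
#' @return A `dla_aggregate`: a tibble of lattice coordinates `x`, `y` in
#'   attachment order (seed first, at the origin), with the seed stored in
#'   attributes.
#' @export
#' @examples
#' agg <- grow_dla(100, rng_seed = 7)
#' nrow(agg)  # 101
grow_dla <- function(n_particles, rng_seed = 1, launch_margin = 5,
                     kill_factor = 3, max_attempts_per_particle = 1e5) {
  stopifnot(n_particles >= 0)
  set.seed(as.integer(rng_seed))
  if (n_particles == 0) {
    pts <- matrix(c(0L, 0L), 1, 2)
  } else {
    pts <- cpp_grow_dla(as.integer(n_particles), launch_margin, kill_factor,
                        max_attempts_per_particle)
  }
  out <- tibble::tibble(x = pts[, 1], y = pts[, 2])
  attr(out, "rng_seed") <- as.integer(rng_seed)
  attr(out, "seed_site") <- c(0L, 0L)
  class(out) <- c("dla_aggregate", class(out))
  out
}

#' Reduce an aggregate to its branching skeleton
#'
#' Builds the face-adjacency graph of the aggregate sites, takes the
#' breadth-first spanning tree from the seed (pruning any adjacency loops,
#' with a warning), and contracts all degree-2 chains into straight chords.
#' The remaining nodes are the seed (root), the branching points and the
#' tips; edges are straight segments between them.
#'
#' @param aggregate a [grow_dla()] result (or any tibble of connected
#'   lattice sites whose first row is the root site).
#' @return A `skeleton_tree`: list with `nodes` (tibble `id`, `x`, `y`,
#'   `type` in root/branch/tip; root has id 1) and `edges` (tibble `from`,
#'   `to`, `length`, ordered root-outward).
#' @export
skeletonize <- function(aggregate) {
  n <- nrow(aggregate)
  if (n == 0) stop("empty aggregate")
  key <- paste(aggregate$x, aggregate$y)
  idx <- stats::setNames(seq_len(n), key)
  # face adjacency
  from <- integer(0); to <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    nb <- paste(aggregate$x + d[1], aggregate$y + d[2])
    hit <- !is.na(idx[nb])
    from <- c(from, which(hit))
    to <- c(to, unname(idx[nb[hit]]))
  }
  if (n == 1) {
    nodes <- tibble::tibble(id = 1L, x = aggregate$x, y = aggregate$y,
                            type = "root")
    return(structure(list(nodes = nodes,
                          edges = tibble::tibble(from = integer(0),
                                                 to = integer(0),
                                                 length = numeric(0))),
                     class = "skeleton_tree"))
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::components(g)$no != 1) stop("aggregate is not connected")
  if (igraph::ecount(g) > n - 1) {
    warning("aggregate adjacency has ", igraph::ecount(g) - (n - 1),
            " loop edge(s); pruned by spanning tree")
  }
  bf <- igraph::bfs(g, root = 1, father = TRUE)
  father <- as.integer(bf$father)
  children <- vector("list", n)
  order_v <- as.integer(bf$order)
  for (v in order_v) {
    f <- father[v]
    if (!is.na(f)) children[[f]] <- c(children[[f]], v)
  }
  n_children <- lengths(children)
  keep <- n_children != 1L
  keep[1] <- TRUE # root is always a node

  kept_sites <- which(keep)
  node_id <- rep(NA_integer_, n)
  node_id[1] <- 1L
  node_id[setdiff(kept_sites, 1L)] <- seq_along(setdiff(kept_sites, 1L)) + 1L

  # walk root-outward, emitting a chord whenever a kept node is reached
  edges_from <- integer(0); edges_to <- integer(0); edges_len <- numeric(0)
  stack <- list(list(site = 1L, last = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (ch in children[[top$site]]) {
      last <- top$last
      if (keep[ch]) {
        a <- c(aggregate$x[last], aggregate$y[last])
        b <- c(aggregate$x[ch], aggregate$y[ch])
        edges_from <- c(edges_from, node_id[last])
        edges_to <- c(edges_to, node_id[ch])
        edges_len <- c(edges_len, sqrt(sum((a - b)^2)))
        stack[[length(stack) + 1L]] <- list(site = ch, last = ch)
      } else {
        stack[[length(stack) + 1L]] <- list(site = ch, last = last)
      }
    }
  }
  edges <- tibble::tibble(from = edges_from, to = edges_to, length = edges_len)
  edges <- .order_edges_rootward(edges)

  kept_sorted <- kept_sites[order(node_id[kept_sites])]
  deg <- table(factor(c(edges$from, edges$to), levels = node_id[kept_sorted]))
  type <- ifelse(node_id[kept_sorted] == 1L, "root",
                 ifelse(as.integer(deg) <= 1L, "tip", "branch"))
  nodes <- tibble::tibble(id = node_id[kept_sorted],
                          x = aggregate$x[kept_sorted],
                          y = aggregate$y[kept_sorted],
                          type = type)
  structure(list(nodes = nodes, edges = edges), class = "skeleton_tree")
}

# order edges so every edge's 'from' node is the root or a previous 'to'
.order_edges_rootward <- function(edges) {
  n <- nrow(edges)
  if (n == 0) return(edges)
  done <- logical(n)
  reached <- 1L
  out <- integer(0)
  while (length(out) < n) {
    nxt <- which(!done & edges$from %in% reached)
    if (!length(nxt)) stop("skeleton edges do not form a rooted tree")
    out <- c(out, nxt)
    done[nxt] <- TRUE
    reached <- c(reached, edges$to[nxt])
  }
  edges[out, ]
}

#' @export
print.skeleton_tree <- function(x, ...) {
  cat("<skeleton_tree> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(x$nodes$type == "tip"), " tips)\n", sep = "")
  invisible(x)
}

#' Lift a 2D skeleton into the ramuli slab
#'
#' The skeleton's radial distance from its root maps to depth: the root
#' lands on the attachment point (a rami tip, z = `z_range[1]`) and the
#' radially farthest node lands at z = `z_range[2]`, so the deepest point
#' of every lifted subtree reaches the basal end of the slab exactly. The
#' signed lateral coordinate (perpendicular to the skeleton's principal
#' growth direction) is preserved and rescaled to `lateral_halfwidth`,
#' laid out along `lateral_dir` in the xy plane.
#'
#' @param skeleton a [skeletonize()] result with at least one edge.
#' @param z_range depth range (mm), default the ramuli slab 13.5--24.5.
#' @param attach 3D attachment point (mm).
#' @param lateral_dir 2D unit vector for the subtree's lateral plane.
#' @param lateral_halfwidth lateral half-extent (mm).
#' @return list with `nodes` (tibble `id`, `x`, `y`, `z` in mm) and the
#'   skeleton's `edges`.
#' @export
lift_to_3d <- function(skeleton, z_range = c(13.5, 24.5),
                       attach = c(0, 0, 13.5), lateral_dir = c(1, 0),
                       lateral_halfwidth = 4) {
  nodes <- skeleton$nodes
  if (nrow(skeleton$edges) == 0) stop("skeleton has no edges to lift")
  p <- cbind(nodes$x - nodes$x[1], nodes$y - nodes$y[1])
  rho <- sqrt(rowSums(p^2))
  rho_max <- max(rho)
  if (rho_max == 0) stop("degenerate skeleton: all nodes at the root")
  e1 <- p[which.max(rho), ] / rho_max
  lat <- p[, 1] * (-e1[2]) + p[, 2] * e1[1] # signed perpendicular component
  lat_max <- max(abs(lat))
  s_lat <- if (lat_max > 0) lateral_halfwidth / lat_max else 0
  w <- lateral_dir / sqrt(sum(lateral_dir^2))
  z <- z_range[1] + (z_range[2] - z_range[1]) * rho / rho_max
  out_nodes <- tibble::tibble(
    id = nodes$id,
    x = attach[1] + s_lat * lat * w[1],
    y = attach[2] + s_lat * lat * w[2],
    z = z
  )
  list(nodes = out_nodes, edges = skeleton$edges)
}
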