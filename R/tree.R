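# Geometry of the rami chorii arcs ------------------------------------------
#
# Every rami branch departs its junction horizontally (in its own split
# azimuth) and bends back toward +z as a circular arc: curvature radius
# 1.74 mm for the generations with L_b < 1.74 mm, 8.99 mm beyond.
# Generation arclengths follow the L_b differences (0.29, 1.45, 2.90 mm);
# the fourth generation curves from horizontal to vertical and runs
# straight up so all 16 tips land at z = 13.5 mm. The lateral fan fills the
# per-tree territory (equivalent diameter 26-28 mm) that the placental-disc
# arithmetic implies.

.rami_R1 <- 1.74
.rami_R2 <- 8.99
.rami_z0 <- 2.9
.rami_z_end <- 13.5
.rami_gen_len <- c(0.29, 1.45, 2.90, NA) # gen 4 runs to vertical, then up
.rami_gen_R <- c(1.74, 1.74, 8.99, 8.99)

.new_branch <- function(id, tier, parent, axis, diameter) {
  tibble::tibble(id = as.integer(id), tier = tier,
                 parent = as.integer(parent),
                 axis = list(axis), diameter = list(diameter))
}

#' Build the truncus chorii branch
#'
#' A single vertical branch from the chorionic plate (z = 0) to the
#' truncus--rami boundary, with the quarter-ellipse radius profile of
#' [truncus_radius()].
#'
#' @param profile a [truncus_profile()].
#' @param center xy position of the axis (mm).
#' @param step axis sampling step (mm).
#' @return A one-row branch table.
#' @export
build_truncus <- function(profile = truncus_profile(),
                          center = c(17.4, 17.4), step = 0.1) {
  z <- unique(c(seq(0, profile$z_tr, by = step), profile$z_tr))
  axis <- cbind(x = rep(center[1], length(z)), y = rep(center[2], length(z)), z = z)
  .new_branch(1L, "truncus", NA_integer_, axis, 2 * truncus_radius(z, profile))
}

#' Build the rami chorii subtrees
#'
#' Two complete binary subtrees of four generations leave the truncus tip in
#' opposite horizontal directions; every branch departs its junction
#' horizontally in its own split azimuth and curves toward the basal plate
#' (curvature radius 1.74 mm for the first two generations, 8.99 mm
#' beyond), the fourth generation bending up to vertical so all 16 tips
#' reach z = 13.5 mm. Diameters taper linearly with arclength from 1 mm at
#' the junction with the truncus to 0.5 mm at the tips.
#'
#' @param origin 3D position of the truncus tip (mm).
#' @param parent_id id of the truncus branch.
#' @param first_id id given to the first rami branch.
#' @param base_azimuth azimuth (rad) of the first subtree; the second runs
#'   opposite.
#' @param step axis sampling step (mm).
#' @return A branch table with 30 rows (2 subtrees x 15 branches).
#' @export
build_rami_subtrees <- function(origin, parent_id = 1L, first_id = 2L,
                                base_azimuth = 0, step = 0.1) {
  # split azimuth offsets per generation: the sign combinations fold the 16
  # root-to-tip paths to four distinct tip radii, tiling the ~26 mm
  # territory instead of piling every tip on one ring
  half_spread <- c(NA, pi / 2, 3 * pi / 8, 3 * pi / 16)
  # per-path cumulative arclength, for the diameter taper (all paths equal)
  gen4_arc <- .rami_R2 * pi / 2
  gen4_vert <- .rami_z_end -
    (.rami_z0 + sum(.rami_gen_R[1:3] * (1 - cos(.rami_gen_len[1:3] /
                                                  .rami_gen_R[1:3]))) +
       .rami_R2)
  s_total <- sum(.rami_gen_len[1:3]) + gen4_arc + gen4_vert
  diam <- function(s_cum) 1 - 0.5 * s_cum / s_total

  rows <- list()
  next_id <- as.integer(first_id)

  # one branch: horizontal departure at azimuth alpha, circular climb of
  # radius R over arclength len; gen 4 (len NA) climbs to vertical then runs
  # straight to z = 13.5
  branch_axis <- function(p0, alpha, gen) {
    R <- .rami_gen_R[gen]
    if (gen < 4) {
      len <- .rami_gen_len[gen]
      s <- unique(c(seq(0, len, by = step), len))
      psi <- s / R
      lat <- R * sin(psi)
      zz <- p0[3] + R * (1 - cos(psi))
    } else {
      arc <- R * pi / 2
      s_arc <- unique(c(seq(0, arc, by = step), arc))
      psi <- s_arc / R
      lat <- R * sin(psi)
      zz <- p0[3] + R * (1 - cos(psi))
      vert <- .rami_z_end - zz[length(zz)]
      if (vert > 0) {
        zv <- seq(zz[length(zz)], .rami_z_end,
                  length.out = max(2L, ceiling(vert / step) + 1L))[-1]
        lat <- c(lat, rep(lat[length(lat)], length(zv)))
        zz <- c(zz, zv)
      } else {
        zz[length(zz)] <- .rami_z_end
      }
      # arclength including the vertical run
      s <- s_arc
      if (length(zz) > length(s_arc)) {
        extra <- zz[(length(s_arc) + 1):length(zz)] - zz[length(s_arc)]
        s <- c(s_arc, s_arc[length(s_arc)] + extra)
      }
    }
    list(axis = cbind(x = p0[1] + lat * cos(alpha),
                      y = p0[2] + lat * sin(alpha),
                      z = zz),
         s = s)
  }

  grow <- function(p0, alpha, gen, parent, s0) {
    ba <- branch_axis(p0, alpha, gen)
    id <- next_id
    next_id <<- next_id + 1L
    rows[[length(rows) + 1L]] <<- .new_branch(id, "rami", parent, ba$axis,
                                              diam(s0 + ba$s))
    if (gen < 4) {
      p_end <- ba$axis[nrow(ba$axis), ]
      for (sgn in c(-1, 1)) {
        grow(p_end, alpha + sgn * half_spread[gen + 1], gen + 1L, id,
             s0 + ba$s[length(ba$s)])
      }
    }
    invisible(NULL)
  }

  for (alpha0 in c(base_azimuth, base_azimuth + pi)) {
    grow(origin, alpha0, 1L, as.integer(parent_id), 0)
  }
  dplyr::bind_rows(rows)
}

#' Build the ramuli chorii subtrees from DLA skeletons
#'
#' One skeletonized diffusion-limited aggregate is lifted into the ramuli
#' slab (z = 13.5--24.5 mm) per rami tip; see [lift_to_3d()]. Diameters are
#' mapped from the centripetal order u of each branch onto the tier range
#' 0.3--0.5 mm, increasing with u, and matched to the parent diameter at
#' every junction.
#'
#' @param skeletons list of 16 [skeletonize()] results.
#' @param tips data frame with the rami tip `id`, `x`, `y` columns (mm).
#' @param center xy centre of the model (mm), used to orient each subtree's
#'   lateral plane radially.
#' @param first_id id of the first ramuli branch.
#' @param lateral_halfwidth lateral half-extent of each lifted subtree (mm).
#' @param step axis sampling step (mm).
#' @return A branch table.
#' @export
build_ramuli_subtrees <- function(skeletons, tips, center = c(17.4, 17.4),
                                  first_id, lateral_halfwidth = 4, step = 0.25) {
  stopifnot(length(skeletons) == nrow(tips))
  rows <- list()
  next_id <- as.integer(first_id)
  for (t in seq_len(nrow(tips))) {
    attach <- c(tips$x[t], tips$y[t], .rami_z_end)
    radial <- c(tips$x[t] - center[1], tips$y[t] - center[2])
    if (sqrt(sum(radial^2)) < 1e-9) radial <- c(1, 0)
    radial <- radial / sqrt(sum(radial^2))
    lifted <- lift_to_3d(skeletons[[t]], z_range = c(.rami_z_end, 24.5),
                         attach = attach, lateral_dir = radial,
                         lateral_halfwidth = lateral_halfwidth)
    # lifted: nodes (id, x, y, z), edges (from, to); convert edges to branches
    nodes <- lifted$nodes
    edges <- lifted$edges
    edge_branch <- integer(nrow(edges))
    node_in_branch <- rep(NA_integer_, nrow(nodes)) # branch id ending at node
    for (e in seq_len(nrow(edges))) {
      p0 <- unlist(nodes[nodes$id == edges$from[e], c("x", "y", "z")])
      p1 <- unlist(nodes[nodes$id == edges$to[e], c("x", "y", "z")])
      len <- sqrt(sum((p1 - p0)^2))
      nseg <- max(1L, ceiling(len / step))
      tt <- seq(0, 1, length.out = nseg + 1L)
      axis <- cbind(x = p0[1] + tt * (p1[1] - p0[1]),
                    y = p0[2] + tt * (p1[2] - p0[2]),
                    z = p0[3] + tt * (p1[3] - p0[3]))
      par_branch <- if (edges$from[e] == 1L) tips$id[t] else node_in_branch[edges$from[e]]
      id <- next_id
      next_id <- next_id + 1L
      edge_branch[e] <- id
      node_in_branch[edges$to[e]] <- id
      rows[[length(rows) + 1L]] <- .new_branch(id, "ramuli", par_branch, axis,
                                               rep(0.4, nrow(axis)))
    }
  }
  out <- dplyr::bind_rows(rows)
  .map_ramuli_diameters(out)
}

# Diameter map for the ramuli: within each subtree, d(u) = 0.3 + 0.2 *
# (u - 1) / (u_max - 1) at the distal end of a branch of centripetal order
# u, tapering linearly from the parent's end diameter so junction radii
# match.
.map_ramuli_diameters <- function(branches) {
  ord <- assign_orders(branches[, c("id", "parent")] |>
                         dplyr::mutate(parent = ifelse(.data$parent %in% branches$id,
                                                       .data$parent, NA_integer_)))
  u <- stats::setNames(ord$centripetal, ord$id)
  # subtree label: root branch of each lifted tree (parent outside table)
  root_of <- stats::setNames(rep(NA_integer_, nrow(branches)), branches$id)
  for (i in seq_len(nrow(branches))) {
    p <- branches$parent[i]
    root_of[as.character(branches$id[i])] <-
      if (!p %in% branches$id) branches$id[i] else root_of[as.character(p)]
  }
  u_max <- tapply(u[as.character(branches$id)], root_of, max)
  d_end <- function(id) {
    um <- u_max[as.character(root_of[as.character(id)])]
    if (um <= 1) return(0.3)
    0.3 + 0.2 * (u[as.character(id)] - 1) / (um - 1)
  }
  parent_end <- function(i) {
    p <- branches$parent[i]
    if (!p %in% branches$id) 0.5 else d_end(p)
  }
  for (i in seq_len(nrow(branches))) {
    np <- nrow(branches$axis[[i]])
    branches$diameter[[i]] <- seq(parent_end(i), d_end(branches$id[i]),
                                  length.out = np)
  }
  branches
}

#' Build the full three-tier villous tree
#'
#' Assembles the truncus, the two rami subtrees and the sixteen DLA-derived
#' ramuli subtrees into one rooted branch graph and assigns centripetal and
#' centrifugal orders. The construction is deterministic given
#' `master_seed`: the sixteen DLA growths use seeds
#' `(master_seed - 1) * 16 + 1:16`.
#'
#' @param master_seed integer master seed.
#' @param n_particles DLA particles per ramuli subtree (default calibrated so that lifted subtree generation counts stay within the observed 4--20 range).
#' @param profile a [truncus_profile()].
#' @param center xy centre of the model (mm).
#' @param lateral_halfwidth lateral half-extent of each ramuli subtree (mm).
#' @param step axis sampling step (mm).
#' @return An object of class `villous_tree`: a list with the branch table
#'   (`branches`), the tier table (`bounds`), the truncus profile, the
#'   centre, and the seeds used.
#' @export
#' @examples
#' \donttest{
#' tree <- build_villous_tree(master_seed = 1, n_particles = 50)
#' tree_max_z(tree)
#' }
build_villous_tree <- function(master_seed = 1, n_particles = 300,
                               profile = truncus_profile(),
                               center = c(17.4, 17.4),
                               lateral_halfwidth = 4, step = 0.1) {
  truncus <- build_truncus(profile, center, step)
  rami <- build_rami_subtrees(origin = c(center[1], center[2], profile$z_tr),
                              parent_id = 1L, first_id = 2L, step = step)
  # rami tips: branches of generation 4 (no rami children)
  tip_rows <- rami$id[!rami$id %in% rami$parent]
  tips <- dplyr::bind_rows(lapply(tip_rows, function(id) {
    ax <- rami$axis[[which(rami$id == id)]]
    tibble::tibble(id = id, x = ax[nrow(ax), 1], y = ax[nrow(ax), 2])
  }))

  seeds <- (as.integer(master_seed) - 1L) * 16L + 1:16
  skeletons <- vector("list", 16)
  used_seeds <- integer(16)
  for (i in 1:16) {
    seed_i <- seeds[i]
    repeat {
      agg <- grow_dla(n_particles, rng_seed = seed_i)
      sk <- skeletonize(agg)
      if (nrow(sk$edges) >= 2) break
      seed_i <- seed_i + 16L # degenerate aggregate: regenerate with next seed
    }
    skeletons[[i]] <- sk
    used_seeds[i] <- seed_i
  }
  ramuli <- build_ramuli_subtrees(skeletons, tips, center = center,
                                  first_id = max(rami$id) + 1L,
                                  lateral_halfwidth = lateral_halfwidth)

  branches <- dplyr::bind_rows(truncus, rami, ramuli)
  tree <- structure(
    list(branches = branches, bounds = tier_bounds(), profile = profile,
         center = center, master_seed = as.integer(master_seed),
         dla_seeds = used_seeds, n_particles = n_particles),
    class = "villous_tree"
  )
  assign_orders(tree)
}

#' @export
print.villous_tree <- function(x, ...) {
  cat("<villous_tree> ", nrow(x$branches), " branches (",
      paste(names(table(x$branches$tier)), table(x$branches$tier),
            sep = ": ", collapse = ", "),
      "), max z = ", format(tree_max_z(x), digits = 4), " mm\n", sep = "")
  invisible(x)
}

#' Deepest point of the tree
#'
#' @param tree a `villous_tree` or branch table.
#' @return Maximum z coordinate (mm) over all branch axis points.
#' @export
tree_max_z <- function(tree) {
  branches <- if (inherits(tree, "villous_tree")) tree$branches else tree
  max(vapply(branches$axis, function(a) max(a[, 3]), numeric(1)))
}

#' Sample all branch axes with proximally oriented tangents
#'
#' Every axis point of every branch, with the unit tangent oriented toward
#' the branch's proximal junction (i.e. toward the root): the direction in
#' which the contractile cells pull the surface.
#'
#' @param tree a `villous_tree` or branch table.
#' @return A tibble with `branch_id`, `tier`, `x`, `y`, `z` (mm) and the
#'   proximal unit tangent `tx`, `ty`, `tz`.
#' @export
axis_samples <- function(tree) {
  branches <- if (inherits(tree, "villous_tree")) tree$branches else tree
  out <- lapply(seq_len(nrow(branches)), function(i) {
    a <- branches$axis[[i]]
    n <- nrow(a)
    if (n == 1) {
      tan <- matrix(c(0, 0, -1), 1, 3)
    } else {
      nxt <- a[c(2:n, n), , drop = FALSE]
      prv <- a[c(1, 1:(n - 1)), , drop = FALSE]
      tan <- prv - nxt # points toward the branch start (proximal)
      nrm <- sqrt(rowSums(tan^2))
      nrm[nrm == 0] <- 1
      tan <- tan / nrm
    }
    tibble::tibble(branch_id = branches$id[i], tier = branches$tier[i],
                   x = a[, 1], y = a[, 2], z = a[, 3],
                   tx = tan[, 1], ty = tan[, 2], tz = tan[, 3])
  })
  dplyr::bind_rows(out)
}

#' Per-subtree morphometry of the ramuli chorii
#'
#' Groups the ramuli branches by the rami tip they hang from and computes,
#' within each subtree in isolation, the branch count, the tip generation
#' count C_f (maximum centrifugal order) and the bifurcation ratio R_b.
#'
#' @param tree a `villous_tree`.
#' @return A tibble with one row per ramuli subtree: `rami_tip`,
#'   `n_branches`, `c_f`, `u_max`, `r_b` (NA when fewer than two orders).
#' @export
ramuli_subtree_stats <- function(tree) {
  br <- tree$branches
  ram <- br[br$tier == "ramuli", ]
  sub_of <- rep(NA_integer_, nrow(ram))
  for (i in seq_len(nrow(ram))) {
    p <- ram$parent[i]
    sub_of[i] <- if (!p %in% ram$id) p else sub_of[match(p, ram$id)]
  }
  rows <- lapply(unique(sub_of), function(tip) {
    s <- ram[sub_of == tip, c("id", "parent")]
    s$parent[!s$parent %in% s$id] <- NA_integer_
    so <- assign_orders(s)
    rb <- tryCatch(
      estimate_bifurcation_ratio(order_counts(so))$r_b,
      error = function(e) NA_real_
    )
    tibble::tibble(rami_tip = tip, n_branches = nrow(s),
                   c_f = max(so$centrifugal), u_max = max(so$centripetal),
                   r_b = rb)
  })
  dplyr::bind_rows(rows)
}

#' Serialize a villous tree to JSON
#'
#' @param tree a `villous_tree`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  branches <- tree$branches
  payload <- list(
    master_seed = tree$master_seed,
    dla_seeds = tree$dla_seeds,
    n_particles = tree$n_particles,
    center = tree$center,
    profile = unclass(tree$profile),
    branches = lapply(seq_len(nrow(branches)), function(i) {
      list(id = branches$id[i], tier = branches$tier[i],
           parent = branches$parent[i],
           centripetal = branches$centripetal[i],
           centrifugal = branches$centrifugal[i],
           axis = unname(branches$axis[[i]]),
           diameter = branches$diameter[[i]])
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a villous tree written by [write_tree_json()]
#'
#' @param path JSON file.
#' @return A `villous_tree`.
#' @export
read_tree_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  rows <- lapply(payload$branches, function(b) {
    ax <- matrix(unlist(b$axis), ncol = 3,
                 dimnames = list(NULL, c("x", "y", "z")))
    br <- .new_branch(b$id, b$tier,
                      if (is.null(b$parent)) NA_integer_ else b$parent,
                      ax, as.numeric(unlist(b$diameter)))
    br$centripetal <- as.integer(b$centripetal)
    br$centrifugal <- as.integer(b$centrifugal)
    br
  })
  structure(
    list(branches = dplyr::bind_rows(rows), bounds = tier_bounds(),
         profile = do.call(truncus_profile, payload$profile),
         center = as.numeric(payload$center),
         master_seed = payload$master_seed,
         dla_seeds = as.integer(unlist(payload$dla_seeds)),
         n_particles = payload$n_particles),
    class = "villous_tree"
  )
}
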