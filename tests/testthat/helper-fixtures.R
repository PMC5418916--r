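# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; nothing is read from disk.

# a single straight z-aligned tube as a branch table
cylinder_branches <- function(x = 0.87, y = 0.87, z0 = 0.1, z1 = 3.0,
                              diameter = 1.0, tier = "ramuli") {
  tibble::tibble(
    id = 1L, tier = tier, parent = NA_integer_,
    axis = list(cbind(x = c(x, x), y = c(y, y), z = c(z0, z1))),
    diameter = list(c(diameter, diameter))
  )
}

# independent recursive order labelling (the brute-force oracle for
# assign_orders): tips 1; parent = max(children) + 1 when the max is tied,
# else max; centrifugal = depth from root
brute_force_orders <- function(id, parent) {
  n <- length(id)
  children <- lapply(id, function(i) id[!is.na(parent) & parent == i])
  centripetal <- function(i) {
    ch <- children[[match(i, id)]]
    if (length(ch) == 0) return(1L)
    orders <- vapply(ch, centripetal, integer(1))
    m <- max(orders)
    if (sum(orders == m) >= 2L) m + 1L else m
  }
  centrifugal <- function(i) {
    p <- parent[match(i, id)]
    if (is.na(p)) 1L else centrifugal(p) + 1L
  }
  tibble::tibble(
    id = id,
    centripetal = vapply(id, centripetal, integer(1)),
    centrifugal = vapply(id, centrifugal, integer(1))
  )
}

# random rooted tree on n nodes: each node's parent drawn among earlier nodes
random_tree <- function(n) {
  parent <- c(NA_integer_, vapply(2:n, function(i) {
    sample.int(i - 1L, 1L)
  }, integer(1)))
  tibble::tibble(id = seq_len(n), parent = parent)
}

# exhaustive O(N * 6) surface oracle
brute_force_surface <- function(occ) {
  d <- dim(occ)
  out <- array(FALSE, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!occ[i, j, k]) next
    nb <- c(
      if (i > 1) occ[i - 1, j, k] else FALSE,
      if (i < d[1]) occ[i + 1, j, k] else FALSE,
      if (j > 1) occ[i, j - 1, k] else FALSE,
      if (j < d[2]) occ[i, j + 1, k] else FALSE,
      if (k > 1) occ[i, j, k - 1] else FALSE,
      if (k < d[3]) occ[i, j, k + 1] else FALSE
    )
    out[i, j, k] <- any(!nb)
  }
  out
}

# all-pairs minimum distance oracle for the distance transform; squared
# distances are computed in integer voxel units so ties are exact
brute_force_nearest <- function(occ, surf, pixel_mm) {
  d <- dim(occ)
  dist <- array(NA_real_, dim = d)
  src <- array(0L, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (occ[i, j, k]) next
    d2 <- (surf$i - i)^2 + (surf$j - j)^2 + (surf$k - k)^2
    dist[i, j, k] <- sqrt(min(d2)) * pixel_mm
    src[i, j, k] <- which.max(d2 == min(d2)) # first (= smallest id) tie
  }
  list(distance = dist, source = src)
}

# half-space occupancy fixture: occupied for i <= i0, so unoccupied voxels
# sit at exact multiples of the pixel size from the surface plane
halfspace_grid <- function(n = 24, i0 = 5, pixel_um = 100) {
  occ <- array(FALSE, dim = c(n, n, n))
  occ[seq_len(i0), , ] <- TRUE
  voxel_grid(occ, pixel_um)
}

# fabricate an assigned surface for a grid, all elements pulling along `dir`
uniform_surface <- function(grid, dir = c(0, 0, -1)) {
  surf <- extract_surface(grid)
  surf$branch_id <- 1L
  surf$tier <- "ramuli"
  surf$dir_x <- dir[1]
  surf$dir_y <- dir[2]
  surf$dir_z <- dir[3]
  surf$phi_o <- acos(dir[3])
  surf$theta_o <- atan2(dir[2], dir[1])
  surf
}

# aggregate from explicit lattice coordinates (seed first)
aggregate_from_coords <- function(x, y) {
  out <- tibble::tibble(x = as.integer(x), y = as.integer(y))
  attr(out, "rng_seed") <- NA_integer_
  attr(out, "seed_site") <- c(out$x[1], out$y[1])
  class(out) <- c("dla_aggregate", class(out))
  out
}

# small tree + grid for pipeline-level tests (DLA kept tiny)
tiny_config <- function(out_dir, condition = "lambda1.45_dmax4.35") {
  run_config(pixel_size_um = 464, master_seed = 1, n_particles = 40,
             condition = condition, out_dir = out_dir,
             write_volumes = TRUE)
}
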