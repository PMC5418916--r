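# the default tree is reused across several blocks (construction is the
# expensive part); deterministic given the master seed
default_tree <- suppressWarnings(build_villous_tree(master_seed = 1))

test_that("rami subtrees are complete, equally dichotomous and reach z = 13.5", {
  rami <- default_tree$branches[default_tree$branches$tier == "rami", ]
  expect_identical(nrow(rami), 30L) # 2 subtrees x (1 + 2 + 4 + 8)
  tips <- rami$id[!rami$id %in% rami$parent]
  expect_identical(length(tips), 16L)
  tip_z <- vapply(tips, function(id) {
    a <- rami$axis[[match(id, rami$id)]]
    a[nrow(a), 3]
  }, numeric(1))
  expect_true(all(abs(tip_z - 13.5) < 0.058)) # within half a test voxel

  # per subtree: R_b exactly 2 and four generations at the tips
  for (root in rami$id[rami$parent == 1L]) {
    ids <- root
    repeat {
      nxt <- rami$id[rami$parent %in% ids & !rami$id %in% ids]
      if (!length(nxt)) break
      ids <- c(ids, nxt)
    }
    sub <- rami[rami$id %in% ids, c("id", "parent")]
    sub$parent[sub$id == root] <- NA_integer_
    so <- assign_orders(sub)
    expect_identical(max(so$centrifugal), 4L)
    expect_equal(estimate_bifurcation_ratio(order_counts(so))$r_b, 2,
                 tolerance = 1e-12)
  }
})

test_that("diameters respect the tier ranges and match at junctions", {
  br <- default_tree$branches
  rng <- list(truncus = c(1, 3), rami = c(0.5, 1), ramuli = c(0.3, 0.5))
  for (tier in names(rng)) {
    d <- unlist(br$diameter[br$tier == tier])
    expect_true(all(d >= rng[[tier]][1] - 1e-9 & d <= rng[[tier]][2] + 1e-9))
  }
  # a child's first diameter equals its parent's last
  for (i in seq_len(nrow(br))) {
    p <- br$parent[i]
    if (is.na(p)) next
    pd <- br$diameter[[match(p, br$id)]]
    expect_equal(br$diameter[[i]][1], pd[length(pd)], tolerance = 1e-9)
  }
})

test_that("ramuli subtrees are unequally dichotomous with bounded generations", {
  st <- ramuli_subtree_stats(default_tree)
  expect_identical(nrow(st), 16L)
  # generation counts within the observed anatomical range
  expect_true(all(st$c_f >= 4 & st$c_f <= 20))
  # unequal dichotomy: R_b dispersed above 2
  expect_true(all(st$r_b > 2, na.rm = TRUE))
  expect_gt(stats::sd(st$r_b, na.rm = TRUE), 0)
  # diameter endpoints of the order map: tips 0.3 mm, subtree roots 0.5 mm
  ram <- default_tree$branches[default_tree$branches$tier == "ramuli", ]
  tips <- !ram$id %in% ram$parent
  tip_end <- vapply(which(tips), function(i) {
    d <- ram$diameter[[i]]
    d[length(d)]
  }, numeric(1))
  expect_true(all(abs(tip_end - 0.3) < 1e-9))
  roots <- !ram$parent %in% ram$id
  root_start <- vapply(which(roots), function(i) ram$diameter[[i]][1], numeric(1))
  expect_true(all(abs(root_start - 0.5) < 1e-9))
})

test_that("the deepest branch point sits at 24.5 mm and z ranges fit the tiers", {
  expect_equal(tree_max_z(default_tree), 24.5)
  br <- default_tree$branches
  tb <- tier_bounds()
  for (tier in tb$tier) {
    zr <- range(unlist(lapply(br$axis[br$tier == tier], function(a) a[, 3])))
    expect_gte(zr[1], tb$z_min[tb$tier == tier] - 1e-9)
    expect_lte(zr[2], tb$z_max[tb$tier == tier] + 1e-9)
  }
})

test_that("rebuilding with the same master seed is bit-identical", {
  again <- suppressWarnings(build_villous_tree(master_seed = 1))
  expect_identical(default_tree$branches, again$branches)
  other <- suppressWarnings(build_villous_tree(master_seed = 2,
                                               n_particles = 60))
  expect_false(identical(default_tree$branches, other$branches))
})

test_that("tree JSON serialization round-trips", {
  small <- suppressWarnings(build_villous_tree(master_seed = 3,
                                               n_particles = 30))
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(small, path)
  back <- read_tree_json(path)
  expect_equal(back$branches$id, small$branches$id)
  expect_equal(back$branches$parent, small$branches$parent)
  expect_equal(back$branches$tier, small$branches$tier)
  for (i in seq_len(nrow(small$branches))) {
    expect_equal(unname(back$branches$axis[[i]]),
                 unname(small$branches$axis[[i]]), tolerance = 1e-12)
    expect_equal(back$branches$diameter[[i]], small$branches$diameter[[i]],
                 tolerance = 1e-12)
  }
  expect_equal(tree_max_z(back), 24.5)
})
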