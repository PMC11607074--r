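test_that("unobstructed AV is a ball of the linker length", {
  s <- structure_from_xyz(matrix(c(500, 500, 500), 1))  # far-away atom
  dye <- dye_model(linker_length = 10, linker_width = 4,
                   radii = c(3, 3, 3), attach_id = 1)
  s2 <- rbind(s, s)                                      # attach + obstacle
  s2$eleno <- 1:2
  s2$x[1] <- 0; s2$y[1] <- 0; s2$z[1] <- 0
  class(s2) <- class(s)
  av <- compute_av(s2, dye, spacing = 0.5)
  vol <- nrow(av$points) * 0.5^3
  expect_equal(vol, 4 / 3 * pi * 10^3, tolerance = 0.05 * 4 / 3 * pi * 10^3)
  expect_true(all(av$points$dist <= 10 + 1e-9))
})

test_that("a wall of atoms confines the AV to a half-space", {
  # x = 3 plane of atoms, attachment at the origin
  g <- expand.grid(x = 3, y = seq(-15, 15, 1.5), z = seq(-15, 15, 1.5))
  atoms <- structure_from_xyz(rbind(c(0, 0, 0), as.matrix(g)))
  dye <- dye_model(linker_length = 8, linker_width = 3,
                   radii = c(1.5, 1.5, 1.5), attach_id = 1)
  av <- compute_av(atoms, dye, spacing = 1)
  expect_gt(nrow(av$points), 0)
  expect_true(all(av$points$x < 3))
  # brute-force constraint check: no AV point clashes with any atom
  xyz <- as.matrix(g)
  for (i in seq_len(nrow(av$points))) {
    p <- unlist(av$points[i, c("x", "y", "z")])
    d <- sqrt(colSums((t(xyz) - p)^2))
    expect_gt(min(d), 1.7 + 1.5 - 1e-9)   # carbon vdW + smallest dye radius
  }
})

test_that("AV grows with linker length and shrinks with dye radius", {
  g <- expand.grid(x = 4, y = seq(-12, 12, 2), z = seq(-12, 12, 2))
  atoms <- structure_from_xyz(rbind(c(0, 0, 0), as.matrix(g)))
  mk <- function(L, r) dye_model(linker_length = L, linker_width = 2,
                                 radii = rep(r, 3), attach_id = 1)
  av_small <- compute_av(atoms, mk(5, 1.5), spacing = 1)
  av_large <- compute_av(atoms, mk(10, 1.5), spacing = 1)
  expect_gt(nrow(av_large$points), nrow(av_small$points))
  key <- function(av) paste(av$points$x, av$points$y, av$points$z)
  expect_true(all(key(av_small) %in% key(av_large)))   # strict containment
  av_fat <- compute_av(atoms, mk(10, 3), spacing = 1)
  expect_lte(nrow(av_fat$points), nrow(av_large$points))
})

test_that("grid geodesics agree with an igraph shortest-path oracle", {
  skip_if_not_installed("igraph")
  # partial wall obstruction, coarse grid
  g <- expand.grid(x = 4, y = seq(-6, 6, 1.5), z = seq(-6, 0, 1.5))
  atoms <- structure_from_xyz(rbind(c(0, 0, 0), as.matrix(g)))
  dye <- dye_model(linker_length = 6, linker_width = 2,
                   radii = c(1.5, 1.5, 1.5), attach_id = 1)
  av <- compute_av(atoms, dye, spacing = 1)
  # oracle: 26-neighbour graph over linker-free nodes
  half <- 6; dim <- 2 * half + 1
  nodes <- expand.grid(i = -half:half, j = -half:half, k = -half:half)
  xyz <- as.matrix(nodes)
  free <- rep(TRUE, nrow(nodes))
  obst <- as.matrix(g)
  for (a in seq_len(nrow(obst))) {
    d2 <- colSums((t(xyz) - obst[a, ])^2)
    free <- free & d2 >= (1.7 + 1)^2     # vdW + linker halfwidth
  }
  free[xyz[, 1] == 0 & xyz[, 2] == 0 & xyz[, 3] == 0] <- TRUE
  idx <- which(free)
  id_of <- function(i, j, k) (i + half) * dim^2 + (j + half) * dim + k + half + 1
  edges <- NULL; weights <- NULL
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  node_id <- integer(dim^3); node_id[id_of(xyz[idx, 1], xyz[idx, 2], xyz[idx, 3])] <- seq_along(idx)
  el <- list()
  for (m in seq_len(nrow(offs))) {
    nb <- sweep(xyz[idx, , drop = FALSE], 2, -offs[m, ])
    ok <- abs(nb[, 1]) <= half & abs(nb[, 2]) <= half & abs(nb[, 3]) <= half
    tid <- rep(0L, length(idx))
    tid[ok] <- node_id[id_of(nb[ok, 1], nb[ok, 2], nb[ok, 3])]
    ok <- ok & tid > 0
    el[[m]] <- cbind(seq_along(idx)[ok], tid[ok], sqrt(sum(offs[m, ]^2)))
  }
  el <- do.call(rbind, el)
  gr <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  gr <- igraph::add_edges(gr, t(el[, 1:2]))
  igraph::E(gr)$weight <- el[, 3]
  src <- node_id[id_of(0, 0, 0)]
  expect_gt(src, 0)
  dist <- igraph::distances(gr, v = src)[1, ]
  # containment: every linker-free dye-free node within graph distance L
  # must be inside the AV (the AV metric is never larger than the graph's)
  key_av <- paste(av$points$x, av$points$y, av$points$z)
  reach <- idx[dist <= 6]
  for (n in reach) {
    p <- xyz[match(n, idx) * 0 + n, , drop = FALSE]  # node coordinates
    p <- xyz[n, ]
    dmin <- sqrt(min(colSums((t(obst) - p)^2)))
    if (dmin < 1.7 + 1.5) next                       # dye-clashed: not in AV
    expect_true(paste(p[1], p[2], p[3]) %in% key_av)
  }
  # soundness: every AV point is reachable and within the Euclidean bound
  ids_free <- id_of(xyz[idx, 1], xyz[idx, 2], xyz[idx, 3])
  for (i in seq_len(nrow(av$points))) {
    p <- unlist(av$points[i, c("x", "y", "z")])
    expect_lte(sqrt(sum(p^2)), 6 + 1e-9)
    j <- match(id_of(p[1], p[2], p[3]), ids_free)
    expect_false(is.na(j))            # linker-free in the oracle too
    expect_true(is.finite(dist[j]))   # connected to the attachment point
  }
})

test_that("buried attachment points raise an error", {
  shell <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2),
                                 z = c(-2, 0, 2)))
  shell <- shell[rowSums(shell^2) > 0, ]
  atoms <- structure_from_xyz(rbind(c(0, 0, 0), shell))
  dye <- dye_model(linker_length = 6, linker_width = 3,
                   radii = c(2, 2, 2), attach_id = 1)
  expect_error(compute_av(atoms, dye, spacing = 1), "no accessible volume")
})

test_that("FRET-averaged distance behaves in the limiting geometries", {
  mk_av <- function(xyz) {
    pts <- as.data.frame(matrix(xyz, ncol = 3))
    names(pts) <- c("x", "y", "z")
    pts$weight <- 1; pts$dist <- 0
    structure(list(points = pts, attach = c(0, 0, 0), spacing = 1),
              class = "accessible_volume")
  }
  # two single points at exactly R0
  a <- mk_av(c(0, 0, 0)); b <- mk_av(c(67.4, 0, 0))
  mf <- mean_fret_distance(a, b, 67.4)
  expect_equal(mf$E_avg, 0.5)
  expect_equal(mf$R_da, 67.4)
  # two compact distant clouds: distance near the centroid separation
  set.seed(3)
  ca <- matrix(rnorm(30 * 3, 0, 0.5), ncol = 3)
  cb <- sweep(matrix(rnorm(30 * 3, 0, 0.5), ncol = 3), 2, c(80, 0, 0), "+")
  mf2 <- mean_fret_distance(mk_av(ca), mk_av(cb), 67.4)
  expect_equal(mf2$R_da, 80, tolerance = 2)
  # exchange symmetry (exhaustive branch)
  mf3 <- mean_fret_distance(mk_av(cb), mk_av(ca), 67.4)
  expect_equal(mf2$R_da, mf3$R_da, tolerance = 1e-12)
  # coincident clouds: dominated by short distances
  mf4 <- mean_fret_distance(mk_av(ca), mk_av(ca + 0.1), 67.4)
  expect_lt(mf4$R_da, 20)
  expect_error(mean_fret_distance(mk_av(ca)[c()], mk_av(ca), 67.4))
})

test_that("rigid rotation preserves intra-half distances", {
  set.seed(8)
  pts <- matrix(rnorm(30), ncol = 3)
  rot <- rotafret:::rotate_points(pts, origin = c(1, 2, 0),
                                  axis = c(0.3, 0.5, 1), angle_deg = 137)
  expect_equal(as.numeric(dist(rot)), as.numeric(dist(pts)),
               tolerance = 1e-9)
  # 360 degrees is the identity
  full <- rotafret:::rotate_points(pts, c(0, 0, 0), c(0, 0, 1), 360)
  expect_equal(full, pts, tolerance = 1e-9)
})

# Toy "synapse": two sparse arms on a rotation axis; dyes at the arm
# tips.  Atoms are spaced so the linker can leave the tip region.
toy_synapse <- function(asym = FALSE) {
  arm1 <- cbind(c(2, 6, 10), 0, 8)       # fixed arm at z = 8
  arm2 <- cbind(c(2, 6, 10), 0, -8)      # rotating arm at z = -8
  if (asym) arm2 <- cbind(c(2, 6, 10), c(0, 2.5, 5), -8)
  structure_from_xyz(rbind(arm1, arm2))
}

test_that("rotation scan starts at the unrotated geometry and closes at 360", {
  s <- toy_synapse()
  n1 <- 3
  dye_fix <- dye_model(6, 2, c(1.5, 1.5, 1.5), attach_id = n1)       # tip of arm 1
  dye_rot <- dye_model(6, 2, c(1.5, 1.5, 1.5), attach_id = n1 + 3)   # tip of arm 2
  prof <- rotation_scan(s, rotating = c(rep(FALSE, n1), rep(TRUE, 3)),
                        axis_point1 = c(0, 0, -10), axis_point2 = c(0, 0, 10),
                        step = 90, dye_rot = dye_rot, dye_fix = dye_fix,
                        R0 = 50, spacing = 1, n_pairs = 2e6)
  expect_equal(prof$angle, c(0, 90, 180, 270, 360))
  # unrotated reference
  av_f <- compute_av(s, dye_fix, 1); av_r <- compute_av(s, dye_rot, 1)
  ref <- mean_fret_distance(av_r, av_f, 50, n_pairs = 2e6)
  expect_equal(prof$R_da[1], ref$R_da, tolerance = 1e-9)
  # periodicity within grid tolerance
  expect_equal(prof$R_da[5], prof$R_da[1], tolerance = 0.5)
  # tips start on the same side (angle 0 near) -> distance grows to 180
  expect_gt(prof$R_da[3], prof$R_da[1])
})

test_that("an asymmetric synapse breaks the rotation-direction symmetry", {
  s <- toy_synapse(asym = TRUE)
  n1 <- 3
  dye_fix <- dye_model(6, 2, c(1.5, 1.5, 1.5), attach_id = n1)
  dye_rot <- dye_model(6, 2, c(1.5, 1.5, 1.5), attach_id = n1 + 3)
  prof <- rotation_scan(s, rotating = c(rep(FALSE, n1), rep(TRUE, 3)),
                        axis_point1 = c(0, 0, -10), axis_point2 = c(0, 0, 10),
                        step = 45, dye_rot = dye_rot, dye_fix = dye_fix,
                        R0 = 50, spacing = 1)
  # profile over 0-180 is not the mirror of 180-360
  fwd <- prof$R_da[prof$angle %in% c(45, 90, 135)]
  bwd <- rev(prof$R_da[prof$angle %in% c(225, 270, 315)])
  expect_gt(max(abs(fwd - bwd)), 0.5)
})

test_that("rotation scan validates its selection and axis", {
  s <- toy_synapse()
  dye <- dye_model(6, 2, c(1.5, 1.5, 1.5), attach_id = 1)
  expect_error(rotation_scan(s, rep(TRUE, 6), c(0, 0, -1), c(0, 0, 1),
                             90, dye, dye, 50), "proper")
  expect_error(rotation_scan(s, c(rep(FALSE, 3), rep(TRUE, 3)),
                             c(0, 0, 1), c(0, 0, 1), 90, dye, dye, 50),
               "axis")
})
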