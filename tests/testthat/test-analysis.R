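# Field maps, profiles and junction metrics, checked against hand-built
# oracles on synthetic inputs.

test_that("Delaunay triangulation covers the hull and the interpolant is
           exact at the nodes", {
  set.seed(1)
  P <- cbind(runif(40, -10, 10), runif(40, -10, 10))
  tri <- episheet:::delaunay_triangulate(P)
  expect_gt(nrow(tri), 20)
  v <- P[, 1]^2 - 3 * P[, 2]
  at_nodes <- episheet:::interp_linear(P, matrix(v, ncol = 1),
                                       sort(P[, 1]), sort(P[, 2]))
  # nodes lie on the sorted grids at their own (x, y): check a sample
  for (i in c(1, 7, 23)) {
    gi <- match(P[i, 1], sort(P[, 1])) +
      (match(P[i, 2], sort(P[, 2])) - 1) * 40
    expect_equal(at_nodes[gi, 1], v[i], tolerance = 1e-9)
  }
})

test_that("a linear field is reproduced exactly by the interpolating map", {
  set.seed(2)
  P <- cbind(runif(30, 0, 20), runif(30, 0, 20))
  v <- 2 * P[, 1] - 0.5 * P[, 2] + 3
  m <- field_map(P, v, spacing = 1)
  tb <- as_tibble(m)
  tb <- tb[!is.na(tb$value), ]
  expect_lt(max(abs(tb$value - (2 * tb$x - 0.5 * tb$y + 3))), 1e-8)
})

test_that("three-cell displacement toy matches hand interpolation", {
  # centroids at a unit-ish triangle; displacements (1,0), (0,0), (0,0)
  P <- rbind(c(0, 0), c(10, 0), c(0, 10))
  U <- rbind(c(1, 0), c(0, 0), c(0, 0))
  m <- field_map(P, U, spacing = 1)
  # value at the first centroid is its own displacement
  i <- which(m$x == 0); j <- which(m$y == 0)
  expect_equal(m$vals[i, j, 1], 1, tolerance = 1e-9)
  # halfway along the edge to centroid 2: barycentric weight 1/2
  i5 <- which(m$x == 5)
  expect_equal(m$vals[i5, j, 1], 0.5, tolerance = 1e-9)
  # at the opposite edge: zero
  i0 <- which(m$x == 10)
  expect_equal(m$vals[i0, j, 1], 0, tolerance = 1e-9)
})

test_that("run averaging is idempotent on identical maps and
           order-independent", {
  set.seed(3)
  P <- cbind(runif(12, 0, 10), runif(12, 0, 10))
  m1 <- field_map(P, rnorm(12), spacing = 1, extent = c(0, 10, 0, 10))
  m2 <- field_map(P, rnorm(12), spacing = 1, extent = c(0, 10, 0, 10))
  same <- average_field_maps(list(m1, m1))
  expect_equal(same$vals, m1$vals)
  ab <- average_field_maps(list(m1, m2))
  ba <- average_field_maps(list(m2, m1))
  expect_equal(ab$vals, ba$vals)
  expect_error(average_field_maps(list(m1, field_map(P, rnorm(12),
    spacing = 2, extent = c(0, 10, 0, 10)))), "grid mismatch")
})

test_that("radial fields give identical parallel and perpendicular
           profiles, and crossings solve the closed form", {
  gx <- seq(-30, 30, by = 3)
  P <- expand.grid(x = gx, y = gx)
  r <- sqrt(P$x^2 + P$y^2)
  m <- field_map(as.matrix(P), 1 / (1 + r), spacing = 1,
                 extent = c(-30, 30, -30, 30))
  pa <- axis_profile(m, "parallel")
  pe <- axis_profile(m, "perpendicular")
  n <- min(nrow(pa), nrow(pe))
  ok <- pa$valid[1:n] & pe$valid[1:n]
  expect_equal(pa$value[1:n][ok], pe$value[1:n][ok], tolerance = 1e-9)
  # threshold crossing on max(0, 10 - 0.2 d): crosses 5 at d = 25
  lin <- field_map(as.matrix(P), pmax(0, 10 - 0.2 * sqrt(P$x^2 + P$y^2)),
                   spacing = 1, extent = c(-30, 30, -30, 30))
  pl <- axis_profile(lin, "parallel")
  expect_equal(profile_crossing(pl, 5), 25, tolerance = 1e-6)
  # monotone profile: unique crossing (value decreasing)
  expect_true(all(diff(pl$value[pl$valid][1:26]) <= 1e-9))
})

test_that("maps are equivariant under frame translation", {
  set.seed(4)
  P <- cbind(runif(15, 0, 10), runif(15, 0, 10))
  v <- rnorm(15)
  m0 <- field_map(P, v, spacing = 1, extent = c(0, 10, 0, 10))
  sh <- c(3, -2)
  m1 <- field_map(sweep(P, 2, sh, `+`), v, spacing = 1,
                  extent = c(0, 10, 0, 10) + sh[c(1, 1, 2, 2)],
                  origin = sh)
  expect_equal(m0$vals, m1$vals, tolerance = 1e-9)
})

test_that("force maps average per-cell vertex magnitudes and ignore other
           components", {
  p <- epi_params()
  st <- make_fixture("two_cell", p = p)
  ts <- st$tissue
  fb <- total_cell_force(ts, p)
  # hand-set per-vertex fa magnitudes: cell 1 {1,1,3,3,...}, cell 2 {2,...}
  n1 <- ts$clen[1]; n2 <- ts$clen[2]
  fa <- matrix(0, ts$n, 2)
  fa[cell_indices(ts, 1), 1] <- rep(c(1, 3), length.out = n1)
  fa[cell_indices(ts, 2), 1] <- 2
  traj <- structure(list(
    before = st, after = st, origin = c(0, 0), cell = 1L,
    breakdown_after = modifyList(fb, list(fa = fa))
  ), class = "epi_trajectory")
  m <- force_map(traj, "fa", spacing = 1)
  ctr <- tissue_centroids(ts)
  val_at <- function(m, pt) {
    i <- which.min(abs(m$x - pt[1])); j <- which.min(abs(m$y - pt[2]))
    m$vals[i, j, 1]
  }
  expect_equal(val_at(m, ctr[1, ]), 2, tolerance = 0.05)
  expect_equal(val_at(m, ctr[2, ]), 2, tolerance = 0.05)
  # component independence: junc map unaffected by the fa values
  mj1 <- force_map(traj, "junc", spacing = 1)
  traj2 <- traj
  traj2$breakdown_after$fa <- 5 * fa
  mj2 <- force_map(traj2, "junc", spacing = 1)
  expect_identical(mj1$vals, mj2$vals)
  expect_error(force_map(traj, "bogus"))
})

test_that("difference profiles do plain arithmetic and vanish for identical
           runs", {
  gx <- seq(-20, 20, by = 4)
  P <- as.matrix(expand.grid(x = gx, y = gx))
  d <- sqrt(P[, 1]^2 + P[, 2]^2)
  mg <- field_map(P, d, spacing = 1, extent = c(-20, 20, -20, 20))
  mu <- field_map(P, 2 * d, spacing = 1, extent = c(-20, 20, -20, 20))
  same <- difference_profile(mg, mg)
  expect_equal(max(abs(same$diff), na.rm = TRUE), 0)
  dp <- difference_profile(mg, mu)
  ok <- dp$valid
  expect_equal(dp$diff[ok], -dp$distance[ok], tolerance = 1e-9)
})

test_that("substrate maps equal raw point displacements at lattice sites", {
  p <- epi_params()
  lat <- build_lattice(c(-10, 10, -10, 10), 2)
  lat$S <- lat$S0 + matrix(c(0, -2), nrow(lat$S0), 2, byrow = TRUE)
  st <- make_fixture("single_cell", p = p)
  traj <- structure(list(before = st, after = modifyList(st, list(lattice = lat)),
                         origin = c(0, 0)), class = "epi_trajectory")
  traj$after$lattice <- lat
  m <- substrate_displacement_map(list(traj), spacing = 1)
  tb <- as_tibble(m)
  expect_equal(max(abs(tb$magnitude - 2), na.rm = TRUE), 0, tolerance = 1e-9)
})

test_that("junction metrics recover hand-built two-bump peak statistics and
           the half-length-change pairing", {
  lat <- build_lattice(c(-30, 30, -30, 30), 2)
  # synthetic displacement field: two Gaussian bumps of heights .08/.12 at
  # x = -10 and +10 along the x axis
  S0 <- lat$S0
  bump <- function(x0, hgt) hgt * exp(-((S0[, 1] - x0)^2 + S0[, 2]^2) / 32)
  disp <- bump(-10, 0.08) + bump(10, 0.12)
  S_off <- lat$S0 + cbind(disp, 0)
  L_series <- tibble::tibble(time = c(0, 120, 720, 1320),
                             L = c(10, 10, 7, 6),
                             L_rel = c(10, 10, 7, 6) / 10)
  traj <- structure(list(
    L_series = L_series, L0 = 10,
    junction_center = c(0, 0), junction_axis = c(1, 0),
    S_on = lat$S0, S_off = S_off, lattice = lat,
    protocol = activation_protocol(),
    destroyed = FALSE
  ), class = "opto_trajectory")
  jm <- junction_metrics(traj, step = 0.5, half_width = 20)
  expect_equal(jm$peak_mean, 0.10, tolerance = 0.06)
  # dL over the activation window: L(120) - L(1320) = 4; half is 2
  expect_equal(jm$dL, 4)
  expect_equal(jm$half_dL, 2)
  expect_false(jm$flagged)
  expect_equal(jm$L_rel_end, 0.6)
})
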