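# Substrate lattice: geometry, stiffness fields, calibration, internal
# forces, focal adhesions, and the static-load oracle.

p0 <- epi_params()

test_that("lattice geometry: coordination 6, rest edges h, closed-form count", {
  lat <- build_lattice(c(-5, 5, -5, 5), 1)
  nnbr <- rowSums(!is.na(lat$nbr))
  interior <- nnbr == 6
  expect_gt(sum(interior), 0)
  # every rest edge has length h
  e <- lat$edges
  L <- sqrt(rowSums((lat$S0[e[, 2], ] - lat$S0[e[, 1], ])^2))
  expect_lt(max(abs(L - lat$h)), 1e-12)
  # rows x cols closed form vs direct construction
  expect_equal(nrow(lat$S), lat$nx * lat$ny)
  expect_equal(lat$nx, floor(10 / 1) + 1L)
  expect_equal(lat$ny, floor(10 / (sqrt(3) / 2)) + 1L)
  expect_error(build_lattice(c(0, 1, 0, 1), 1), "extent")
  expect_error(build_lattice(c(-5, 5, -5, 5), -1), "positive")
})

test_that("stiffness fields: uniform, interface endpoints, gradient slope
           bound", {
  f <- stiffness_field("uniform", 1.1)
  expect_equal(field_E(f, c(-50, 0, 50)), rep(1.1, 3))
  fi <- stiffness_field("interface", 1.1, 11, y_transition = 40, width = 2)
  expect_equal(field_E(fi, -39), 1.1)
  expect_equal(field_E(fi, -41), 11)
  mid <- field_E(fi, -40)
  expect_gt(mid, 1.1); expect_lt(mid, 11)
  fg <- stiffness_field("gradient", 1.1, 11, y_transition = 40, width = 50)
  y <- seq(-100, 20, by = 0.25)
  slope <- abs(diff(field_E(fg, y)) / diff(y))
  expect_lt(max(slope), (11 - 1.1) / 50 * (1 + 1e-9))
  # monotone and continuous between the plateaus
  expect_true(all(diff(field_E(fg, rev(y))) >= 0))
})

test_that("applying a field assigns E per point and warns out of range", {
  lat <- build_lattice(c(-10, 10, -60, 10), 2)
  lat <- apply_stiffness_field(lat, stiffness_field("uniform", 1.1))
  expect_equal(unique(lat$E), 1.1)
  fi <- stiffness_field("interface", 1.1, 11, y_transition = 40, width = 2)
  lat2 <- apply_stiffness_field(lat, fi)
  expect_equal(lat2$E[which.max(lat2$S0[, 2])], 1.1)
  expect_equal(lat2$E[which.min(lat2$S0[, 2])], 11)
  expect_warning(apply_stiffness_field(lat, stiffness_field("uniform", 35)),
                 "calibrated")
})

test_that("calibration is linear in E, positive, and matches the bonded-layer
           profile within 15%", {
  c1 <- calibrate_substrate(1.1, 0.5, 2, 100)
  c2 <- calibrate_substrate(11, 0.5, 2, 100)
  expect_equal(c2$k_central, 10 * c1$k_central, tolerance = 1e-12)
  expect_equal(c2$k_rest, 10 * c1$k_rest, tolerance = 1e-12)
  expect_gt(c1$k_rest, 0)                  # bonded finite-thickness gel
  expect_lt(c1$resid, 0.15)
  expect_error(calibrate_substrate(-1, 0.5, 2, 100), "positive")
})

test_that("central springs: zero at rest, Hooke along an edge, translation
           invariant", {
  lat <- build_lattice(c(-4, 4, -4, 4), 1)
  expect_equal(max(abs(central_force(lat))), 0)
  Ft <- central_force(lat, lat$S + 3.3)      # uniform translation
  expect_lt(max(abs(Ft)), 1e-9)
  # displace one interior point along an edge direction
  i <- which.min(rowSums(lat$S0^2))
  nb <- lat$nbr[i, 1]
  u <- (lat$S0[nb, ] - lat$S0[i, ]) / lat$h
  S <- lat$S0; delta <- 0.05
  S[i, ] <- S[i, ] + delta * u
  F <- central_force(lat, S)
  ke <- lat$k_edge[which(lat$edges[, 1] == min(i, nb) &
                           lat$edges[, 2] == max(i, nb))]
  # contribution from that edge alone: project onto u for the pair
  expect_equal(sum(F[i, ] * u) + sum(F[nb, ] * -u) < 0, TRUE)
  expect_lt(max(abs(colSums(F))), 1e-9)      # pairwise antisymmetric
})

test_that("repulsive force: zero at rest, pushes a point off a close
           opposite edge, monotone in distance", {
  lat <- build_lattice(c(-4, 4, -4, 4), 1)
  expect_equal(max(abs(repulsive_force(lat))), 0)
  i <- which.min(rowSums(lat$S0^2))
  nb <- lat$nbr[i, ]; nb <- nb[!is.na(nb)]
  # move the point toward the midpoint of two adjacent neighbors
  a <- nb[1]
  b <- intersect(lat$nbr[a, ], nb); b <- b[!is.na(b)][1]
  mid <- 0.5 * (lat$S0[a, ] + lat$S0[b, ])
  push_mag <- function(frac) {
    S <- lat$S0
    S[i, ] <- mid + frac * (lat$S0[i, ] - mid)
    F <- repulsive_force(lat, S)
    sqrt(sum(F[i, ]^2))
  }
  m1 <- push_mag(0.10); m2 <- push_mag(0.30); m3 <- push_mag(0.8)
  expect_gt(m1, m2)
  expect_gte(m2, m3)
  expect_gt(m1, 0)
  # direction: away from the edge
  S <- lat$S0; S[i, ] <- mid + 0.1 * (lat$S0[i, ] - mid)
  F <- repulsive_force(lat, S)
  away <- (lat$S0[i, ] - mid) / sqrt(sum((lat$S0[i, ] - mid)^2))
  expect_gt(sum(F[i, ] * away), 0)
})

test_that("restorative springs pull points home; uniform translation sums
           to minus N k_rest u", {
  lat <- build_lattice(c(-4, 4, -4, 4), 1)
  expect_equal(max(abs(restorative_force(lat))), 0)
  S <- lat$S0
  S[5, ] <- S[5, ] + c(0, 3)
  F <- restorative_force(lat, S)
  expect_equal(F[5, ], c(0, -3 * lat$k_rest[5]), tolerance = 1e-12)
  St <- lat$S0 + matrix(c(1, -2), nrow(lat$S0), 2, byrow = TRUE)
  Ft <- restorative_force(lat, St)
  expect_equal(colSums(Ft), -c(1, -2) * sum(lat$k_rest), tolerance = 1e-9)
})

test_that("statically loaded lattice matches a brute-force energy
           minimization oracle to 1e-6 relative", {
  lat <- build_lattice(c(-6, 6, -6, 6), 1.5, E = 1.1)
  N <- nrow(lat$S)
  ctr <- which.min(rowSums(lat$S0^2))
  Fext <- matrix(0, N, 2); Fext[ctr, 1] <- 0.5
  # oracle: first-principles spring energy minimized by L-BFGS-B
  e <- lat$edges; ke <- lat$k_edge; kr <- lat$k_rest; h <- lat$h; S0 <- lat$S0
  en <- function(x) {
    S <- matrix(x, ncol = 2)
    D <- S[e[, 2], ] - S[e[, 1], ]
    L <- sqrt(rowSums(D^2))
    sum(0.5 * ke * (L - h)^2) + sum(0.5 * kr * rowSums((S - S0)^2)) -
      sum(Fext * S)
  }
  gr <- function(x) {
    S <- matrix(x, ncol = 2)
    D <- S[e[, 2], ] - S[e[, 1], ]
    L <- sqrt(rowSums(D^2))
    f <- ke * (L - h) / L
    G <- matrix(0, N, 2)
    for (k in seq_len(nrow(e))) {
      G[e[k, 1], ] <- G[e[k, 1], ] - f[k] * D[k, ]
      G[e[k, 2], ] <- G[e[k, 2], ] + f[k] * D[k, ]
    }
    as.vector(G + kr * (S - S0) - Fext)
  }
  op <- stats::optim(as.vector(lat$S0), en, gr, method = "L-BFGS-B",
                     control = list(maxit = 5000, factr = 1))
  S_oracle <- matrix(op$par, ncol = 2)
  # package route: relax the lattice dynamics under the same load
  S <- lat$S0
  dtE <- 0.3 / max(lat$k_pt)           # stable explicit gradient-flow step
  for (iter in 1:30000) {
    F <- central_force(lat, S) + restorative_force(lat, S) + Fext
    S <- S + dtE * F
    if (max(abs(F)) < 1e-10) break
  }
  u_oracle <- S_oracle[ctr, 1] - S0[ctr, 1]
  u_pkg <- S[ctr, 1] - S0[ctr, 1]
  expect_lt(abs(u_pkg - u_oracle) / abs(u_oracle), 1e-6)
})

test_that("equilibrium displacement scales as 1/E and decreases with E over
           the calibrated stiffnesses", {
  disp_at <- function(E) {
    lat <- build_lattice(c(-6, 6, -6, 6), 1.5, E = E)
    ctr <- which.min(rowSums(lat$S0^2))
    Fext <- matrix(0, nrow(lat$S), 2); Fext[ctr, 1] <- 0.2
    S <- lat$S0
    dtE <- 0.3 / max(lat$k_pt)
    for (iter in 1:30000) {
      F <- central_force(lat, S) + restorative_force(lat, S) + Fext
      S <- S + dtE * F
      if (max(abs(F)) < 1e-11) break
    }
    S[ctr, 1] - lat$S0[ctr, 1]
  }
  u <- vapply(c(1.1, 4.5, 11), disp_at, 1)
  expect_true(all(diff(u) < 0))                       # strictly decreasing
  expect_equal(u[1] / u[3], 11 / 1.1, tolerance = 1e-2)  # 1/E linearity
})

test_that("adhesion anchors carry unit barycentric weights and corner hits", {
  p <- epi_params()
  st <- make_fixture("single_cell", p = p)
  lat <- build_lattice(c(-15, 15, -15, 15), 2)
  fa <- attach_adhesions(st$tissue, lat, p)
  expect_true(all(abs(rowSums(fa$w) - 1) < 1e-9))
  expect_true(all(fa$w >= 0))
  # a vertex placed exactly on a lattice point gets weight 1 there
  cl <- epi_cell(sweep(regular_polygon(6, 40), 2, lat$S0[40, ], `+`), p = p)
  ts1 <- epi_tissue(list(cl))
  ts1$V[1, ] <- lat$S0[40, ]
  fa1 <- attach_adhesions(ts1, lat, p)
  expect_equal(max(fa1$w[1, ]), 1, tolerance = 1e-9)
  # outside the lattice: error naming the vertex
  clo <- epi_cell(sweep(regular_polygon(6, 40), 2, c(100, 0), `+`), p = p)
  expect_error(attach_adhesions(epi_tissue(list(clo)), lat, p), "outside")
})

test_that("adhesion strength scales with local stiffness: 11 vs 1.1 kPa
           force ratio is 2 for the same slip", {
  p <- epi_params()
  st <- make_fixture("single_cell", p = p)
  pull <- function(E) {
    lat <- build_lattice(c(-15, 15, -15, 15), 2, E = E)
    fa <- attach_adhesions(st$tissue, lat, p)
    ts <- st$tissue
    V <- ts$V; V[, 1] <- V[, 1] + 1              # 1 um slip everywhere
    af <- adhesion_forces(fa, ts, lat, V = V)
    sum(sqrt(rowSums(af$on_vertices^2)))
  }
  expect_equal(pull(11) / pull(1.1), 1.0 / 0.5, tolerance = 1e-9)
})

test_that("adhesion springs are Hookean with exact lattice reactions, and
           rupture is irreversible", {
  p <- epi_params()
  st <- make_fixture("single_cell", p = p)
  lat <- build_lattice(c(-15, 15, -15, 15), 2)
  fa <- attach_adhesions(st$tissue, lat, p)
  ts <- st$tissue
  af0 <- adhesion_forces(fa, ts, lat)
  expect_equal(max(abs(af0$on_vertices)), 0)      # vertex at anchor
  V <- ts$V; V[1, ] <- V[1, ] + c(1, 0)
  af <- adhesion_forces(fa, ts, lat, V = V)
  expect_equal(sqrt(sum(af$on_vertices[1, ]^2)), fa$strength[1],
               tolerance = 1e-12)
  expect_equal(colSums(af$on_points), -colSums(af$on_vertices),
               tolerance = 1e-9)
  # stretch past the threshold: force drops to zero and stays zero
  V2 <- ts$V; V2[1, ] <- V2[1, ] + c(p$d_fa_rupture + 1, 0)
  # rupture requires the threshold on two consecutive checks
  cr <- check_ruptures(fa, ts, lat, p, V = V2)
  expect_false(cr$fa$ruptured[1])
  cr <- check_ruptures(cr$fa, ts, lat, p, V = V2)
  expect_true(cr$fa$ruptured[1])
  af2 <- adhesion_forces(cr$fa, ts, lat, V = ts$V)   # back at the anchor
  expect_equal(max(abs(af2$on_vertices[1, ])), 0)
  cr2 <- check_ruptures(cr$fa, ts, lat, p, V = ts$V)
  expect_true(cr2$fa$ruptured[1])                    # monotone rupture set
})

test_that("total substrate force is the exact component sum and balances
           the focal-adhesion pull on cells", {
  p <- epi_params()
  st <- make_fixture("single_cell", p = p)
  lat <- build_lattice(c(-15, 15, -15, 15), 2)
  fa <- attach_adhesions(st$tissue, lat, p)
  expect_equal(max(abs(total_substrate_force(lat)$tot)), 0)
  V <- st$tissue$V; V[, 2] <- V[, 2] + 0.7
  ts <- st$tissue; ts$V <- V
  tot <- total_substrate_force(lat, fa, ts)
  expect_identical(tot$tot, tot$cent + tot$rep + tot$rest + tot$fa)
  af <- adhesion_forces(fa, ts, lat)
  expect_equal(colSums(tot$fa), -colSums(af$on_vertices), tolerance = 1e-9)
})
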