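# The eight per-vertex force laws: energy-gradient oracles, action-reaction
# bookkeeping, and the superposition contract of the total.

test_that("cortical tension cancels on a straight membrane run", {
  p <- epi_params()
  # an 8-gon with three collinear vertices on one side
  V <- rbind(c(0, 0), c(4, 0), c(8, 0), c(10, 4), c(8, 8), c(4, 9),
             c(0, 8), c(-2, 4))
  cl <- epi_cell(V, p = p)
  cl$P0 <- polygon_perimeter(V)       # uniform tension = k_cort_const
  F <- cortical_force(cl, p)
  # middle vertex of the collinear run: tangents oppose exactly
  expect_lt(sqrt(sum(F[2, ]^2)), 1e-12 * p$k_cort_const)
})

test_that("cortical, area and membrane forces match the finite-difference
           energy gradient on an off-rest cell", {
  p <- epi_params()
  cl <- wobbly_cell(p)
  ts <- epi_tissue(list(cl))
  F <- cortical_force(cl, p) + area_force(cl, p) + membrane_force(cl, p)
  Fg <- fd_gradient(cell_energy_fn(cl, p), cl$V)
  expect_rel_equal(F, Fg, 1e-6)
})

test_that("regular hexagon under perimeter elasticity matches the energy
           gradient to 1e-6 relative", {
  p <- epi_params(k_cort_perim = 0.2)
  cl <- epi_cell(regular_polygon(6, 90), A0 = 90, p = p)
  cl$P0 <- 0.9 * polygon_perimeter(cl$V)     # P > P0
  F <- cortical_force(cl, p)
  en <- function(V) {
    n <- nrow(V); j <- c(2:n, 1)
    P <- sum(sqrt(rowSums((V[j, ] - V)^2)))
    p$k_cort_const * P + p$k_cort_perim / 2 * (P - cl$P0)^2
  }
  expect_rel_equal(F, fd_gradient(en, cl$V), 1e-6)
})

test_that("concave vertices get an outward push, convex do not", {
  p <- epi_params()
  # arrowhead: vertex 4 lies inside the triangle of its neighbors
  V <- rbind(c(0, 0), c(10, 0), c(10, 10), c(5, 3), c(0, 10))
  cl <- epi_cell(V, p = p)
  cl$P0 <- polygon_perimeter(V)
  F <- cortical_force(cl, p)
  ctr <- polygon_centroid(V)
  # compare against the same cell without the concave term: pure tension
  n <- nrow(V); j <- c(2:n, 1)
  D <- V[j, ] - V; len <- sqrt(rowSums(D^2)); U <- D / len
  prv <- c(n, 1:(n - 1))
  Ften <- U * p$k_cort_const - U[prv, ] * p$k_cort_const
  extra <- F[4, ] - Ften[4, ]
  # the extra component points away from the cell interior: a small step
  # along it must leave the polygon
  stepped <- V[4, ] + 0.05 * extra / sqrt(sum(extra^2))
  expect_false(points_in_polygon(matrix(stepped, 1, 2), V))
  expect_gt(sqrt(sum(extra^2)), 0.01)
  # convex vertices carry no extra component
  expect_rel_equal(F[1, ], Ften[1, ], 1e-9)
})

test_that("area force is zero at target area and sums to zero on any polygon", {
  p <- epi_params()
  cl <- epi_cell(regular_polygon(7, 80), A0 = polygon_area(regular_polygon(7, 80)),
                 p = p)
  expect_equal(max(abs(area_force(cl, p))), 0)
  cl2 <- wobbly_cell(p)
  expect_lt(max(abs(colSums(area_force(cl2, p)))), 1e-10)
})

test_that("unit square with A0 = 2A expands outward, matching the energy
           gradient", {
  p <- epi_params()
  V <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  cl <- epi_cell(V, A0 = 2, p = p)
  F <- area_force(cl, p)
  en <- function(Vm) {
    n <- nrow(Vm); j <- c(2:n, 1)
    A <- 0.5 * sum(Vm[, 1] * Vm[j, 2] - Vm[j, 1] * Vm[, 2])
    p$k_area / (2 * cl$A0) * (A - cl$A0)^2
  }
  expect_rel_equal(F, fd_gradient(en, V), 1e-6)
  ctr <- c(0.5, 0.5)
  mags <- sqrt(rowSums(F^2))
  expect_rel_equal(mags, rep(mags[1], 4), 1e-9)   # four equal magnitudes
  expect_true(all(rowSums(F * sweep(V, 2, ctr)) > 0))  # outward
})

test_that("junction springs are zero-rest-length, equal-opposite, linear", {
  p <- epi_params()
  expect_equal(junction_force(rbind(c(1, 2), c(1, 2)), p),
               matrix(0, 2, 2))
  d <- 1.3
  F <- junction_force(rbind(c(d, 0), c(0, 0)), p)
  expect_equal(F[1, ], c(-p$k_junc * d, 0))
  expect_equal(F[1, ] + F[2, ], c(0, 0))
  F2 <- junction_force(rbind(c(2 * d, 0), c(0, 0)), p)
  expect_equal(F2[1, ], 2 * F[1, ])
})

test_that("membrane springs are strain-normalized and at rest give zero", {
  p <- epi_params()
  cl <- epi_cell(regular_polygon(8, 90), p = p)
  expect_equal(max(abs(membrane_force(cl, p))), 0)
  # stretch one segment by moving a vertex outward along it
  cl2 <- cl
  seg_dir <- (cl$V[2, ] - cl$V[1, ]) / sqrt(sum((cl$V[2, ] - cl$V[1, ])^2))
  delta <- 0.4
  cl2$V[2, ] <- cl$V[2, ] + delta * seg_dir
  F <- membrane_force(cl2, p)
  en <- function(Vm) {
    n <- nrow(Vm); j <- c(2:n, 1)
    len <- sqrt(rowSums((Vm[j, ] - Vm)^2))
    sum(p$k_mem / 2 * (len - cl$l0)^2 / cl$l0)
  }
  expect_rel_equal(F, fd_gradient(en, cl2$V), 1e-6)
})

test_that("membrane rest lengths are mandatory", {
  p <- epi_params()
  cl <- epi_cell(regular_polygon(6, 90), p = p)
  cl$l0[2] <- NA
  ts <- epi_tissue(list(cl))
  expect_error(force_membrane(ts, ts$V, p), "rest length")
})

test_that("contact force is zero for disjoint cells and conserves momentum
           under penetration", {
  p <- epi_params()
  sq <- function(x0) epi_cell(rbind(c(x0, 0), c(x0 + 5, 0), c(x0 + 5, 5),
                                    c(x0, 5)), p = p)
  far <- epi_tissue(list(sq(0), sq(20)))
  expect_equal(max(abs(contact_force(far, p))), 0)
  # vertex of cell 2 penetrating 0.5 inside cell 1's right edge: the
  # linear branch of the C1-smoothed law gives k_cont * (pen - 0.05)
  c1 <- sq(0)
  c2 <- epi_cell(rbind(c(4.5, 2.5), c(9, 1), c(9, 4)), p = p)
  ts <- epi_tissue(list(c1, c2))
  F <- contact_force(ts, p)
  iv <- cell_indices(ts, 2)[1]
  expect_equal(F[iv, 1], 0.45 * p$k_cont, tolerance = 1e-9)  # outward = +x
  expect_equal(F[iv, 2], 0, tolerance = 1e-9)
  expect_lt(max(abs(colSums(F))), 1e-10)                    # zero momentum
  # shallow grazing contact follows the quadratic onset
  c3 <- epi_cell(rbind(c(4.92, 2.5), c(9, 1), c(9, 4)), p = p)
  ts3 <- epi_tissue(list(c1, c3))
  F3 <- contact_force(ts3, p)
  iv3 <- cell_indices(ts3, 2)[1]
  expect_equal(F3[iv3, 1], p$k_cont * 0.08^2 / 0.2, tolerance = 1e-9)
})

test_that("edge anchors restore boundary vertices only, by Hooke's law", {
  p <- epi_params()
  cl <- epi_cell(regular_polygon(6, 90), p = p)
  cl$bnd <- c(TRUE, rep(FALSE, 5))
  cl$V[1, ] <- cl$ref[1, ] + c(0, 2)
  cl$V[3, ] <- cl$V[3, ] + c(1, 1)        # interior vertex displaced
  F <- edge_force(cl, p)
  expect_equal(F[1, ], c(0, -2 * p$k_edge))
  expect_equal(F[3, ], c(0, 0))
})

test_that("division force: zero unless dividing; symmetric, internal", {
  p <- epi_params()
  cl <- epi_cell(regular_polygon(20, 90), p = p)
  expect_equal(max(abs(division_force(cl, p))), 0)
  cl$div <- list(dir = c(1, 0))
  F <- division_force(cl, p)
  # vertices nearest the cleavage plane (the x axis here) pinch hardest
  q <- cl$V[, 2] - mean(cl$V[, 2])
  s <- cl$V[, 1] - mean(cl$V[, 1])
  inward <- -sign(s) * F[, 1]
  expect_gt(stats::cor(abs(q), -inward), 0.5)  # force fades away from plane
  # mirror symmetry across the division axis (the x axis here): vertex i
  # of the regular 20-gon maps to 20 + 2 - i
  n <- 20
  mirror <- c(1, n:2)
  expect_lt(max(abs(F[, 1] - F[mirror, 1])), 1e-9)
  expect_lt(max(abs(F[, 2] + F[mirror, 2])), 1e-9)
  # internal: no net force, no net torque
  expect_lt(max(abs(colSums(F))), 1e-9)
  u <- sweep(cl$V, 2, colMeans(cl$V))
  expect_lt(abs(sum(u[, 1] * F[, 2] - u[, 2] * F[, 1])), 1e-9)
  expect_error(division_force(structure(modifyList(cl, list(div = list(dir = NULL))),
                                        class = "epi_cell"), p),
               "axis undefined")
})

test_that("total force is exact superposition and components toggle cleanly", {
  p <- epi_params()
  st <- make_fixture("two_cell", p = p)
  fb <- total_cell_force(st$tissue, p)
  sum8 <- fb$cort + fb$junc + fb$area + fb$div + fb$fa + fb$mem + fb$cont +
    fb$edge
  expect_identical(fb$tot, sum8)
  for (comp in c("cort", "junc", "area", "mem", "cont")) {
    solo <- total_cell_force(st$tissue, p, components = comp)
    expect_identical(solo$tot, fb[[comp]])
  }
})

test_that("an isolated rest-state cell carries zero total force", {
  p0 <- epi_params(k_cort_const = 0)      # prestress-free rest geometry
  cl <- epi_cell(regular_polygon(10, 90), A0 = polygon_area(
    regular_polygon(10, 90)), p = p0)
  cl$P0 <- polygon_perimeter(cl$V)       # rest geometry: P = P0, A = A0
  fb <- total_cell_force(epi_tissue(list(cl)), p0)
  expect_lt(max(abs(fb$tot)), 1e-12)
  # with prestress, the balanced fixture is the rest state
  st <- make_fixture("single_cell")
  expect_lt(max_residual_force(st), 1e-9)
})

test_that("force laws are homogeneous degree 1 in their constants", {
  base <- epi_params()
  dbl <- epi_params(k_cort_const = 2 * base$k_cort_const,
                    k_cort_perim = 2 * base$k_cort_perim,
                    k_area = 2 * base$k_area, k_mem = 2 * base$k_mem)
  cl <- wobbly_cell(base)
  expect_equal(2 * cortical_force(cl, base), cortical_force(cl, dbl))
  expect_equal(2 * area_force(cl, base), area_force(cl, dbl))
  expect_equal(2 * membrane_force(cl, base), membrane_force(cl, dbl))
})

test_that("cortical, area and membrane forces are translation invariant", {
  p <- epi_params()
  cl <- wobbly_cell(p)
  shift <- function(c0, v) { c0$V <- sweep(c0$V, 2, v, `+`); c0 }
  cl2 <- shift(cl, c(13.7, -8.2))
  expect_equal(cortical_force(cl, p), cortical_force(cl2, p), tolerance = 1e-9)
  expect_equal(area_force(cl, p), area_force(cl2, p), tolerance = 1e-9)
  expect_equal(membrane_force(cl, p), membrane_force(cl2, p), tolerance = 1e-9)
})

test_that("degenerate segments are reported with cell and vertex", {
  p <- epi_params()
  V <- regular_polygon(6, 90)
  V[2, ] <- V[1, ] + c(1e-12, 0)
  cl <- list(V = V, A0 = 90, l0 = rep(2, 6), P0 = 30, bnd = rep(FALSE, 6),
             ref = V, junc = rep(NA_integer_, 6), act = rep(1, 6),
             t_next_div = Inf, div = NULL)
  class(cl) <- "epi_cell"
  expect_error(cortical_force(cl, p), "degenerate or non-finite segment")
})
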