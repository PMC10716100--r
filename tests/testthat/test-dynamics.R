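# Time integration and structural remodeling.

# a 1-dof exponential test rig: a triangle whose vertices only feel the
# edge anchor spring, so each coordinate relaxes as x0 exp(-k t / eta)
exp_rig <- function(k = 2, eta = 0.5, x0 = 1.5) {
  p <- only_param("k_edge", k, base = list(eta = eta, dt_max = 10))
  cl <- epi_cell(regular_polygon(3, 50), p = p)
  cl$bnd <- rep(TRUE, 3)
  cl$V[1, 1] <- cl$ref[1, 1] + x0
  epi_state(epi_tissue(list(cl)), params = p)
}

test_that("zero total force leaves the state unchanged", {
  st <- make_fixture("single_cell")
  st2 <- step(st, 0.01)
  expect_equal(st2$tissue$V, st$tissue$V, tolerance = 1e-12)
  expect_error(step(st, -0.1), "positive")
})

test_that("single-spring relaxation matches the closed-form exponential to
           1e-6 with RK4", {
  k <- 2; eta <- 0.5; x0 <- 1.5
  st <- exp_rig(k, eta, x0)
  st$order <- 4L
  dt <- 0.01 * eta / k
  nsteps <- round(3 * eta / k / dt)
  for (i in seq_len(nsteps)) st <- step(st, dt)
  x_num <- st$tissue$V[1, 1] - st$tissue$ref[1, 1]
  x_exact <- x0 * exp(-k * st$time / eta)
  expect_lt(abs(x_num - x_exact) / x0, 1e-6)
})

test_that("halving dt reduces the one-step RK4 error about 2^5-fold", {
  k <- 2; eta <- 0.5; x0 <- 1.5
  one_step_err <- function(dt) {
    st <- exp_rig(k, eta, x0)
    st$order <- 4L
    st <- step(st, dt)
    abs((st$tissue$V[1, 1] - st$tissue$ref[1, 1]) - x0 * exp(-k * dt / eta))
  }
  dt <- 0.3 * eta / k
  ratio <- one_step_err(dt) / one_step_err(dt / 2)
  expect_gt(ratio, 2^5 / 2)
  expect_lt(ratio, 2^5 * 2)
})

test_that("RK2 is second order on the same rig", {
  k <- 2; eta <- 0.5; x0 <- 1.5
  one_step_err <- function(dt) {
    st <- exp_rig(k, eta, x0)
    st$order <- 2L
    st <- step(st, dt, order = 2)
    abs((st$tissue$V[1, 1] - st$tissue$ref[1, 1]) - x0 * exp(-k * dt / eta))
  }
  dt <- 0.3 * eta / k
  ratio <- one_step_err(dt) / one_step_err(dt / 2)
  expect_gt(ratio, 2^3 / 2)
  expect_lt(ratio, 2^3 * 2)
})

test_that("adapt_dt follows the halve/grow/clamp rules", {
  p <- epi_params(err_tol = 1e-2, dt_min = 1e-6, dt_max = 1)
  expect_equal(adapt_dt(0.1, 0, p), 0.15)              # err = 0: grow 1.5x
  expect_equal(adapt_dt(0.1, 10 * p$err_tol, p), 0.05) # err high: halve
  expect_equal(adapt_dt(0.1, p$err_tol / 2, p), 0.1)   # in band: hold
  expect_equal(adapt_dt(0.9, 0, p), 1)                 # clamped at dt_max
  expect_error(adapt_dt(1.5e-6, 1, p), "dt_min")
})

test_that("adaptive stepping keeps the accepted error at or below tolerance
           on a stiff adhesion-spring rig", {
  p <- only_param("k_edge", 50, base = list(eta = 0.5, err_tol = 1e-4,
                                            dt_max = 0.5, dt_init = 0.2))
  cl <- epi_cell(regular_polygon(3, 50), p = p)
  cl$bnd <- rep(TRUE, 3)
  cl$V[1, 1] <- cl$ref[1, 1] + 2
  st <- epi_state(epi_tissue(list(cl)), params = p, order = 4L)
  st <- advance(st, 0.2)
  # compare against a fine-dt reference trajectory
  stf <- epi_state(epi_tissue(list(cl)), params = p, order = 4L)
  for (i in 1:2000) stf <- step(stf, 1e-4)
  expect_lt(abs(st$tissue$V[1, 1] - stf$tissue$V[1, 1]), 5 * p$err_tol)
})

test_that("vertex remodeling splits long and merges short segments and
           reaches a fixed point", {
  p <- epi_params(l_min = 1, l_max = 3)
  # a rectangle with one long side (6 um) and a short edge pair
  V <- rbind(c(0, 0), c(6, 0), c(6, 2), c(5.2, 2.05), c(0, 2))
  cl <- epi_cell(V, p = p)
  st <- epi_state(epi_tissue(list(cl)), params = p, remodel = TRUE)
  r1 <- episheet:::remodel_vertices_impl(st, p)
  expect_true(r1$changed)
  ts <- r1$state$tissue
  D <- ts$V[ts$nxt, ] - ts$V
  len1 <- sqrt(rowSums(D^2))
  expect_true(all(len1 <= p$l_max + 1e-9))
  # area preserved up to the merge shifts (midpoint insertion is exact)
  expect_lt(abs(tissue_areas(ts)[1] - polygon_area(V)) / polygon_area(V),
            0.1)
  # repeated passes reach a fixed point
  r2 <- episheet:::remodel_vertices_impl(r1$state, p)
  r3 <- episheet:::remodel_vertices_impl(r2$state, p)
  expect_false(r3$changed)
})

test_that("pure midpoint insertion preserves the polygon area exactly", {
  p <- epi_params(l_min = 0.1, l_max = 3)
  V <- rbind(c(0, 0), c(6, 0), c(6, 4), c(0, 4))
  cl <- epi_cell(V, p = p)
  st <- epi_state(epi_tissue(list(cl)), params = p, remodel = TRUE)
  r <- episheet:::remodel_vertices_impl(st, p)
  expect_lt(abs(tissue_areas(r$state$tissue)[1] - polygon_area(V)), 1e-9)
})

test_that("no remodeling happens when all segments are in bounds", {
  p <- epi_params()
  st <- make_fixture("single_cell", p = p)
  r <- episheet:::remodel_vertices_impl(st, p)
  expect_false(r$changed)
})

test_that("junction remodeling pairs close free vertices reciprocally and
           dissolves stretched links", {
  p <- epi_params(d_junc_pair = 0.8, d_junc_unpair = 1.6)
  sq1 <- epi_cell(rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5)), p = p)
  sq2 <- epi_cell(rbind(c(5.3, 0), c(10, 0), c(10, 5), c(5.3, 5)), p = p)
  ts <- epi_tissue(list(sq1, sq2))
  ts2 <- episheet:::remodel_junctions_ts(ts, p)
  has <- which(!is.na(ts2$junc))
  expect_gt(length(has), 0)
  expect_true(all(ts2$junc[ts2$junc[has]] == has))     # reciprocal
  # far cells never pair
  sq3 <- epi_cell(rbind(c(20, 0), c(25, 0), c(25, 5), c(20, 5)), p = p)
  ts3 <- episheet:::remodel_junctions_ts(epi_tissue(list(sq1, sq3)), p)
  expect_true(all(is.na(ts3$junc)))
  # stretched links dissolve
  ts4 <- ts2
  ts4$V[cell_indices(ts4, 2), 1] <- ts4$V[cell_indices(ts4, 2), 1] + 10
  ts4 <- episheet:::remodel_junctions_ts(ts4, p)
  expect_true(all(is.na(ts4$junc)))
})

test_that("junction pairing is order-independent on a mirrored fixture", {
  p <- epi_params()
  sq1 <- epi_cell(rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5)), p = p)
  sq2 <- epi_cell(rbind(c(5.3, 0), c(10.3, 0), c(10.3, 5), c(5.3, 5)), p = p)
  tsA <- episheet:::remodel_junctions_ts(epi_tissue(list(sq1, sq2)), p)
  tsB <- episheet:::remodel_junctions_ts(epi_tissue(list(sq2, sq1)), p)
  pairsA <- cbind(seq_len(tsA$n), tsA$junc)
  # map B's indices back to A's labelling (cells swapped block-wise)
  nb <- 4L
  mapB <- c(nb + 1:nb, 1:nb)
  juncB_in_A <- rep(NA_integer_, tsB$n)
  juncB_in_A[mapB] <- ifelse(is.na(tsB$junc), NA, mapB[tsB$junc])
  expect_equal(tsA$junc, juncB_in_A)
})

test_that("division conserves area, splits a symmetric hexagon into
           congruent daughters, and draws sane clocks", {
  p <- epi_params()
  set.seed(42)
  cl <- epi_cell(regular_polygon(12, 90), p = p)
  st <- epi_state(epi_tissue(list(cl)), params = p, growth = TRUE)
  st$tissue$div[[1]] <- list(dir = c(0, 1), t_end = 0)
  A_parent <- tissue_areas(st$tissue)[1]
  st2 <- divide_cell(st, 1)
  expect_equal(st2$tissue$ncell, 2L)
  A_d <- tissue_areas(st2$tissue)
  expect_lt(abs(sum(A_d) - A_parent) / A_parent, 1e-6)
  expect_lt(abs(A_d[1] - A_d[2]) / A_parent, 1e-9)     # symmetric split
  # interval draws: sample statistics near the configured clock
  set.seed(7)
  draws <- replicate(100, episheet:::draw_T_div(p))
  se <- p$T_div_sd / sqrt(100)
  expect_lt(abs(mean(draws) - p$T_div_mean), 3 * se + 0.2)
})

test_that("with remodeling disabled the topology is bit-stable under
           stepping", {
  st <- make_fixture("two_cell")
  st$remodel <- FALSE
  before <- list(st$tissue$n, st$tissue$junc, st$tissue$clen)
  st2 <- advance(st, 0.05)
  expect_identical(list(st2$tissue$n, st2$tissue$junc, st2$tissue$clen),
                   before)
})

test_that("the relaxed fixture is a fixed point of the dynamics", {
  st <- make_fixture("single_cell")
  expect_lt(max_residual_force(st), 1e-9)
  st2 <- advance(st, 1)
  expect_lt(max_residual_force(st2), 1e-9)
})

test_that("identical seeds give bit-identical grown tissues", {
  a <- grow_epithelium(3, 6)
  b <- grow_epithelium(3, 6)
  expect_identical(a$tissue$V, b$tissue$V)
  expect_identical(a$tissue$junc, b$tissue$junc)
  c2 <- grow_epithelium(4, 6)
  expect_false(isTRUE(all.equal(dim(a$tissue$V), dim(c2$tissue$V))) &&
                 isTRUE(all.equal(a$tissue$V, c2$tissue$V)))
})

test_that("non-finite forces abort with the offending entity named", {
  st <- make_fixture("single_cell")
  st$tissue$V[2, 1] <- NaN
  expect_error(step(st, 0.01), "vertex")
})
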