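# Shared oracles and small builders for the test suite.

# Central finite-difference gradient of a scalar energy over flattened
# vertex coordinates; the independent check for every energy-derived force.
fd_gradient <- function(energy, V, h = 1e-5) {
  x0 <- as.vector(V)
  g <- numeric(length(x0))
  for (i in seq_along(x0)) {
    e <- numeric(length(x0)); e[i] <- h
    g[i] <- (energy(matrix(x0 + e, ncol = 2)) -
               energy(matrix(x0 - e, ncol = 2))) / (2 * h)
  }
  matrix(-g, ncol = 2)
}

# Total mechanical energy of an isolated cell written from first
# principles (independent of the force implementations).
cell_energy_fn <- function(cell, p) {
  function(V) {
    n <- nrow(V)
    j <- c(2:n, 1)
    len <- sqrt(rowSums((V[j, , drop = FALSE] - V)^2))
    P <- sum(len)
    A <- 0.5 * sum(V[, 1] * V[j, 2] - V[j, 1] * V[, 2])
    p$k_cort_const * P + p$k_cort_perim / 2 * (P - cell$P0)^2 +
      p$k_area / (2 * cell$A0) * (A - cell$A0)^2 +
      sum(p$k_mem / 2 * (len - cell$l0)^2 / cell$l0)
  }
}

# a slightly irregular convex test cell (deterministic)
wobbly_cell <- function(p = epi_params(), n = 9, scale = 1.07) {
  V <- regular_polygon(n, p$A0_mean)
  th <- 2 * pi * (0:(n - 1)) / n
  V <- V * (1 + 0.08 * cos(3 * th))
  cl <- epi_cell(V, A0 = p$A0_mean, p = p)
  cl$V <- cl$V * scale              # off-rest so every force is non-trivial
  cl
}

# params with a single non-zero constant, for component isolation
only_param <- function(name, value, base = list()) {
  zeros <- list(k_cort_const = 0, k_cort_perim = 0, k_junc = 0, k_area = 0,
                k_mem = 0, k_cont = 0, k_edge = 0, k_div = 0)
  zeros[[name]] <- value
  do.call(epi_params, utils::modifyList(zeros, base))
}

expect_rel_equal <- function(actual, expected, tol) {
  scale <- max(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
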