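# Deterministic small states for tests and examples.

#' Construct deterministic test fixtures
#'
#' * `single_cell`: one regular polygon in exact mechanical rest: the rest
#'   perimeter equals the current perimeter and the target area is chosen so
#'   the pressure balances the constant cortical tension, so every vertex
#'   carries zero net force at creation.
#' * `two_cell`: two square cells facing across a small gap with their
#'   facing vertices junction-linked (reciprocal links).
#' * `ring`: a ring of hexagonal cells around the origin, junction-paired
#'   where vertices face each other.
#' * `mini_epithelium`: a grown-and-relaxed tissue of `n_cells` cells
#'   (seeded growth; identical calls give identical states).
#'
#' @param kind fixture kind.
#' @param p an [epi_params()].
#' @param n_vertices vertices of the single cell.
#' @param n_cells cells in the ring / mini epithelium.
#' @param seed seed for `mini_epithelium`.
#' @return an [epi_state()].
#' @export
make_fixture <- function(kind = c("single_cell", "two_cell", "ring",
                                  "mini_epithelium"),
                         p = epi_params(), n_vertices = 12, n_cells = 12,
                         seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    single_cell = fixture_single_cell(p, n_vertices),
    two_cell = fixture_two_cell(p),
    ring = fixture_ring(p, n_cells),
    mini_epithelium = grow_epithelium(seed, n_cells)
  )
}

# Exact rest state of an isolated regular n-gon: with P0 = P the cortical
# tension is k_cort_const; the pressure k_area (A0 - A)/A0 balances it when
# A0 = A / (1 - T/(R cos(pi/n) k_area)).
fixture_single_cell <- function(p, n = 12) {
  A <- p$A0_mean
  V <- regular_polygon(n, A)
  R <- sqrt(sum(V[1, ]^2))
  T0 <- p$k_cort_const
  press <- T0 / (R * cos(pi / n))
  if (press >= p$k_area)
    stop("fixture_single_cell(): cortical prestress exceeds pressure stiffness")
  A0 <- A / (1 - press / p$k_area)
  cl <- epi_cell(V, A0 = A0, p = p)
  cl$P0 <- polygon_perimeter(V)
  epi_state(epi_tissue(list(cl)), params = p)
}

fixture_two_cell <- function(p, gap = 0.4) {
  side <- sqrt(p$A0_mean)
  nseg <- 4L
  sq <- function(x0) {
    s <- seq(0, side, length.out = nseg + 1L)
    up <- s[-length(s)]; down <- rev(s)[-length(s)]
    rbind(
      cbind(x0 + up, 0),
      cbind(x0 + side, up),
      cbind(x0 + down, side),
      cbind(x0, down)
    )
  }
  c1 <- epi_cell(sq(0), p = p)
  c2 <- epi_cell(sq(side + gap), p = p)
  ts <- epi_tissue(list(c1, c2))
  ts <- remodel_junctions_ts(ts, epi_params_with(p, d_junc_pair = gap * 1.5))
  epi_state(ts, params = p)
}

fixture_ring <- function(p, n_cells = 12) {
  A <- p$A0_mean
  # hexagon circumradius for area A
  Rhex <- sqrt(2 * A / (6 * sin(pi / 3)))
  Rring <- (2 * Rhex * cos(pi / 6) + 0.3) / (2 * sin(pi / n_cells))
  cells <- lapply(seq_len(n_cells), function(k) {
    th <- 2 * pi * (k - 1) / n_cells
    ctr <- Rring * c(cos(th), sin(th))
    V <- regular_polygon(6, A, center = c(0, 0))
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    epi_cell(sweep(V %*% t(rot), 2, ctr, `+`), p = p)
  })
  ts <- remodel_junctions_ts(epi_tissue(cells), p)
  epi_state(ts, params = p)
}

# params copy with overrides, preserving class
epi_params_with <- function(p, ...) {
  ov <- list(...)
  p[names(ov)] <- ov
  validate_params(p)
  structure(p, class = "epi_params")
}
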