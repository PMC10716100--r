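# The per-vertex force laws of the cell model. Each law has a flat kernel
# (`force_*`) operating on the whole tissue at once (n x 2 in, n x 2 out)
# plus a small spec-level wrapper for single cells. All laws are linear in
# their spring constants and, where derived from an energy, match its
# analytic gradient (tested against central finite differences).

# ---- shared segment quantities -------------------------------------------

seg_geometry <- function(ts, V) {
  D <- V[ts$nxt, , drop = FALSE] - V
  len <- sqrt(D[, 1]^2 + D[, 2]^2)
  bad <- !is.finite(len) | len < 1e-9
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("degenerate or non-finite segment: cell %d, segment starting at vertex %d",
                 ts$cell[i], i))
  }
  list(D = D, len = len, U = D / len)
}

# ---- cortical force -------------------------------------------------------

force_cortical <- function(ts, V, p, sg = seg_geometry(ts, V)) {
  P <- tissue_perimeters(ts, V)
  Tcell <- p$k_cort_const + p$k_cort_perim * (P - ts$P0)
  aseg <- 0.5 * (ts$act + ts$act[ts$nxt])        # activation along the segment
  Tseg <- Tcell[ts$cell] * aseg
  # tension of both incident segments pulls the vertex toward its neighbors
  F <- sg$U * Tseg - sg$U[ts$prv, , drop = FALSE] * Tseg[ts$prv]
  # concave vertices: the cortical link spanning the neighbors runs behind
  # the vertex and pushes it outwards; magnitude = tension x turning-angle
  # deficit, direction = outward normal (bisector pointing away from the
  # cell interior).
  Dp <- sg$D[ts$prv, , drop = FALSE]
  cr <- Dp[, 1] * sg$D[, 2] - Dp[, 2] * sg$D[, 1]
  concave <- cr < 0
  if (any(concave)) {
    i <- which(concave)
    dt <- sg$D[i, , drop = FALSE]
    dp <- Dp[i, , drop = FALSE]
    turn <- atan2(dp[, 1] * dt[, 2] - dp[, 2] * dt[, 1],
                  dp[, 1] * dt[, 1] + dp[, 2] * dt[, 2])
    u1 <- -dp / sg$len[ts$prv][i]                # unit toward previous vertex
    u2 <- dt / sg$len[i]                         # unit toward next vertex
    nb <- u1 + u2                                # outward at a concave vertex
    nn <- sqrt(nb[, 1]^2 + nb[, 2]^2)
    ok <- nn > 1e-12
    Tv <- 0.5 * (Tseg[i] + Tseg[ts$prv][i])
    push <- (Tv * (-turn) / pmax(nn, 1e-12)) * nb
    push[!ok, ] <- 0
    F[i, ] <- F[i, ] + push
  }
  F
}

#' Cortical actomyosin force of one cell
#'
#' Constant line tension plus linear perimeter elasticity: every membrane
#' segment carries tension `k_cort_const + k_cort_perim * (P - P0)` pulling
#' its end vertices toward each other, and concave vertices receive an extra
#' outward push from the cortical link spanning their neighbors.
#'
#' @param cell an [epi_cell()].
#' @param p an [epi_params()].
#' @return n x 2 matrix of per-vertex forces (AU).
#' @export
cortical_force <- function(cell, p = epi_params()) {
  ts <- epi_tissue(list(cell))
  force_cortical(ts, ts$V, p)
}

# ---- area (pressure) force ------------------------------------------------

force_area <- function(ts, V, p) {
  A <- tissue_areas(ts, V)
  # trial positions inside a Runge-Kutta stage may transiently pinch a
  # polygon; the pressure saturates (strongly expansive) instead of
  # failing, so the dynamics can push it back open
  A <- pmax(A, 0.02 * ts$A0)
  coef <- (p$k_area * (ts$A0 - A) / ts$A0)[ts$cell]
  # gradient of the signed area: dA/dr_i = 0.5 * (y_{i+1}-y_{i-1}, x_{i-1}-x_{i+1})
  gx <- 0.5 * (V[ts$nxt, 2] - V[ts$prv, 2])
  gy <- 0.5 * (V[ts$prv, 1] - V[ts$nxt, 1])
  cbind(coef * gx, coef * gy)
}

#' Internal pressure (area) force of one cell
#'
#' Pressure proportional to the relative area deficit, `k_area * (A0 - A) /
#' A0`, applied along the area gradient (outward normals weighted by the
#' adjacent segment lengths): expansive when A < A0, compressive when A > A0.
#' The vector sum over a closed polygon is exactly zero.
#'
#' @inheritParams cortical_force
#' @return n x 2 matrix of per-vertex forces (AU).
#' @export
area_force <- function(cell, p = epi_params()) {
  ts <- epi_tissue(list(cell))
  if (tissue_areas(ts)[1] <= 0)
    stop("invalid polygon: non-positive area")
  force_area(ts, ts$V, p)
}

# ---- membrane force -------------------------------------------------------

force_membrane <- function(ts, V, p, sg = seg_geometry(ts, V)) {
  if (any(!is.finite(ts$l0)) || any(ts$l0 <= 0))
    stop("configuration error: missing or non-positive membrane rest length")
  f <- p$k_mem * (sg$len - ts$l0) / ts$l0       # strain-normalized tension
  sg$U * f - sg$U[ts$prv, , drop = FALSE] * f[ts$prv]
}

#' Membrane elasticity force of one cell
#'
#' Each membrane segment is a linear spring about its rest length with
#' strain normalization (tension `k_mem * (l - l0) / l0`), so inserting or
#' removing vertices does not change the net membrane stiffness of a region.
#'
#' @inheritParams cortical_force
#' @return n x 2 matrix of per-vertex forces (AU).
#' @export
membrane_force <- function(cell, p = epi_params()) {
  ts <- epi_tissue(list(cell))
  force_membrane(ts, ts$V, p)
}

# ---- junction force -------------------------------------------------------

force_junction <- function(ts, V, p) {
  F <- matrix(0, ts$n, 2)
  has <- which(!is.na(ts$junc))
  if (length(has)) {
    jj <- ts$junc[has]
    if (any(ts$junc[jj] != has))
      stop("consistency error: dangling (non-reciprocal) junction link")
    F[has, ] <- -p$k_junc * (V[has, , drop = FALSE] - V[jj, , drop = FALSE])
  }
  F
}

#' Cell-cell junction spring force on a vertex pair
#'
#' A linear spring of constant `k_junc` and zero rest length between the two
#' paired vertices of neighboring cells; the two forces are equal and
#' opposite.
#'
#' @param pair 2 x 2 matrix: rows are the positions of the linked vertices.
#' @param p an [epi_params()].
#' @return 2 x 2 matrix of forces, one row per vertex.
#' @export
junction_force <- function(pair, p = epi_params()) {
  stopifnot(is.matrix(pair), nrow(pair) == 2, ncol(pair) == 2)
  d <- pair[1, ] - pair[2, ]
  rbind(-p$k_junc * d, p$k_junc * d)
}

# ---- edge force -----------------------------------------------------------

force_edge <- function(ts, V, p) {
  F <- matrix(0, ts$n, 2)
  b <- which(ts$bnd)
  if (length(b))
    F[b, ] <- -p$k_edge * (V[b, , drop = FALSE] - ts$ref[b, , drop = FALSE])
  F
}

#' Epithelium-edge anchor force of one cell
#'
#' Boundary-flagged vertices are tied by a linear spring of constant
#' `k_edge` to their reference (initial) positions, standing in for the
#' continuity of the epithelium outside the simulated area. Interior
#' vertices receive zero.
#'
#' @inheritParams cortical_force
#' @return n x 2 matrix of per-vertex forces (AU).
#' @export
edge_force <- function(cell, p = epi_params()) {
  ts <- epi_tissue(list(cell))
  force_edge(ts, ts$V, p)
}

# ---- division (furrow) force ---------------------------------------------

force_division <- function(ts, V, p) {
  F <- matrix(0, ts$n, 2)
  active <- which(vapply(ts$div, function(d) !is.null(d), TRUE))
  for (ci in active) {
    idx <- cell_indices(ts, ci)
    F[idx, ] <- division_furrow_field(V[idx, , drop = FALSE],
                                      ts$div[[ci]]$dir, ts$A0[ci], p)
  }
  F
}

# Constriction field for one dividing cell: the contractile ring lies along
# the cleavage line (centroid + short principal axis `sdir`); membrane
# regions nearest that plane are pulled toward it, pinching the waist. The
# raw field is then projected free of net force and net torque so the furrow
# is strictly internal.
division_furrow_field <- function(V, sdir, A0, p) {
  ctr <- polygon_centroid(V)
  u <- sweep(V, 2, ctr)
  ldir <- c(-sdir[2], sdir[1])                   # long axis (daughter axis)
  s <- u %*% sdir                                # coordinate along cleavage line
  q <- u %*% ldir                                # distance from cleavage plane
  sigma <- sqrt(A0) / 4
  w <- exp(-q^2 / (2 * sigma^2))
  mag <- -p$k_div * w * tanh(s / 1.0)
  F <- cbind(mag * sdir[1], mag * sdir[2])
  # remove rigid-body components (internal force: zero net force and torque)
  F <- sweep(F, 2, colMeans(F))
  um <- sweep(V, 2, colMeans(V))
  tau <- sum(um[, 1] * F[, 2] - um[, 2] * F[, 1])
  I0 <- sum(um^2)
  if (I0 > 0) F <- F - (tau / I0) * cbind(-um[, 2], um[, 1])
  F
}

#' Division-furrow constriction force of one cell
#'
#' Zero unless the cell is in a division state. For a dividing cell the
#' constriction pulls the membrane regions nearest the cleavage plane
#' (through the centroid along the short principal axis) toward that plane,
#' producing a furrow; the field carries no net force or torque.
#'
#' @inheritParams cortical_force
#' @return n x 2 matrix of per-vertex forces (AU).
#' @export
division_force <- function(cell, p = epi_params()) {
  if (is.null(cell$div)) return(matrix(0, nrow(cell$V), 2))
  if (is.null(cell$div$dir)) stop("state error: division axis undefined")
  division_furrow_field(cell$V, cell$div$dir, cell$A0, p)
}

# ---- contact force --------------------------------------------------------

# Broad phase: candidate (vertex, foreign segment) pairs within `margin` um.
# Cached by the integrator and refreshed between accepted steps.
contact_candidates <- function(ts, V, margin = 2.4) {
  nc <- ts$ncell
  if (nc < 2) return(NULL)
  # cell bounding boxes (grouped min/max over the flat arrays)
  g <- ts$cell
  lox <- tapply(V[, 1], g, min); hix <- tapply(V[, 1], g, max)
  loy <- tapply(V[, 2], g, min); hiy <- tapply(V[, 2], g, max)
  # all ordered pairs of cells with overlapping expanded boxes, vectorized
  OX <- outer(lox, hix, function(a, b) a <= b + margin) &
        outer(hix, lox, function(a, b) a + margin >= b)
  OY <- outer(loy, hiy, function(a, b) a <= b + margin) &
        outer(hiy, loy, function(a, b) a + margin >= b)
  ov <- which(OX & OY, arr.ind = TRUE)
  ov <- ov[ov[, 1] != ov[, 2], , drop = FALSE]
  if (!nrow(ov)) return(NULL)
  # collect all (vertex of a, segment of b) combos, then one vectorized
  # point-segment distance pass over the stacked combos
  vs_l <- vector("list", nrow(ov)); ss_l <- vector("list", nrow(ov))
  for (pk in seq_len(nrow(ov))) {
    a <- ov[pk, 1]; b <- ov[pk, 2]
    ia <- cell_indices(ts, a); ib <- cell_indices(ts, b)
    inb <- V[ia, 1] >= lox[b] - margin & V[ia, 1] <= hix[b] + margin &
           V[ia, 2] >= loy[b] - margin & V[ia, 2] <= hiy[b] + margin
    if (!any(inb)) next
    va <- ia[inb]
    vs_l[[pk]] <- rep(va, times = length(ib))
    ss_l[[pk]] <- rep(ib, each = length(va))
  }
  vv <- unlist(vs_l, use.names = FALSE)
  sg <- unlist(ss_l, use.names = FALSE)
  if (!length(vv)) return(NULL)
  ax <- V[sg, 1]; ay <- V[sg, 2]
  abx <- V[ts$nxt[sg], 1] - ax; aby <- V[ts$nxt[sg], 2] - ay
  dxa <- V[vv, 1] - ax; dya <- V[vv, 2] - ay
  tt <- (dxa * abx + dya * aby) / (abx^2 + aby^2)
  tt[tt < 0] <- 0; tt[tt > 1] <- 1
  ex <- dxa - tt * abx; ey <- dya - tt * aby
  hit <- ex * ex + ey * ey < margin^2
  vs <- vv[hit]; ss <- sg[hit]
  if (!length(vs)) return(NULL)
  cbind(v = vs, s = ss)
}

force_contact <- function(ts, V, p, cand = NULL, depth_cap = 2.0) {
  F <- matrix(0, ts$n, 2)
  if (is.null(cand)) cand <- contact_candidates(ts, V)
  if (is.null(cand) || nrow(cand) == 0) return(F)
  v <- cand[, 1]; s <- cand[, 2]; s2 <- ts$nxt[s]
  A <- V[s, , drop = FALSE]; B <- V[s2, , drop = FALSE]
  ab <- B - A
  L <- sqrt(ab[, 1]^2 + ab[, 2]^2)
  t <- ((V[v, 1] - A[, 1]) * ab[, 1] + (V[v, 2] - A[, 2]) * ab[, 2]) / L^2
  inside_t <- t > -1e-9 & t < 1 + 1e-9
  t <- pmin(pmax(t, 0), 1)
  # outward normal of a CCW polygon segment points right of its direction
  nx <- ab[, 2] / L; ny <- -ab[, 1] / L
  pen <- -((V[v, 1] - A[, 1]) * nx + (V[v, 2] - A[, 2]) * ny)
  hit <- inside_t & pen > 0 & pen < depth_cap
  if (!any(hit)) return(F)
  v <- v[hit]; s <- s[hit]; s2 <- s2[hit]; t <- t[hit]
  # quadratic onset below pen_s keeps the force C1 at first touch, which
  # spares the step controller from chattering on grazing contacts
  pen_s <- 0.1
  ph <- pen[hit]
  fmag <- p$k_cont * ifelse(ph < pen_s, ph^2 / (2 * pen_s), ph - pen_s / 2)
  fx <- fmag * nx[hit]; fy <- fmag * ny[hit]
  # force on the penetrating vertex along the segment's outward normal;
  # reaction shared by the endpoints by projection weights (momentum-exact)
  ii <- c(v, s, s2)
  addx <- c(fx, -(1 - t) * fx, -t * fx)
  addy <- c(fy, -(1 - t) * fy, -t * fy)
  acc <- rowsum(cbind(addx, addy), ii, reorder = TRUE)
  rows <- sort(unique.default(ii))
  F[rows, ] <- F[rows, ] + acc
  F
}

#' Contact (anti-overlap) force between cells
#'
#' A vertex penetrating a foreign cell's membrane segment by depth `d`
#' receives `k_cont * d` along that segment's outward normal; the reaction
#' is distributed to the segment endpoints by projection weights, so every
#' contact event injects zero net momentum.
#'
#' @param tissue an [epi_tissue()] (or list of [epi_cell()] objects).
#' @param p an [epi_params()].
#' @return n x 2 matrix of per-vertex forces over all tissue vertices.
#' @export
contact_force <- function(tissue, p = epi_params()) {
  if (!inherits(tissue, "epi_tissue")) tissue <- epi_tissue(tissue)
  force_contact(tissue, tissue$V, p)
}

# ---- total ---------------------------------------------------------------

CELL_FORCE_NAMES <- c("cort", "junc", "area", "div", "fa", "mem", "cont", "edge")

# Flat total with per-component breakdown. `fa_pull` is the precomputed
# focal-adhesion force on vertices (from adhesion_forces()), zero if absent.
force_cell_total <- function(ts, V, p, fa_pull = NULL, cand = NULL,
                             components = CELL_FORCE_NAMES) {
  sg <- seg_geometry(ts, V)
  z <- matrix(0, ts$n, 2)
  out <- list(
    cort = if ("cort" %in% components) force_cortical(ts, V, p, sg) else z,
    junc = if ("junc" %in% components) force_junction(ts, V, p) else z,
    area = if ("area" %in% components) force_area(ts, V, p) else z,
    div  = if ("div" %in% components) force_division(ts, V, p) else z,
    fa   = if ("fa" %in% components && !is.null(fa_pull)) fa_pull else z,
    mem  = if ("mem" %in% components) force_membrane(ts, V, p, sg) else z,
    cont = if ("cont" %in% components) force_contact(ts, V, p, cand) else z,
    edge = if ("edge" %in% components) force_edge(ts, V, p) else z
  )
  out$tot <- out$cort + out$junc + out$area + out$div + out$fa + out$mem +
    out$cont + out$edge
  class(out) <- "force_breakdown"
  out
}

#' Total force on every cell vertex, by component
#'
#' Pure superposition of the eight per-vertex force components (cortical,
#' junction, area, division, focal adhesion, membrane, contact, edge);
#' `tot` equals their sum to machine precision. Components can be toggled
#' off, which reproduces each law's standalone output bit-for-bit.
#'
#' @param tissue an [epi_tissue()] (or list of [epi_cell()]s).
#' @param p an [epi_params()].
#' @param lattice optional [build_lattice()] substrate.
#' @param fa optional [attach_adhesions()] adhesion set.
#' @param components character vector of components to evaluate.
#' @return a `force_breakdown`: list of n x 2 matrices `cort`, `junc`,
#'   `area`, `div`, `fa`, `mem`, `cont`, `edge` and their sum `tot`.
#' @export
total_cell_force <- function(tissue, p = epi_params(), lattice = NULL,
                             fa = NULL, components = CELL_FORCE_NAMES) {
  if (!inherits(tissue, "epi_tissue")) tissue <- epi_tissue(tissue)
  fa_pull <- NULL
  if (!is.null(fa) && !is.null(lattice))
    fa_pull <- adhesion_forces(fa, tissue, lattice)$on_vertices
  force_cell_total(tissue, tissue$V, p, fa_pull = fa_pull,
                   components = components)
}

#' @export
print.force_breakdown <- function(x, ...) {
  mx <- vapply(x[CELL_FORCE_NAMES], function(F) max(abs(F)), 1)
  cat("<force_breakdown> max |component| (AU):\n")
  cat(paste(sprintf("  %s: %.4g", names(mx), mx), collapse = "\n"), "\n")
  cat(sprintf("  tot: %.4g\n", max(abs(x$tot))))
  invisible(x)
}
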