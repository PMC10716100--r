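# Focal adhesions: rupturable springs between cell vertices and material
# points of the substrate lattice. The anchor is the vertex's position at
# attachment time expressed in barycentric coordinates of its containing
# lattice triangle, so the spring measures cell-versus-substrate slip and
# folds in the apico-basal elasticity of the cell.

#' Attach focal adhesions between a tissue and a substrate lattice
#'
#' Anchors every cell vertex at its current position inside its containing
#' lattice triangle (barycentric weights >= 0 summing to 1). The anchor
#' strength is `k_fa(E_local)` times half the summed length of the vertex's
#' two incident membrane segments, i.e. the membrane length the vertex
#' represents.
#'
#' @param tissue an [epi_tissue()].
#' @param lattice a [build_lattice()] substrate.
#' @param p an [epi_params()].
#' @return an object of class `focal_adhesions`: a list with parallel
#'   vectors `vtx`, `tri` (3-col matrix), `w` (3-col weights), `strength`,
#'   `ruptured`.
#' @export
attach_adhesions <- function(tissue, lattice, p = epi_params()) {
  loc <- locate_in_lattice(tissue$V, lattice)
  if (anyNA(loc$tri[, 1])) {
    bad <- which(is.na(loc$tri[, 1]))[1]
    stop(sprintf("attach_adhesions(): vertex %d of cell %d at (%.2f, %.2f) lies outside the lattice",
                 bad, tissue$cell[bad], tissue$V[bad, 1], tissue$V[bad, 2]))
  }
  sg <- seg_geometry(tissue, tissue$V)
  mem_len <- 0.5 * (sg$len + sg$len[tissue$prv])
  E_local <- rowSums(loc$w * matrix(lattice$E[loc$tri], ncol = 3))
  structure(list(
    vtx = seq_len(tissue$n),
    tri = loc$tri, w = loc$w,
    strength = k_fa(E_local, p) * mem_len,
    ruptured = rep(FALSE, tissue$n),
    slack = matrix(0, tissue$n, 2),
    pending = rep(FALSE, tissue$n)
  ), class = "focal_adhesions")
}

#' @export
print.focal_adhesions <- function(x, ...) {
  cat(sprintf("<focal_adhesions> %d anchors (%d ruptured)\n",
              length(x$vtx), sum(x$ruptured)))
  invisible(x)
}

# Locate points in the lattice triangulation (on the REST geometry, which
# is structured): returns containing triangle indices and barycentric
# weights, NA where outside.
locate_in_lattice <- function(P, lattice) {
  tri <- lattice$tri
  S0 <- lattice$S0
  m <- nrow(P)
  out_tri <- matrix(NA_integer_, m, 3)
  out_w <- matrix(NA_real_, m, 3)
  # map each triangle once; use barycentric test against candidate triangles
  # found through the nearest lattice point's incidence list
  pt_tri <- lattice_point_triangles(lattice)
  h <- lattice$h
  for (i in seq_len(m)) {
    # nearest lattice point by brute grid arithmetic
    d2 <- (S0[, 1] - P[i, 1])^2 + (S0[, 2] - P[i, 2])^2
    near <- order(d2)[1:min(3, nrow(S0))]
    cands <- unique(unlist(pt_tri[near]))
    for (tID in cands) {
      a <- S0[tri[tID, 1], ]; b <- S0[tri[tID, 2], ]; cc <- S0[tri[tID, 3], ]
      w <- barycentric(P[i, ], a, b, cc)
      if (all(w >= -1e-9)) {
        out_tri[i, ] <- tri[tID, ]
        out_w[i, ] <- pmax(w, 0) / sum(pmax(w, 0))
        break
      }
    }
  }
  list(tri = out_tri, w = out_w)
}

lattice_point_triangles <- function(lattice) {
  if (!is.null(lattice$.pt_tri)) return(lattice$.pt_tri)
  tri <- lattice$tri
  N <- nrow(lattice$S0)
  idx <- rep(seq_len(nrow(tri)), 3)
  split(idx, factor(as.vector(tri), levels = seq_len(N)))
}

barycentric <- function(p, a, b, c) {
  M <- cbind(b - a, c - a)
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  v <- p - a
  l2 <- (v[1] * M[2, 2] - v[2] * M[1, 2]) / det
  l3 <- (-v[1] * M[2, 1] + v[2] * M[1, 1]) / det
  c(1 - l2 - l3, l2, l3)
}

#' Focal-adhesion forces on cell vertices and substrate points
#'
#' Each unruptured anchor is a linear spring between the cell vertex and
#' its material anchor point (which moves with the lattice); the vertex
#' receives one end and the three triangle corners share the exact opposite
#' reaction by barycentric weights.
#'
#' @param fa a [attach_adhesions()] set.
#' @param tissue the tissue.
#' @param lattice the substrate lattice.
#' @param V,S optional position overrides.
#' @return list with `on_vertices` (n x 2), `on_points` (N x 2) and the
#'   per-anchor spring `extension` (um; NA for ruptured anchors).
#' @export
adhesion_forces <- function(fa, tissue, lattice, V = tissue$V, S = lattice$S) {
  Fv <- matrix(0, tissue$n, 2)
  Fp <- matrix(0, nrow(S), 2)
  ext <- rep(NA_real_, length(fa$vtx))
  live <- which(!fa$ruptured)
  if (!length(live)) return(list(on_vertices = Fv, on_points = Fp, extension = ext))
  tri <- fa$tri[live, , drop = FALSE]; w <- fa$w[live, , drop = FALSE]
  ax <- w[, 1] * S[tri[, 1], 1] + w[, 2] * S[tri[, 2], 1] + w[, 3] * S[tri[, 3], 1]
  ay <- w[, 1] * S[tri[, 1], 2] + w[, 2] * S[tri[, 2], 2] + w[, 3] * S[tri[, 3], 2]
  vi <- fa$vtx[live]
  dx <- V[vi, 1] - ax - fa$slack[live, 1]
  dy <- V[vi, 2] - ay - fa$slack[live, 2]
  ext[live] <- sqrt(dx^2 + dy^2)
  s <- fa$strength[live]
  Fv[vi, 1] <- Fv[vi, 1] - s * dx
  Fv[vi, 2] <- Fv[vi, 2] - s * dy
  ii <- c(tri[, 1], tri[, 2], tri[, 3])
  addx <- c(w[, 1] * s * dx, w[, 2] * s * dx, w[, 3] * s * dx)
  addy <- c(w[, 1] * s * dy, w[, 2] * s * dy, w[, 3] * s * dy)
  acc <- rowsum(cbind(addx, addy), ii, reorder = TRUE)
  Fp[sort(unique.default(ii)), ] <- acc
  list(on_vertices = Fv, on_points = Fp, extension = ext)
}

# Irreversible rupture: an anchor breaks when its extension exceeds
# d_fa_rupture (geometric detachment cap) or its spring force exceeds
# f_fa_rupture. The force route carries the stiffness dependence: anchor
# strength grows with k_fa(E), so identical slips break anchors on stiff
# substrates first. Returns the updated set and the newly ruptured indices.
check_ruptures <- function(fa, tissue, lattice, p, V = tissue$V, S = lattice$S) {
  af <- adhesion_forces(fa, tissue, lattice, V = V, S = S)
  force <- fa$strength * af$extension
  over <- !fa$ruptured & !is.na(af$extension) &
    (af$extension > p$d_fa_rupture | force > p$f_fa_rupture)
  # rupture requires the threshold to hold on two consecutive checks, so a
  # single-step integration overshoot cannot break an anchor
  newly <- which(over & fa$pending)
  fa$pending <- over
  if (length(newly)) fa$ruptured[newly] <- TRUE
  list(fa = fa, newly = newly)
}

# Maxwell turnover of the adhesion springs: the slack offset relaxes toward
# the current extension with time constant tau_fa, so on minutes timescales
# adhesions track the membrane while staying elastic on short timescales.
relax_adhesions <- function(fa, tissue, lattice, dt, p,
                            V = tissue$V, S = lattice$S) {
  live <- which(!fa$ruptured)
  if (!length(live)) return(fa)
  tri <- fa$tri[live, , drop = FALSE]; w <- fa$w[live, , drop = FALSE]
  ax <- w[, 1] * S[tri[, 1], 1] + w[, 2] * S[tri[, 2], 1] + w[, 3] * S[tri[, 3], 1]
  ay <- w[, 1] * S[tri[, 1], 2] + w[, 2] * S[tri[, 2], 2] + w[, 3] * S[tri[, 3], 2]
  vi <- fa$vtx[live]
  f <- 1 - exp(-dt / p$tau_fa)
  fa$slack[live, 1] <- fa$slack[live, 1] +
    f * ((V[vi, 1] - ax) - fa$slack[live, 1])
  fa$slack[live, 2] <- fa$slack[live, 2] +
    f * ((V[vi, 2] - ay) - fa$slack[live, 2])
  fa
}
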