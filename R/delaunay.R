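# Bowyer-Watson Delaunay triangulation of scattered points, used to build
# the linear (triangulation-based) interpolant behind the analysis maps.
# Point counts are a few hundred (cell centroids), so the simple O(n^2)
# insertion algorithm is ample.

delaunay_triangulate <- function(P) {
  n <- nrow(P)
  if (n < 3) stop("delaunay_triangulate(): need at least 3 points")
  # break exact cocircularity (e.g. perfectly regular inputs) with a tiny
  # deterministic perturbation; the interpolant is unaffected at this scale
  scale <- max(diff(range(P[, 1])), diff(range(P[, 2])), 1)
  P <- P + 1e-9 * scale * cbind(sin(7.3 * seq_len(n)), cos(11.7 * seq_len(n)))
  # super-triangle enclosing all points
  ctr <- colMeans(P)
  R <- 3 * max(sqrt((P[, 1] - ctr[1])^2 + (P[, 2] - ctr[2])^2)) + 1
  sup <- rbind(ctr + R * c(0, 2), ctr + R * c(-1.8, -1), ctr + R * c(1.8, -1))
  pts <- rbind(P, sup)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  cc <- circumcircle(pts, tris)
  for (i in seq_len(n)) {
    bad <- which((pts[i, 1] - cc[, 1])^2 + (pts[i, 2] - cc[, 2])^2 <= cc[, 3])
    if (!length(bad)) next                       # degenerate; shouldn't happen
    # boundary polygon of the cavity: edges of bad triangles not shared twice
    ed <- rbind(tris[bad, c(1, 2), drop = FALSE],
                tris[bad, c(2, 3), drop = FALSE],
                tris[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    ed <- ed[keep, , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(ed, i)
    tris <- rbind(tris, newt)
    cc <- rbind(cc, circumcircle(pts, newt))
  }
  keep <- apply(tris, 1, function(t) all(t <= n))
  tris <- tris[keep, , drop = FALSE]
  # orient counter-clockwise
  a <- pts[tris[, 1], , drop = FALSE]
  b <- pts[tris[, 2], , drop = FALSE]
  c2 <- pts[tris[, 3], , drop = FALSE]
  cw <- (b[, 1] - a[, 1]) * (c2[, 2] - a[, 2]) -
        (b[, 2] - a[, 2]) * (c2[, 1] - a[, 1]) < 0
  tris[cw, ] <- tris[cw, c(1, 3, 2)]
  tris
}

circumcircle <- function(pts, tris) {
  a <- pts[tris[, 1], , drop = FALSE]
  b <- pts[tris[, 2], , drop = FALSE]
  c2 <- pts[tris[, 3], , drop = FALSE]
  d <- 2 * (a[, 1] * (b[, 2] - c2[, 2]) + b[, 1] * (c2[, 2] - a[, 2]) +
              c2[, 1] * (a[, 2] - b[, 2]))
  d[abs(d) < 1e-12] <- 1e-12
  a2 <- a[, 1]^2 + a[, 2]^2; b2 <- b[, 1]^2 + b[, 2]^2; c22 <- c2[, 1]^2 + c2[, 2]^2
  ux <- (a2 * (b[, 2] - c2[, 2]) + b2 * (c2[, 2] - a[, 2]) +
           c22 * (a[, 2] - b[, 2])) / d
  uy <- (a2 * (c2[, 1] - b[, 1]) + b2 * (a[, 1] - c2[, 1]) +
           c22 * (b[, 1] - a[, 1])) / d
  r2 <- (a[, 1] - ux)^2 + (a[, 2] - uy)^2
  cbind(ux, uy, r2 * (1 + 1e-12))
}

# Linear interpolation of scattered values onto grid points: exact at the
# nodes, NA outside the triangulation. `tri` may be supplied (e.g. the
# structured substrate triangulation); otherwise Delaunay is built here.
interp_linear <- function(P, values, gx, gy, tri = NULL) {
  values <- as.matrix(values)
  ng <- length(gx) * length(gy)
  G <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  if (is.null(tri) && nrow(P) < 3) {
    # too few sites to triangulate: nearest-site assignment (still exact
    # at the sites themselves)
    out <- matrix(NA_real_, ng, ncol(values))
    ni <- apply(G, 1, function(g)
      which.min((P[, 1] - g[1])^2 + (P[, 2] - g[2])^2))
    out[] <- values[ni, , drop = FALSE]
    return(out)
  }
  if (is.null(tri)) tri <- delaunay_triangulate(P)
  out <- matrix(NA_real_, ng, ncol(values))
  assigned <- rep(FALSE, ng)
  for (k in seq_len(nrow(tri))) {
    a <- P[tri[k, 1], ]; b <- P[tri[k, 2], ]; c2 <- P[tri[k, 3], ]
    lo <- pmin(a, pmin(b, c2)); hi <- pmax(a, pmax(b, c2))
    cand <- which(!assigned & G[, 1] >= lo[1] - 1e-9 & G[, 1] <= hi[1] + 1e-9 &
                    G[, 2] >= lo[2] - 1e-9 & G[, 2] <= hi[2] + 1e-9)
    if (!length(cand)) next
    M11 <- b[1] - a[1]; M21 <- b[2] - a[2]
    M12 <- c2[1] - a[1]; M22 <- c2[2] - a[2]
    det <- M11 * M22 - M12 * M21
    if (abs(det) < 1e-12) next
    vx <- G[cand, 1] - a[1]; vy <- G[cand, 2] - a[2]
    l2 <- (vx * M22 - vy * M12) / det
    l3 <- (-vx * M21 + vy * M11) / det
    l1 <- 1 - l2 - l3
    ok <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(ok)) next
    gi <- cand[ok]
    for (j in seq_len(ncol(values))) {
      out[gi, j] <- l1[ok] * values[tri[k, 1], j] +
        l2[ok] * values[tri[k, 2], j] + l3[ok] * values[tri[k, 3], j]
    }
    assigned[gi] <- TRUE
  }
  out
}
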