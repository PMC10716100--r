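# Planar polygon utilities shared by the cell and analysis code. All
# polygons are n x 2 matrices of vertices ordered counter-clockwise, closed
# implicitly (vertex n connects back to vertex 1).

#' Signed area of a polygon (positive for counter-clockwise order)
#' @param V n x 2 matrix of vertices.
#' @return signed area in um^2.
#' @export
polygon_area <- function(V) {
  n <- nrow(V)
  j <- c(2:n, 1L)
  0.5 * sum(V[, 1] * V[j, 2] - V[j, 1] * V[, 2])
}

#' Polygon centroid (area-weighted)
#' @param V n x 2 matrix of vertices.
#' @return length-2 centroid.
#' @export
polygon_centroid <- function(V) {
  n <- nrow(V)
  j <- c(2:n, 1L)
  cr <- V[, 1] * V[j, 2] - V[j, 1] * V[, 2]
  A <- 0.5 * sum(cr)
  if (abs(A) < 1e-12) return(colMeans(V))
  c(sum((V[, 1] + V[j, 1]) * cr), sum((V[, 2] + V[j, 2]) * cr)) / (6 * A)
}

#' Polygon perimeter
#' @param V n x 2 matrix of vertices.
#' @return perimeter in um.
#' @export
polygon_perimeter <- function(V) {
  n <- nrow(V)
  j <- c(2:n, 1L)
  sum(sqrt(rowSums((V[j, , drop = FALSE] - V)^2)))
}

#' Test a polygon for self-intersection
#'
#' TRUE when any two non-adjacent edges of the polygon cross.
#' @param V n x 2 matrix of vertices.
#' @return logical.
#' @export
polygon_self_intersects <- function(V) {
  n <- nrow(V)
  if (n < 4) return(FALSE)
  j <- c(2:n, 1L)
  A <- V; B <- V[j, , drop = FALSE]
  for (i in 1:(n - 1)) {
    # candidate edges k > i, skipping the two neighbors of edge i
    k <- setdiff((i + 1):n, c(i, if (i == 1) n else i - 1, j[i]))
    k <- k[j[k] != i]
    if (!length(k)) next
    if (any(segments_intersect(A[i, ], B[i, ], A[k, , drop = FALSE],
                               B[k, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

# Vectorized proper-intersection test of segment p1-p2 against rows of q1/q2.
segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- cross2(p2 - p1, sweep(q1, 2, p1))
  d2 <- cross2(p2 - p1, sweep(q2, 2, p1))
  d3 <- cross2v(q2 - q1, sweep(matrix(p1, nrow(q1), 2, byrow = TRUE), 1, 0) - q1)
  d4 <- cross2v(q2 - q1, matrix(p2, nrow(q1), 2, byrow = TRUE) - q1)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

cross2 <- function(v, M) v[1] * M[, 2] - v[2] * M[, 1]
cross2v <- function(M1, M2) M1[, 1] * M2[, 2] - M1[, 2] * M2[, 1]

#' Points-in-polygon test (crossing number)
#' @param P m x 2 matrix of query points.
#' @param V n x 2 polygon.
#' @return logical vector of length m.
#' @export
points_in_polygon <- function(P, V) {
  n <- nrow(V); m <- nrow(P)
  inside <- logical(m)
  j <- n
  for (i in 1:n) {
    yi <- V[i, 2]; yj <- V[j, 2]; xi <- V[i, 1]; xj <- V[j, 1]
    crosses <- ((yi > P[, 2]) != (yj > P[, 2])) &
      (P[, 1] < (xj - xi) * (P[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Overlap area of two polygons
#'
#' Estimated by uniform grid sampling of the intersection of the bounding
#' boxes; used in geometric audits of grown tissues.
#' @param V1,V2 polygons (n x 2 matrices).
#' @param res sampling resolution, um.
#' @return overlap area estimate, um^2.
#' @export
polygon_overlap_area <- function(V1, V2, res = 0.2) {
  lo <- pmax(apply(V1, 2, min), apply(V2, 2, min))
  hi <- pmin(apply(V1, 2, max), apply(V2, 2, max))
  if (any(hi <= lo)) return(0)
  xs <- seq(lo[1] + res / 2, hi[1], by = res)
  ys <- seq(lo[2] + res / 2, hi[2], by = res)
  if (!length(xs) || !length(ys)) return(0)
  G <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  mean2 <- points_in_polygon(G, V1) & points_in_polygon(G, V2)
  sum(mean2) * res^2
}

# Principal axes of the vertex scatter: returns unit vectors of the long and
# short axes (eigenvectors of the 2x2 covariance).
principal_axes <- function(V) {
  Vc <- sweep(V, 2, colMeans(V))
  C <- crossprod(Vc) / nrow(V)
  e <- eigen(C, symmetric = TRUE)
  list(long = e$vectors[, 1], short = e$vectors[, 2])
}

# Split a CCW polygon by the line through `origin` with unit direction `dir`.
# Returns list(left, right) of CCW polygons with the two intersection points
# inserted in both, or NULL when the line does not cut the polygon cleanly
# (other than exactly two boundary crossings).
polygon_split <- function(V, origin, dir) {
  n <- nrow(V)
  nrm <- c(-dir[2], dir[1])                    # left normal of the cut line
  s <- as.numeric((V[, 1] - origin[1]) * nrm[1] + (V[, 2] - origin[2]) * nrm[2])
  s[abs(s) < 1e-9] <- 1e-9                     # nudge vertices off the line
  j <- c(2:n, 1L)
  crossing <- which(s * s[j] < 0)
  if (length(crossing) != 2L) return(NULL)
  # intersection points on the two crossed edges
  ip <- lapply(crossing, function(i) {
    t <- s[i] / (s[i] - s[j[i]])
    V[i, ] + t * (V[j[i], ] - V[i, ])
  })
  build_side <- function(side) {
    # walk the original ring, inserting intersection points at the crossings;
    # `src` records each output vertex's original index (NA for cut points)
    out <- list(); src <- integer(0)
    for (i in 1:n) {
      if ((s[i] > 0) == (side > 0)) {
        out[[length(out) + 1L]] <- V[i, ]; src <- c(src, i)
      }
      ci <- match(i, crossing)
      if (!is.na(ci)) {
        out[[length(out) + 1L]] <- ip[[ci]]; src <- c(src, NA_integer_)
      }
    }
    P <- do.call(rbind, out)
    if (is.null(P) || nrow(P) < 3) return(NULL)
    if (polygon_area(P) < 0) { P <- P[nrow(P):1, , drop = FALSE]; src <- rev(src) }
    attr(P, "src") <- src
    P
  }
  left <- build_side(1); right <- build_side(-1)
  if (is.null(left) || is.null(right)) return(NULL)
  list(left = left, right = right)
}

# Distance from points P (m x 2) to segment a-b, with projection parameter t
# clamped to [0,1]. Returns list(d, t).
point_segment_distance <- function(P, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  t <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2]) / L2
  t <- pmin(pmax(t, 0), 1)
  dx <- P[, 1] - (a[1] + t * ab[1])
  dy <- P[, 2] - (a[2] + t * ab[2])
  list(d = sqrt(dx^2 + dy^2), t = t)
}

#' Regular polygon of a given area
#'
#' Counter-clockwise regular n-gon with area `A` centered at `center`.
#' @param n vertex count.
#' @param A target area, um^2.
#' @param center length-2 center.
#' @return n x 2 vertex matrix.
#' @export
regular_polygon <- function(n, A, center = c(0, 0)) {
  R <- sqrt(2 * A / (n * sin(2 * pi / n)))
  th <- 2 * pi * (0:(n - 1)) / n
  cbind(center[1] + R * cos(th), center[2] + R * sin(th))
}
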