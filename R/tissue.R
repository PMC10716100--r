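# Cell and tissue containers.
#
# A single cell is a closed CCW polygon with per-vertex attributes; a tissue
# stores all cells in flat arrays (one contiguous block of vertices per cell)
# so that force evaluations are plain vectorized matrix arithmetic. The flat
# arrays are authoritative between topology changes; structural remodeling
# edits per-cell views and re-flattens.

#' Construct a single cell polygon
#'
#' @param V n x 2 matrix of vertex positions (um), counter-clockwise.
#' @param A0 target area (um^2); defaults to the current area.
#' @param l0 per-segment rest lengths (segment i runs from vertex i to
#'   vertex i+1); defaults to the current lengths.
#' @param P0 rest perimeter for the perimeter-elastic cortical term;
#'   defaults to `p0_coef * sqrt(A0)` of the supplied parameters.
#' @param bnd logical per-vertex epithelium-boundary flags.
#' @param ref n x 2 reference positions for the edge anchors (defaults to
#'   the initial positions).
#' @param p an [epi_params()] object supplying `p0_coef`.
#' @return an object of class `epi_cell`.
#' @export
epi_cell <- function(V, A0 = NULL, l0 = NULL, P0 = NULL, bnd = NULL,
                     ref = NULL, p = epi_params()) {
  V <- unname(as.matrix(V))
  if (ncol(V) != 2 || nrow(V) < 3)
    stop("epi_cell(): V must be an n x 2 matrix with n >= 3")
  A <- polygon_area(V)
  if (A <= 0) stop("epi_cell(): vertices must be counter-clockwise (area > 0)")
  if (polygon_self_intersects(V)) stop("epi_cell(): polygon is self-intersecting")
  n <- nrow(V)
  j <- c(2:n, 1L)
  len <- sqrt(rowSums((V[j, , drop = FALSE] - V)^2))
  if (any(len < 1e-9)) stop("epi_cell(): degenerate (zero-length) segment")
  if (is.null(A0)) A0 <- A
  if (is.null(l0)) l0 <- len
  if (is.null(P0)) P0 <- p$p0_coef * sqrt(A0)
  if (is.null(bnd)) bnd <- rep(FALSE, n)
  if (is.null(ref)) ref <- V
  structure(list(V = V, A0 = A0, l0 = l0, P0 = P0, bnd = bnd, ref = ref,
                 junc = rep(NA_integer_, n), act = rep(1, n),
                 t_next_div = Inf, div = NULL),
            class = "epi_cell")
}

#' Assemble a tissue from a list of cells
#'
#' Flattens the cells into contiguous vertex blocks with next/previous index
#' maps so that all force laws evaluate as vectorized arithmetic over the
#' whole tissue at once. Junction links (`junc`) are global vertex indices
#' and must be reciprocal.
#'
#' @param cells list of [epi_cell()] objects.
#' @return an object of class `epi_tissue`.
#' @export
epi_tissue <- function(cells) {
  stopifnot(length(cells) >= 1)
  ns <- vapply(cells, function(c) nrow(c$V), 1L)
  cstart <- cumsum(c(1L, ns[-length(ns)]))
  n <- sum(ns)
  ts <- list(
    n = n, ncell = length(cells),
    V = unname(do.call(rbind, lapply(cells, `[[`, "V"))),
    cell = rep(seq_along(cells), ns),
    cstart = cstart, clen = ns,
    nxt = integer(n), prv = integer(n),
    l0 = unlist(lapply(cells, `[[`, "l0"), use.names = FALSE),
    junc = unlist(lapply(cells, `[[`, "junc"), use.names = FALSE),
    bnd = unlist(lapply(cells, `[[`, "bnd"), use.names = FALSE),
    ref = unname(do.call(rbind, lapply(cells, `[[`, "ref"))),
    act = unlist(lapply(cells, `[[`, "act"), use.names = FALSE),
    A0 = vapply(cells, `[[`, 1, "A0"),
    P0 = vapply(cells, `[[`, 1, "P0"),
    t_next_div = vapply(cells, `[[`, 1, "t_next_div"),
    div = lapply(cells, `[[`, "div")
  )
  for (ci in seq_along(cells)) {
    idx <- cstart[ci]:(cstart[ci] + ns[ci] - 1L)
    ts$nxt[idx] <- c(idx[-1], idx[1])
    ts$prv[idx] <- c(idx[length(idx)], idx[-length(idx)])
  }
  class(ts) <- "epi_tissue"
  ts
}

#' @export
print.epi_tissue <- function(x, ...) {
  cat(sprintf("<epi_tissue> %d cells, %d vertices, %d junction links\n",
              x$ncell, x$n, sum(!is.na(x$junc)) %/% 2))
  invisible(x)
}

#' Global vertex indices of one cell
#' @param ts an `epi_tissue`.
#' @param ci cell index.
#' @return integer vector of flat vertex indices.
#' @export
cell_indices <- function(ts, ci) ts$cstart[ci]:(ts$cstart[ci] + ts$clen[ci] - 1L)

#' Extract one cell of a tissue as an `epi_cell`
#' @param ts an `epi_tissue`.
#' @param ci cell index.
#' @return an [epi_cell()] with junction links as global vertex indices.
#' @export
tissue_cell <- function(ts, ci) {
  idx <- cell_indices(ts, ci)
  structure(list(V = ts$V[idx, , drop = FALSE], A0 = ts$A0[ci],
                 l0 = ts$l0[idx], P0 = ts$P0[ci], bnd = ts$bnd[idx],
                 ref = ts$ref[idx, , drop = FALSE], junc = ts$junc[idx],
                 act = ts$act[idx], t_next_div = ts$t_next_div[ci],
                 div = ts$div[[ci]]),
            class = "epi_cell")
}

# Rebuild a tissue from edited per-cell views. `remap` (optional) gives, for
# bookkeeping by callers, old-global-index -> new-global-index (NA if
# removed); here we return it so adhesion sets can be remapped.
tissue_rebuild <- function(cells, old_global = NULL) {
  ts <- epi_tissue(cells)
  ts
}

#' Validate tissue consistency
#'
#' Checks polygon simplicity, positive area, vertex counts, and junction
#' reciprocity. Errors on the first violation.
#' @param ts an `epi_tissue`.
#' @return the tissue, invisibly.
#' @export
tissue_validate <- function(ts) {
  for (ci in seq_len(ts$ncell)) {
    idx <- cell_indices(ts, ci)
    V <- ts$V[idx, , drop = FALSE]
    if (nrow(V) < 3) stop("tissue_validate(): cell ", ci, " has < 3 vertices")
    if (polygon_area(V) <= 0)
      stop("tissue_validate(): cell ", ci, " has non-positive area")
    if (polygon_self_intersects(V))
      stop("tissue_validate(): cell ", ci, " is self-intersecting")
  }
  has <- which(!is.na(ts$junc))
  bad <- has[ts$junc[ts$junc[has]] != has]
  if (length(bad))
    stop("tissue_validate(): non-reciprocal junction link at vertex ", bad[1])
  if (any(ts$junc[has] == has))
    stop("tissue_validate(): self junction link")
  invisible(ts)
}

#' Per-cell polygon areas
#' @param ts an `epi_tissue`.
#' @param V optional position override.
#' @return numeric vector of signed areas (um^2).
#' @export
tissue_areas <- function(ts, V = ts$V) {
  j <- ts$nxt
  as.numeric(rowsum(0.5 * (V[, 1] * V[j, 2] - V[j, 1] * V[, 2]), ts$cell,
                    reorder = TRUE))
}

tissue_perimeters <- function(ts, V = ts$V) {
  D <- V[ts$nxt, , drop = FALSE] - V
  as.numeric(rowsum(sqrt(D[, 1]^2 + D[, 2]^2), ts$cell, reorder = TRUE))
}

#' Cell centroids
#' @param ts an `epi_tissue`.
#' @param V optional position override.
#' @param exact use exact polygon centroids (default) or vertex means.
#' @return ncell x 2 matrix.
#' @export
tissue_centroids <- function(ts, V = ts$V, exact = TRUE) {
  out <- matrix(0, ts$ncell, 2)
  for (ci in seq_len(ts$ncell)) {
    idx <- cell_indices(ts, ci)
    out[ci, ] <- if (exact) polygon_centroid(V[idx, , drop = FALSE])
                 else colMeans(V[idx, , drop = FALSE])
  }
  out
}
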