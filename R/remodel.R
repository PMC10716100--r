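# Structural remodeling between integration steps: vertex insertion and
# removal, dynamic cell-cell junction (re)pairing, and cell division.
# All moves edit per-cell views carrying their old global vertex ids, then
# re-flatten; junction links and focal-adhesion anchors are remapped
# through the resulting old->new index map.

tissue_views <- function(ts) {
  lapply(seq_len(ts$ncell), function(ci) {
    idx <- cell_indices(ts, ci)
    list(V = ts$V[idx, , drop = FALSE], l0 = ts$l0[idx], junc = ts$junc[idx],
         bnd = ts$bnd[idx], ref = ts$ref[idx, , drop = FALSE],
         act = ts$act[idx], gid = idx, A0 = ts$A0[ci], P0 = ts$P0[ci],
         t_next_div = ts$t_next_div[ci], div = ts$div[[ci]])
  })
}

views_flatten <- function(views, old_n) {
  ns <- vapply(views, function(v) nrow(v$V), 1L)
  cstart <- cumsum(c(1L, ns[-length(ns)]))
  n <- sum(ns)
  gid <- unlist(lapply(views, `[[`, "gid"), use.names = FALSE)
  map <- rep(NA_integer_, old_n)
  keep <- !is.na(gid)
  map[gid[keep]] <- which(keep)
  junc_old <- unlist(lapply(views, `[[`, "junc"), use.names = FALSE)
  junc <- rep(NA_integer_, n)
  has <- which(!is.na(junc_old))
  junc[has] <- map[junc_old[has]]
  # drop half-links whose partner vanished, and enforce reciprocity
  ok <- !is.na(junc)
  junc[!ok] <- NA_integer_
  chk <- which(!is.na(junc))
  bad <- chk[is.na(junc[junc[chk]]) | junc[junc[chk]] != chk]
  junc[bad] <- NA_integer_
  ts <- list(
    n = n, ncell = length(views),
    V = unname(do.call(rbind, lapply(views, `[[`, "V"))),
    cell = rep(seq_along(views), ns),
    cstart = cstart, clen = ns,
    nxt = integer(n), prv = integer(n),
    l0 = unlist(lapply(views, `[[`, "l0"), use.names = FALSE),
    junc = junc,
    bnd = unlist(lapply(views, `[[`, "bnd"), use.names = FALSE),
    ref = unname(do.call(rbind, lapply(views, `[[`, "ref"))),
    act = unlist(lapply(views, `[[`, "act"), use.names = FALSE),
    A0 = vapply(views, `[[`, 1, "A0"),
    P0 = vapply(views, `[[`, 1, "P0"),
    t_next_div = vapply(views, `[[`, 1, "t_next_div"),
    div = lapply(views, `[[`, "div")
  )
  for (ci in seq_along(views)) {
    idx <- cstart[ci]:(cstart[ci] + ns[ci] - 1L)
    ts$nxt[idx] <- c(idx[-1], idx[1])
    ts$prv[idx] <- c(idx[length(idx)], idx[-length(idx)])
  }
  class(ts) <- "epi_tissue"
  list(ts = ts, map = map)
}

# Carry focal-adhesion anchors through a topology change in a
# stress-preserving way: anchors of kept vertices are remapped; a merge
# combines the two anchors (material midpoint, summed strength) so that no
# adhesion load is silently discarded; a new (inserted) vertex inherits the
# material midpoint of its ring neighbors' anchors, so insertion does not
# reset local adhesion stress. Only vertices with no anchored neighbors are
# anchored fresh at their current position.
remap_adhesions <- function(fa, map, ts, lattice, p, merged = NULL) {
  if (is.null(fa)) return(NULL)
  newv <- map[fa$vtx]
  keep <- !is.na(newv)
  fa2 <- list(vtx = newv[keep], tri = fa$tri[keep, , drop = FALSE],
              w = fa$w[keep, , drop = FALSE],
              strength = fa$strength[keep], ruptured = fa$ruptured[keep],
              slack = fa$slack[keep, , drop = FALSE],
              pending = fa$pending[keep])
  # rest-frame anchor positions of the OLD set, for material interpolation
  anchor_rest <- function(tri, w) {
    cbind(w[, 1] * lattice$S0[tri[, 1], 1] + w[, 2] * lattice$S0[tri[, 2], 1] +
            w[, 3] * lattice$S0[tri[, 3], 1],
          w[, 1] * lattice$S0[tri[, 1], 2] + w[, 2] * lattice$S0[tri[, 2], 2] +
            w[, 3] * lattice$S0[tri[, 3], 2])
  }
  old_rest <- if (!is.null(lattice)) anchor_rest(fa$tri, fa$w)
  old_by_vtx <- match(seq_len(length(map)), fa$vtx)
  # merges: move the survivor's anchor to the material midpoint and carry
  # the removed anchor's strength
  if (!is.null(lattice) && length(merged)) {
    for (mg in merged) {
      os <- old_by_vtx[mg[1]]; orm <- old_by_vtx[mg[2]]
      ns <- map[mg[1]]
      if (is.na(ns) || is.na(os) || is.na(orm)) next
      if (fa$ruptured[os] || fa$ruptured[orm]) next
      pos <- 0.5 * (old_rest[os, ] + old_rest[orm, ])
      loc <- locate_in_lattice(matrix(pos, 1, 2), lattice)
      if (is.na(loc$tri[1, 1])) next
      k <- which(fa2$vtx == ns)[1]
      if (is.na(k)) next
      fa2$tri[k, ] <- loc$tri[1, ]
      fa2$w[k, ] <- loc$w[1, ]
      fa2$strength[k] <- fa$strength[os] + fa$strength[orm]
      fa2$slack[k, ] <- 0.5 * (fa$slack[os, ] + fa$slack[orm, ])
    }
  }
  missing <- setdiff(seq_len(ts$n), fa2$vtx)
  if (length(missing) && !is.null(lattice)) {
    sg <- seg_geometry(ts, ts$V)
    mem_len <- 0.5 * (sg$len + sg$len[ts$prv])
    pos <- matrix(NA_real_, length(missing), 2)
    slk <- matrix(0, length(missing), 2)
    inherit <- logical(length(missing))
    at2 <- match(seq_len(ts$n), fa2$vtx)    # new-index -> fa2 row
    for (q in seq_along(missing)) {
      mi <- missing[q]
      kp <- at2[ts$prv[mi]]; kn <- at2[ts$nxt[mi]]
      if (!is.na(kp) && !is.na(kn) && !fa2$ruptured[kp] && !fa2$ruptured[kn]) {
        rest2 <- anchor_rest(fa2$tri[c(kp, kn), , drop = FALSE],
                             fa2$w[c(kp, kn), , drop = FALSE])
        pos[q, ] <- colMeans(rest2)
        slk[q, ] <- 0.5 * (fa2$slack[kp, ] + fa2$slack[kn, ])
        inherit[q] <- TRUE
      } else pos[q, ] <- ts$V[mi, ]
    }
    loc <- locate_in_lattice(pos, lattice)
    ok <- !is.na(loc$tri[, 1])
    if (any(ok)) {
      mi <- missing[ok]
      E_local <- rowSums(loc$w[ok, , drop = FALSE] *
                           matrix(lattice$E[loc$tri[ok, , drop = FALSE]], ncol = 3))
      fa2$vtx <- c(fa2$vtx, mi)
      fa2$tri <- rbind(fa2$tri, loc$tri[ok, , drop = FALSE])
      fa2$w <- rbind(fa2$w, loc$w[ok, , drop = FALSE])
      fa2$strength <- c(fa2$strength, k_fa(E_local, p) * mem_len[mi])
      fa2$ruptured <- c(fa2$ruptured, rep(FALSE, sum(ok)))
      fa2$slack <- rbind(fa2$slack, slk[ok, , drop = FALSE])
      fa2$pending <- c(fa2$pending, rep(FALSE, sum(ok)))
    }
  }
  ord <- order(fa2$vtx)
  structure(list(vtx = fa2$vtx[ord], tri = fa2$tri[ord, , drop = FALSE],
                 w = fa2$w[ord, , drop = FALSE],
                 strength = fa2$strength[ord], ruptured = fa2$ruptured[ord],
                 slack = fa2$slack[ord, , drop = FALSE],
                 pending = fa2$pending[ord]),
            class = "focal_adhesions")
}

# ---- vertex insertion / removal ------------------------------------------

# One remodeling pass: segments longer than l_max gain a midpoint vertex
# (rest lengths split, attributes interpolated); segments shorter than
# l_min merge their endpoints (the surviving vertex moves to the midpoint
# and inherits the removed vertex's links where it has none). Merges that
# would drop a cell below 3 vertices are skipped.
remodel_vertices_impl <- function(st, p) {
  ts <- st$tissue
  sg_len <- {
    D <- ts$V[ts$nxt, , drop = FALSE] - ts$V
    sqrt(D[, 1]^2 + D[, 2]^2)
  }
  if (all(sg_len <= p$l_max) && all(sg_len >= p$l_min))
    return(list(state = st, changed = FALSE))
  views <- tissue_views(ts)
  changed <- FALSE
  transfer <- list()     # junction transfers: old removed gid -> surviving gid
  merges <- list()       # anchor merges: (survivor old gid, removed old gid)
  for (ci in seq_along(views)) {
    v <- views[[ci]]
    k <- nrow(v$V)
    lens <- sqrt(rowSums((v$V[c(2:k, 1), , drop = FALSE] - v$V)^2))
    if (any(lens > p$l_max)) {
      out <- list()
      for (i in seq_len(k)) {
        nxt <- if (i == k) 1L else i + 1L
        out[[length(out) + 1L]] <- list(
          V = v$V[i, ], l0 = v$l0[i], junc = v$junc[i], bnd = v$bnd[i],
          ref = v$ref[i, ], act = v$act[i], gid = v$gid[i])
        if (lens[i] > p$l_max) {
          mid <- 0.5 * (v$V[i, ] + v$V[nxt, ])
          out[[length(out) - 1L + 1L]]$l0 <- v$l0[i] / 2
          out[[length(out) + 1L]] <- list(
            V = mid, l0 = v$l0[i] / 2, junc = NA_integer_,
            bnd = v$bnd[i] && v$bnd[nxt],
            ref = 0.5 * (v$ref[i, ] + v$ref[nxt, ]),
            act = 0.5 * (v$act[i] + v$act[nxt]), gid = NA_integer_)
          changed <- TRUE
        }
      }
      v <- list(V = do.call(rbind, lapply(out, `[[`, "V")),
                l0 = vapply(out, `[[`, 1, "l0"),
                junc = vapply(out, `[[`, 1L, "junc"),
                bnd = vapply(out, `[[`, TRUE, "bnd"),
                ref = do.call(rbind, lapply(out, `[[`, "ref")),
                act = vapply(out, `[[`, 1, "act"),
                gid = vapply(out, `[[`, 1L, "gid"),
                A0 = v$A0, P0 = v$P0, t_next_div = v$t_next_div, div = v$div)
    }
    # merges, applied one at a time on the current view
    repeat {
      k <- nrow(v$V)
      if (k <= 3) break
      lens <- sqrt(rowSums((v$V[c(2:k, 1), , drop = FALSE] - v$V)^2))
      i <- which(lens < p$l_min)
      if (!length(i)) break
      i <- i[1]
      j <- if (i == k) 1L else i + 1L
      mid <- 0.5 * (v$V[i, ] + v$V[j, ])
      v$V[i, ] <- mid
      if (is.na(v$junc[i]) && !is.na(v$junc[j]) && !is.na(v$gid[i]))
        transfer[[length(transfer) + 1L]] <- c(v$junc[j], v$gid[i])
      if (!is.na(v$gid[i]) && !is.na(v$gid[j]))
        merges[[length(merges) + 1L]] <- c(v$gid[i], v$gid[j])
      v$l0[i] <- v$l0[i] + v$l0[j]               # preserve total rest length
      v$bnd[i] <- v$bnd[i] || v$bnd[j]
      v$ref[i, ] <- 0.5 * (v$ref[i, ] + v$ref[j, ])
      v$act[i] <- 0.5 * (v$act[i] + v$act[j])
      keep <- setdiff(seq_len(k), j)
      v$V <- v$V[keep, , drop = FALSE]; v$l0 <- v$l0[keep]
      v$junc <- v$junc[keep]; v$bnd <- v$bnd[keep]
      v$ref <- v$ref[keep, , drop = FALSE]; v$act <- v$act[keep]
      v$gid <- v$gid[keep]
      changed <- TRUE
    }
    views[[ci]] <- v
  }
  if (!changed) return(list(state = st, changed = FALSE))
  fl <- views_flatten(views, ts$n)
  ts2 <- fl$ts
  # junction transfers recorded during merges (partner old-gid, survivor old-gid)
  for (tr in transfer) {
    pnew <- fl$map[tr[1]]; snew <- fl$map[tr[2]]
    if (!is.na(pnew) && !is.na(snew) && is.na(ts2$junc[pnew]) &&
        is.na(ts2$junc[snew])) {
      ts2$junc[pnew] <- snew; ts2$junc[snew] <- pnew
    }
  }
  st$tissue <- ts2
  st$fa <- remap_adhesions(st$fa, fl$map, ts2, st$lattice, p, merged = merges)
  list(state = st, changed = TRUE)
}

#' Vertex remodeling pass
#'
#' Splits membrane segments longer than `l_max` at their midpoint and
#' merges the endpoints of segments shorter than `l_min` (skipped when the
#' cell would drop below three vertices). Adhesion anchors and junction
#' links are carried through the topology change.
#'
#' @param state an [epi_state()].
#' @param p an [epi_params()].
#' @return the updated state.
#' @export
remodel_vertices <- function(state, p = state$params) {
  remodel_vertices_impl(state, p)$state
}

# ---- junction remodeling --------------------------------------------------

remodel_junctions_ts <- function(ts, p) {
  V <- ts$V
  linked <- which(!is.na(ts$junc))
  if (length(linked)) {
    d <- sqrt(rowSums((V[linked, , drop = FALSE] -
                         V[ts$junc[linked], , drop = FALSE])^2))
    far <- linked[d > p$d_junc_unpair]
    # also dissolve links threaded through a third cell (can arise when a
    # division inserts new membrane between formerly adjacent cells)
    lk <- linked[d <= p$d_junc_unpair & linked < ts$junc[linked]]
    if (length(lk)) {
      mid <- 0.5 * (V[lk, , drop = FALSE] + V[ts$junc[lk], , drop = FALSE])
      blocked <- rep(FALSE, length(lk))
      for (ci in seq_len(ts$ncell)) {
        idx <- cell_indices(ts, ci)
        Vc <- V[idx, , drop = FALSE]
        inbox <- mid[, 1] >= min(Vc[, 1]) & mid[, 1] <= max(Vc[, 1]) &
                 mid[, 2] >= min(Vc[, 2]) & mid[, 2] <= max(Vc[, 2])
        third <- inbox & ts$cell[lk] != ci & ts$cell[ts$junc[lk]] != ci
        if (any(third))
          blocked[third] <- blocked[third] |
            points_in_polygon(mid[third, , drop = FALSE], Vc)
      }
      far <- union(far, lk[blocked])
    }
    if (length(far)) {
      ts$junc[ts$junc[far]] <- NA_integer_
      ts$junc[far] <- NA_integer_
    }
  }
  free <- which(is.na(ts$junc))
  if (length(free) >= 2) {
    cand <- close_pairs(V[free, , drop = FALSE], p$d_junc_pair)
    if (!is.null(cand) && nrow(cand)) {
      a <- free[cand[, 1]]; b <- free[cand[, 2]]
      diffc <- ts$cell[a] != ts$cell[b]
      a <- a[diffc]; b <- b[diffc]; dd <- cand[diffc, 3]
      if (length(a)) {
        # drop pairs whose midpoint lies inside a third cell: a junction
        # must not thread through an interposed membrane
        mid <- 0.5 * (V[a, , drop = FALSE] + V[b, , drop = FALSE])
        blocked <- rep(FALSE, length(a))
        for (ci in seq_len(ts$ncell)) {
          idx <- cell_indices(ts, ci)
          Vc <- V[idx, , drop = FALSE]
          inbox <- mid[, 1] >= min(Vc[, 1]) & mid[, 1] <= max(Vc[, 1]) &
                   mid[, 2] >= min(Vc[, 2]) & mid[, 2] <= max(Vc[, 2])
          third <- inbox & ts$cell[a] != ci & ts$cell[b] != ci
          if (any(third))
            blocked[third] <- blocked[third] |
              points_in_polygon(mid[third, , drop = FALSE], Vc)
        }
        a <- a[!blocked]; b <- b[!blocked]; dd <- dd[!blocked]
      }
      if (length(a)) {
        ord <- order(dd, a, b)                   # nearest pairs first
        taken <- logical(ts$n)
        for (k in ord) {
          if (!taken[a[k]] && !taken[b[k]]) {
            ts$junc[a[k]] <- b[k]; ts$junc[b[k]] <- a[k]
            taken[a[k]] <- TRUE; taken[b[k]] <- TRUE
          }
        }
      }
    }
  }
  ts
}

#' Junction remodeling pass
#'
#' Dissolves junction links stretched beyond `d_junc_unpair` and pairs free
#' facing vertices of distinct cells within `d_junc_pair`, nearest pairs
#' first, at most one partner per vertex.
#'
#' @inheritParams remodel_vertices
#' @return the updated state.
#' @export
remodel_junctions <- function(state, p = state$params) {
  state$tissue <- remodel_junctions_ts(state$tissue, p)
  state
}

# all index pairs within `cutoff`, via grid hashing: returns cbind(i, j, d)
close_pairs <- function(P, cutoff) {
  m <- nrow(P)
  if (m < 2) return(NULL)
  gx <- floor(P[, 1] / cutoff); gy <- floor(P[, 2] / cutoff)
  key <- paste(gx, gy)
  buckets <- split(seq_len(m), key)
  out <- list()
  for (b in buckets) {
    # same-bucket pairs and pairs with the 4 forward neighbor buckets
    g <- c(gx[b[1]], gy[b[1]])
    neigh <- unlist(lapply(list(c(1, 0), c(-1, 1), c(0, 1), c(1, 1)),
                           function(o) buckets[[paste(g[1] + o[1], g[2] + o[2])]]),
                    use.names = FALSE)
    cand_i <- c(if (length(b) > 1) rep(b, times = length(b)),
                rep(b, times = length(neigh)))
    cand_j <- c(if (length(b) > 1) rep(b, each = length(b)),
                rep(neigh, each = length(b)))
    keep <- cand_i < cand_j
    cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
    if (!length(cand_i)) next
    d <- sqrt((P[cand_i, 1] - P[cand_j, 1])^2 + (P[cand_i, 2] - P[cand_j, 2])^2)
    hit <- d <= cutoff
    if (any(hit))
      out[[length(out) + 1L]] <- cbind(cand_i[hit], cand_j[hit], d[hit])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# ---- cell division --------------------------------------------------------

# Activate furrows for cells whose clock expired, split cells whose furrow
# completed. New furrows are not begun once the cell-count target (plus
# active furrows) is reached, so growth ends at exactly the target count.
division_clock <- function(st) {
  ts <- st$tissue
  p <- st$params
  changed <- FALSE
  active <- vapply(ts$div, Negate(is.null), TRUE)
  due <- which(!active & st$time >= ts$t_next_div)
  n_active <- sum(active)
  for (ci in due) {
    if (ts$ncell + n_active >= st$target_cells) break
    idx <- cell_indices(ts, ci)
    ax <- principal_axes(ts$V[idx, , drop = FALSE])
    ts$div[[ci]] <- list(dir = ax$short, t_end = st$time + p$T_furrow)
    n_active <- n_active + 1L
  }
  st$tissue <- ts
  ripe <- which(vapply(ts$div, function(d)
    !is.null(d) && st$time >= d$t_end, TRUE))
  for (ci in rev(ripe)) {                       # indexes stay valid in reverse
    st <- divide_cell(st, ci)
    changed <- TRUE
  }
  list(state = st, changed = changed || length(due) > 0)
}

#' Split a dividing cell into two daughters
#'
#' Cuts the polygon by the cleavage line (centroid + stored short-axis
#' direction), inserting the two intersection points in both daughters so
#' the summed daughter area equals the parent area exactly. Daughters draw
#' fresh target areas and division times from the configured distributions;
#' junction links are inherited by position through the next junction
#' remodeling pass. A split that would produce a degenerate daughter is
#' deferred.
#'
#' @param state an [epi_state()].
#' @param ci index of the cell to divide (must carry a division state).
#' @param p an [epi_params()].
#' @return the updated state.
#' @export
divide_cell <- function(state, ci, p = state$params) {
  ts <- state$tissue
  dv <- ts$div[[ci]]
  if (is.null(dv) || is.null(dv$dir)) stop("divide_cell(): division axis undefined")
  idx <- cell_indices(ts, ci)
  V <- ts$V[idx, , drop = FALSE]
  ctr <- polygon_centroid(V)
  sp <- polygon_split(V, ctr, dv$dir)
  if (is.null(sp) ||
      polygon_self_intersects(sp$left) || polygon_self_intersects(sp$right)) {
    # deferred: let the furrow keep working and retry later
    state$tissue$div[[ci]]$t_end <- state$time + p$T_furrow / 2
    state$events[[length(state$events) + 1L]] <-
      list(time = state$time, type = "division_deferred", cell = ci)
    return(state)
  }
  views <- tissue_views(ts)
  parent <- views[[ci]]
  mk_daughter <- function(P) {
    src <- attr(P, "src")
    k <- nrow(P)
    nxt <- c(2:k, 1)
    lens <- sqrt(rowSums((P[nxt, , drop = FALSE] - P)^2))
    A0 <- draw_A0(p)
    list(V = unname(P), l0 = lens, junc = ifelse(is.na(src), NA_integer_,
                                                 parent$junc[src]),
         bnd = ifelse(is.na(src), FALSE, parent$bnd[src]),
         ref = unname(P),
         act = ifelse(is.na(src), 1, parent$act[src]),
         gid = ifelse(is.na(src), NA_integer_, parent$gid[src]),
         A0 = A0, P0 = p$p0_coef * sqrt(A0),
         t_next_div = state$time + draw_T_div(p), div = NULL)
  }
  d1 <- mk_daughter(sp$left); d2 <- mk_daughter(sp$right)
  views[[ci]] <- d1
  views[[length(views) + 1L]] <- d2
  fl <- views_flatten(views, ts$n)
  state$tissue <- fl$ts
  state$fa <- remap_adhesions(state$fa, fl$map, fl$ts, state$lattice, p)
  state$events[[length(state$events) + 1L]] <-
    list(time = state$time, type = "division", cell = ci)
  state
}

draw_A0 <- function(p) {
  a <- stats::rnorm(1, p$A0_mean, p$A0_cv * p$A0_mean)
  min(max(a, 0.5 * p$A0_mean), 1.6 * p$A0_mean)
}

draw_T_div <- function(p) {
  max(stats::rnorm(1, p$T_div_mean, p$T_div_sd), 0.2 * p$T_div_mean)
}
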