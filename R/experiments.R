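# Scenario drivers: epithelium growth from a single cell, placement on a
# substrate, single-cell micromanipulation, optogenetic junction
# contraction, and the stiffness-gradient scenario sweep.
#
# The damping coefficient eta fixes only the clock of the overdamped
# dynamics, so each driver runs on the timescale that makes its protocol
# quasi-static at the measurement times: growth uses a coarse clock
# (eta = 1 g/s), micromanipulation the default fast clock (eta = 0.1 g/s,
# so the 30 um/s pull is near-elastic), and optogenetic activation a slow
# clock (eta = 20 g/s) matched to its minutes-long protocol.

#' Grow a virtual epithelium from a single cell
#'
#' Cells divide at normally distributed intervals with target areas drawn
#' from the configured distribution; growth runs without a substrate (edge
#' and adhesion forces off) under 2nd-order Runge-Kutta with remodeling
#' enabled. Once the target count is reached the tissue relaxes
#' division-free until the residual force falls below `relax_tol`.
#'
#' @param seed integer seed (randomness contract: same seed, same tissue).
#' @param target_cell_count cells to grow.
#' @param p an [epi_params()]; the growth clock defaults to eta = 1 g/s.
#' @param relax_tol residual-force tolerance after growth, AU.
#' @param max_sim_time abort limit on the growth phase, s.
#' @return a relaxed [epi_state()] without substrate.
#' @export
grow_epithelium <- function(seed, target_cell_count,
                            p = epi_params(eta = 1, dt_init = 0.02,
                                           dt_max = 0.3, err_tol = 0.3),
                            relax_tol = 0.05, max_sim_time = 600) {
  if (target_cell_count < 1) stop("grow_epithelium(): target must be >= 1")
  set.seed(as.integer(seed))
  cell0 <- epi_cell(regular_polygon(16, p$A0_mean), A0 = p$A0_mean, p = p)
  st <- epi_state(epi_tissue(list(cell0)), params = p, remodel = TRUE,
                  growth = TRUE, order = 2L)
  st$target_cells <- target_cell_count
  st$tissue$t_next_div[1] <- draw_T_div(p)
  while (st$tissue$ncell < target_cell_count) {
    st <- advance(st, p$T_div_mean / 2)
    if (st$time > max_sim_time)
      stop("grow_epithelium(): target cell count not reached in time budget")
  }
  st$growth <- FALSE
  # the division-free relaxation runs under a tighter step tolerance: the
  # coarse growth tolerance lets vertices overshoot contact membranes,
  # which would keep the residual force artificially high
  st$params <- epi_params_with(p, err_tol = 0.03, dt_max = 0.1)
  st$dt <- min(st$dt, 0.1)
  st <- relax(st, tol = relax_tol, max_time = max_sim_time)
  st$params <- p
  st$tissue$t_next_div[] <- Inf
  st
}

#' Place a grown epithelium on a substrate and attach focal adhesions
#'
#' Builds a lattice covering the tissue (with margin), applies the
#' stiffness field, anchors every vertex at its current position, and flags
#' exposed rim vertices as epithelium-edge anchors (reference = current
#' position). The tissue is recentered so the reference cell's centroid
#' sits at the origin of the analysis frame.
#'
#' @param state a grown [epi_state()] (no substrate).
#' @param field a [stiffness_field()].
#' @param p an [epi_params()] for the coupled phase (fast clock default).
#' @param center_cell cell whose centroid defines the frame origin;
#'   defaults to the cell nearest the tissue centroid.
#' @param margin lattice margin beyond the tissue bounding box, um.
#' @param remodel enable remodeling in the coupled state.
#' @return an [epi_state()] with lattice and adhesions, order 4.
#' @export
place_on_substrate <- function(state, field = stiffness_field("uniform", 1.1),
                               p = epi_params(), center_cell = NULL,
                               margin = 16, remodel = FALSE) {
  ts <- state$tissue
  ctr_all <- tissue_centroids(ts)
  if (is.null(center_cell)) {
    mid <- colMeans(ctr_all)
    center_cell <- which.min((ctr_all[, 1] - mid[1])^2 + (ctr_all[, 2] - mid[2])^2)
  }
  shift <- ctr_all[center_cell, ]
  ts$V <- sweep(ts$V, 2, shift)
  ts$ref <- sweep(ts$ref, 2, shift)
  ext <- c(min(ts$V[, 1]) - margin, max(ts$V[, 1]) + margin,
           min(ts$V[, 2]) - margin, max(ts$V[, 2]) + margin)
  lat <- build_lattice(ext, p$substrate_h, p = p)
  lat <- apply_stiffness_field(lat, field)
  # exposed rim vertices: unpaired and with no foreign vertex nearby
  free <- which(is.na(ts$junc))
  ts$bnd[] <- FALSE
  if (length(free)) {
    cp <- close_pairs(ts$V, 2 * p$d_junc_unpair)
    near_foreign <- rep(FALSE, ts$n)
    if (!is.null(cp)) {
      diffc <- ts$cell[cp[, 1]] != ts$cell[cp[, 2]]
      near_foreign[cp[diffc, 1]] <- TRUE
      near_foreign[cp[diffc, 2]] <- TRUE
    }
    ts$bnd[free[!near_foreign[free]]] <- TRUE
  }
  ts$ref <- ts$V
  st <- epi_state(ts, params = p, lattice = lat, time = 0,
                  remodel = remodel, growth = FALSE, order = 4L)
  st$fa <- attach_adhesions(ts, lat, p)
  st$center_cell <- center_cell
  st
}

#' Pipette protocol for single-cell micromanipulation
#'
#' @param distance pipette travel, um (30 for uniform-stiffness runs, 20
#'   for gradient runs).
#' @param speed pipette speed, um/s.
#' @param direction unit movement vector (+y by convention).
#' @param grab_radius radius of the grabbed membrane arc around the cell's
#'   leading pole, um.
#' @param hold_after settle time integrated after the movement, s.
#' @return an object of class `pipette_protocol`.
#' @export
pipette_protocol <- function(distance = 30, speed = 30, direction = c(0, 1),
                             grab_radius = 4, hold_after = 1) {
  if (distance < 0) stop("pipette_protocol(): distance must be >= 0")
  if (speed <= 0) stop("pipette_protocol(): speed must be positive")
  direction <- direction / sqrt(sum(direction^2))
  structure(list(distance = distance, speed = speed, direction = direction,
                 grab_radius = grab_radius, hold_after = hold_after),
            class = "pipette_protocol")
}

#' Run a single-cell micromanipulation
#'
#' Grabs a contiguous vertex arc at the leading pole of the center cell and
#' translates it kinematically at the protocol speed; all other degrees of
#' freedom are integrated. Remodeling is frozen (elastic short-timescale
#' response): vertex counts, junction pairs and adhesion anchors are
#' topology-stable, with adhesion rupture as the only structural event.
#'
#' @param state an [epi_state()] from [place_on_substrate()].
#' @param protocol a [pipette_protocol()].
#' @return an `epi_trajectory`: list with `before`/`after` states, the
#'   analysis-frame `origin`, the grabbed vertex indices, rupture events
#'   (with pipette travel at rupture) and the after-state force breakdown.
#' @export
run_micromanipulation <- function(state, protocol = pipette_protocol()) {
  st <- state
  st$remodel <- FALSE
  st$growth <- FALSE
  ci <- st$center_cell
  if (is.null(ci)) stop("run_micromanipulation(): state lacks a center cell")
  idx <- cell_indices(st$tissue, ci)
  if (any(st$tissue$bnd[idx]))
    stop("run_micromanipulation(): manipulated cell touches the epithelium boundary")
  V0 <- st$tissue$V
  ctr <- polygon_centroid(V0[idx, , drop = FALSE])
  dir <- protocol$direction
  # leading pole of the cell and the contiguous grabbed arc around it
  proj <- (V0[idx, 1] - ctr[1]) * dir[1] + (V0[idx, 2] - ctr[2]) * dir[2]
  pole <- idx[which.max(proj)]
  polep <- V0[pole, ]
  d_pole <- sqrt((V0[idx, 1] - polep[1])^2 + (V0[idx, 2] - polep[2])^2)
  in_r <- d_pole <= protocol$grab_radius
  arc <- grab_arc(idx, which(idx == pole), in_r)
  # the pipette presses onto the apical surface and decouples the grabbed
  # membrane patch from the substrate: release those anchors (not counted
  # as detachment events)
  released <- integer(0)
  if (!is.null(st$fa)) {
    rel <- which(st$fa$vtx %in% arc)
    if (length(rel)) {
      released <- st$fa$vtx[rel]
      st$fa$vtx <- st$fa$vtx[-rel]
      st$fa$tri <- st$fa$tri[-rel, , drop = FALSE]
      st$fa$w <- st$fa$w[-rel, , drop = FALSE]
      st$fa$strength <- st$fa$strength[-rel]
      st$fa$ruptured <- st$fa$ruptured[-rel]
      st$fa$slack <- st$fa$slack[-rel, , drop = FALSE]
      st$fa$pending <- st$fa$pending[-rel]
    }
  }
  t0 <- st$time
  T_move <- protocol$distance / protocol$speed
  P0 <- V0[arc, , drop = FALSE]
  st$constraint <- list(
    idx = arc,
    pos = function(t) {
      s <- min(max(t - t0, 0), T_move) * protocol$speed
      cbind(P0[, 1] + s * dir[1], P0[, 2] + s * dir[2])
    },
    vel = function(t) if (t - t0 < T_move) protocol$speed * dir else c(0, 0)
  )
  before <- st
  st <- advance(st, T_move + protocol$hold_after)
  st$constraint <- NULL
  trav <- function(tt) protocol$speed * min(max(tt - t0, 0), T_move)
  ruptures <- Filter(function(e) e$type == "rupture", st$events)
  ruptures <- lapply(ruptures, function(e) {
    e$pipette_travel <- trav(e$time); e
  })
  structure(list(before = before, after = st,
                 origin = c(0, 0), direction = dir, cell = ci,
                 grabbed = arc, released = released, protocol = protocol,
                 ruptures = ruptures,
                 breakdown_after = total_cell_force(st$tissue, st$params,
                                                    st$lattice, st$fa)),
            class = "epi_trajectory")
}

# contiguous run of TRUE flags around position `at` in a cyclic index set
grab_arc <- function(idx, at, flag) {
  k <- length(idx)
  sel <- at
  i <- at
  repeat {
    i <- if (i == k) 1L else i + 1L
    if (i == at || !flag[i]) break
    sel <- c(sel, i)
  }
  i <- at
  repeat {
    i <- if (i == 1L) k else i - 1L
    if (i == at || !flag[i]) break
    sel <- c(sel, i)
  }
  idx[sort(unique(sel))]
}

#' Parameter set for optogenetic runs
#'
#' The minutes-long activation protocol runs on a slow clock whose damping
#' scales with the stiffest substrate modulus in the field, keeping the
#' explicit integrator's step roughly stiffness-independent while all
#' end-of-window readouts remain quasi-static (the slowest junction mode
#' still relaxes an order of magnitude faster than the activation window).
#'
#' @param field the [stiffness_field()] of the run.
#' @return an [epi_params()] with the optogenetic clock.
#' @export
opto_params <- function(field = stiffness_field("uniform", 1.1)) {
  Emax <- max(field$E_near, field$E_far)
  eta <- min(max(40 * Emax / 1.1, 40), 400)
  epi_params(eta = eta, dt_max = 8, dt_init = 0.5)
}

#' Optogenetic activation protocol
#'
#' @param multiplier contractility multiplier applied to both cortical
#'   tension constants inside the activation region (> 1).
#' @param t_on,t_off activation window, s (2 and 22 min).
#' @param duration total simulated time, s.
#' @param margin half-width added around the junction run to form the
#'   activation rectangle, um.
#' @return an object of class `activation_protocol`.
#' @export
activation_protocol <- function(multiplier = 13, t_on = 120, t_off = 1320,
                                duration = 1560, margin = 1.5) {
  if (!(t_on < t_off && t_off <= duration))
    stop("activation_protocol(): need t_on < t_off <= duration")
  structure(list(multiplier = multiplier, t_on = t_on, t_off = t_off,
                 duration = duration, margin = margin),
            class = "activation_protocol")
}

# Shared junction run between cells a and b: the vertices of each cell
# linked to the other, as cyclic-contiguous index arcs.
junction_run <- function(ts, a, b) {
  ia <- cell_indices(ts, a)
  la <- ia[!is.na(ts$junc[ia]) & ts$cell[ts$junc[ia]] == b]
  ib <- cell_indices(ts, b)
  lb <- ib[!is.na(ts$junc[ib]) & ts$cell[ts$junc[ib]] == a]
  list(a = la, b = lb)
}

# Polyline length of the junction run on each side, averaged. The length
# is measured over the full membrane span between the outermost linked
# vertices (interior link churn during remodeling does not change it).
junction_run_length <- function(ts, a, b) {
  run <- junction_run(ts, a, b)
  side_len <- function(iv, ci) {
    if (length(iv) < 2) return(NA_real_)
    idx <- cell_indices(ts, ci)
    pos <- sort(match(iv, idx))
    # contiguous span in ring order (runs never wrap in practice; if they
    # do, measure the shorter closed arc)
    span <- idx[pos[1]:pos[length(pos)]]
    P <- ts$V[span, , drop = FALSE]
    sum(sqrt(rowSums(diff(P)^2)))
  }
  mean(c(side_len(run$a, a), side_len(run$b, b)), na.rm = TRUE)
}

#' Run an optogenetic junction-contraction experiment
#'
#' Multiplies both cortical tension constants for the vertices inside a
#' rectangle enclosing the shared junction run of two adjacent cells during
#' the activation window; remodeling stays enabled (minutes timescale).
#' Tracks the relative junction length L/L0 and stores the substrate state
#' before activation and at its end for the displacement-peak analysis.
#'
#' @param state an [epi_state()] from [place_on_substrate()] with
#'   `remodel = TRUE`; its parameter set should use the slow clock
#'   (eta = 20 g/s) matched to the minutes-long protocol.
#' @param protocol an [activation_protocol()].
#' @param cells optional pair of adjacent cell indices; defaults to the
#'   pair sharing the longest junction run near the tissue center.
#' @return an `opto_trajectory`: tibble `L_series` (time, L, L_rel), the
#'   junction center/axis, substrate states `S_on`/`S_off`, the lattice and
#'   final state, and a `destroyed` flag if remodeling dissolved the run.
#' @export
run_optogenetic <- function(state, protocol = activation_protocol(),
                            cells = NULL) {
  st <- state
  st$remodel <- TRUE
  p <- st$params
  if (is.null(cells)) cells <- pick_junction_pair(st$tissue)
  a <- cells[1]; b <- cells[2]
  run0 <- junction_run(st$tissue, a, b)
  if (length(run0$a) < 2)
    stop("run_optogenetic(): chosen cells share no junction run")
  L0 <- junction_run_length(st$tissue, a, b)
  Pj <- st$tissue$V[run0$a, , drop = FALSE]
  jctr <- colMeans(Pj)
  dirv <- Pj[nrow(Pj), ] - Pj[1, ]
  jaxis <- dirv / sqrt(sum(dirv^2))
  # activation rectangle: oriented box around the run plus margin
  along <- as.numeric((Pj - matrix(jctr, nrow(Pj), 2, byrow = TRUE)) %*% jaxis)
  half_len <- max(abs(along)) + protocol$margin
  rect <- list(center = jctr, axis = jaxis, half_len = half_len,
               half_wid = protocol$margin)
  sample_L <- function(s) {
    c(time = s$time, L = junction_run_length(s$tissue, a, b))
  }
  st <- advance(st, protocol$t_on, sample_every = 30, callback = sample_L)
  s_pre <- st$samples; st$samples <- NULL
  S_on <- st$lattice$S
  # light activation is positional: vertices of the two chosen cells inside
  # the fixed rectangle carry the multiplier, re-evaluated between steps
  st$activation <- list(rect = rect, multiplier = protocol$multiplier,
                        cells = c(a, b))
  st <- advance(st, protocol$t_off - protocol$t_on, sample_every = 30,
                callback = sample_L)
  s_act <- st$samples; st$samples <- NULL
  S_off <- st$lattice$S
  st$activation <- NULL
  st$tissue$act[] <- 1
  st <- advance(st, protocol$duration - protocol$t_off, sample_every = 30,
                callback = sample_L)
  s_post <- st$samples; st$samples <- NULL
  smp <- do.call(rbind, c(s_pre, s_act, s_post))
  L_series <- tibble::tibble(time = smp[, "time"], L = smp[, "L"],
                             L_rel = smp[, "L"] / L0)
  runF <- junction_run(st$tissue, a, b)
  structure(list(L_series = L_series, L0 = L0, cells = c(a, b),
                 junction_center = jctr, junction_axis = jaxis,
                 S_on = S_on, S_off = S_off, lattice = st$lattice,
                 final = st, protocol = protocol,
                 destroyed = length(runF$a) < 2 || !is.finite(
                   junction_run_length(st$tissue, a, b))),
            class = "opto_trajectory")
}

in_rect <- function(P, rect) {
  d <- sweep(P, 2, rect$center)
  u <- d %*% rect$axis
  v <- d %*% c(-rect$axis[2], rect$axis[1])
  abs(u) <= rect$half_len & abs(v) <= rect$half_wid
}

# Adjacent pair with the longest shared junction run among cells near the
# tissue center (deterministic given the tissue; the seed enters through
# the grown tissue itself).
pick_junction_pair <- function(ts) {
  ctr <- tissue_centroids(ts)
  mid <- colMeans(ctr)
  d <- sqrt((ctr[, 1] - mid[1])^2 + (ctr[, 2] - mid[2])^2)
  near <- order(d)[seq_len(min(6, ts$ncell))]
  best <- NULL; best_len <- -Inf
  for (a in near) {
    ia <- cell_indices(ts, a)
    partners <- unique(ts$cell[ts$junc[ia][!is.na(ts$junc[ia])]])
    for (b in partners) {
      L <- junction_run_length(ts, a, b)
      if (is.finite(L) && L > best_len) { best <- c(a, b); best_len <- L }
    }
  }
  if (is.null(best)) stop("pick_junction_pair(): no junction runs found")
  best
}

#' Build the stiffness-gradient scenario set
#'
#' Cartesian product of transition distances x ramp widths x direction,
#' plus the two uniform controls (1.1 and 11 kPa). `soft_to_stiff` places
#' the manipulated cell on the soft side (E_near = 1.1, E_far = 11 kPa);
#' `stiff_to_soft` mirrors the profile.
#'
#' @param distances transition distances from the pipette origin, um.
#' @param widths ramp widths, um (2 interface, 10 sharp, 50 shallow).
#' @param direction `"soft_to_stiff"` or `"stiff_to_soft"`.
#' @return named list of [stiffness_field()] objects (`uniform_soft` and
#'   `uniform_stiff` controls first).
#' @export
make_gradient_scenarios <- function(distances = c(20, 40, 60, 80),
                                    widths = 2,
                                    direction = c("soft_to_stiff", "stiff_to_soft")) {
  direction <- match.arg(direction)
  if (any(distances <= 0)) stop("make_gradient_scenarios(): distances must be positive")
  En <- if (direction == "soft_to_stiff") 1.1 else 11
  Ef <- if (direction == "soft_to_stiff") 11 else 1.1
  out <- list(uniform_soft = stiffness_field("uniform", 1.1),
              uniform_stiff = stiffness_field("uniform", 11))
  for (w in widths) for (d in distances) {
    kind <- if (w <= 2) "interface" else "gradient"
    out[[sprintf("%s_d%g_w%g", direction, d, w)]] <-
      stiffness_field(kind, E_near = En, E_far = Ef, y_transition = d, width = w)
  }
  out
}
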