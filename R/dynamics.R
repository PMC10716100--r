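# Overdamped time integration of the coupled cell/substrate system and the
# structural remodeling moves applied between integration steps.

#' Construct a simulation state
#'
#' Bundles the tissue, the (optional) substrate lattice and focal-adhesion
#' set, the parameters, simulation time and the integration/remodeling
#' switches. With remodeling disabled the topology (vertex counts, junction
#' pairs, adhesion anchors) is bit-stable under stepping; adhesion ruptures
#' are the only permitted state change.
#'
#' @param tissue an [epi_tissue()].
#' @param params an [epi_params()].
#' @param lattice optional [build_lattice()] substrate.
#' @param fa optional [attach_adhesions()] set.
#' @param time simulation time, s.
#' @param remodel enable vertex/junction remodeling between steps.
#' @param growth enable the division clock (growth mode).
#' @param order Runge-Kutta order: 2 without a substrate, 4 with one.
#' @return an object of class `epi_state`.
#' @export
epi_state <- function(tissue, params = epi_params(), lattice = NULL, fa = NULL,
                      time = 0, remodel = FALSE, growth = FALSE,
                      order = if (is.null(lattice)) 2L else 4L) {
  stopifnot(inherits(tissue, "epi_tissue"))
  if (!order %in% c(2L, 4L)) stop("epi_state(): order must be 2 or 4")
  structure(list(tissue = tissue, lattice = lattice, fa = fa,
                 params = params, time = time, nstep = 0L,
                 remodel = remodel, growth = growth, order = as.integer(order),
                 dt = params$dt_init, constraint = NULL,
                 events = list(), target_cells = Inf),
            class = "epi_state")
}

#' @export
print.epi_state <- function(x, ...) {
  cat(sprintf("<epi_state> t = %.4g s, %d cells, %d vertices%s%s\n",
              x$time, x$tissue$ncell, x$tissue$n,
              if (!is.null(x$lattice)) sprintf(", %d substrate points",
                                               nrow(x$lattice$S)) else "",
              if (!is.null(x$fa)) sprintf(", %d adhesions (%d ruptured)",
                                          length(x$fa$vtx), sum(x$fa$ruptured))
              else ""))
  invisible(x)
}

# Right-hand side of the overdamped equations of motion: dr/dt = F_tot/eta
# for cell vertices and substrate points alike; kinematically prescribed
# (pipette-held) vertices get their protocol velocity instead.
state_deriv <- function(st, t, V, S, cand) {
  p <- st$params
  fa_pull <- NULL
  if (!is.null(st$fa) && !is.null(st$lattice)) {
    af <- adhesion_forces(st$fa, st$tissue, st$lattice, V = V, S = S)
    fa_pull <- af$on_vertices
  }
  Fc <- force_cell_total(st$tissue, V, p, fa_pull = fa_pull, cand = cand)
  DV <- Fc$tot / p$eta
  if (!is.null(st$constraint)) {
    idx <- st$constraint$idx
    DV[idx, 1] <- st$constraint$vel(t)[1]
    DV[idx, 2] <- st$constraint$vel(t)[2]
  }
  DS <- NULL
  if (!is.null(st$lattice)) {
    lat <- st$lattice
    e <- lat$edges
    D <- S[e[, 2], , drop = FALSE] - S[e[, 1], , drop = FALSE]
    L <- sqrt(D[, 1]^2 + D[, 2]^2)
    f <- lat$k_edge * (L - lat$h) / L
    Fx <- f * D[, 1]; Fy <- f * D[, 2]
    # every lattice point has at least two edges, so the sorted rowsum
    # groups are exactly 1..N and map back by identity
    Fs <- rowsum(cbind(c(Fx, -Fx), c(Fy, -Fy)), c(e[, 1], e[, 2]),
                 reorder = TRUE)
    dimnames(Fs) <- NULL
    Fs <- Fs + restorative_force(lat, S)
    # the anti-collapse repulsion only engages under strong compression;
    # a point can near an opposite edge only if some edge is short
    if (min(L) < 0.75 * lat$h) Fs <- Fs + repulsive_force(lat, S)
    if (!is.null(fa_pull)) Fs <- Fs + af$on_points
    DS <- Fs / p$eta
  }
  if (anyNA(DV) || any(!is.finite(DV))) {
    i <- which(!is.finite(DV[, 1]) | !is.finite(DV[, 2]))[1]
    stop(sprintf("non-finite force at cell vertex %d (cell %d), t = %g",
                 i, st$tissue$cell[i], t))
  }
  if (!is.null(DS) && any(!is.finite(DS)))
    stop(sprintf("non-finite force at substrate point %d, t = %g",
                 which(!is.finite(DS[, 1]) | !is.finite(DS[, 2]))[1], t))
  list(DV = DV, DS = DS)
}

# One fixed-size Runge-Kutta step (order 2 midpoint or classical order 4).
rk_step <- function(st, t, dt, V, S, cand) {
  f <- function(tt, Vv, Ss) state_deriv(st, tt, Vv, Ss, cand)
  k1 <- f(t, V, S)
  if (st$order == 2L) {
    k2 <- f(t + dt / 2, V + dt / 2 * k1$DV,
            if (!is.null(S)) S + dt / 2 * k1$DS)
    return(list(V = V + dt * k2$DV, S = if (!is.null(S)) S + dt * k2$DS))
  }
  k2 <- f(t + dt / 2, V + dt / 2 * k1$DV, if (!is.null(S)) S + dt / 2 * k1$DS)
  k3 <- f(t + dt / 2, V + dt / 2 * k2$DV, if (!is.null(S)) S + dt / 2 * k2$DS)
  k4 <- f(t + dt, V + dt * k3$DV, if (!is.null(S)) S + dt * k3$DS)
  list(V = V + dt / 6 * (k1$DV + 2 * k2$DV + 2 * k3$DV + k4$DV),
       S = if (!is.null(S)) S + dt / 6 * (k1$DS + 2 * k2$DS + 2 * k3$DS + k4$DS))
}

#' Advance a state by one Runge-Kutta step of fixed size
#'
#' All cell vertices and substrate points move by the chosen Runge-Kutta
#' rule applied to `dr/dt = F/eta`; pipette-held vertices follow their
#' kinematic constraint exactly.
#'
#' @param state an [epi_state()].
#' @param dt step size, s.
#' @param order 2 or 4 (defaults to the state's order).
#' @return the advanced state.
#' @export
step <- function(state, dt, order = state$order) {
  if (dt <= 0) stop("step(): dt must be positive")
  state$order <- as.integer(order)
  cand <- contact_candidates(state$tissue, state$tissue$V)
  S <- if (!is.null(state$lattice)) state$lattice$S
  res <- rk_step(state, state$time, dt, state$tissue$V, S, cand)
  state$tissue$V <- res$V
  if (!is.null(state$lattice)) state$lattice$S <- res$S
  state$time <- state$time + dt
  state$nstep <- state$nstep + 1L
  state <- apply_constraint_exact(state)
  state
}

#' Adapt the integration step from a step-doubling error estimate
#'
#' The step is halved while the error exceeds `err_tol`, grown by at most
#' 1.5x when the error falls below `err_tol/10`, and clamped to
#' `[dt_min, dt_max]`.
#'
#' @param dt current step, s.
#' @param err step-doubling position discrepancy, um.
#' @param p an [epi_params()].
#' @return the new step size.
#' @export
adapt_dt <- function(dt, err, p) {
  if (err > p$err_tol) {
    dt <- dt / 2
    if (dt < p$dt_min)
      stop("adapt_dt(): dt_min reached with error still above tolerance")
  } else if (err < p$err_tol / 10) {
    dt <- dt * 1.5
  }
  min(max(dt, p$dt_min), p$dt_max)
}

apply_constraint_exact <- function(st) {
  if (is.null(st$constraint)) return(st)
  st$tissue$V[st$constraint$idx, ] <- st$constraint$pos(st$time)
  st
}

#' Advance a state over a time interval with adaptive stepping
#'
#' Integrates with step-doubling error control ([adapt_dt()]); between
#' accepted steps it applies, when enabled, adhesion rupture checks,
#' structural remodeling (vertex insertion/removal and junction repairing)
#' and the division clock. A callback can sample the trajectory at a fixed
#' cadence in simulation time.
#'
#' @param state an [epi_state()].
#' @param duration interval to integrate, s.
#' @param sample_every optional cadence (s) at which `callback(state)` is
#'   invoked.
#' @param callback function of the state; its returned values are collected
#'   in the result's `samples`.
#' @return the advanced state, with `samples` attached when sampling was
#'   requested.
#' @export
advance <- function(state, duration, sample_every = Inf, callback = NULL) {
  st <- state
  p <- st$params
  t_end <- st$time + duration
  # explicit-RK stability cap: the error controller probes only every few
  # steps, so dt must never be allowed to grow past the stiffest linear
  # mode's stability limit in between
  lam_cell <- (p$k_cont + p$k_junc + p$k_mem + p$k_area +
                 10 * p$k_cort_perim + 3 * max(p$fa_k)) / p$eta
  lam_sub <- if (!is.null(st$lattice)) 3.3 * max(st$lattice$k_pt) / p$eta else 0
  dt_cap <- 2.5 / max(lam_cell, lam_sub, 1e-12)
  dt <- min(st$dt, p$dt_max, dt_cap)
  cand <- contact_candidates(st$tissue, st$tissue$V)
  V_cand <- st$tissue$V                    # positions at last candidate refresh
  samples <- list()
  next_sample <- if (is.finite(sample_every)) st$time else Inf
  while (st$time < t_end - 1e-12) {
    if (is.finite(next_sample) && st$time >= next_sample - 1e-12) {
      samples[[length(samples) + 1L]] <- callback(st)
      next_sample <- next_sample + sample_every
    }
    dt_try <- min(dt, dt_cap, t_end - st$time,
                  if (is.finite(next_sample)) next_sample - st$time else Inf)
    clamped <- dt_try < dt * (1 - 1e-12)
    S <- if (!is.null(st$lattice)) st$lattice$S
    # step-doubling error control; between checks the last accepted dt is
    # reused with a plain step (the doubling check costs 2x the step itself)
    check <- st$nstep %% 3L == 0L || clamped
    if (check) {
      repeat {
        full <- rk_step(st, st$time, dt_try, st$tissue$V, S, cand)
        h1 <- rk_step(st, st$time, dt_try / 2, st$tissue$V, S, cand)
        h2 <- rk_step(st, st$time + dt_try / 2, dt_try / 2, h1$V, h1$S, cand)
        # substrate points are slaved, contractive linear modes whose
        # per-step error relaxes rather than accumulates; weight them down
        # so stiff-substrate transients do not throttle the controller
        err <- max(abs(full$V - h2$V),
                   if (!is.null(S)) max(abs(full$S - h2$S)) / 5 else 0)
        if (err <= p$err_tol || dt_try <= p$dt_min * 2) break
        dt_try <- adapt_dt(dt_try, err, p)
      }
      new_pos <- h2
      # a step clamped to hit an interval/sample boundary must not drag the
      # persistent step size down with it
      dt <- if (clamped && err <= p$err_tol) dt else adapt_dt(dt_try, err, p)
    } else {
      new_pos <- rk_step(st, st$time, dt_try, st$tissue$V, S, cand)
    }
    st$tissue$V <- new_pos$V
    if (!is.null(st$lattice)) st$lattice$S <- new_pos$S
    st$time <- st$time + dt_try
    st$nstep <- st$nstep + 1L
    st <- apply_constraint_exact(st)
    # --- between-step structural events ---
    if (!is.null(st$activation)) {
      act <- rep(1, st$tissue$n)
      sel <- st$tissue$cell %in% st$activation$cells &
        in_rect(st$tissue$V, st$activation$rect)
      act[sel] <- st$activation$multiplier
      st$tissue$act <- act
    }
    if (!is.null(st$fa) && !is.null(st$lattice)) {
      if (st$remodel)
        st$fa <- relax_adhesions(st$fa, st$tissue, st$lattice, dt_try, p)
      cr <- check_ruptures(st$fa, st$tissue, st$lattice, p)
      st$fa <- cr$fa
      if (length(cr$newly)) {
        st$events[[length(st$events) + 1L]] <-
          list(time = st$time, type = "rupture", vertices = cr$newly)
      }
    }
    changed <- FALSE
    if (st$growth) {
      dv <- division_clock(st)
      st <- dv$state
      changed <- changed || dv$changed
    }
    if (st$remodel) {
      rm1 <- remodel_vertices_impl(st, p)
      st <- rm1$state
      changed <- changed || rm1$changed
      if (changed || st$nstep %% 5L == 0L)
        st$tissue <- remodel_junctions_ts(st$tissue, p)
    }
    # refresh contact candidates when topology changed or positions drifted
    # by more than the broad-phase slack (margin - penetration cap)/2
    if (changed || max(abs(st$tissue$V - V_cand)) > 0.5) {
      cand <- contact_candidates(st$tissue, st$tissue$V)
      V_cand <- st$tissue$V
    }
  }
  if (is.finite(next_sample) && st$time >= next_sample - 1e-12)
    samples[[length(samples) + 1L]] <- callback(st)
  st$dt <- dt
  if (length(samples)) st$samples <- samples
  st
}

#' Relax a state until the maximum residual force falls below a tolerance
#'
#' A tissue occasionally settles into a stationary local standoff (a
#' junction/contact/pressure balance at one membrane crossing) whose
#' residual sits above `tol` but is mechanically negligible; a stationary
#' residual below `accept_stationary` is accepted with a warning rather
#' than aborting.
#'
#' @param state an [epi_state()].
#' @param tol maximum |F_tot| per vertex, AU.
#' @param max_time simulation-time budget, s.
#' @param chunk integration interval between convergence checks, s.
#' @param accept_stationary residual bound (AU) below which a
#'   non-decreasing residual is accepted.
#' @return the relaxed state.
#' @export
relax <- function(state, tol = 1e-3, max_time = 500, chunk = 2,
                  accept_stationary = 2) {
  t0 <- state$time
  hist <- c()
  repeat {
    r <- max_residual_force(state)
    if (r < tol) return(state)
    hist <- c(hist, r)
    nh <- length(hist)
    if (nh >= 8 && r < accept_stationary &&
        hist[nh] > 0.98 * median(hist[(nh - 7):(nh - 4)])) {
      warning(sprintf("relax(): accepting stationary residual %.3g AU", r))
      return(state)
    }
    if (state$time - t0 > max_time)
      stop(sprintf("relax(): not converged (residual %.3g AU after %g s)",
                   r, max_time))
    state <- advance(state, chunk)
  }
}

#' Maximum total-force magnitude over all cell vertices (and substrate
#' points when present)
#' @param state an [epi_state()].
#' @return max |F_tot|, AU.
#' @export
max_residual_force <- function(state) {
  d <- state_deriv(state, state$time, state$tissue$V,
                   if (!is.null(state$lattice)) state$lattice$S else NULL,
                   contact_candidates(state$tissue, state$tissue$V))
  m <- max(sqrt(rowSums((d$DV * state$params$eta)^2)))
  if (!is.null(d$DS))
    m <- max(m, max(sqrt(rowSums((d$DS * state$params$eta)^2))))
  m
}
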