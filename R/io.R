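# Configuration, snapshot serialization and run manifests.
#
# Configs are YAML with a versioned schema and fully documented defaults;
# unknown keys are rejected. Snapshots are versioned JSON carrying every
# array at full (17-significant-digit) precision, so a reloaded state
# continues bit-identically.

CONFIG_VERSION <- "1.0"
SNAPSHOT_VERSION <- "1.0"

config_defaults <- function() {
  list(
    version = CONFIG_VERSION,
    scenario = "grow",                 # grow | manipulate | optogenetic
    seed = 1L,
    target_cells = 30L,
    params = list(),                   # epi_params() overrides
    stiffness = list(kind = "uniform", E_near = 1.1, E_far = 1.1,
                     y_transition = 40, width = 2),
    pipette = list(distance = 30, speed = 30, grab_radius = 4,
                   hold_after = 1),
    activation = list(multiplier = 13, t_on = 120, t_off = 1320,
                      duration = 1560),
    out_dir = ".",
    snapshot_every = Inf
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML config, rejects unknown keys, fills all defaults and
#' validates the result (including parameter overrides). Stiffness outside
#' the calibrated 1.1-11 kPa range loads with a prominent warning: the
#' substrate model is not validated there.
#'
#' @param path YAML file, or a named list already in memory.
#' @return a fully resolved object of class `run_config`.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  def <- config_defaults()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stop("load_config(): unknown key(s): ", paste(unknown, collapse = ", "))
  for (blk in c("stiffness", "pipette", "activation")) {
    if (!is.null(raw[[blk]])) {
      bad <- setdiff(names(raw[[blk]]), names(def[[blk]]))
      if (length(bad))
        stop("load_config(): unknown key(s) in '", blk, "': ",
             paste(bad, collapse = ", "))
      def[[blk]][names(raw[[blk]])] <- raw[[blk]]
    }
  }
  for (k in setdiff(names(raw), c("stiffness", "pipette", "activation")))
    def[[k]] <- raw[[k]]
  if (!def$scenario %in% c("grow", "manipulate", "optogenetic"))
    stop("load_config(): scenario must be grow, manipulate or optogenetic")
  if (!is.numeric(def$seed)) stop("load_config(): seed must be an integer")
  do.call(epi_params, def$params)      # validates override names and values
  Es <- c(def$stiffness$E_near, def$stiffness$E_far)
  if (any(Es < 1.1 - 1e-9) || any(Es > 11 + 1e-9))
    warning("load_config(): stiffness ", paste(unique(Es), collapse = "/"),
            " kPa is outside the validated 1.1-11 kPa range; the substrate ",
            "model is known to fail at high stiffness", call. = FALSE)
  structure(def, class = "run_config")
}

#' Write a configuration to YAML
#' @param config a `run_config`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$snapshot_every <- if (is.finite(cfg$snapshot_every))
    cfg$snapshot_every else "Inf"
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# ---- snapshots ------------------------------------------------------------

num <- function(x) {
  # full-precision, locale-independent numeric serialization
  if (is.matrix(x)) list(dim = dim(x), data = sprintf("%.17g", as.vector(x)))
  else sprintf("%.17g", x)
}

denum <- function(x) {
  if (is.list(x) && !is.null(x$dim))
    matrix(as.numeric(x$data), nrow = x$dim[[1]], ncol = x$dim[[2]])
  else as.numeric(x)
}

#' Save a simulation state to a versioned JSON snapshot
#'
#' Lossless round trip of cells, substrate lattice, adhesions, RNG state
#' and simulation time: all floating-point payloads are serialized with 17
#' significant digits, so continuing a reloaded state is bit-identical to
#' continuing the original.
#'
#' @param state an [epi_state()].
#' @param path output file (.json).
#' @return the path, invisibly.
#' @export
save_snapshot <- function(state, path) {
  ts <- state$tissue
  if (is.null(ts) || ts$ncell < 1 || ts$n < 3)
    stop("save_snapshot(): refusing to save an empty epithelium")
  tissue_validate(ts)
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  obj <- list(
    version = SNAPSHOT_VERSION,
    time = num(state$time), nstep = state$nstep, dt = num(state$dt),
    order = state$order, remodel = state$remodel, growth = state$growth,
    target_cells = if (is.finite(state$target_cells))
      state$target_cells else "Inf",
    center_cell = state$center_cell,
    params = lapply(unclass(state$params), num),
    tissue = list(
      V = num(ts$V), cell = ts$cell, clen = ts$clen, l0 = num(ts$l0),
      junc = ifelse(is.na(ts$junc), -1L, ts$junc), bnd = ts$bnd,
      ref = num(ts$ref), act = num(ts$act), A0 = num(ts$A0), P0 = num(ts$P0),
      t_next_div = ifelse(is.finite(ts$t_next_div),
                          num(ts$t_next_div), "Inf")
    ),
    lattice = if (!is.null(state$lattice)) {
      lat <- state$lattice
      list(extent = num(lat$extent), h = num(lat$h), E = num(lat$E),
           S = num(lat$S), nu = num(lat$nu), thickness = num(lat$thickness))
    },
    fa = if (!is.null(state$fa)) {
      list(vtx = state$fa$vtx, tri = state$fa$tri[, 1:3],
           w = num(state$fa$w), strength = num(state$fa$strength),
           ruptured = state$fa$ruptured, slack = num(state$fa$slack),
           pending = state$fa$pending)
    },
    rng = rng
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Load a simulation state from a snapshot
#'
#' Refuses snapshots of a different schema version, naming both versions.
#' Restores the RNG state so stochastic continuation matches the original
#' process.
#'
#' @param path snapshot file from [save_snapshot()].
#' @return an [epi_state()].
#' @export
load_snapshot <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(obj$version), SNAPSHOT_VERSION))
    stop(sprintf("load_snapshot(): snapshot version %s does not match supported version %s",
                 obj$version, SNAPSHOT_VERSION))
  pl <- lapply(obj$params, function(x)
    if (is.character(x) || is.numeric(x)) suppressWarnings(as.numeric(x)) else x)
  p <- do.call(epi_params, pl)
  tj <- obj$tissue
  ncell <- length(tj$clen)
  cstart <- cumsum(c(1L, tj$clen[-ncell]))
  n <- sum(tj$clen)
  ts <- list(
    n = n, ncell = ncell, V = denum(tj$V), cell = as.integer(tj$cell),
    cstart = as.integer(cstart), clen = as.integer(tj$clen),
    nxt = integer(n), prv = integer(n), l0 = denum(tj$l0),
    junc = ifelse(tj$junc < 0, NA_integer_, as.integer(tj$junc)),
    bnd = as.logical(tj$bnd), ref = denum(tj$ref), act = denum(tj$act),
    A0 = denum(tj$A0), P0 = denum(tj$P0),
    t_next_div = suppressWarnings(
      ifelse(tj$t_next_div == "Inf", Inf, as.numeric(tj$t_next_div))),
    div = vector("list", ncell)
  )
  for (ci in seq_len(ncell)) {
    idx <- cstart[ci]:(cstart[ci] + tj$clen[ci] - 1L)
    ts$nxt[idx] <- c(idx[-1], idx[1])
    ts$prv[idx] <- c(idx[length(idx)], idx[-length(idx)])
  }
  class(ts) <- "epi_tissue"
  lat <- NULL
  if (!is.null(obj$lattice)) {
    lj <- obj$lattice
    lat <- build_lattice(denum(lj$extent), denum(lj$h), p = epi_params(
      nu = denum(lj$nu), substrate_thickness = denum(lj$thickness)))
    lat$E <- denum(lj$E)
    lat <- lattice_set_constants(lat)
    lat$S <- denum(lj$S)
  }
  fa <- NULL
  if (!is.null(obj$fa)) {
    fa <- structure(list(
      vtx = as.integer(obj$fa$vtx),
      tri = matrix(as.integer(as.matrix(obj$fa$tri)), ncol = 3),
      w = denum(obj$fa$w), strength = denum(obj$fa$strength),
      ruptured = as.logical(obj$fa$ruptured),
      slack = denum(obj$fa$slack),
      pending = as.logical(obj$fa$pending)
    ), class = "focal_adhesions")
  }
  st <- epi_state(ts, params = p, lattice = lat, fa = fa,
                  time = denum(obj$time), remodel = obj$remodel,
                  growth = obj$growth, order = obj$order)
  st$nstep <- as.integer(obj$nstep)
  st$dt <- denum(obj$dt)
  st$target_cells <- if (identical(obj$target_cells, "Inf")) Inf
    else as.numeric(obj$target_cells)
  st$center_cell <- obj$center_cell
  if (!is.null(obj$rng))
    assign(".Random.seed", as.integer(obj$rng), envir = globalenv())
  st
}

#' Write a run manifest
#'
#' Records the resolved configuration, its hash, the seed and the package
#' version: enough to reproduce the run bit-exactly.
#'
#' @param config a `run_config`.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_manifest <- function(config, path) {
  cfg_str <- yaml::as.yaml(unclass(config))
  obj <- list(
    package = "episheet",
    version = as.character(utils::packageVersion("episheet")),
    config = unclass(config),
    config_hash = sum(utf8ToInt(cfg_str) * seq_along(utf8ToInt(cfg_str))) %%
      .Machine$integer.max,
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
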