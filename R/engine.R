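# State container, operator sequencing, replicates and persistence.
#
# One engine step applies, in order: (1) on its cadence, the stochastic
# column perturbation of the chemical matrices; (2) vascular remodeling
# F_vr; (3) metabolism/proliferation/necrosis F_pn, consuming the supply
# rates just computed; (4) the chemical diffusion multiplies F_o, F_gl;
# (5) every kappa steps, tumor-cell invasion F_c; (6) the angiogenesis
# switch update on the post-diffusion fields. Random draws are consumed in a
# fixed documented order (perturbation draws, then r1..r4, then the
# glycolysis-fraction uniforms), so a run is fully determined by its seed,
# and the compiled and pure-R engines consume the identical stream.

#' Initialize a simulation state
#'
#' Builds the nine per-voxel state vectors at time 0: oxygen and glucose
#' stocks at the normal-tissue levels `o0_bar`/`gl0_bar`, supply rates at
#' the normal-tissue balance `M K_o` / `M K_gl` (provision and consumption
#' cancel exactly), capacity caps at their baseline values, no necrotic
#' cells, the angiogenesis switch off, and live tumor cells as seeded
#' (default: `5e5` cells in the central voxel).
#'
#' @param params A [model_params()].
#' @param seeding A data frame with columns `i`, `j`, `k`, `cells`; default
#'   seeds `5e5` cells at the lattice center. Use a 0-row data frame for a
#'   pure-host state.
#' @return An object of class `tg_state`: the vectors `l`, `nc`, `nn`, `o`,
#'   `gl`, `o_b`, `gl_b`, `o_b_max`, `gl_b_max`, `sw` plus the clock `t`
#'   (s) and `step_index`.
#' @export
init_state <- function(params, seeding = default_seeding(params)) {
  nv <- params$spec$nvox
  l <- numeric(nv)
  if (nrow(seeding)) {
    stopifnot(all(c("i", "j", "k", "cells") %in% names(seeding)))
    if (any(seeding$cells > params$M_max)) {
      stop("seeded population exceeds M_max in some voxel")
    }
    idx <- linear_index(as.matrix(seeding[, c("i", "j", "k")]), params$n)
    l[idx] <- l[idx] + seeding$cells
  }
  state <- structure(list(
    l = l, nc = numeric(nv), nn = numeric(nv),
    o = rep(params$o0_bar, nv), gl = rep(params$gl0_bar, nv),
    o_b = rep(params$M * params$K_o, nv),
    gl_b = rep(params$M * params$K_gl, nv),
    o_b_max = rep(params$o_b_max0, nv),
    gl_b_max = rep(params$gl_b_max0, nv),
    sw = integer(nv), t = 0, step_index = 0L
  ), class = "tg_state")
  validate_state(state, params, "init_state")
  state
}

#' @rdname init_state
#' @export
default_seeding <- function(params) {
  ctr <- as.integer(ceiling(params$n / 2))
  data.frame(i = ctr, j = ctr, k = ctr, cells = 5e5)
}

#' Validate state invariants
#'
#' Checks nonnegativity of populations, stocks and caps, the supply-rate
#' clipping contract `|o_b| <= o_b_max`, `|gl_b| <= gl_b_max`, and vector
#' lengths. Called after every operator when a run has
#' `debug_invariants = TRUE`.
#'
#' @param state A `tg_state`.
#' @param params A [model_params()].
#' @param where Label used in error messages (typically the operator name).
#' @return The state, invisibly; errors on violation.
#' @export
validate_state <- function(state, params, where = "state") {
  nv <- params$spec$nvox
  vecs <- c("l", "nc", "nn", "o", "gl", "o_b", "gl_b", "o_b_max",
            "gl_b_max", "sw")
  for (v in vecs) {
    if (length(state[[v]]) != nv) {
      stop(sprintf("%s: vector '%s' has length %d, expected %d",
                   where, v, length(state[[v]]), nv))
    }
  }
  tol <- 1e-9
  for (v in c("l", "nc", "nn", "o", "gl", "o_b_max", "gl_b_max")) {
    if (any(state[[v]] < -tol * max(1, max(abs(state[[v]]))))) {
      stop(sprintf("%s: vector '%s' has negative entries", where, v))
    }
  }
  if (any(abs(state$o_b) > state$o_b_max * (1 + 1e-12) + 1e-12) ||
      any(abs(state$gl_b) > state$gl_b_max * (1 + 1e-12) + 1e-12)) {
    stop(sprintf("%s: supply rate exceeds its capacity cap", where))
  }
  invisible(state)
}

#' Build the diffusion operators for a parameter set
#'
#' Estimates the oxygen, glucose and cell transition kernels by Monte Carlo
#' (on a private RNG stream seeded from `params$kernel_seed`, leaving the
#' caller's stream untouched) and assembles the three sparse operators:
#' fixed-Dirichlet chemical matrices `T_o`, `T_gl` and the reflecting,
#' column-stochastic cell matrix `T_c`.
#'
#' @param params A [model_params()].
#' @return An object of class `tg_operators` with fields `To`, `Tgl`, `Tc`
#'   and `kernels`.
#' @export
build_operators <- function(params) {
  spec <- params$spec
  ko <- sample_isotropic_kernel(params$D_o, spec, params$kernel_n,
                                params$kernel_seed)
  kgl <- sample_isotropic_kernel(params$D_gl, spec, params$kernel_n,
                                 params$kernel_seed + 1)
  kc <- sample_anisotropic_kernel(params$tensor, spec, params$kernel_n,
                                  params$kernel_seed + 2)
  To <- build_chemical_matrix(ko, spec, species = "oxygen")
  Tgl <- build_chemical_matrix(kgl, spec, species = "glucose")
  structure(list(
    To = To,
    Tgl = Tgl,
    Tc = build_cell_matrix(kc, spec),
    # pristine value arrays: each perturbation event re-derives the active
    # columns from the nominal matrices, so deviations stay bounded by the
    # perturbation magnitude instead of accumulating into a random walk
    To_base_x = To$T@x,
    Tgl_base_x = Tgl$T@x,
    kernels = list(oxygen = ko, glucose = kgl, cells = kc)
  ), class = "tg_operators")
}

# Voxels in or adjacent to the tumor (l + nc > 0), the set whose chemical
# matrix columns are perturbed.
tumor_vicinity <- function(state, ops) {
  w <- (state$l + state$nc) > 0
  as.logical(w | as.numeric(ops$Tc$T %*% w) > 0)
}

#' One engine step (pure-R reference path)
#'
#' Applies the full operator sequence once. This is the reference
#' implementation the compiled engine is checked against; both consume
#' random draws in the identical order.
#'
#' @param state A `tg_state`.
#' @param ops A `tg_operators` (may be modified by the column
#'   perturbation).
#' @param params A [model_params()].
#' @param debug_invariants Validate state invariants after each operator.
#' @return A list with the advanced `state` and the (possibly perturbed)
#'   `ops`.
#' @export
tg_step <- function(state, ops, params, debug_invariants = FALSE) {
  s <- state$step_index + 1L
  nv <- params$spec$nvox
  if (params$perturb_period > 0L && params$perturb_magnitude > 0 &&
      s %% params$perturb_period == 0L) {
    active <- tumor_vicinity(state, ops)
    ops$To$T@x <- ops$To_base_x     # restart from the nominal kernel
    ops$Tgl$T@x <- ops$Tgl_base_x
    ops$To <- perturb_columns(ops$To, active, params$perturb_magnitude)
    ops$Tgl <- perturb_columns(ops$Tgl, active, params$perturb_magnitude)
  }
  r <- cbind(stats::runif(nv), stats::runif(nv),
             stats::runif(nv), stats::runif(nv))
  state <- apply_vascular_remodeling(state, params, r = r)
  if (debug_invariants) validate_state(state, params, "F_vr")
  u <- stats::runif(nv)
  state <- apply_metabolism(state, params, u = u)
  if (debug_invariants) validate_state(state, params, "F_pn")
  state$o <- apply_transition(ops$To, state$o, t = state$t)
  state$gl <- apply_transition(ops$Tgl, state$gl, t = state$t)
  if (debug_invariants) validate_state(state, params, "F_o/F_gl")
  if (s %% params$kappa == 0L) {
    state$l <- apply_cell_diffusion(state$l, state$nc, state$nn, ops$Tc,
                                    params$M_max)
    if (debug_invariants) validate_state(state, params, "F_c")
  }
  state$sw <- update_switch(state, params)
  state$t <- state$t + params$delta_tau
  state$step_index <- s
  list(state = state, ops = ops)
}

summarize_state <- function(state, params) {
  data.frame(
    step = state$step_index,
    t_days = state$t / 86400,
    live = sum(state$l),
    necrotic_tumor = sum(state$nc),
    necrotic_host = sum(state$nn),
    hypoxic = sum(state$o < params$h_o * params$o0_bar),
    hypoglycemic = sum(state$gl < params$h_gl * params$gl0_bar)
  )
}

#' Run a simulation
#'
#' Advances a state `n_steps` steps, recording per-interval summaries
#' (default: once per simulated day). The compiled engine and the pure-R
#' engine produce the same trajectory for the same seed.
#'
#' @param params A [model_params()].
#' @param n_steps Number of steps (`>= 0`); 90 days at `delta_tau = 10` is
#'   777600 steps.
#' @param seed Integer seed for the run (`set.seed`); `NULL` continues the
#'   current stream.
#' @param ops Prebuilt [build_operators()] object (rebuilt if `NULL`). The
#'   run perturbs a private copy; the argument is not modified.
#' @param state Initial state; default [init_state()].
#' @param record_every Summary cadence in steps; default one simulated day.
#' @param engine `"compiled"` (C++ inner loop) or `"r"` (pure-R reference).
#' @param callback Optional function `(state, summary_row)` invoked at every
#'   record point.
#' @param snapshot_every Optional cadence (steps; rounded to record points)
#'   at which full state copies are kept in the result.
#' @param debug_invariants Validate invariants (per operator in the R
#'   engine, per record in the compiled engine).
#' @return An object of class `tg_run`: `summary` (data frame with one row
#'   per record, the first at step 0), `final_state`, `snapshots`,
#'   `params`, `n_steps`.
#' @export
run <- function(params, n_steps, seed = NULL, ops = NULL, state = NULL,
                record_every = NULL, engine = c("compiled", "r"),
                callback = NULL, snapshot_every = NULL,
                debug_invariants = FALSE) {
  engine <- match.arg(engine)
  stopifnot(n_steps >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ops)) ops <- build_operators(params)
  if (is.null(state)) state <- init_state(params)
  if (is.null(record_every)) {
    record_every <- max(1L, as.integer(round(86400 / params$delta_tau)))
  }
  start <- state$step_index
  bounds <- start + unique(c(seq_len(n_steps %/% record_every) * record_every,
                             n_steps))
  bounds <- bounds[bounds > start]
  rows <- list(summarize_state(state, params))
  if (!is.null(callback)) callback(state, rows[[1L]])
  snapshots <- list()
  for (b in bounds) {
    chunk <- b - state$step_index
    if (engine == "compiled") {
      res <- cpp_run_chunk(state, ops, params, chunk)
      state <- res$state
      ops <- res$ops
      if (debug_invariants) validate_state(state, params, "compiled chunk")
    } else {
      for (ii in seq_len(chunk)) {
        res <- tg_step(state, ops, params, debug_invariants = debug_invariants)
        state <- res$state
        ops <- res$ops
      }
    }
    row <- summarize_state(state, params)
    rows[[length(rows) + 1L]] <- row
    if (!is.null(callback)) callback(state, row)
    if (!is.null(snapshot_every) && b %% snapshot_every == 0L) {
      snapshots[[as.character(b)]] <- state
    }
  }
  structure(list(summary = do.call(rbind, rows), final_state = state,
                 snapshots = snapshots, params = params, n_steps = n_steps,
                 record_every = record_every, engine = engine),
            class = "tg_run")
}

# Bridge to the compiled inner loop: passes the CSC slots of the three
# operators; perturbation inside the chunk mutates copies of the chemical
# matrices' value arrays, which are written back here.
cpp_run_chunk <- function(state, ops, params, n_steps) {
  p <- params
  res <- run_chunk_cpp(
    state, ops$To$T@p, ops$To$T@i, ops$To$T@x, ops$To_base_x,
    ops$Tgl$T@p, ops$Tgl$T@i, ops$Tgl$T@x, ops$Tgl_base_x,
    ops$Tc$T@p, ops$Tc$T@i, ops$Tc$T@x,
    list(delta_tau = p$delta_tau, M = p$M, M_max = p$M_max, K_o = p$K_o,
         K_gl = p$K_gl, K_ATP = p$K_ATP, lambda = p$lambda, cc = p$cc,
         a_max = p$a_max, beta1 = p$beta1, beta2 = p$beta2, v_r = p$v_r,
         v_e = p$v_e, h_o = p$h_o, h_gl = p$h_gl, o0_bar = p$o0_bar,
         gl0_bar = p$gl0_bar, kappa = p$kappa,
         perturb_period = p$perturb_period,
         perturb_magnitude = p$perturb_magnitude),
    as.integer(n_steps), as.integer(state$step_index))
  st <- state
  for (v in c("l", "nc", "nn", "o", "gl", "o_b", "gl_b", "o_b_max",
              "gl_b_max")) {
    st[[v]] <- res[[v]]
  }
  st$sw <- as.integer(res$sw)
  st$t <- state$t + n_steps * params$delta_tau
  st$step_index <- state$step_index + as.integer(n_steps)
  ops$To$T@x <- res$To_x
  ops$Tgl$T@x <- res$Tgl_x
  list(state = st, ops = ops)
}

#' Run a replicate ensemble
#'
#' Runs `n_replicates` independent simulations (replicate `i` is seeded with
#' `base_seed + i`), sharing one operator build, and summarizes them the way
#' ensemble studies of stochastic tumor growth are reported: the survival
#' probability (fraction of replicates with a nonzero final live population),
#' the expected final live population conditioned on survival, the sorted
#' final populations, and per-record expected live-cell trajectories.
#'
#' @param params A [model_params()].
#' @param n_steps Steps per replicate.
#' @param n_replicates Number of replicates.
#' @param base_seed Integer; replicate `i` uses seed `base_seed + i`.
#' @param ... Passed to [run()] (e.g. `record_every`, `engine`).
#' @return An object of class `tg_ensemble`: `finals` (final live counts per
#'   replicate), `survival`, `conditional_mean` (`NA` if all replicates went
#'   extinct), `trajectories` (long data frame: per replicate per record),
#'   `params`, `base_seed`.
#' @export
run_ensemble <- function(params, n_steps, n_replicates = 20, base_seed = 1,
                         ...) {
  stopifnot(n_replicates >= 1)
  ops <- build_operators(params)
  finals <- numeric(n_replicates)
  traj <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    res <- run(params, n_steps, seed = base_seed + i, ops = ops, ...)
    finals[i] <- res$summary$live[nrow(res$summary)]
    traj[[i]] <- cbind(replicate = i, res$summary)
  }
  surviving <- finals > 0
  structure(list(
    finals = finals,
    survival = mean(surviving),
    conditional_mean = if (any(surviving)) mean(finals[surviving]) else NA_real_,
    trajectories = do.call(rbind, traj),
    n_replicates = n_replicates, n_steps = n_steps,
    params = params, base_seed = base_seed
  ), class = "tg_ensemble")
}

#' @export
print.tg_run <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(paste0("<tg_run> %d steps (%.3g days), N = %d, engine = %s\n",
                     "  final: %.4g live, %.4g necrotic tumor, %.4g necrotic host cells\n"),
              x$n_steps, x$n_steps * x$params$delta_tau / 86400, x$params$n,
              x$engine, last$live, last$necrotic_tumor, last$necrotic_host))
  invisible(x)
}

#' @export
print.tg_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<tg_ensemble> %d replicates x %d steps\n",
                     "  survival probability %.2f; conditional mean final live cells %.4g\n"),
              x$n_replicates, x$n_steps, x$survival, x$conditional_mean))
  invisible(x)
}

#' Write and read plain-text state snapshots
#'
#' `write_state()` stores the nine state vectors plus the switch as one CSV
#' (one column per vector, voxels in linear-index order) and a JSON sidecar
#' (`<path>.json`) with the clock and lattice side; `read_state()` restores
#' the `tg_state`.
#'
#' @param state A `tg_state`.
#' @param path CSV file path.
#' @return `write_state()` the path, invisibly; `read_state()` a
#'   `tg_state`.
#' @export
write_state <- function(state, path) {
  df <- as.data.frame(unclass(state)[c("l", "nc", "nn", "o", "gl", "o_b",
                                       "gl_b", "o_b_max", "gl_b_max", "sw")])
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(t = state$t, step_index = state$step_index),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  state <- c(as.list(df), list(t = meta$t,
                               step_index = as.integer(meta$step_index)))
  state$sw <- as.integer(state$sw)
  structure(state, class = "tg_state")
}
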