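# The vascular-remodeling operator: stochastic relaxation of the supply
# rates toward blood/tissue concentration balance, capacity evolution under
# tumor-induced regression and angiogenesis, and the angiogenesis switch.

#' Symmetric clipping
#'
#' `clip(x, mu)` clamps `x` to the interval `[-mu, mu]`. Used to bound
#' vascular supply rates by the local network capacity.
#'
#' @param x Numeric vector.
#' @param mu Nonnegative bound (scalar or vector).
#' @return The clamped values.
#' @examples
#' clip(c(-7, 3, 7), 5)
#' @export
clip <- function(x, mu) {
  stopifnot(all(mu >= 0))
  pmin(pmax(x, -mu), mu)
}

#' Angiogenesis switch
#'
#' A voxel's switch is on exactly when it contains live tumor cells and its
#' oxygen or glucose stock is below the hypoxia/hypoglycemia threshold
#' (`h_o * o0_bar`, `h_gl * gl0_bar`). Recomputed at the end of every full
#' engine step, after diffusion.
#'
#' @param state A simulation state ([init_state()]).
#' @param params A [model_params()].
#' @return An integer 0/1 vector of length `n^3`.
#' @export
update_switch <- function(state, params) {
  as.integer(state$l > 0 &
               (state$o < params$h_o * params$o0_bar |
                  state$gl < params$h_gl * params$gl0_bar))
}

#' Vascular-remodeling operator
#'
#' Computes the supply rates and capacity caps for the coming interval.
#' Every voxel's supply rate relaxes toward blood/tissue balance by a random
#' fraction of the concentration imbalance:
#' `o_b' = o_b + r1 (o0_bar - o) / dt` (and analogously for glucose with
#' `r2`). In voxels the tumor has reached (`l + nc > 0`) the capacity caps
#' are multiplied by `1 - f_r r3 v_r + sw f_e r4 v_e` with the linear
#' occupancy fractions `f_r = (l + nc)/M` and
#' `f_e = (M - l - nc - nn)/M`, both sanity-clamped to `[0, 1]`; both
#' species' caps evolve by the same factor, so they stay proportional.
#' Tumor-free voxels keep their caps. Finally each supply rate is clipped to
#' `[-cap, cap]` by [clip()].
#'
#' @param state A simulation state.
#' @param params A [model_params()].
#' @param r Optional `n^3 x 4` matrix of Uniform(0, 1) draws (columns
#'   `r1..r4`); pass fixed values to make the operator deterministic.
#'   Default: drawn from the current RNG stream in column order.
#' @return The state with `o_b`, `gl_b`, `o_b_max`, `gl_b_max` updated.
#' @export
apply_vascular_remodeling <- function(state, params, r = NULL) {
  nv <- length(state$l)
  if (is.null(r)) {
    r <- cbind(stats::runif(nv), stats::runif(nv),
               stats::runif(nv), stats::runif(nv))
  }
  stopifnot(is.matrix(r), nrow(r) == nv, ncol(r) == 4L)
  dt <- params$delta_tau
  ob_bar <- state$o_b + r[, 1L] * ((params$o0_bar - state$o) / dt)
  glb_bar <- state$gl_b + r[, 2L] * ((params$gl0_bar - state$gl) / dt)
  reached <- (state$l + state$nc) > 0
  ob_max <- state$o_b_max
  glb_max <- state$gl_b_max
  if (any(reached)) {
    idx <- which(reached)
    f_r <- pmin(pmax((state$l[idx] + state$nc[idx]) / params$M, 0), 1)
    f_e <- pmin(pmax((params$M - state$l[idx] - state$nc[idx] -
                        state$nn[idx]) / params$M, 0), 1)
    fac <- 1 - f_r * r[idx, 3L] * params$v_r +
      state$sw[idx] * f_e * r[idx, 4L] * params$v_e
    ob_max[idx] <- pmax(fac * state$o_b_max[idx], 0)
    glb_max[idx] <- pmax(fac * state$gl_b_max[idx], 0)
  }
  state$o_b <- clip(ob_bar, ob_max)
  state$gl_b <- clip(glb_bar, glb_max)
  state$o_b_max <- ob_max
  state$gl_b_max <- glb_max
  state
}
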