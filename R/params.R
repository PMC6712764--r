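# Model parameters: every symbol of the simulation in one validated object,
# with the derived ATP consumption rate.

#' ATP consumption rate of a normal cell
#'
#' From the stoichiometry of clean combustion (1 glucose + 6 O2 -> 36 ATP)
#' and glycolysis (1 glucose -> 2 ATP), a normal cell consuming oxygen at
#' `K_o` and glucose at `K_gl` consumes ATP at
#' `K_ATP = (17/3) K_o + 2 K_gl` (all rates in pmol/s): `K_o/6` of the
#' glucose is burned with the oxygen yielding `6 K_o` ATP, and the remaining
#' `K_gl - K_o/6` glucose is glycolysed yielding `2 K_gl - K_o/3` ATP.
#'
#' @param K_o Oxygen consumption rate of a normal cell (pmol/s).
#' @param K_gl Glucose consumption rate of a normal cell (pmol/s).
#' @return `K_ATP` in pmol/s.
#' @examples
#' k_atp(250e-6, 50e-6)
#' @export
k_atp <- function(K_o, K_gl) {
  stopifnot(K_o >= 0, K_gl >= 0)
  (17 / 3) * K_o + 2 * K_gl
}

#' Vasculature rates from half- and doubling times
#'
#' The per-step maximum regression rate `v_r` giving capacity halving over
#' `days` when regression proceeds at full rate, and the per-step maximum
#' expansion rate `v_e` giving capacity doubling over `days`:
#' `(1 - v_r)^m = 1/2` and `(1 + v_e)^m = 2` with `m = days * 86400 /
#' delta_tau` steps.
#'
#' @param days Minimum halftime (regression) or doubling time (expansion), in
#'   days.
#' @param delta_tau Time step in seconds.
#' @return The per-step rate.
#' @examples
#' rate_from_halftime(5)  # ~1.6e-5
#' rate_from_doubling(1)  # ~8e-5
#' @export
rate_from_halftime <- function(days, delta_tau = 10) {
  stopifnot(days > 0)
  1 - 0.5^(delta_tau / (days * 86400))
}

#' @rdname rate_from_halftime
#' @export
rate_from_doubling <- function(days, delta_tau = 10) {
  stopifnot(days > 0)
  2^(delta_tau / (days * 86400)) - 1
}

#' Model parameters
#'
#' All tunable constants of the simulator, with defaults reproducing the
#' reference parameterization: a 21-voxel lattice of 2 mm voxels stepped at
#' 10 s; voxel capacities `M = 8e6` cells (maximum `1.02 M`); normal-cell
#' consumption `K_o = 250e-6`, `K_gl = 50e-6` pmol/s (derived
#' `K_ATP = (17/3) K_o + 2 K_gl`); proliferating-cell ATP multiplier
#' `lambda = 10`; 24 h cell cycle; maximum mitosis rate `16e-6`
#' mitoses/cell/step (5-day minimum doubling time); glycolysis-fraction
#' window `[0.1, 0.2]`; vasculature regression/expansion rates for a 5-day
#' minimum halftime and 1-day minimum doubling time; hypoxia and
#' hypoglycemia thresholds at 30% and 50% of the normal-tissue levels
#' `o0_bar = 1.2e3`, `gl0_bar = 40e3` pmol; supply caps `2.8e3` and `560`
#' pmol/s; oxygen and glucose diffusion coefficients `1.8e-5` and `1.05e-5`
#' cm^2/s; cell invasion applied every `kappa = 30` steps; chemical-matrix
#' columns perturbed every 6 steps with log-scale magnitude 0.1.
#'
#' @param n,delta_s,delta_tau Lattice side (voxels), voxel edge (mm), time
#'   step (s).
#' @param M,M_max Average and maximum voxel cell capacity (cells).
#' @param K_o,K_gl Normal-cell oxygen/glucose consumption (pmol/s).
#' @param lambda ATP multiplier of an actively proliferating tumor cell
#'   (`> 1`; quiescent cells use 1).
#' @param cc Cell-cycle duration (s).
#' @param a_max Maximum mitosis rate (mitoses/cell/step).
#' @param beta1,beta2 Bounds of the glycolysis fraction, `0 <= beta1 <=
#'   beta2 <= 1`.
#' @param v_r,v_e Maximum per-step vasculature regression/expansion rates.
#' @param h_o,h_gl Hypoxia/hypoglycemia threshold fractions of the
#'   normal-tissue levels.
#' @param o0_bar,gl0_bar Normal-tissue oxygen/glucose quantity per voxel
#'   (pmol).
#' @param o_b_max0,gl_b_max0 Baseline supply-capacity caps (pmol/s).
#' @param D_o,D_gl Oxygen/glucose diffusion coefficients (cm^2/s).
#' @param tensor Cell-diffusion [diffusion_tensor()].
#' @param kappa Cell-invasion sub-stepping period (steps).
#' @param perturb_period,perturb_magnitude Cadence (steps; 0 disables) and
#'   log-scale magnitude of the stochastic column perturbation of the
#'   chemical matrices.
#' @param kernel_n,kernel_seed Monte Carlo sample count and seed for kernel
#'   estimation.
#' @return A validated object of class `model_params`, including the derived
#'   `K_ATP` and the [lattice_spec()] in `$spec`.
#' @export
model_params <- function(n = 21, delta_s = 2, delta_tau = 10,
                         M = 8e6, M_max = 1.02 * M,
                         K_o = 250e-6, K_gl = 50e-6,
                         lambda = 10, cc = 24 * 3600, a_max = 16e-6,
                         beta1 = 0.1, beta2 = 0.2,
                         v_r = rate_from_halftime(5, delta_tau),
                         v_e = rate_from_doubling(1, delta_tau),
                         h_o = 0.30, h_gl = 0.50,
                         o0_bar = 1.2e3, gl0_bar = 40e3,
                         o_b_max0 = 2.8e3, gl_b_max0 = 560,
                         D_o = 1.8e-5, D_gl = 1.05e-5,
                         tensor = synthetic_tensor(),
                         kappa = 30, perturb_period = 6,
                         perturb_magnitude = 0.1,
                         kernel_n = 1e6, kernel_seed = 20260101) {
  spec <- lattice_spec(n, delta_s, delta_tau)
  stopifnot(M > 0, M_max >= M,
            K_o >= 0, K_gl >= 0, cc > 0, a_max >= 0,
            beta1 >= 0, beta2 >= beta1, beta2 <= 1,
            v_r >= 0, v_r <= 1, v_e >= 0,
            h_o > 0, h_o < 1, h_gl > 0, h_gl < 1,
            o0_bar >= 0, gl0_bar >= 0, o_b_max0 >= 0, gl_b_max0 >= 0,
            D_o >= 0, D_gl >= 0,
            inherits(tensor, "diffusion_tensor"),
            kappa >= 1, perturb_period >= 0, perturb_magnitude >= 0)
  if (lambda <= 1) stop("lambda must be > 1 (proliferating cells consume more ATP than quiescent ones)")
  structure(list(
    spec = spec, n = spec$n, delta_s = delta_s, delta_tau = delta_tau,
    M = M, M_max = M_max, K_o = K_o, K_gl = K_gl,
    K_ATP = k_atp(K_o, K_gl),
    lambda = lambda, cc = cc, a_max = a_max,
    beta1 = beta1, beta2 = beta2, v_r = v_r, v_e = v_e,
    h_o = h_o, h_gl = h_gl, o0_bar = o0_bar, gl0_bar = gl0_bar,
    o_b_max0 = o_b_max0, gl_b_max0 = gl_b_max0,
    D_o = D_o, D_gl = D_gl, tensor = tensor,
    kappa = as.integer(kappa), perturb_period = as.integer(perturb_period),
    perturb_magnitude = perturb_magnitude,
    kernel_n = kernel_n, kernel_seed = kernel_seed
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("<model_params> N = %d, ds = %g mm, dt = %g s\n",
                     "  M = %g, M_max = %g, K_o = %g, K_gl = %g, K_ATP = %g\n",
                     "  lambda = %g, cc = %g s, a_max = %g, beta in [%g, %g]\n",
                     "  v_r = %g, v_e = %g, h_o = %g, h_gl = %g, kappa = %d\n"),
              x$n, x$delta_s, x$delta_tau, x$M, x$M_max, x$K_o, x$K_gl,
              x$K_ATP, x$lambda, x$cc, x$a_max, x$beta1, x$beta2,
              x$v_r, x$v_e, x$h_o, x$h_gl, x$kappa))
  invisible(x)
}
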