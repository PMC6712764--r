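# The proliferation/necrosis operator: per-voxel consumption of oxygen and
# glucose by normal and tumor cells, the glycolysis-fraction feasibility
# window, mitosis-rate selection and necrosis bookkeeping.
#
# All functions are vectorized over voxels; an independently coded scalar
# reference lives in the test suite.

#' Per-cell resource needs at a glycolysis fraction
#'
#' A tumor cell meeting a fraction `beta` of its ATP demand by glycolysis and
#' the rest by clean combustion needs `((17 beta + 1)/36) lambda_eff K_ATP`
#' pmol glucose/s and `((1 - beta)/6) lambda_eff K_ATP` pmol oxygen/s, where
#' `lambda_eff` is 1 for a quiescent cell and `lambda` for an actively
#' proliferating one.
#'
#' @param beta Glycolysis fraction(s) in `[0, 1]`.
#' @param lambda_eff ATP multiplier (`>= 1`).
#' @param K_ATP Normal-cell ATP consumption rate (pmol/s), see [k_atp()].
#' @return A list with numeric fields `glucose` and `oxygen` (pmol/s).
#' @examples
#' cell_needs(0, 1, k_atp(250e-6, 50e-6)) # oxygen:glucose = 6:1
#' @export
cell_needs <- function(beta, lambda_eff = 1, K_ATP) {
  stopifnot(all(beta >= 0 & beta <= 1), all(lambda_eff >= 1), K_ATP >= 0)
  list(glucose = ((17 * beta + 1) / 36) * lambda_eff * K_ATP,
       oxygen = ((1 - beta) / 6) * lambda_eff * K_ATP)
}

#' Normal-cell consumption step
#'
#' First stage of the metabolism operator: live normal cells (the implicit
#' population `s(M - l - nc - nn)`) consume oxygen and glucose from the voxel
#' stock plus this interval's vascular supply. If both resources cover the
#' full normal population, the leftovers become available to tumor cells;
#' otherwise the surviving normal count is
#' `N_n = min((o + o_b dt)/(K_o dt), (gl + gl_b dt)/(K_gl dt))`, the
#' remainder becomes necrotic, and the leftovers are recomputed over the
#' survivors.
#'
#' @param l,nc,nn Per-voxel live tumor, necrotic tumor and necrotic normal
#'   cell counts.
#' @param o,gl Per-voxel oxygen/glucose stocks (pmol).
#' @param o_b,gl_b Supply rates for the current interval (pmol/s).
#' @param params A [model_params()].
#' @return A list with fields `O_av`, `Gl_av` (resources available to tumor
#'   cells, both `>= 0`) and `nn_next`.
#' @export
normal_cell_step <- function(l, nc, nn, o, gl, o_b, gl_b, params) {
  dt <- params$delta_tau
  if (any(l < 0) || any(nc < 0) || any(nn < 0) || any(o < 0) || any(gl < 0)) {
    stop("populations and stocks must be nonnegative")
  }
  lnorm <- pmax(params$M - l - nc - nn, 0)
  o_in <- o + o_b * dt
  gl_in <- gl + gl_b * dt
  O1 <- o_in - lnorm * (params$K_o * dt)
  Gl1 <- gl_in - lnorm * (params$K_gl * dt)
  ok <- O1 >= 0 & Gl1 >= 0
  Nn <- pmin(o_in / (params$K_o * dt), gl_in / (params$K_gl * dt))
  Nn <- pmax(Nn, 0) # supply may not exceed absorption; never below zero cells
  O_av <- O1
  Gl_av <- Gl1
  nn_next <- nn
  short <- !ok
  if (any(short)) {
    O_av[short] <- pmax(o_in[short] - Nn[short] * (params$K_o * dt), 0)
    Gl_av[short] <- pmax(gl_in[short] - Nn[short] * (params$K_gl * dt), 0)
    nn_next[short] <- nn[short] + (lnorm[short] - Nn[short])
  }
  list(O_av = O_av, Gl_av = Gl_av, nn_next = nn_next)
}

#' Glycolysis-fraction feasibility window
#'
#' For voxels with live tumor cells, the available oxygen imposes a lower
#' bound `beta_low = 1 - 6 O_av / (l K_ATP dt)` and the available glucose an
#' upper bound `beta_high = (36 Gl_av / (l K_ATP dt) - 1) / 17` on the
#' glycolysis fraction compatible with a nonnegative mitosis rate. The voxel
#' is feasible when the window
#' `[max(beta_low, beta1), min(beta_high, beta2)]` is nonempty (inclusive
#' bounds).
#'
#' @param O_av,Gl_av Resources available to tumor cells (from
#'   [normal_cell_step()]).
#' @param l Live tumor cells (`> 0`).
#' @param params A [model_params()].
#' @return A list with fields `beta_low`, `beta_high` (the raw bounds), `lo`,
#'   `hi` (the bounds intersected with `[beta1, beta2]`) and logical
#'   `feasible`.
#' @export
beta_window <- function(O_av, Gl_av, l, params) {
  if (any(l <= 0)) stop("beta_window requires voxels with live tumor cells (l > 0)")
  dt <- params$delta_tau
  den <- l * params$K_ATP * dt
  beta_low <- 1 - 6 * O_av / den
  beta_high <- (36 * Gl_av / den - 1) / 17
  lo <- pmax(beta_low, params$beta1)
  hi <- pmin(beta_high, params$beta2)
  list(beta_low = beta_low, beta_high = beta_high, lo = lo, hi = hi,
       feasible = lo <= hi)
}

#' Tumor-cell proliferation/necrosis step
#'
#' Second stage of the metabolism operator. Voxels without live tumor cells
#' pass through. In voxels where the glycolysis window is empty
#' (starvation), a fraction `beta_tilde` is drawn uniformly on
#' `[beta1, beta2]`, the surviving count is set by the binding resource and
#' the rest become necrotic. In feasible voxels `beta_tilde` is drawn
#' uniformly on the feasibility window and the mitosis rate is
#' `a = min(a_o(beta_tilde), a_gl(beta_tilde), a_max)`, with the oxygen
#' constraint dropped at `beta_tilde = 1` (pure glycolysis). Stocks are
#' decremented by the quiescent plus proliferative consumption.
#'
#' @param l,nc Live/necrotic tumor cell counts.
#' @param O_av,Gl_av Available resources from [normal_cell_step()].
#' @param params A [model_params()].
#' @param u Uniform(0, 1) draws, one per voxel, mapped affinely onto the
#'   relevant beta interval; pass a fixed vector to make the operator
#'   deterministic. Default: drawn from the current RNG stream.
#' @return A list with fields `l_next`, `nc_next`, `o_next`, `gl_next`,
#'   `beta` (chosen fraction; `NA` where `l = 0`) and `a` (mitosis rate;
#'   `NA` where no proliferation happened).
#' @export
tumor_cell_step <- function(l, nc, O_av, Gl_av, params, u = NULL) {
  nv <- length(l)
  if (is.null(u)) u <- stats::runif(nv)
  stopifnot(length(u) == nv)
  dt <- params$delta_tau
  K <- params$K_ATP
  l_next <- l
  nc_next <- nc
  o_next <- O_av
  gl_next <- Gl_av
  beta <- rep(NA_real_, nv)
  a <- rep(NA_real_, nv)

  has <- which(l > 0)
  if (length(has)) {
    den <- l[has] * K * dt
    bl <- 1 - 6 * O_av[has] / den
    bh <- (36 * Gl_av[has] / den - 1) / 17
    lo <- pmax(bl, params$beta1)
    hi <- pmin(bh, params$beta2)
    feas <- lo <= hi

    starve <- has[!feas]
    if (length(starve)) {
      bt <- params$beta1 + u[starve] * (params$beta2 - params$beta1)
      g_o <- ((1 - bt) / 6) * K * dt
      g_gl <- ((17 * bt + 1) / 36) * K * dt
      Nc <- ifelse(bt != 1,
                   pmin(O_av[starve] / g_o, Gl_av[starve] / g_gl),
                   Gl_av[starve] / g_gl)
      Nc <- pmin(pmax(Nc, 0), l[starve])
      l_next[starve] <- Nc
      nc_next[starve] <- nc[starve] + (l[starve] - Nc)
      o_next[starve] <- ifelse(bt != 1, pmax(O_av[starve] - Nc * g_o, 0),
                               O_av[starve])
      gl_next[starve] <- pmax(Gl_av[starve] - Nc * g_gl, 0)
      beta[starve] <- bt
    }

    grow <- has[feas]
    if (length(grow)) {
      lo_g <- lo[feas]
      hi_g <- hi[feas]
      bt <- lo_g + u[grow] * (hi_g - lo_g)
      g_o <- ((1 - bt) / 6) * K * dt
      g_gl <- ((17 * bt + 1) / 36) * K * dt
      prolif <- (params$lambda - 1) * l[grow] * (params$cc / dt)
      a_o <- ifelse(bt != 1, (O_av[grow] - l[grow] * g_o) / (prolif * g_o), Inf)
      a_gl <- (Gl_av[grow] - l[grow] * g_gl) / (prolif * g_gl)
      ag <- pmax(pmin(pmin(a_o, a_gl), params$a_max), 0)
      l_next[grow] <- l[grow] + ag * l[grow]
      o_next[grow] <- ifelse(bt != 1,
                             pmax(O_av[grow] - l[grow] * g_o -
                                    prolif * ag * g_o, 0),
                             O_av[grow])
      gl_next[grow] <- pmax(Gl_av[grow] - l[grow] * g_gl -
                              prolif * ag * g_gl, 0)
      beta[grow] <- bt
      a[grow] <- ag
    }
  }
  list(l_next = l_next, nc_next = nc_next, o_next = o_next,
       gl_next = gl_next, beta = beta, a = a)
}

#' Metabolism operator
#'
#' Applies [normal_cell_step()] then [tumor_cell_step()] voxelwise, updating
#' `l`, `nc`, `nn`, `o` and `gl`. Supply rates `o_b`, `gl_b` must already
#' hold the values for the current interval (computed by
#' [apply_vascular_remodeling()]).
#'
#' @param state A simulation state, see [init_state()].
#' @param params A [model_params()].
#' @param u Optional fixed Uniform(0, 1) draws (one per voxel) for the
#'   glycolysis-fraction choice; default draws from the current RNG stream.
#' @return The updated state.
#' @export
apply_metabolism <- function(state, params, u = NULL) {
  s1 <- normal_cell_step(state$l, state$nc, state$nn, state$o, state$gl,
                         state$o_b, state$gl_b, params)
  s2 <- tumor_cell_step(state$l, state$nc, s1$O_av, s1$Gl_av, params, u = u)
  state$l <- s2$l_next
  state$nc <- s2$nc_next
  state$nn <- s1$nn_next
  state$o <- s2$o_next
  state$gl <- s2$gl_next
  state
}
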