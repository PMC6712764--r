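# Independent scalar per-voxel re-implementations of the metabolism and
# vascular-remodeling operators, coded directly from the printed algorithm
# (plain loops and scalars, no sharing with the package internals). Used to
# verify the vectorized/compiled operators.

oracle_s <- function(x) if (x >= 0) x else 0

oracle_metabolism_voxel <- function(l, nc, nn, o, gl, ob, glb, u, p) {
  dt <- p$delta_tau
  K <- p$K_ATP
  # Step 1: normal cells consume first
  ln <- oracle_s(p$M - l - nc - nn)
  O1 <- o + ob * dt - ln * (p$K_o * dt)
  G1 <- gl + glb * dt - ln * (p$K_gl * dt)
  if (O1 >= 0 && G1 >= 0) {
    Oav <- O1
    Gav <- G1
    nn2 <- nn
  } else {
    Nn <- min((o + ob * dt) / (p$K_o * dt), (gl + glb * dt) / (p$K_gl * dt))
    Nn <- max(Nn, 0)
    Oav <- max(o + ob * dt - Nn * (p$K_o * dt), 0)
    Gav <- max(gl + glb * dt - Nn * (p$K_gl * dt), 0)
    nn2 <- nn + (ln - Nn)
  }
  # Step 2: tumor cells
  if (l == 0) {
    return(list(l = l, nc = nc, nn = nn2, o = Oav, gl = Gav))
  }
  den <- l * K * dt
  beta_lo <- 1 - 6 * Oav / den
  beta_hi <- (36 * Gav / den - 1) / 17
  lo <- max(beta_lo, p$beta1)
  hi <- min(beta_hi, p$beta2)
  if (lo <= hi) {
    # Case 2.2.2: proliferation at the resource-limited mitosis rate
    bt <- lo + u * (hi - lo)
    g_o <- ((1 - bt) / 6) * K * dt
    g_gl <- ((17 * bt + 1) / 36) * K * dt
    prolif <- (p$lambda - 1) * l * (p$cc / dt)
    a_o <- if (bt != 1) (Oav - l * g_o) / (prolif * g_o) else Inf
    a_gl <- (Gav - l * g_gl) / (prolif * g_gl)
    a <- max(min(min(a_o, a_gl), p$a_max), 0)
    list(l = l + a * l, nc = nc, nn = nn2,
         o = if (bt != 1) max(Oav - l * g_o - prolif * a * g_o, 0) else Oav,
         gl = max(Gav - l * g_gl - prolif * a * g_gl, 0))
  } else {
    # Case 2.2.1: starvation, survivors set by the binding resource
    bt <- p$beta1 + u * (p$beta2 - p$beta1)
    g_o <- ((1 - bt) / 6) * K * dt
    g_gl <- ((17 * bt + 1) / 36) * K * dt
    Nc <- if (bt != 1) min(Oav / g_o, Gav / g_gl) else Gav / g_gl
    Nc <- min(max(Nc, 0), l)
    list(l = Nc, nc = nc + (l - Nc), nn = nn2,
         o = if (bt != 1) max(Oav - Nc * g_o, 0) else Oav,
         gl = max(Gav - Nc * g_gl, 0))
  }
}

oracle_metabolism <- function(state, params, u) {
  out <- state
  for (v in seq_along(state$l)) {
    res <- oracle_metabolism_voxel(state$l[v], state$nc[v], state$nn[v],
                                   state$o[v], state$gl[v], state$o_b[v],
                                   state$gl_b[v], u[v], params)
    out$l[v] <- res$l
    out$nc[v] <- res$nc
    out$nn[v] <- res$nn
    out$o[v] <- res$o
    out$gl[v] <- res$gl
  }
  out
}

oracle_vascular_voxel <- function(l, nc, nn, o, gl, ob, glb, obmax, glbmax,
                                  sw, r1, r2, r3, r4, p) {
  dt <- p$delta_tau
  ob_bar <- ob + r1 * ((p$o0_bar - o) / dt)
  glb_bar <- glb + r2 * ((p$gl0_bar - gl) / dt)
  if (l + nc > 0) {
    fr <- (l + nc) / p$M
    fr <- min(max(fr, 0), 1)
    fe <- (p$M - l - nc - nn) / p$M
    fe <- min(max(fe, 0), 1)
    fac <- 1 - fr * r3 * p$v_r + sw * fe * r4 * p$v_e
    obmax <- max(fac * obmax, 0)
    glbmax <- max(fac * glbmax, 0)
  }
  list(o_b = min(max(ob_bar, -obmax), obmax),
       gl_b = min(max(glb_bar, -glbmax), glbmax),
       o_b_max = obmax, gl_b_max = glbmax)
}

oracle_vascular <- function(state, params, r) {
  out <- state
  for (v in seq_along(state$l)) {
    res <- oracle_vascular_voxel(state$l[v], state$nc[v], state$nn[v],
                                 state$o[v], state$gl[v], state$o_b[v],
                                 state$gl_b[v], state$o_b_max[v],
                                 state$gl_b_max[v], state$sw[v],
                                 r[v, 1], r[v, 2], r[v, 3], r[v, 4], params)
    out$o_b[v] <- res$o_b
    out$gl_b[v] <- res$gl_b
    out$o_b_max[v] <- res$o_b_max
    out$gl_b_max[v] <- res$gl_b_max
  }
  out
}
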