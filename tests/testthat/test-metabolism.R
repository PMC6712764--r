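p <- make_params(n = 5)

test_that("ATP stoichiometry: K_ATP, the 6:1 uptake ratio and the 18x yield gap", {
  expect_equal(k_atp(0, 0), 0)
  expect_equal(k_atp(250e-6, 50e-6), (17 / 3) * 250e-6 + 2 * 50e-6)
  expect_equal(k_atp(250e-6, 50e-6), 1.5167e-3, tolerance = 1e-4)

  K <- k_atp(250e-6, 50e-6)
  # beta = 0: clean combustion only, oxygen:glucose uptake is exactly 6
  q0 <- cell_needs(0, 1, K)
  expect_equal(q0$oxygen / q0$glucose, 6, tolerance = 1e-14)
  # beta = 1: pure glycolysis, no oxygen need
  q1 <- cell_needs(1, 1, K)
  expect_identical(q1$oxygen, 0)
  # ATP yield per glucose: combustion vs glycolysis differ by exactly 18
  yield_combustion <- K / q0$glucose
  yield_glycolysis <- K / q1$glucose
  expect_equal(yield_combustion / yield_glycolysis, 18, tolerance = 1e-14)
  # proliferating cells scale by lambda
  ql <- cell_needs(0.3, 10, K)
  qq <- cell_needs(0.3, 1, K)
  expect_equal(ql$glucose / qq$glucose, 10)
  expect_equal(ql$oxygen / qq$oxygen, 10)
})

test_that("normal-cell step reproduces the balanced-voxel arithmetic", {
  # empty voxel at background stock with balance supply M K_o:
  # O1 = 1200 + 20000 - 20000 = 1200
  res <- normal_cell_step(l = 0, nc = 0, nn = 0, o = 1.2e3, gl = 40e3,
                          o_b = p$M * p$K_o, gl_b = p$M * p$K_gl, p)
  expect_equal(res$O_av, 1.2e3)
  expect_equal(res$Gl_av, 40e3)
  expect_equal(res$nn_next, 0)
})

test_that("zero supply and zero stock kill every live normal cell", {
  res <- normal_cell_step(l = 0, nc = 0, nn = 0, o = 0, gl = 0,
                          o_b = 0, gl_b = 0, p)
  expect_equal(res$nn_next, p$M) # N_n = 0: all of them necrose
  expect_equal(res$O_av, 0)
  expect_equal(res$Gl_av, 0)
})

test_that("the glycolysis window follows its printed bounds and edge cases", {
  dt <- p$delta_tau
  # abundant resources: window is the full [beta1, beta2]
  w <- beta_window(O_av = 1e9, Gl_av = 1e9, l = 1e5, p)
  expect_lte(w$beta_low, 0)
  expect_gte(w$beta_high, 1)
  expect_true(w$feasible)
  expect_equal(w$lo, p$beta1)
  expect_equal(w$hi, p$beta2)

  # no oxygen and beta2 < 1: beta_low = 1 > beta2, infeasible
  w0 <- beta_window(O_av = 0, Gl_av = 1e9, l = 1e5, p)
  expect_identical(w0$beta_low, 1)
  expect_false(w0$feasible)

  # boundary case beta_low == beta2 exactly is feasible (inclusive bounds);
  # synthetic stoichiometry chosen so every intermediate is exact in binary
  pp <- p
  pp$K_ATP <- 6
  pp$delta_tau <- 1
  pp$beta1 <- 0
  pp$beta2 <- 0.25
  wb <- beta_window(O_av = 0.75, Gl_av = 100, l = 1, pp)
  expect_identical(wb$beta_low, pp$beta2) # 1 - 6*0.75/6 is exactly 0.25
  expect_true(wb$feasible)
  expect_identical(wb$lo, wb$hi)

  expect_error(beta_window(1, 1, 0, p), "l > 0")
})

test_that("tumor-free voxels pass through; abundance caps mitosis at a_max", {
  res <- tumor_cell_step(l = 0, nc = 3, O_av = 7, Gl_av = 9, p, u = 0.5)
  expect_identical(res$l_next, 0)
  expect_identical(res$nc_next, 3)
  expect_identical(res$o_next, 7)
  expect_identical(res$gl_next, 9)
  expect_true(is.na(res$beta))

  res2 <- tumor_cell_step(l = 1e5, nc = 0, O_av = 1e12, Gl_av = 1e12, p,
                          u = 0.5)
  expect_equal(res2$a, p$a_max)
  expect_equal(res2$l_next, 1e5 * (1 + p$a_max))
  expect_equal(res2$nc_next, 0)
})

test_that("starvation converts the unsupported fraction to necrotic cells", {
  # no resources at all: every tumor cell necroses
  res <- tumor_cell_step(l = 1e5, nc = 1e3, O_av = 0, Gl_av = 0, p, u = 0.5)
  expect_equal(res$l_next, 0)
  expect_equal(res$nc_next, 1e3 + 1e5)
  # the chosen beta lies in [beta1, beta2]
  expect_gte(res$beta, p$beta1)
  expect_lte(res$beta, p$beta2)
})

test_that("vectorized metabolism equals the scalar per-voxel oracle", {
  st <- random_state(p, seed = 7)
  set.seed(99)
  u <- runif(p$spec$nvox)
  got <- apply_metabolism(st, p, u = u)
  want <- oracle_metabolism(st, p, u)
  for (v in c("l", "nc", "nn", "o", "gl")) {
    expect_equal(got[[v]], want[[v]], tolerance = 1e-12)
  }
  # ledgers: stocks never negative, populations never negative
  expect_true(all(got$o >= 0) && all(got$gl >= 0))
  expect_true(all(got$l >= 0) && all(got$nc >= 0) && all(got$nn >= 0))
  # with the same stubbed draws the operator is deterministic
  again <- apply_metabolism(st, p, u = u)
  expect_identical(again$l, got$l)
})

test_that("resource monotonicity: more oxygen/glucose never shrinks window or mitosis", {
  set.seed(5)
  dt <- p$delta_tau
  for (i in 1:50) {
    l <- runif(1, 1, 2e6)
    O <- runif(1, 0, 2 * l * p$K_ATP * dt)
    G <- runif(1, 0, 2 * l * p$K_ATP * dt)
    w1 <- beta_window(O, G, l, p)
    w2 <- beta_window(O * 1.5, G * 2, l, p)
    width <- function(w) max(w$hi - w$lo, -Inf)
    expect_gte(width(w2), width(w1))
  }
  # with a point window (beta1 = beta2) the chosen rate is monotone in each
  # resource; a_o increases in beta, a_gl decreases in beta
  for (beta in c(0, 0.25, 0.5, 0.9)) {
    pp <- make_params(n = 5, beta1 = beta, beta2 = beta)
    l <- 1e5
    base_o <- l * pp$K_ATP * dt
    grid <- seq(0.5, 3, length.out = 6) * base_o
    a_of_O <- vapply(grid, function(O)
      tumor_cell_step(l, 0, O, 1e12, pp, u = 0)$a, numeric(1))
    expect_false(is.unsorted(a_of_O))
    a_of_G <- vapply(grid, function(G)
      tumor_cell_step(l, 0, 1e12, G, pp, u = 0)$a, numeric(1))
    expect_false(is.unsorted(a_of_G))
  }
  # a_o(beta) increasing, a_gl(beta) decreasing on a beta grid
  l <- 1e5
  O <- 0.9 * l * p$K_ATP * dt / 6
  G <- 0.9 * l * p$K_ATP * dt
  betas <- seq(0.15, 0.95, by = 0.1) # all above beta_low = 0.1 here
  a_o <- vapply(betas, function(b) {
    pp <- make_params(n = 5, beta1 = b, beta2 = b)
    tumor_cell_step(l, 0, O, 1e12, pp, u = 0)$a
  }, numeric(1))
  a_gl <- vapply(betas, function(b) {
    pp <- make_params(n = 5, beta1 = b, beta2 = b)
    tumor_cell_step(l, 0, 1e12, G, pp, u = 0)$a
  }, numeric(1))
  expect_false(is.unsorted(a_o))
  expect_false(is.unsorted(rev(a_gl)))
})

test_that("per-voxel oxygen and glucose ledgers balance across the operator", {
  st <- random_state(p, seed = 11)
  u <- rep(0.3, p$spec$nvox)
  got <- apply_metabolism(st, p, u = u)
  dt <- p$delta_tau
  consumed_o <- st$o + st$o_b * dt - got$o
  consumed_gl <- st$gl + st$gl_b * dt - got$gl
  # wherever the net inflow is physical (stock plus supply nonnegative),
  # cells only ever remove mass; voxels whose vasculature would absorb more
  # than the stock holds are truncated at an empty stock instead
  ok_o <- st$o + st$o_b * dt >= 0
  ok_gl <- st$gl + st$gl_b * dt >= 0
  expect_true(all(consumed_o[ok_o] >= -1e-6))
  expect_true(all(consumed_gl[ok_gl] >= -1e-6))
  expect_true(all(got$o[!ok_o] == 0))
  expect_true(all(got$gl[!ok_gl] == 0))
})

test_that("configuration rejects lambda <= 1", {
  expect_error(model_params(n = 5, lambda = 1), "lambda")
})
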