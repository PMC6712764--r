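p5 <- make_params(n = 5)

empty_seeding <- data.frame(i = integer(), j = integer(), k = integer(),
                            cells = numeric())

test_that("initialization seeds the center and satisfies the state invariants", {
  p21 <- model_params(n = 21, kernel_n = 1e4)
  st <- init_state(p21)
  idx <- linear_index(c(11, 11, 11), 21)
  expect_equal(st$l[idx], 5e5)
  expect_equal(sum(st$l), 5e5) # nonzero only at the center
  expect_true(all(st$o == p21$o0_bar) && all(st$gl == p21$gl0_bar))
  expect_true(all(st$o_b == p21$M * p21$K_o))
  expect_true(all(st$gl_b == p21$M * p21$K_gl))
  expect_true(all(st$nc == 0) && all(st$nn == 0) && all(st$sw == 0))
  expect_silent(validate_state(st, p21))

  expect_error(init_state(p21, data.frame(i = 1, j = 1, k = 1,
                                          cells = 2 * p21$M_max)), "M_max")
})

test_that("a balanced pure-host lattice is a fixed point of full steps", {
  p <- make_params(n = 5, perturb_period = 0)
  ops <- cached_ops_noperturb <- build_operators(p)
  st0 <- init_state(p, seeding = empty_seeding)
  set.seed(1)
  res <- run(p, n_steps = 50, ops = ops, state = st0, record_every = 50,
             engine = "r")
  st <- res$final_state
  for (v in c("l", "nc", "nn", "o_b_max", "gl_b_max", "sw")) {
    expect_identical(st[[v]], st0[[v]])
  }
  expect_equal(st$o, st0$o, tolerance = 1e-12)
  expect_equal(st$gl, st0$gl, tolerance = 1e-12)
  expect_equal(st$o_b, st0$o_b, tolerance = 1e-12)
})

test_that("compiled and pure-R engines produce the same trajectory from one seed", {
  p <- make_params(n = 5, kappa = 7, perturb_period = 3)
  ops <- build_operators(p)
  st <- init_state(p)
  # push the seed voxel into overflow so F_c has work to do
  st$l[linear_index(c(3, 3, 3), 5)] <- p$M_max + 5e5

  run_r <- run(p, n_steps = 25, seed = 77, ops = ops, state = st,
               record_every = 5, engine = "r")
  run_c <- run(p, n_steps = 25, seed = 77, ops = ops, state = st,
               record_every = 5, engine = "compiled")
  for (v in c("l", "nc", "nn", "o", "gl", "o_b", "gl_b", "o_b_max",
              "gl_b_max")) {
    expect_equal(run_c$final_state[[v]], run_r$final_state[[v]],
                 tolerance = 1e-9)
  }
  expect_identical(run_c$final_state$sw, run_r$final_state$sw)
  expect_equal(run_c$summary$live, run_r$summary$live, tolerance = 1e-9)
})

test_that("two runs with the same master seed are bit-identical", {
  p <- make_params(n = 5)
  ops <- build_operators(p)
  r1 <- run(p, n_steps = 30, seed = 5, ops = ops, record_every = 10)
  r2 <- run(p, n_steps = 30, seed = 5, ops = ops, record_every = 10)
  expect_identical(r1$final_state, r2$final_state)
  expect_identical(r1$summary, r2$summary)
})

test_that("cell invasion fires exactly on the kappa cadence", {
  # resources made abundant and a_max = 0 so metabolism never changes l;
  # the only l-changing operator left is F_c on its cadence
  p <- make_params(n = 5, kappa = 5, a_max = 0, perturb_period = 0,
                   o0_bar = 1e9, gl0_bar = 1e9,
                   o_b_max0 = 1e9, gl_b_max0 = 1e9,
                   # isotropic, fast cell tensor: all 26 offsets well sampled
                   tensor = diffusion_tensor(diag(3), rep(2 * 100 * 1.8e-5, 3)))
  ops <- build_operators(p)
  st <- init_state(p, seeding = empty_seeding)
  st$l[linear_index(c(3, 3, 3), 5)] <- p$M_max + 1e6
  seen <- list()
  res <- run(p, n_steps = 12, seed = 2, ops = ops, state = st,
             record_every = 1, engine = "r",
             callback = function(state, row) {
               seen[[length(seen) + 1L]] <<- sum(state$l > 0)
             })
  occupied <- unlist(seen) # number of voxels holding live cells, per step
  expect_equal(occupied[1], 1) # initial record
  # steps 1..4: no invasion yet; step 5: the excess scatters into the 26
  # neighbors; afterwards nothing is overfull, so the occupancy is stable
  expect_true(all(occupied[2:5] == 1))
  expect_true(all(occupied[6:13] == 27))
})

test_that("n_steps = 0 returns only the initial summary", {
  res <- run(p5, n_steps = 0, seed = 1, ops = cached_ops(p5),
             record_every = 10)
  expect_equal(nrow(res$summary), 1L)
  expect_equal(res$summary$step, 0)
  expect_equal(res$summary$live, 5e5)
})

test_that("record cadence and snapshots are honored exactly", {
  p <- make_params(n = 5)
  ops <- cached_ops(p)
  res <- run(p, n_steps = 23, seed = 3, ops = ops, record_every = 10,
             snapshot_every = 20)
  expect_equal(res$summary$step, c(0, 10, 20, 23))
  expect_named(res$snapshots, "20")
  expect_s3_class(res$snapshots[["20"]], "tg_state")
})

test_that("ensembles are reproducible and summarized correctly", {
  p <- make_params(n = 5)
  e1 <- run_ensemble(p, n_steps = 15, n_replicates = 3, base_seed = 100,
                     record_every = 5)
  e2 <- run_ensemble(p, n_steps = 15, n_replicates = 3, base_seed = 100,
                     record_every = 5)
  expect_identical(e1$finals, e2$finals)
  expect_identical(e1$trajectories, e2$trajectories)
  expect_equal(nrow(e1$trajectories), 3 * 4) # 3 replicates x 4 records
  expect_equal(e1$survival, mean(e1$finals > 0))
  if (any(e1$finals > 0)) {
    expect_equal(e1$conditional_mean, mean(e1$finals[e1$finals > 0]))
  }

  # all-extinct ensembles report survival 0 and a missing conditional mean
  e0 <- run_ensemble(make_params(n = 5), n_steps = 5, n_replicates = 2,
                     base_seed = 1, record_every = 5,
                     state = init_state(p5, seeding = empty_seeding))
  expect_equal(e0$survival, 0)
  expect_true(is.na(e0$conditional_mean))
})

test_that("state snapshots round-trip through the plain-text format", {
  st <- random_state(p5, seed = 9)
  st$t <- 120
  st$step_index <- 12L
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_state(st, tmp)
  back <- read_state(tmp)
  for (v in c("l", "nc", "nn", "o", "gl", "o_b", "gl_b", "o_b_max",
              "gl_b_max")) {
    expect_equal(back[[v]], st[[v]])
  }
  expect_identical(back$sw, st$sw)
  expect_equal(back$t, 120)
  expect_identical(back$step_index, 12L)
})

test_that("invariant violations name the offending operator", {
  p <- make_params(n = 5)
  st <- init_state(p)
  st$l[1] <- -5
  expect_error(validate_state(st, p, "F_pn"), "F_pn")
})
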