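spec <- lattice_spec(5, delta_s = 2, delta_tau = 10)

test_that("zero diffusion keeps all mass in the source voxel", {
  k <- sample_isotropic_kernel(0, spec, n_samples = 1e3, seed = 1)
  expect_equal(k$p_self, 1)
  expect_equal(k$p_face + k$p_edge + k$p_vertex + k$escape, 0)
  ka <- analytic_isotropic_kernel(0, spec)
  expect_equal(ka$p_self, 1)
  expect_equal(check_containment(ka), 0)
  expect_error(sample_isotropic_kernel(-1e-6, spec), "nonnegative")
})

test_that("class probabilities and escape partition the samples exactly", {
  for (D in c(1.8e-5, 1.05e-5, 1e-3)) {
    k <- sample_isotropic_kernel(D, spec, n_samples = 5e4, seed = 7)
    expect_equal(k$p_self + 6 * k$p_face + 12 * k$p_edge + 8 * k$p_vertex +
                   k$escape, 1, tolerance = 1e-12)
  }
})

test_that("Monte Carlo kernel matches the quadrature oracle within 3 SE", {
  n <- 2e5
  for (D in c(1.8e-5, 1.05e-5)) {
    k <- sample_isotropic_kernel(D, spec, n_samples = n, seed = 11)
    ka <- analytic_isotropic_kernel(D, spec)
    for (cls in c("p_self", "p_face", "p_edge", "p_vertex")) {
      mult <- c(p_self = 1, p_face = 6, p_edge = 12, p_vertex = 8)[[cls]]
      p_pool <- ka[[cls]] * mult # pooled class mass, the binomial proportion
      se <- sqrt(p_pool * (1 - p_pool) / n) / mult
      expect_lt(abs(k[[cls]] - ka[[cls]]), 3 * se + 1e-12)
    }
  }
})

test_that("oxygen kernel shows the strict self > face > edge > vertex ordering", {
  k <- sample_isotropic_kernel(1.8e-5, spec, n_samples = 2e5, seed = 3)
  expect_gt(k$p_self / k$p_face, 8)   # roughly an order of magnitude apart
  expect_gt(k$p_face / k$p_edge, 8)
  expect_gt(k$p_edge / k$p_vertex, 8)
  expect_lt(check_containment(k), 1e-4)
})

test_that("containment rejects an absurdly fast diffusion", {
  ka <- analytic_isotropic_kernel(1, spec) # 1 cm^2/s at 2 mm / 10 s
  expect_gt(check_containment(ka), 0.5)
  expect_error(renormalize_kernel(ka), "escape mass")
})

test_that("renormalization makes the class masses sum to one exactly", {
  k <- renormalize_kernel(sample_isotropic_kernel(1.8e-5, spec,
                                                  n_samples = 1e5, seed = 5))
  expect_equal(k$p_self + 6 * k$p_face + 12 * k$p_edge + 8 * k$p_vertex, 1,
               tolerance = 1e-15)
  expect_equal(k$escape, 0)
})

test_that("anisotropic kernel with an isotropic tensor reduces to the isotropic kernel", {
  D <- 1.8e-5
  # alpha * lambda = 2 D on all axes (in mm^2/s)
  tensor <- diffusion_tensor(diag(3), rep(2 * 100 * D, 3), alpha = 1)
  n <- 2e5
  kan <- sample_anisotropic_kernel(tensor, spec, n_samples = n, seed = 21)
  ka <- analytic_isotropic_kernel(D, spec)
  for (cls in c("face", "edge", "vertex")) {
    sel <- kan$class == cls
    iso_p <- ka[[paste0("p_", cls)]]
    se <- sqrt(iso_p * (1 - iso_p) / n)
    expect_true(all(abs(kan$p[sel] - iso_p) < 4 * se + 1e-12))
  }
  self_p <- kan$p[kan$class == "self"]
  expect_lt(abs(self_p - ka$p_self), 4 * sqrt(ka$p_self * (1 - ka$p_self) / n))
  expect_equal(sum(kan$p) + kan$escape, 1, tolerance = 1e-12)
})

test_that("a vanishing tensor keeps cells in place", {
  tensor <- diffusion_tensor(diag(3), rep(1, 3), alpha = 1e-300)
  k <- sample_anisotropic_kernel(tensor, spec, n_samples = 1e3, seed = 2)
  expect_equal(k$p[k$class == "self"], 1)
})

test_that("an elongated tensor prefers its principal axis", {
  # strong diffusion along +x only
  tensor <- diffusion_tensor(diag(3), c(2e-2, 2e-6, 2e-6), alpha = 1)
  k <- sample_anisotropic_kernel(tensor, spec, n_samples = 2e5, seed = 9)
  p_of <- function(d) k$p[k$offsets[, 1] == d[1] & k$offsets[, 2] == d[2] &
                            k$offsets[, 3] == d[3]]
  expect_gt(p_of(c(1, 0, 0)), 50 * max(p_of(c(0, 1, 0)), 1e-9))
  expect_gt(p_of(c(-1, 0, 0)), 50 * max(p_of(c(0, 0, 1)), 1e-9))
})

test_that("tensor validation rejects bad frames and eigenvalues", {
  expect_error(diffusion_tensor(matrix(1, 3, 3), rep(1, 3)), "orthonormal")
  expect_error(diffusion_tensor(diag(3), c(1, -1, 1)), "positive")
  expect_error(diffusion_tensor(diag(3), rep(1, 3), alpha = 0), "positive")
})

test_that("kernel cache files round-trip", {
  tmp <- withr::local_tempfile(fileext = ".json")
  k <- sample_isotropic_kernel(1.8e-5, spec, n_samples = 1e4, seed = 13)
  write_kernel(k, tmp)
  k2 <- read_kernel(tmp)
  expect_equal(k2$p_self, k$p_self)
  expect_equal(k2$p_vertex, k$p_vertex)
  expect_s3_class(k2, "isotropic_kernel")
  expect_equal(k2$spec$n, spec$n)

  tmp2 <- withr::local_tempfile(fileext = ".json")
  kan <- sample_anisotropic_kernel(synthetic_tensor(), spec,
                                   n_samples = 1e4, seed = 14)
  write_kernel(kan, tmp2)
  kan2 <- read_kernel(tmp2)
  expect_equal(kan2$p, kan$p)
  expect_equal(kan2$offsets, kan$offsets)
  expect_equal(kan2$tensor$U, kan$tensor$U)
})

test_that("Monte Carlo sampling leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(sample_isotropic_kernel(1.8e-5, spec, n_samples = 1e3, seed = 4))
  expect_identical(runif(1), before)
})
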