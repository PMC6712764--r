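# Per-step voxel-to-neighbor transition kernels estimated from the diffusion
# SDEs. Isotropic kernels (chemicals) pool the symmetric neighbor classes into
# four numbers; anisotropic kernels (tumor cells) keep all 26 offsets.

#' Diffusion tensor
#'
#' A positive-definite diffusion ellipsoid given by an orthonormal eigenvector
#' frame `U`, positive eigenvalues `lambda` and a species-specific positive
#' scale `alpha`. The per-step displacement of a particle is
#' `U diag(sqrt(alpha * lambda)) b` with `b` Gaussian of covariance
#' `delta_tau * I`; a scalar diffusion coefficient `D` corresponds to
#' `alpha * lambda = 2 D` on every axis.
#'
#' @param U 3x3 matrix with orthonormal columns.
#' @param lambda Numeric vector of 3 positive eigenvalues (mm^2/s when
#'   `alpha = 1`).
#' @param alpha Positive scalar rescaling the eigenvalues.
#' @return An object of class `diffusion_tensor`.
#' @seealso [synthetic_tensor()] for the anisotropic frame used in the
#'   shipped simulations.
#' @export
diffusion_tensor <- function(U, lambda, alpha = 1) {
  U <- as.matrix(U)
  stopifnot(identical(dim(U), c(3L, 3L)), length(lambda) == 3L,
            is.numeric(alpha), length(alpha) == 1L)
  if (max(abs(crossprod(U) - diag(3))) > 1e-8) {
    stop("U must have orthonormal columns")
  }
  if (any(lambda <= 0)) stop("eigenvalues must be positive")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(U = U, lambda = as.numeric(lambda), alpha = as.numeric(alpha)),
            class = "diffusion_tensor")
}

#' Synthetic anisotropic cell-diffusion tensor
#'
#' The spatially constant tensor used for tumor-cell motility in the shipped
#' simulations: an orthonormal frame whose first axis is `(1/2, 1/2, sqrt(2)/2)`
#' with a much larger diffusion coefficient than the two transverse axes, so
#' cells spread preferentially along that direction. Coefficients are given in
#' cm^2/s and converted through `alpha * lambda = 2 D` (with `alpha = 1`, in
#' mm^2/s).
#'
#' @param D_major Diffusion coefficient along the principal axis (cm^2/s).
#' @param D_minor Diffusion coefficient along each transverse axis (cm^2/s).
#' @return A [diffusion_tensor()].
#' @export
synthetic_tensor <- function(D_major = 1.5e-6, D_minor = 1.5e-8) {
  stopifnot(D_major > 0, D_minor > 0)
  s2 <- sqrt(2) / 2
  U <- cbind(c(0.5, 0.5, s2), c(-0.5, -0.5, s2), c(s2, -s2, 0))
  # cm^2/s -> mm^2/s is a factor of 100
  diffusion_tensor(U, lambda = 2 * 100 * c(D_major, D_minor, D_minor), alpha = 1)
}

new_isotropic_kernel <- function(p_self, p_face, p_edge, p_vertex, escape,
                                 n_samples, seed, D, spec) {
  structure(list(p_self = p_self, p_face = p_face, p_edge = p_edge,
                 p_vertex = p_vertex, escape = escape,
                 n_samples = n_samples, seed = seed, D = D, spec = spec),
            class = "isotropic_kernel")
}

#' @export
print.isotropic_kernel <- function(x, ...) {
  cat(sprintf(paste0("<isotropic_kernel> D = %g cm^2/s, ds = %g mm, dt = %g s\n",
                     "  p_self = %.6g, p_face = %.6g, p_edge = %.6g, ",
                     "p_vertex = %.6g, escape = %.3g\n"),
              x$D, x$spec$delta_s, x$spec$delta_tau,
              x$p_self, x$p_face, x$p_edge, x$p_vertex, x$escape))
  invisible(x)
}

# Run fn with a private RNG seeded by `seed`, restoring the caller's stream.
with_private_seed <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  fn()
}

#' Monte Carlo isotropic transition kernel
#'
#' Estimates the per-step probabilities that a particle starting uniformly
#' distributed in a voxel ends in the same voxel, a face, edge or vertex
#' neighbor, or escapes beyond the 26-neighborhood, for isotropic diffusion
#' with coefficient `D`. Displacements are zero-mean Gaussian with per-axis
#' variance `2 D delta_tau`. Estimates for the symmetric members of each class
#' are pooled, so the returned `p_face` is the probability of landing in one
#' specific face neighbor (and similarly for `p_edge`, `p_vertex`).
#'
#' @param D Isotropic diffusion coefficient in cm^2/s (`>= 0`).
#' @param spec A [lattice_spec()].
#' @param n_samples Number of Monte Carlo samples.
#' @param seed Seed for the private sampling stream (the caller's RNG state is
#'   left untouched); `NULL` uses the current stream.
#' @return An `isotropic_kernel` with fields `p_self`, `p_face`, `p_edge`,
#'   `p_vertex`, `escape` satisfying
#'   `p_self + 6 p_face + 12 p_edge + 8 p_vertex + escape = 1`.
#' @examples
#' k <- sample_isotropic_kernel(1.8e-5, lattice_spec(5), n_samples = 1e5, seed = 1)
#' k$p_self > k$p_face
#' @export
sample_isotropic_kernel <- function(D, spec, n_samples = 1e6, seed = 20260101) {
  stopifnot(is.numeric(D), length(D) == 1L, n_samples >= 1)
  if (D < 0) stop("diffusion coefficient must be nonnegative")
  ds <- spec$delta_s
  sigma <- sqrt(2 * (100 * D) * spec$delta_tau) # mm; cm^2/s -> mm^2/s
  counts <- with_private_seed(seed, function() {
    n <- as.integer(n_samples)
    # per-axis: start uniform in [0, ds), displaced endpoint binned by floor
    d1 <- abs(floor((stats::runif(n) * ds + stats::rnorm(n, sd = sigma)) / ds))
    d2 <- abs(floor((stats::runif(n) * ds + stats::rnorm(n, sd = sigma)) / ds))
    d3 <- abs(floor((stats::runif(n) * ds + stats::rnorm(n, sd = sigma)) / ds))
    esc <- d1 > 1 | d2 > 1 | d3 > 1
    nz <- d1 + d2 + d3 # number of off-axis moves when not escaped
    c(self = sum(!esc & nz == 0L), face = sum(!esc & nz == 1L),
      edge = sum(!esc & nz == 2L), vertex = sum(!esc & nz == 3L),
      escape = sum(esc))
  })
  p <- counts / n_samples
  new_isotropic_kernel(p_self = unname(p["self"]),
                       p_face = unname(p["face"]) / 6,
                       p_edge = unname(p["edge"]) / 12,
                       p_vertex = unname(p["vertex"]) / 8,
                       escape = unname(p["escape"]),
                       n_samples = as.integer(n_samples), seed = seed,
                       D = D, spec = spec)
}

#' Quadrature isotropic transition kernel
#'
#' Deterministic reference values for [sample_isotropic_kernel()]. For
#' isotropic diffusion the three axes are independent, so each class
#' probability is a product of three 1-D terms
#' `q(d) = E_u[ Phi((d + 1 - u) ds / sigma) - Phi((d - u) ds / sigma) ]`
#' with `u` uniform in the source voxel: `p_self = q(0)^3`,
#' `p_face = q(1) q(0)^2`, `p_edge = q(1)^2 q(0)`, `p_vertex = q(1)^3`.
#' The 1-D integrals are evaluated by adaptive quadrature. Intended as an
#' independent oracle for tests and containment checks.
#'
#' @inheritParams sample_isotropic_kernel
#' @return An `isotropic_kernel` (with `n_samples = 0`).
#' @export
analytic_isotropic_kernel <- function(D, spec) {
  stopifnot(is.numeric(D), length(D) == 1L)
  if (D < 0) stop("diffusion coefficient must be nonnegative")
  ds <- spec$delta_s
  sigma <- sqrt(2 * (100 * D) * spec$delta_tau)
  if (sigma == 0) {
    q0 <- 1; q1 <- 0
  } else {
    qd <- function(d) {
      f <- function(u) {
        stats::pnorm((d + 1 - u) * ds / sigma) - stats::pnorm((d - u) * ds / sigma)
      }
      stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 1e-14)$value
    }
    q0 <- qd(0)
    q1 <- qd(1)
  }
  new_isotropic_kernel(p_self = q0^3, p_face = q1 * q0^2, p_edge = q1^2 * q0,
                       p_vertex = q1^3,
                       escape = max(0, 1 - (q0 + 2 * q1)^3),
                       n_samples = 0L, seed = NA_integer_, D = D, spec = spec)
}

#' Monte Carlo anisotropic transition kernel
#'
#' Estimates the 26 voxel-to-neighbor transition probabilities (plus the self
#' and escape probabilities) for anisotropic diffusion governed by a
#' spatially constant [diffusion_tensor()]: displacements are
#' `U diag(sqrt(alpha * lambda)) b` with `b` Gaussian of covariance
#' `delta_tau * I`. Because the tensor is constant, one shared kernel serves
#' every voxel.
#'
#' @param tensor A [diffusion_tensor()].
#' @inheritParams sample_isotropic_kernel
#' @return An object of class `anisotropic_kernel`: `p` is a numeric vector of
#'   length 27 over the offsets of `offsets` (rows `di, dj, dk` in
#'   `{-1,0,1}^3`), plus `escape`, `n_samples`, `seed`.
#' @export
sample_anisotropic_kernel <- function(tensor, spec, n_samples = 1e6,
                                      seed = 20260102) {
  stopifnot(inherits(tensor, "diffusion_tensor"), n_samples >= 1)
  ds <- spec$delta_s
  A <- tensor$U %*% diag(sqrt(tensor$alpha * tensor$lambda))
  off <- neighbor_offsets(include_self = TRUE)
  counts <- with_private_seed(seed, function() {
    n <- as.integer(n_samples)
    b <- matrix(stats::rnorm(3L * n, sd = sqrt(spec$delta_tau)), nrow = 3L)
    disp <- A %*% b # mm
    start <- matrix(stats::runif(3L * n) * ds, nrow = 3L)
    d <- floor((start + disp) / ds)
    esc <- d[1L, ] < -1 | d[1L, ] > 1 | d[2L, ] < -1 | d[2L, ] > 1 |
      d[3L, ] < -1 | d[3L, ] > 1
    key <- (d[1L, ] + 1) + (d[2L, ] + 1) * 3 + (d[3L, ] + 1) * 9 + 1
    key[esc] <- 0
    tab <- tabulate(key, nbins = 27L)
    list(tab = tab, escape = sum(esc))
  })
  # offsets of neighbor_offsets(include_self = TRUE) follow expand.grid order,
  # which is exactly key = (di+1) + (dj+1)*3 + (dk+1)*9 + 1
  p <- counts$tab / n_samples
  structure(list(p = p, offsets = off$offsets, class = off$class,
                 escape = counts$escape / n_samples,
                 n_samples = as.integer(n_samples), seed = seed,
                 tensor = tensor, spec = spec),
            class = "anisotropic_kernel")
}

#' @export
print.anisotropic_kernel <- function(x, ...) {
  cat(sprintf("<anisotropic_kernel> %d offsets, escape = %.3g, n = %d\n",
              length(x$p), x$escape, x$n_samples))
  invisible(x)
}

#' Containment residual of a kernel
#'
#' Returns the estimated probability mass escaping beyond the 26-neighborhood
#' in one step. The discretization contract requires particles to diffuse at
#' most into the neighbors of their voxel, i.e. an escape mass that is
#' negligible at the chosen `delta_s`, `delta_tau`; the caller compares the
#' returned residual against a tolerance.
#'
#' @param kernel An `isotropic_kernel` or `anisotropic_kernel`.
#' @return The escape probability (numeric scalar).
#' @export
check_containment <- function(kernel) {
  stopifnot(inherits(kernel, c("isotropic_kernel", "anisotropic_kernel")))
  kernel$escape
}

#' Renormalize an isotropic kernel
#'
#' After containment passes, rescales the four class probabilities so that
#' `p_self + 6 p_face + 12 p_edge + 8 p_vertex = 1` exactly, enforcing the
#' containment condition as an equality. This makes spatially uniform fields
#' exact fixed points of the interior diffusion operator and removes
#' escape-mass drift.
#'
#' @param kernel An `isotropic_kernel`.
#' @param tol Maximum escape mass accepted before renormalizing.
#' @return The renormalized `isotropic_kernel` (escape set to 0).
#' @export
renormalize_kernel <- function(kernel, tol = 1e-4) {
  stopifnot(inherits(kernel, "isotropic_kernel"))
  total <- kernel$p_self + 6 * kernel$p_face + 12 * kernel$p_edge +
    8 * kernel$p_vertex
  if (1 - total > tol) {
    stop(sprintf("kernel escape mass %.3g exceeds tolerance %.3g; choose a smaller time step or larger voxels",
                 1 - total, tol))
  }
  kernel$p_self <- kernel$p_self / total
  kernel$p_face <- kernel$p_face / total
  kernel$p_edge <- kernel$p_edge / total
  kernel$p_vertex <- kernel$p_vertex / total
  kernel$escape <- 0
  kernel
}

#' Write or read a kernel cache file
#'
#' Kernels are expensive to resample; `write_kernel()` stores the estimated
#' probabilities with their parameters, seed and sample count as JSON, and
#' `read_kernel()` restores them.
#'
#' @param kernel An `isotropic_kernel` or `anisotropic_kernel`.
#' @param path File path.
#' @return `write_kernel()` the path, invisibly; `read_kernel()` the kernel.
#' @export
write_kernel <- function(kernel, path) {
  obj <- unclass(kernel)
  obj$.class <- class(kernel)
  if (!is.null(obj$tensor)) obj$tensor <- unclass(obj$tensor)
  if (!is.null(obj$spec)) obj$spec <- unclass(obj$spec)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  if (!is.null(obj$spec)) {
    obj$spec <- lattice_spec(obj$spec$n, obj$spec$delta_s, obj$spec$delta_tau)
  }
  if (!is.null(obj$tensor)) {
    obj$tensor <- diffusion_tensor(obj$tensor$U, obj$tensor$lambda,
                                   obj$tensor$alpha)
  }
  if (!is.null(obj$offsets)) {
    storage.mode(obj$offsets) <- "integer"
    colnames(obj$offsets) <- c("di", "dj", "dk")
  }
  structure(obj, class = cls)
}
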