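# Sparse N^3 x N^3 voxel-transition operators. Chemical matrices implement
# fixed (or periodic) Dirichlet boundaries: interior rows gather mass from the
# 26-neighborhood, boundary rows are identity rows. The cell matrix implements
# a reflecting (homogeneous Neumann) boundary: columns scatter overflow mass
# to in-lattice neighbors only, normalized to sum to 1, with a zero diagonal.

new_transition_matrix <- function(T, boundary_mode, species, spec) {
  structure(list(T = T, boundary_mode = boundary_mode, species = species,
                 spec = spec),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %s, %d x %d, %d nonzeros (%s)\n",
              x$boundary_mode, nrow(x$T), ncol(x$T),
              length(x$T@x), x$species))
  invisible(x)
}

# linear-index shift of a coordinate offset
offset_linear <- function(off, n) off[, 1L] + off[, 2L] * n + off[, 3L] * n^2L

#' Chemical diffusion matrix (fixed Dirichlet boundary)
#'
#' Assembles the sparse transition matrix `T` such that `q_{t+dt} = T q_t`
#' propagates a per-voxel chemical quantity one step. Interior rows implement
#' the neighborhood gather
#' `Q'(A) = Pr(A->A) Q(A) + sum_i Pr(B_i->A) Q(B_i)` with the pooled
#' class probabilities of an isotropic kernel (renormalized so interior rows
#' sum to exactly 1); rows of boundary voxels are identity rows, holding the
#' boundary values fixed over time. Each row has at most 27 nonzeros.
#'
#' @param kernel An `isotropic_kernel` (see [sample_isotropic_kernel()]); it
#'   is renormalized via [renormalize_kernel()], which enforces the
#'   containment condition.
#' @param spec The [lattice_spec()] the kernel was estimated for.
#' @param species Free-text tag (e.g. `"oxygen"`).
#' @param containment_tol Maximum escape mass accepted.
#' @return A `transition_matrix` with `boundary_mode = "dirichlet_fixed"`.
#' @export
build_chemical_matrix <- function(kernel, spec, species = "chemical",
                                  containment_tol = 1e-4) {
  stopifnot(inherits(kernel, "isotropic_kernel"))
  if (!identical(unclass(kernel$spec)[c("n", "delta_s", "delta_tau")],
                 unclass(spec)[c("n", "delta_s", "delta_tau")])) {
    stop("kernel was estimated for a different lattice spec")
  }
  kernel <- renormalize_kernel(kernel, tol = containment_tol)
  n <- spec$n
  nvox <- spec$nvox
  off <- neighbor_offsets(include_self = TRUE)
  loff <- offset_linear(off$offsets, n)
  pclass <- c(self = kernel$p_self, face = kernel$p_face,
              edge = kernel$p_edge, vertex = kernel$p_vertex)
  pvals <- unname(pclass[off$class])
  interior <- which(boundary_category_all(spec) == "interior")
  ni <- length(interior)
  rows <- rep(interior, times = length(loff))
  cols <- rows + rep(loff, each = ni)
  vals <- rep(pvals, each = ni)
  bdry <- setdiff(seq_len(nvox), interior)
  T <- Matrix::sparseMatrix(i = c(rows, bdry), j = c(cols, bdry),
                            x = c(vals, rep(1, length(bdry))),
                            dims = c(nvox, nvox))
  new_transition_matrix(T, "dirichlet_fixed", species, spec)
}

#' Periodic Dirichlet operator
#'
#' Wraps a fixed-Dirichlet chemical matrix so that after each multiply the
#' boundary entries are overwritten by a prescribed (typically periodic)
#' function of time, `g(t)`.
#'
#' @param base A `transition_matrix` built by [build_chemical_matrix()].
#' @param g Function of the simulation time (s) returning either a scalar or a
#'   vector of length the number of boundary voxels.
#' @return A `transition_matrix` with `boundary_mode = "dirichlet_periodic"`;
#'   apply it with [apply_transition()].
#' @export
build_periodic_dirichlet <- function(base, g) {
  stopifnot(inherits(base, "transition_matrix"),
            base$boundary_mode == "dirichlet_fixed", is.function(g))
  out <- base
  out$boundary_mode <- "dirichlet_periodic"
  out$g <- g
  out$boundary_idx <- which(boundary_category_all(base$spec) != "interior")
  out
}

#' Apply a transition operator to a field
#'
#' One diffusion step: `q' = T q`, with the boundary handling of the
#' operator's mode (fixed Dirichlet rows are identity rows inside `T`;
#' periodic Dirichlet overwrites the boundary entries with `g(t)` after the
#' multiply).
#'
#' @param tm A `transition_matrix`.
#' @param q Numeric vector of length `n^3` in linear-index order.
#' @param t Simulation time (s), used by periodic boundaries.
#' @return The propagated field.
#' @export
apply_transition <- function(tm, q, t = 0) {
  stopifnot(inherits(tm, "transition_matrix"), length(q) == nrow(tm$T))
  out <- as.numeric(tm$T %*% q)
  if (tm$boundary_mode == "dirichlet_periodic") {
    out[tm$boundary_idx] <- tm$g(t)
  }
  out
}

#' Tumor-cell diffusion matrix (reflecting boundary)
#'
#' Assembles the column-stochastic operator that scatters overflowing live
#' tumor cells to neighboring voxels. For every voxel `A` the probabilities
#' `Pr(A -> B_i)` over its in-lattice neighbors are taken from an anisotropic
#' kernel and normalized to sum to 1; the main diagonal is zero (cells in
#' excess always leave the voxel). Restricting to in-lattice neighbors and
#' renormalizing makes the boundary reflecting: no cell mass ever leaves the
#' lattice.
#'
#' @param kernel An `anisotropic_kernel` ([sample_anisotropic_kernel()]),
#'   shared by all voxels (spatially constant tensor).
#' @param spec The [lattice_spec()].
#' @return A `transition_matrix` with `boundary_mode = "neumann_reflecting"`.
#' @export
build_cell_matrix <- function(kernel, spec) {
  stopifnot(inherits(kernel, "anisotropic_kernel"))
  n <- spec$n
  nvox <- spec$nvox
  keep <- kernel$class != "self"
  offs <- kernel$offsets[keep, , drop = FALSE]
  pv <- kernel$p[keep]
  ijk <- voxel_coords(seq_len(nvox), n)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    if (pv[r] <= 0) next
    d <- offs[r, ]
    ok <- ijk[, 1L] + d[1L] >= 1L & ijk[, 1L] + d[1L] <= n &
      ijk[, 2L] + d[2L] >= 1L & ijk[, 2L] + d[2L] <= n &
      ijk[, 3L] + d[3L] >= 1L & ijk[, 3L] + d[3L] <= n
    src <- which(ok)
    cols <- c(cols, src)
    rows <- c(rows, src + offset_linear(matrix(d, 1L), n))
    vals <- c(vals, rep(pv[r], length(src)))
  }
  T <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(nvox, nvox))
  cs <- Matrix::colSums(T)
  if (any(cs <= 0)) {
    stop("degenerate kernel: some voxel has zero total outflow probability")
  }
  T <- T %*% Matrix::Diagonal(x = 1 / cs)
  new_transition_matrix(methods::as(T, "CsparseMatrix"), "neumann_reflecting",
                        "cells", spec)
}

# Pairwise strict-order preservation: whenever old_i > old_j, new_i > new_j.
# Ties in `old` are unconstrained.
ranks_preserved <- function(old, new) {
  o <- order(old)
  ov <- old[o]; nv <- new[o]
  if (length(ov) < 2L) return(TRUE)
  grp <- cumsum(c(TRUE, diff(ov) > 0))
  gmax <- tapply(nv, grp, max)
  gmin <- tapply(nv, grp, min)
  ng <- length(gmax)
  if (ng < 2L) return(TRUE)
  all(gmax[-ng] < gmin[-1L])
}

#' Stochastic column perturbation
#'
#' Randomly perturbs the columns of a transition matrix flagged by `active`
#' (typically the voxels in or near the tumor), so that each perturbed
#' column's nonzero entries retain their relative orders of magnitude and
#' their sum is preserved. Each nonzero entry of an active column is
#' multiplied by `exp(magnitude * u)` with `u ~ Uniform(-1, 1)` and the column
#' is rescaled to its original sum; a column whose entry order would change is
#' redrawn. This models the largely stochastic, collective effect of the
#' irregular tumor vasculature and local heterogeneity on chemical transport.
#'
#' @param tm A `transition_matrix`.
#' @param active Logical vector of length `n^3`: columns to perturb.
#' @param magnitude Perturbation strength on the log scale (`<= 0.5` keeps
#'   order-of-magnitude-separated entries strictly ordered).
#' @return The perturbed `transition_matrix`. Uses the current RNG stream;
#'   draws occur column-by-column in ascending column order.
#' @export
perturb_columns <- function(tm, active, magnitude) {
  stopifnot(inherits(tm, "transition_matrix"),
            length(active) == ncol(tm$T), magnitude >= 0)
  if (magnitude == 0 || !any(active)) return(tm)
  T <- tm$T
  p <- T@p
  xs <- T@x
  for (j in which(active)) {
    lo <- p[j] + 1L
    hi <- p[j + 1L]
    if (hi < lo) next
    old <- xs[lo:hi]
    s <- sum(old)
    for (try in 1:100) {
      u <- stats::runif(hi - lo + 1L, -1, 1)
      new <- old * exp(magnitude * u)
      new <- new * (s / sum(new))
      if (ranks_preserved(old, new)) break
    }
    xs[lo:hi] <- new
  }
  T@x <- xs
  tm$T <- T
  tm
}

#' Export a transition matrix in MatrixMarket format
#'
#' @param tm A `transition_matrix`.
#' @param path Output file path (`.mtx`).
#' @return The path, invisibly.
#' @export
export_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "transition_matrix"))
  Matrix::writeMM(tm$T, path)
  invisible(path)
}
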