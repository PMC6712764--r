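# Voxel-grid geometry: linear indexing, neighbor enumeration and
# classification, boundary-category detection.

#' Lattice specification
#'
#' Geometry and discretization of the cubic `N x N x N` voxel grid. Each voxel
#' is a cube of edge `delta_s` (mm); the simulation advances in discrete steps
#' of `delta_tau` (s).
#'
#' @param n Integer lattice side, in voxels (`n >= 3`).
#' @param delta_s Voxel edge length in mm (`> 0`).
#' @param delta_tau Time step in seconds (`> 0`).
#'
#' @return An object of class `lattice_spec` with fields `n`, `delta_s`,
#'   `delta_tau` and the derived voxel count `nvox = n^3`.
#' @examples
#' spec <- lattice_spec(21, delta_s = 2, delta_tau = 10)
#' spec$nvox
#' @export
lattice_spec <- function(n, delta_s = 2, delta_tau = 10) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 3L,
            is.numeric(delta_s), delta_s > 0,
            is.numeric(delta_tau), delta_tau > 0)
  structure(
    list(n = n, delta_s = as.numeric(delta_s), delta_tau = as.numeric(delta_tau),
         nvox = n^3L),
    class = "lattice_spec"
  )
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec> %d x %d x %d voxels, edge %g mm, step %g s\n",
              x$n, x$n, x$n, x$delta_s, x$delta_tau))
  invisible(x)
}

#' Linear voxel index
#'
#' Maps 1-based voxel coordinates `(i, j, k)` to the 1-based linear index
#' `i + (j - 1) N + (k - 1) N^2`, a bijection onto `1..N^3`. The inverse is
#' [voxel_coords()].
#'
#' @param ijk Integer vector of length 3, or a matrix with 3 columns (one
#'   voxel per row); each coordinate in `1..n`.
#' @param n Lattice side.
#' @return Integer linear index (or vector of indices), in `1..n^3`.
#' @examples
#' linear_index(c(2, 3, 1), 5) # 12
#' @export
linear_index <- function(ijk, n) {
  if (is.null(dim(ijk))) ijk <- matrix(as.integer(ijk), ncol = 3L)
  storage.mode(ijk) <- "integer"
  if (any(ijk < 1L) || any(ijk > n)) {
    stop("voxel coordinates must lie in 1..n")
  }
  as.integer(ijk[, 1L] + (ijk[, 2L] - 1L) * n + (ijk[, 3L] - 1L) * n^2L)
}

#' Voxel coordinates from linear index
#'
#' Inverse of [linear_index()].
#'
#' @param idx Linear index (or vector), in `1..n^3`.
#' @param n Lattice side.
#' @return Integer matrix with columns `i`, `j`, `k`.
#' @export
voxel_coords <- function(idx, n) {
  idx <- as.integer(idx)
  if (any(idx < 1L) || any(idx > n^3L)) stop("linear index must lie in 1..n^3")
  z <- idx - 1L
  i <- z %% n
  j <- (z %/% n) %% n
  k <- z %/% (n^2L)
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

# 26 neighbor offsets plus the self offset, in a fixed order; class by the
# number of nonzero components: 0 self, 1 face, 2 edge, 3 vertex.
neighbor_offsets <- function(include_self = FALSE) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  cls <- rowSums(g != 0L)
  if (!include_self) {
    keep <- cls > 0L
    g <- g[keep, , drop = FALSE]
    cls <- cls[keep]
  }
  list(offsets = g, class = c("self", "face", "edge", "vertex")[cls + 1L])
}

#' Neighbors of a voxel
#'
#' Enumerates the in-lattice voxels at Chebyshev distance 1 from `ijk`,
#' classified by whether they share a face, an edge or only a vertex with the
#' center voxel. Interior voxels have 6 + 12 + 8 = 26 neighbors; voxels on the
#' outer faces, edges and vertices of the lattice have 17, 11 and 7.
#' Each class is returned sorted by linear index, so downstream matrix
#' assembly is deterministic.
#'
#' @param ijk Integer vector `(i, j, k)`.
#' @param spec A [lattice_spec()].
#' @return A list with integer-matrix fields `face`, `edge`, `vertex` (3
#'   columns each) and the corresponding linear-index vectors `face_idx`,
#'   `edge_idx`, `vertex_idx`.
#' @examples
#' nb <- neighbors(c(3, 3, 3), lattice_spec(5))
#' nrow(nb$face) + nrow(nb$edge) + nrow(nb$vertex) # 26
#' @export
neighbors <- function(ijk, spec) {
  n <- spec$n
  ijk <- as.integer(ijk)
  if (any(ijk < 1L) || any(ijk > n)) stop("voxel coordinates must lie in 1..n")
  off <- neighbor_offsets()
  nb <- sweep(off$offsets, 2L, ijk, `+`)
  inlat <- rowSums(nb >= 1L & nb <= n) == 3L
  out <- list()
  for (cl in c("face", "edge", "vertex")) {
    sel <- inlat & off$class == cl
    m <- nb[sel, , drop = FALSE]
    idx <- linear_index(m, n)
    o <- order(idx)
    out[[cl]] <- m[o, , drop = FALSE]
    out[[paste0(cl, "_idx")]] <- idx[o]
  }
  out
}

#' Boundary category of a voxel
#'
#' Classifies a voxel as `interior`, `face`, `edge` or `vertex` according to
#' how many of its coordinates lie on the lattice boundary (0, 1, 2 or 3);
#' the categories correspond to neighbor counts 26, 17, 11 and 7.
#'
#' @inheritParams neighbors
#' @return A character scalar.
#' @export
boundary_category <- function(ijk, spec) {
  n <- spec$n
  ijk <- as.integer(ijk)
  if (any(ijk < 1L) || any(ijk > n)) stop("voxel coordinates must lie in 1..n")
  nb <- sum(ijk == 1L | ijk == n)
  c("interior", "face", "edge", "vertex")[nb + 1L]
}

# Boundary categories for every voxel at once; returns a character vector in
# L order. Used by matrix assembly and tests.
boundary_category_all <- function(spec) {
  n <- spec$n
  onb <- function(v) v == 1L | v == n
  ijk <- voxel_coords(seq_len(spec$nvox), n)
  nb <- onb(ijk[, 1L]) + onb(ijk[, 2L]) + onb(ijk[, 3L])
  c("interior", "face", "edge", "vertex")[nb + 1L]
}
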