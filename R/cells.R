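# The tumor-cell invasion operator: overflow-driven diffusion of live tumor
# cells through the reflecting cell-transition matrix.

#' Tumor-cell invasion operator
#'
#' Live tumor cells in excess of the room left by necrotic occupants invade
#' neighboring voxels: with `s1 = max(M_max - nc - nn, 0)` (capacity left
#' over a voxel's necrotic cells) and `s2 = min(l, s1)` (live tumor cells
#' that may remain), the updated live population is
#' `s2 + T_c (l - s2)`. The overflow displaces live normal cells, which are
#' never tracked explicitly (the live-normal count is always derived as
#' `max(M - l - nc - nn, 0)`), and necrotic cells never move. Because `T_c`
#' is column-stochastic with a reflecting boundary, total live tumor mass is
#' conserved and never leaves the lattice; receiving voxels may transiently
#' exceed `M_max`, with the excess resolved at the next application.
#'
#' @param l,nc,nn Per-voxel cell-count vectors (nonnegative).
#' @param Tc The cell `transition_matrix` from [build_cell_matrix()].
#' @param M_max Maximum voxel cell capacity.
#' @param reweight Optional hook: a function `(Tc, l, nc, nn) -> Tc` applied
#'   before the scatter, e.g. to bias invasion toward nutrient-rich voxels
#'   (a rough chemotaxis). Disabled (`NULL`) by default.
#' @return The updated live-tumor vector `l`.
#' @examples
#' # no overflow: the operator is the identity on l
#' @export
apply_cell_diffusion <- function(l, nc, nn, Tc, M_max, reweight = NULL) {
  stopifnot(inherits(Tc, "transition_matrix"),
            Tc$boundary_mode == "neumann_reflecting")
  if (any(l < 0) || any(nc < 0) || any(nn < 0)) {
    stop("cell counts must be nonnegative")
  }
  if (!is.null(reweight)) Tc <- reweight(Tc, l, nc, nn)
  s1 <- pmax(M_max - nc - nn, 0)
  s2 <- pmin(l, s1)
  excess <- l - s2
  if (!any(excess > 0)) return(l)
  as.numeric(s2 + Tc$T %*% excess)
}
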