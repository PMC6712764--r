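# Post-processing: planar sections, the occupancy and field classifications
# used for rendering tumor snapshots, and sweep reporting for ensembles.

#' Occupancy classification of voxels
#'
#' The rendering classes of a tumor snapshot. A voxel is `untouched` until
#' the tumor reaches it (`l + nc = 0`; voxels containing only necrotic host
#' cells are not rendered). Reached voxels are `cyan` while the total
#' population of live tumor, necrotic tumor and necrotic host cells does not
#' exceed 50% of `M`; above that they are `blue`, `gray` or `black` as the
#' total necrotic population (`nc + nn`) is below 65% of `M`, in
#' `[65%, 95%)`, or at/above 95% (left-closed bins).
#'
#' @param l,nc,nn Per-voxel cell counts.
#' @param M Average voxel cell capacity.
#' @return A factor with levels `untouched`, `cyan`, `blue`, `gray`,
#'   `black`.
#' @export
classify_occupancy <- function(l, nc, nn, M) {
  stopifnot(M > 0)
  reached <- (l + nc) > 0
  total <- l + nc + nn
  necro <- nc + nn
  cls <- rep("untouched", length(l))
  cls[reached & total <= 0.5 * M] <- "cyan"
  heavy <- reached & total > 0.5 * M
  cls[heavy & necro < 0.65 * M] <- "blue"
  cls[heavy & necro >= 0.65 * M & necro < 0.95 * M] <- "gray"
  cls[heavy & necro >= 0.95 * M] <- "black"
  factor(cls, levels = c("untouched", "cyan", "blue", "gray", "black"))
}

#' Shade classification of a chemical or capacity field
#'
#' Bins the ratio of a per-voxel field to its normal-tissue value into
#' left-closed shade classes. The default breaks render chemical fields the
#' way oxygen/glucose levels are shaded (darkest below 15% of normal,
#' lightest at or above normal); `capacity_breaks()` gives the vasculature
#' palette (below 50%, graded up to normal, 100-125%, 125-150%, above).
#'
#' @param x Per-voxel field.
#' @param x_normal Normal-tissue value (`> 0`).
#' @param breaks Increasing ratio cut points; bins are
#'   `[break_i, break_{i+1})` with open ends below/above.
#' @return An ordered factor of length `length(x)`.
#' @export
classify_field <- function(x, x_normal,
                           breaks = c(0.15, 0.3, 0.5, 0.75, 1)) {
  stopifnot(x_normal > 0, !is.unsorted(breaks, strictly = TRUE))
  ratio <- x / x_normal
  idx <- findInterval(ratio, breaks) # left-closed
  labs <- c(sprintf("<%g", breaks[1L]),
            sprintf("[%g,%g)", breaks[-length(breaks)], breaks[-1L]),
            sprintf(">=%g", breaks[length(breaks)]))
  factor(labs[idx + 1L], levels = labs, ordered = TRUE)
}

#' @rdname classify_field
#' @export
capacity_breaks <- function() c(0.5, 0.75, 1, 1.25, 1.5)

#' Extract a planar section of a state vector
#'
#' Returns the `N x N` slice of a per-voxel vector (in linear-index order)
#' at a fixed coordinate plane.
#'
#' @param x Numeric (or factor) vector of length `n^3`.
#' @param spec A [lattice_spec()].
#' @param axis Which coordinate is fixed: `"i"`, `"j"` or `"k"`.
#' @param index Plane index in `1..n` (default: the central plane).
#' @return An `n x n` matrix; for `axis = "k"` rows index `i` and columns
#'   `j`, and cyclically for the other axes.
#' @export
extract_section <- function(x, spec, axis = c("k", "i", "j"),
                            index = ceiling(spec$n / 2)) {
  axis <- match.arg(axis)
  n <- spec$n
  if (index < 1 || index > n) stop("plane index out of range")
  if (is.factor(x)) x <- as.character(x)
  a <- array(x, dim = c(n, n, n)) # linear-index order: i fastest, then j, k
  switch(axis,
         i = a[index, , ],
         j = a[, index, ],
         k = a[, , index])
}

#' Summarize an ensemble sweep
#'
#' Collects ensembles run over a parameter grid into the standard sweep
#' report: one row per grid cell with the survival probability, the
#' expected final live population conditioned on survival, and the sorted
#' (descending) final populations that form each cell's skewed bar.
#'
#' @param ensembles A named list of `tg_ensemble` objects (names label the
#'   grid cells), or a single `tg_ensemble`.
#' @param cells Optional data frame of grid-cell parameter values, one row
#'   per ensemble, bound onto the report.
#' @return An object of class `tg_sweep`: a data frame with columns `cell`,
#'   any `cells` columns, `n_replicates`, `survival`, `conditional_mean`,
#'   and the list column `finals_sorted`.
#' @export
sweep_report <- function(ensembles, cells = NULL) {
  if (inherits(ensembles, "tg_ensemble")) ensembles <- list(ensembles)
  stopifnot(all(vapply(ensembles, inherits, logical(1), "tg_ensemble")))
  nm <- names(ensembles)
  if (is.null(nm)) nm <- as.character(seq_along(ensembles))
  out <- data.frame(cell = nm,
                    n_replicates = vapply(ensembles, function(e)
                      e$n_replicates, numeric(1)),
                    survival = vapply(ensembles, function(e) e$survival,
                                      numeric(1)),
                    conditional_mean = vapply(ensembles, function(e)
                      e$conditional_mean, numeric(1)))
  if (!is.null(cells)) {
    stopifnot(nrow(cells) == length(ensembles))
    out <- cbind(out[, "cell", drop = FALSE], cells,
                 out[, setdiff(names(out), "cell")])
  }
  out$finals_sorted <- lapply(ensembles, function(e)
    sort(e$finals, decreasing = TRUE))
  class(out) <- c("tg_sweep", "data.frame")
  out
}

#' Plot a classified planar section
#'
#' Renders a section (see [extract_section()]) of the occupancy or shade
#' classification as a tile map.
#'
#' @param section A matrix of class labels (factor or character), e.g.
#'   `extract_section(classify_occupancy(...), spec)`.
#' @param palette Named vector mapping class labels to colors; defaults to
#'   the occupancy palette.
#' @return A `ggplot` object.
#' @export
plot_section <- function(section,
                         palette = c(untouched = "white", cyan = "cyan3",
                                     blue = "blue3", gray = "gray60",
                                     black = "black")) {
  df <- data.frame(
    row = as.vector(row(section)),
    col = as.vector(col(section)),
    class = as.vector(as.character(section))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$col,
                                   fill = .data$class)) +
    ggplot2::geom_tile(color = "gray85", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = palette, drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ensemble live-cell trajectories
#'
#' Per-replicate live tumor-cell counts over time, with the across-replicate
#' expectation overlaid; pass several ensembles to overlay conditions (the
#' way non-monotone sweep cells are compared pairwise).
#'
#' @param ... One or more `tg_ensemble` objects; name the arguments to label
#'   the conditions.
#' @return A `ggplot` object.
#' @export
plot_trajectories <- function(...) {
  ens <- list(...)
  nm <- names(ens)
  if (is.null(nm)) nm <- as.character(seq_along(ens))
  nm[nm == ""] <- as.character(which(nm == ""))
  df <- do.call(rbind, lapply(seq_along(ens), function(i)
    cbind(condition = nm[i], ens[[i]]$trajectories)))
  mean_df <- stats::aggregate(live ~ condition + t_days, data = df, FUN = mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_days, y = .data$live,
                                   color = .data$condition)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$condition,
                                                        .data$replicate)),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_df, linewidth = 1) +
    ggplot2::labs(x = "time (days)", y = "live tumor cells",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sweep report
#'
#' The "skewed bar" rendering: for each sweep cell the sorted final live
#' populations of its replicates are drawn as horizontal lines, longest at
#' the top.
#'
#' @param sweep A `tg_sweep` from [sweep_report()].
#' @return A `ggplot` object.
#' @export
plot_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "tg_sweep"))
  df <- do.call(rbind, lapply(seq_len(nrow(sweep)), function(r) {
    fin <- sweep$finals_sorted[[r]]
    data.frame(cell = sweep$cell[r], rank = seq_along(fin), final = fin)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$final, y = -.data$rank)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$final,
                                       yend = -.data$rank),
                          linewidth = 0.8) +
    ggplot2::facet_wrap(~cell) +
    ggplot2::labs(x = "live cancer cells at horizon", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Tidiers for simulation results
#'
#' `tidy()` on a `tg_run` returns the per-record summary table; on a
#' `tg_ensemble` the long per-replicate trajectory table. `glance()` on a
#' `tg_ensemble` returns its one-row summary (survival probability,
#' conditional mean, replicate count).
#'
#' @param x A `tg_run` or `tg_ensemble`.
#' @param ... Unused.
#' @return A data frame.
#' @export
tidy.tg_run <- function(x, ...) x$summary

#' @rdname tidy.tg_run
#' @export
tidy.tg_ensemble <- function(x, ...) x$trajectories

#' @rdname tidy.tg_run
#' @export
glance.tg_ensemble <- function(x, ...) {
  data.frame(n_replicates = x$n_replicates, n_steps = x$n_steps,
             survival = x$survival, conditional_mean = x$conditional_mean)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 .data
NULL
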