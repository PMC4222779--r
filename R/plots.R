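# Base-graphics visualizations mirroring the standard figures of a landmark
# error study: per-landmark error boxplots with the 0.1 mm working
# reference, the regression-score vs centroid-size scatter, and the
# per-landmark ontogenetic vector plot.

#' Boxplots of landmark placement error
#'
#' One box per (landmark label, group) of the error values, with a dotted
#' horizontal reference line (0.1 mm by default) for intraobserver
#' distances.
#'
#' @param table An intra- or inter-observer error table.
#' @param group Column to facet colours by (`"observer"` or `"age"`).
#' @param value Value column; auto-detected (`distance` or `cs`).
#' @param reference Reference line (mm); `NULL` to omit.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the boxplot statistics.
#' @export
plot_error_boxplots <- function(table, group = "observer", value = NULL,
                                reference = 0.1, ...) {
  if (is.null(value))
    value <- intersect(c("distance", "cs"), names(table))[1]
  sch <- builtin_scheme()
  labs <- unique(landmark_label(sch$id, sch))
  table$label <- factor(table$label, levels = labs)
  grp <- factor(table[[group]])
  cols <- grDevices::hcl.colors(nlevels(grp), "Dark 3")
  b <- graphics::boxplot(table[[value]] ~ grp + table$label,
                         col = cols, las = 2, xlab = "landmark",
                         ylab = paste0(value, " (mm)"), ...)
  if (!is.null(reference))
    graphics::abline(h = reference, lty = 3)
  graphics::legend("topleft", legend = levels(grp), fill = cols, bty = "n")
  invisible(b)
}

#' Regression score versus centroid size
#'
#' The standard visualization of the strength and linearity of an
#' allometric regression: per-specimen regression scores against centroid
#' size, with the least-squares line.
#'
#' @param fit An `allometry_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_regression_scores <- function(fit, ...) {
  cs <- fit$centroid_sizes
  graphics::plot(cs, fit$regression_scores, xlab = "centroid size (mm)",
                 ylab = "regression score", pch = 19, ...)
  graphics::abline(stats::lm(fit$regression_scores ~ cs), lty = 2)
  invisible(fit)
}

#' Ontogenetic vectors of landmark displacement
#'
#' Arrows from each landmark's mean Procrustes position to its position
#' displaced along the fitted allometric slope, projected onto a coordinate
#' plane.  Multiple subsets from a [subset_experiment()] can be overlaid to
#' compare trajectories.
#'
#' @param comparison A `subset_comparison`, or a single vectors data frame
#'   from [ontogenetic_vectors()].
#' @param plane Two axis names from `c("x", "y", "z")` to project onto.
#' @param subsets Which subsets to draw (default all in the comparison).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_ontogenetic_vectors <- function(comparison, plane = c("x", "z"),
                                     subsets = NULL, ...) {
  vecs <- if (inherits(comparison, "subset_comparison")) {
    if (is.null(subsets)) subsets <- names(comparison$vectors)
    comparison$vectors[subsets]
  } else list(fit = comparison)
  ax <- match(plane, c("x", "y", "z"))
  stopifnot(length(ax) == 2, !anyNA(ax))
  all_pts <- do.call(rbind, lapply(vecs, function(v)
    rbind(as.matrix(v[paste0(c("x", "y", "z")[ax], "0")]),
          stats::setNames(as.matrix(v[paste0(c("x", "y", "z")[ax], "1")]),
                          NULL))))
  graphics::plot(range(all_pts[, 1]), range(all_pts[, 2]), type = "n",
                 xlab = plane[1], ylab = plane[2], asp = 1, ...)
  cols <- grDevices::hcl.colors(length(vecs), "Dark 3")
  for (i in seq_along(vecs)) {
    v <- vecs[[i]]
    graphics::arrows(v[[paste0(plane[1], "0")]], v[[paste0(plane[2], "0")]],
                     v[[paste0(plane[1], "1")]], v[[paste0(plane[2], "1")]],
                     length = 0.05, col = cols[i])
  }
  graphics::legend("topright", legend = names(vecs), col = cols, lty = 1,
                   bty = "n")
  invisible(comparison)
}
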