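# Ontogenetic allometry: multivariate regression of Procrustes coordinates
# on centroid size, summary regression scores, percent variance explained,
# per-landmark ontogenetic vectors, and the landmark-subset-removal
# robustness experiment.

#' Regress Procrustes shape on centroid size
#'
#' Fits, by least squares, each Procrustes coordinate against raw centroid
#' size (mm): `y_cj = a_cj + b_cj * CS`.  Reports the slope/intercept per
#' (landmark, axis), the percent of total Procrustes-coordinate variation
#' accounted for by the regression
#' (100 * SS_predicted / SS_total, the multivariate analogue of R-squared),
#' and per-specimen regression scores — the projection of each centered
#' shape vector onto the unit-normalized slope vector, the standard
#' univariate summary of allometric shape.
#'
#' @param fit A `procrustes_fit` from [gpa()] (or a compatible list with
#'   `aligned` shapes and `centroid_sizes`).
#' @return Object of class `allometry_fit`: list with `slopes` and
#'   `intercepts` (k x 3 matrices), `mean_shape`, `regression_scores`,
#'   `pct_variance`, `centroid_sizes`, and `n`.
#' @export
regress_shape_on_size <- function(fit) {
  shapes <- fit$aligned
  cs <- fit$centroid_sizes
  n <- length(shapes)
  if (n < 3) stop("need at least 3 specimens")
  if (max(cs) - min(cs) <= 0)
    stop("centroid size is constant; the regression is undefined")
  k <- nrow(shapes[[1]])
  y <- t(vapply(shapes, as.vector, numeric(3 * k)))   # n x 3k
  ybar <- colMeans(y)
  xc <- cs - mean(cs)
  sxx <- sum(xc^2)
  slopes_v <- colSums((y - rep(ybar, each = n)) * xc) / sxx
  intercepts_v <- ybar - slopes_v * mean(cs)
  pred <- outer(xc, slopes_v)                          # centered predictions
  resid <- sweep(y, 2, ybar) - pred
  ss_pred <- sum(pred^2)
  ss_tot <- sum(sweep(y, 2, ybar)^2)
  bnorm <- sqrt(sum(slopes_v^2))
  if (bnorm == 0) stop("zero coefficient vector; scores undefined")
  scores <- as.vector(sweep(y, 2, ybar) %*% (slopes_v / bnorm))
  names(scores) <- names(shapes)
  dn <- dimnames(shapes[[1]])
  structure(list(slopes = matrix(slopes_v, k, 3, dimnames = dn),
                 intercepts = matrix(intercepts_v, k, 3, dimnames = dn),
                 mean_shape = matrix(ybar, k, 3, dimnames = dn),
                 regression_scores = scores,
                 pct_variance = 100 * ss_pred / ss_tot,
                 centroid_sizes = cs, n = n),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("Shape-on-size regression:", x$n, "specimens,",
      nrow(x$slopes), "landmarks; variance explained",
      sprintf("%.1f%%", x$pct_variance), "\n")
  invisible(x)
}

#' Regression score of a shape under a fitted allometry
#'
#' score = (shape - mean_shape) . beta / ||beta|| where beta is the fitted
#' slope vector.  Zero at the mean shape; adding any shape vector
#' orthogonal to beta leaves the score unchanged.
#'
#' @param fit An `allometry_fit`.
#' @param shape k x 3 matrix in the fit's aligned frame.
#' @return Scalar score (dimensionless).
#' @export
regression_score <- function(fit, shape) {
  b <- as.vector(fit$slopes)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) stop("zero coefficient vector; score undefined")
  sum((as.vector(as.matrix(shape)) - as.vector(fit$mean_shape)) * b) / bnorm
}

#' Per-landmark ontogenetic displacement vectors
#'
#' For each landmark, the vector from its mean Procrustes position to that
#' position displaced by the fitted slope times a centroid-size increment:
#' end = start + slope * delta_cs, per axis.  These are the arrows of the
#' classic allometric-trajectory plot.
#'
#' @param fit An `allometry_fit`.
#' @param delta_cs Centroid-size increment (mm); default 1.
#' @return Data frame with `landmark`, start coordinates `x0, y0, z0`, and
#'   end coordinates `x1, y1, z1`.
#' @export
ontogenetic_vectors <- function(fit, delta_cs = 1) {
  s <- fit$mean_shape
  e <- s + fit$slopes * delta_cs
  data.frame(landmark = rownames(s),
             x0 = s[, 1], y0 = s[, 2], z0 = s[, 3],
             x1 = e[, 1], y1 = e[, 2], z1 = e[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Internal: remove from a k x 3 displacement field its components along the
# similarity transformations (3 translations, 3 infinitesimal rotations,
# uniform scaling) of the configuration `shape`.
project_out_similarity <- function(field, shape) {
  k <- nrow(shape)
  s <- center_shape(shape)
  zero <- rep(0, k); one <- rep(1, k)
  gens <- cbind(as.vector(cbind(one, zero, zero)),
                as.vector(cbind(zero, one, zero)),
                as.vector(cbind(zero, zero, one)),
                as.vector(s),
                as.vector(cbind(-s[, 2], s[, 1], zero)),
                as.vector(cbind(-s[, 3], zero, s[, 1])),
                as.vector(cbind(zero, -s[, 3], s[, 2])))
  q <- qr.Q(qr(gens))
  fv <- as.vector(field)
  matrix(fv - q %*% crossprod(q, fv), k, 3, dimnames = dimnames(field))
}

# Internal: named default subset removals keyed on the scheme's columns.
default_subsets <- function(scheme) {
  list(all = integer(0),
       minus_trouble = scheme$id[scheme$trouble],
       minus_nasal = scheme$id[scheme$subset == "Nasal"],
       minus_maxmand = scheme$id[scheme$subset == "MaxMand"],
       minus_nonfacial = scheme$id[scheme$subset == "NonFacial"])
}

#' Landmark-subset-removal allometry experiment
#'
#' Repeats the shape-on-size regression after removing named groups of
#' landmarks (by default: none, the trouble column, and each anatomical
#' subset) and quantifies how stable the ontogenetic signal is.  For each
#' subset the percent variance explained comes from a fresh GPA + regression
#' on the remaining landmarks.  Ontogenetic-vector *plots* use the
#' three-anchor baseline registration ([baseline_superimpose()]), giving
#' parallel axes across the subsets that retain the anchors; a subset from
#' which an anchor was removed falls back to its GPA frame rotated onto the
#' all-landmark fit (or errors if `require_anchors = TRUE`).  Vector
#' *angles* (degrees, in [0, 180]) are computed registration-consistently:
#' every subset's GPA slope field is rotated onto the all-landmark GPA
#' frame over the common landmarks before comparing, since mixing
#' registrations (anchors pinned vs least-squares) would confound frame
#' choice with real trajectory differences.  The angle metric is this
#' package's operationalization of "does the allometric pattern change";
#' small angles mean the trajectory is robust to landmark choice.
#'
#' @param dataset A `trial_dataset`.
#' @param observers Observers whose mean configurations enter the
#'   regression (default: all; the study convention is the experienced
#'   subset).
#' @param subsets Named list of landmark-id vectors to *remove*; default
#'   [default_subsets()] of the dataset's scheme.  An `all` entry
#'   (empty removal) is added if absent, as the reference.
#' @param anchor_ids Three landmark ids defining the shared baseline frame;
#'   default `c(1, 22, 8)` (two midline points plus a left non-facial,
#'   non-trouble point, present in all subsets except the non-facial
#'   removal).
#' @param delta_cs Centroid-size increment for the vectors (mm).
#' @param min_rel_mag Angles are only reported for landmarks whose
#'   projected reference displacement is at least this fraction of the
#'   root-mean-square displacement (default 0.25): the direction of a
#'   near-stationary landmark is unidentifiable and its angle is noise.
#' @param require_anchors Error (rather than fall back to GPA alignment)
#'   when a subset removes an anchor.
#' @return Object of class `subset_comparison`: list with `fits`
#'   (per-subset `allometry_fit` from GPA), `pct_variance` (named vector),
#'   `vectors` (per-subset plotting vectors, baseline frame where
#'   available), `vectors_gpa` (per-subset vectors in the common
#'   all-landmark GPA frame, used for the angles), `angles` (data frame
#'   `subset, landmark, angle_deg`), `anchor_ids`, and `route` (per
#'   subset, `"baseline"` or `"gpa-aligned"`).
#' @export
subset_experiment <- function(dataset, observers = NULL, subsets = NULL,
                              anchor_ids = c(1, 22, 8), delta_cs = 1,
                              min_rel_mag = 0.25, require_anchors = FALSE) {
  scheme <- dataset$scheme
  if (is.null(subsets)) subsets <- default_subsets(scheme)
  if (!"all" %in% names(subsets))
    subsets <- c(list(all = integer(0)), subsets)
  sm <- specimen_mean_shapes(dataset, observers)
  shapes_full <- sm$shapes

  keep_rows <- function(s, drop_ids)
    s[!(rownames(s) %in% as.character(drop_ids)), , drop = FALSE]

  fits <- list(); vectors <- list(); vectors_gpa <- list()
  route <- character(0); pct <- numeric(0)

  # all-landmark GPA fit: the reference frame for the angle comparison
  ref_gpa <- gpa(shapes_full)
  ref_fit <- regress_shape_on_size(ref_gpa)

  for (nm in names(subsets)) {
    drop_ids <- subsets[[nm]]
    sub_shapes <- lapply(shapes_full, keep_rows, drop_ids = drop_ids)
    if (nrow(sub_shapes[[1]]) < 4)
      stop("subset ", nm, " leaves fewer than 4 landmarks")

    g <- gpa(sub_shapes)
    fit_g <- regress_shape_on_size(g)
    fits[[nm]] <- fit_g
    pct[nm] <- fit_g$pct_variance

    # angle comparison: rotate the subset's GPA frame onto the all-landmark
    # GPA frame over the common landmarks, so every subset's slope field is
    # expressed with registration consistent with the reference
    common <- rownames(sub_shapes[[1]])
    op <- ordinary_procrustes(g$consensus[common, , drop = FALSE],
                              ref_fit$mean_shape[common, , drop = FALSE])
    fit_r <- fit_g
    fit_r$slopes <- op$scale * fit_g$slopes %*% op$rotation
    fit_r$mean_shape <- fit_g$mean_shape %*% (op$scale * op$rotation)
    fit_r$mean_shape <- sweep(fit_r$mean_shape, 2, op$translation, `+`)
    dimnames(fit_r$slopes) <- dimnames(fit_g$slopes)
    dimnames(fit_r$mean_shape) <- dimnames(fit_g$mean_shape)
    vectors_gpa[[nm]] <- ontogenetic_vectors(fit_r, delta_cs)

    # plotting vectors: the shared-anchor baseline frame gives parallel
    # axes across the subsets that retain the anchors
    has_anchors <- all(as.character(anchor_ids) %in% rownames(sub_shapes[[1]]))
    if (has_anchors) {
      aligned <- baseline_superimpose(sub_shapes, anchor_ids)
      fit_b <- regress_shape_on_size(
        list(aligned = aligned,
             centroid_sizes = vapply(sub_shapes, centroid_size, numeric(1))))
      vectors[[nm]] <- ontogenetic_vectors(fit_b, delta_cs)
      route[nm] <- "baseline"
    } else {
      if (require_anchors)
        stop("subset ", nm, " removes anchor landmark(s): ",
             paste(intersect(as.character(anchor_ids),
                             as.character(drop_ids)), collapse = ", "))
      vectors[[nm]] <- vectors_gpa[[nm]]
      route[nm] <- "gpa-aligned"
    }
  }

  # A subset's Procrustes slope field cannot contain the component of the
  # trajectory that acts as a pure translation/rotation/scaling of that
  # subset (superimposition absorbs it), while the restricted all-landmark
  # field still does.  Before measuring angles, both fields are therefore
  # projected onto the subset's shape space (the orthogonal complement of
  # the similarity transformations of the reference mean restricted to the
  # common landmarks); the residual angles reflect genuine trajectory
  # differences.
  ref_vec <- vectors_gpa[["all"]]
  angles <- do.call(rbind, lapply(names(vectors_gpa), function(nm) {
    v <- vectors_gpa[[nm]]
    common <- intersect(v$landmark, ref_vec$landmark)
    a <- v[match(common, v$landmark), ]
    r <- ref_vec[match(common, ref_vec$landmark), ]
    da <- cbind(a$x1 - a$x0, a$y1 - a$y0, a$z1 - a$z0)
    dr <- cbind(r$x1 - r$x0, r$y1 - r$y0, r$z1 - r$z0)
    m <- ref_fit$mean_shape[common, , drop = FALSE]
    da <- project_out_similarity(da, m)
    dr <- project_out_similarity(dr, m)
    la <- sqrt(rowSums(da^2)); lr <- sqrt(rowSums(dr^2))
    ok <- la > 1e-12 & lr >= min_rel_mag * sqrt(mean(lr^2))
    cosang <- rowSums(da * dr)[ok] / (la[ok] * lr[ok])
    data.frame(subset = nm, landmark = common[ok],
               angle_deg = acos(pmin(1, pmax(-1, cosang))) * 180 / pi,
               stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, pct_variance = pct, vectors = vectors,
                 vectors_gpa = vectors_gpa, angles = angles,
                 anchor_ids = anchor_ids, route = route),
            class = "subset_comparison")
}

#' @export
print.subset_comparison <- function(x, ...) {
  cat("Subset-removal allometry experiment\n")
  for (nm in names(x$pct_variance)) {
    ang <- x$angles$angle_deg[x$angles$subset == nm]
    cat(sprintf("  %-16s %5.1f%% variance explained; max vector angle %5.1f deg (%s)\n",
                nm, x$pct_variance[nm],
                if (length(ang)) max(ang) else NA_real_, x$route[nm]))
  }
  invisible(x)
}
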